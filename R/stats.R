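# Nonparametric analysis of the replicated slope measurements: Shapiro-Wilk
# normality screening (reported, never gating) and Kruskal-Wallis rank tests
# across both margins of the trial table.

#' Mid-ranks with ties
#'
#' Standard mid-rank assignment (ties share the average of the ranks they
#' span); the rank sum is always n(n+1)/2.
#'
#' @param values numeric vector, non-empty.
#' @return numeric vector of ranks.
#' @export
ranks_with_ties <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0)
  rank(values, ties.method = "average")
}

# Tie-corrected H statistic from a pooled sample and group labels.
# H = (12 / (N(N+1))) * sum n_i (Rbar_i - (N+1)/2)^2, divided by
# 1 - sum(t^3 - t) / (N^3 - N). All-tied data give H = 0 by convention.
kw_h_statistic <- function(x, g) {
  n <- length(x)
  r <- ranks_with_ties(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)
  h / corr
}

#' Kruskal-Wallis rank test
#'
#' Tests whether k independent groups come from the same distribution using
#' the tie-corrected H statistic. The default p-value is the chi-square upper
#' tail with k - 1 degrees of freedom (via [stats::kruskal.test()]); for
#' small samples `method = "permutation"` enumerates every assignment of the
#' pooled observations to groups of the observed sizes and returns the exact
#' proportion with H at least as large as observed. Groups whose observations
#' are all identical give H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @param method `"chisq"` (default) or `"permutation"` (exact; total n
#'   limited to 12 to bound the enumeration).
#' @return an object of class `rank_test`: list with `h_statistic`, `df`,
#'   `p_value`, `group_sizes`, `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "permutation")) {
  method <- match.arg(method)
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1) || sum(ns) < 3)
    stop("each group needs >= 1 observation and total n >= 3")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  k <- length(groups)
  if (length(unique(x)) == 1) {
    return(structure(list(h_statistic = 0, df = k - 1L, p_value = 1,
                          group_sizes = as.integer(ns), method = method),
                     class = "rank_test"))
  }
  if (method == "chisq") {
    kt <- stats::kruskal.test(x, g)
    res <- list(h_statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  } else {
    if (sum(ns) > 12)
      stop("exact permutation test limited to total n <= 12")
    h_obs <- kw_h_statistic(x, g)
    parts <- group_assignments(seq_along(x), ns)
    hs <- vapply(parts, function(p) {
      gg <- integer(length(x))
      for (i in seq_along(p)) gg[p[[i]]] <- i
      kw_h_statistic(x, gg)
    }, numeric(1))
    res <- list(h_statistic = h_obs, df = k - 1L,
                p_value = mean(hs >= h_obs - 1e-12))
  }
  structure(c(res, list(group_sizes = as.integer(ns), method = method)),
            class = "rank_test")
}

# All ways to assign the index set to labeled groups of the given sizes.
group_assignments <- function(idx, sizes) {
  if (length(sizes) == 1) return(list(list(idx)))
  out <- list()
  for (g1 in utils::combn(idx, sizes[1], simplify = FALSE)) {
    rest <- group_assignments(setdiff(idx, g1), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(list(g1), r)))
  }
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %s (%s, groups n = %s)\n",
              x$h_statistic, x$df, format_p(x$p_value), x$method,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Shapiro-Wilk normality screen of a trial table
#'
#' Runs the Shapiro-Wilk test within every (SPOI, correction) cell; a cell is
#' flagged nonnormal when p < `alpha`. Cells whose replicates are all
#' identical are degenerate (the statistic is undefined): they are flagged
#' and skipped with a warning, as are cells with n outside [3, 50]. The
#' screen justifies the nonparametric analysis; it never gates it.
#'
#' @param trials a `trial_table`.
#' @param alpha flagging level.
#' @return data.frame with one row per cell: `spoi_deg`, `correction_deg`,
#'   `n`, `w_statistic`, `p_value`, `nonnormal`, `degenerate`.
#' @export
normality_screen <- function(trials, alpha = 0.05) {
  stopifnot(inherits(trials, "trial_table"))
  cells <- unique(trials[, c("spoi_deg", "correction_deg")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    v <- trials$slope_deg[trials$spoi_deg == cells$spoi_deg[i] &
                            trials$correction_deg == cells$correction_deg[i]]
    n <- length(v)
    if (n < 3 || n > 50) {
      warning(sprintf("cell (SPOI %g, theta %g): n = %d outside [3, 50], skipped",
                      cells$spoi_deg[i], cells$correction_deg[i], n))
      return(data.frame(n = n, w_statistic = NA_real_, p_value = NA_real_,
                        nonnormal = NA, degenerate = FALSE))
    }
    if (diff(range(v)) == 0) {
      warning(sprintf("cell (SPOI %g, theta %g): constant replicates, skipped",
                      cells$spoi_deg[i], cells$correction_deg[i]))
      return(data.frame(n = n, w_statistic = NA_real_, p_value = NA_real_,
                        nonnormal = TRUE, degenerate = TRUE))
    }
    sw <- stats::shapiro.test(v)
    data.frame(n = n, w_statistic = unname(sw$statistic), p_value = sw$p.value,
               nonnormal = sw$p.value < alpha, degenerate = FALSE)
  })
  cbind(cells, do.call(rbind, res), row.names = NULL)
}

#' Rank-test analysis of the full trial table
#'
#' Reproduces the two test margins of the replicated experiment: within each
#' SPOI, a Kruskal-Wallis test across the correction-angle groups (theta = 0,
#' if present, is excluded: it is the uncut state), and within each
#' correction angle, a Kruskal-Wallis test across the SPOI groups.
#'
#' @param trials a `trial_table` covering a complete (SPOI x correction) grid
#'   with equal replicate counts.
#' @param alpha significance level for the `significant` flags.
#' @return an `analysis_report`: list with data.frames `per_spoi` and
#'   `per_correction` (columns `h_statistic`, `df`, `p_value`, `significant`),
#'   the `normality` screen, and `alpha`.
#' @export
analyze_table <- function(trials, alpha = 0.05) {
  stopifnot(inherits(trials, "trial_table"), alpha > 0, alpha < 1)
  spois <- unique(trials$spoi_deg)
  corrections <- sort(unique(trials$correction_deg))
  counts <- table(trials$spoi_deg, trials$correction_deg)
  if (any(counts == 0) || length(unique(as.vector(counts))) != 1)
    stop("shape error: trial table must cover the full grid with equal n per cell")
  test_groups <- function(split_values, split_col, group_col, group_values) {
    do.call(rbind, lapply(split_values, function(s) {
      sub <- trials[trials[[split_col]] == s, ]
      groups <- lapply(group_values, function(g)
        sub$slope_deg[sub[[group_col]] == g])
      kt <- kruskal_wallis(groups)
      data.frame(value = s, h_statistic = kt$h_statistic, df = kt$df,
                 p_value = kt$p_value, significant = kt$p_value < alpha)
    }))
  }
  theta_groups <- corrections[corrections > 0]
  per_spoi <- test_groups(spois, "spoi_deg", "correction_deg", theta_groups)
  names(per_spoi)[1] <- "spoi_deg"
  per_corr <- test_groups(corrections, "correction_deg", "spoi_deg", spois)
  names(per_corr)[1] <- "correction_deg"
  structure(list(per_spoi = per_spoi, per_correction = per_corr,
                 normality = suppressWarnings(normality_screen(trials, alpha)),
                 alpha = alpha),
            class = "analysis_report")
}

format_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))

#' @export
print.analysis_report <- function(x, ...) {
  cat("Kruskal-Wallis across correction angles, per SPOI:\n")
  df <- x$per_spoi
  df$p_value <- format_p(df$p_value)
  print(df, row.names = FALSE)
  cat("\nKruskal-Wallis across SPOI groups, per correction angle:\n")
  df <- x$per_correction
  df$p_value <- format_p(df$p_value)
  print(df, row.names = FALSE)
  cat(sprintf("\nNonnormal cells (Shapiro-Wilk p < %g): %d of %d\n",
              x$alpha, sum(x$normality$nonnormal, na.rm = TRUE),
              nrow(x$normality)))
  invisible(x)
}

#' Write the replicated-experiment report
#'
#' Renders the summary table with both p-value margins in the usual layout:
#' one row per correction angle with "mean +- SD" per SPOI and the across-SPOI
#' p-value, plus a bottom row of per-SPOI p-values; p-values below 0.001 print
#' as "< 0.001".
#'
#' @param summary a `summary_table` (see [summarize_trials()]).
#' @param report an `analysis_report` (see [analyze_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(summary, report, path) {
  stopifnot(inherits(summary, "summary_table"),
            inherits(report, "analysis_report"))
  spois <- summary$spois
  rows <- lapply(seq_along(summary$corrections), function(i) {
    th <- summary$corrections[i]
    p <- report$per_correction$p_value[report$per_correction$correction_deg == th]
    c(correction_deg = format(th),
      stats::setNames(sprintf("%.1f +- %.1f", summary$mean[i, ], summary$sd[i, ]),
                      paste0("spoi_", format(spois, trim = TRUE))),
      p_value = format_p(p))
  })
  pm <- vapply(spois, function(s)
    format_p(report$per_spoi$p_value[report$per_spoi$spoi_deg == s]),
    character(1))
  rows <- c(rows, list(c(correction_deg = "p_value",
                         stats::setNames(pm, paste0("spoi_", format(spois, trim = TRUE))),
                         p_value = "")))
  df <- as.data.frame(do.call(rbind, rows))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
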