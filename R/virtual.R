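# Deterministic virtual-simulation grid: posterior slope for every
# (correction angle, SPOI) combination, two interchangeable backends.

#' Run the virtual-simulation grid
#'
#' Computes the post-correction posterior slope for every combination of
#' correction angle (rows) and osteotomy inclination (columns), starting from
#' initial slope `alpha0`. Both backends are exact and agree to machine
#' precision: `"closed_form"` evaluates the analytic expression of
#' [closed_form_pts()], `"rodrigues"` runs the 3D rotation pipeline
#' ([opened_slope_direction()] + [sagittal_slope_angle()]).
#'
#' @param alpha0 initial posterior slope, degrees.
#' @param spois osteotomy inclinations (columns), degrees.
#' @param corrections correction angles (rows), degrees.
#' @param digits rounding for the displayed table (half away from zero);
#'   unrounded values are kept alongside.
#' @param backend `"closed_form"` or `"rodrigues"`.
#' @return an object of class `slope_table`: list with `values` (rounded
#'   matrix, rows = correction angles, columns = SPOI), `unrounded`,
#'   `corrections`, `spois`, `alpha0`, `digits`.
#' @examples
#' tab <- run_grid()
#' tab$values["30", "20"]  # 11.3
#' @export
run_grid <- function(alpha0 = 10, spois = c(20, 10, 0, -10),
                     corrections = seq(0, 30, by = 5), digits = 1,
                     backend = c("closed_form", "rodrigues")) {
  backend <- match.arg(backend)
  if (length(spois) == 0 || length(corrections) == 0)
    stop("spois and corrections must be non-empty")
  raw <- outer(corrections, spois, function(th, ph) {
    if (backend == "closed_form") {
      closed_form_pts(alpha0, ph, th)
    } else {
      mapply(function(t1, p1) {
        sagittal_slope_angle(
          opened_slope_direction(alpha0, osteotomy_plan(p1, t1)))
      }, th, ph)
    }
  })
  dimnames(raw) <- list(format(corrections, trim = TRUE),
                        format(spois, trim = TRUE))
  structure(list(values = round_half_away(raw, digits), unrounded = raw,
                 corrections = corrections, spois = spois, alpha0 = alpha0,
                 digits = digits),
            class = "slope_table")
}

#' @export
print.slope_table <- function(x, ...) {
  cat(sprintf("Posterior slope (deg) by correction angle and SPOI (alpha0 = %g deg)\n",
              x$alpha0))
  m <- format(x$values, nsmall = x$digits)
  print(m, quote = FALSE)
  invisible(x)
}

#' Published virtual-simulation reference grid
#'
#' Loads the packaged reference table of posterior slopes from the virtual
#' simulation (correction angles 5-30 degrees, SPOI 20/10/0/-10, initial
#' slope 10 degrees, 0.1-degree precision). Cells the source printed without
#' a decimal ("10") are stored as 10.0.
#'
#' @return a `slope_table` (rounded values only; `unrounded` equals `values`).
#' @export
reference_slope_table <- function() {
  path <- system.file("extdata", "table1_reference.csv", package = "owhto",
                      mustWork = TRUE)
  read_slope_table(path, alpha0 = 10)
}

#' Read a slope grid from CSV
#'
#' Expects the layout written by [write_slope_table()]: a `correction_deg`
#' column followed by one column per SPOI named `spoi_<value>`.
#'
#' @param path CSV file path.
#' @param alpha0 initial slope the grid was computed from (metadata only).
#' @param digits precision of the stored values.
#' @return a `slope_table`.
#' @export
read_slope_table <- function(path, alpha0 = NA_real_, digits = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "correction_deg")
  spois <- as.numeric(sub("^spoi_", "", names(df)[-1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(format(df$correction_deg, trim = TRUE),
                      format(spois, trim = TRUE))
  structure(list(values = m, unrounded = m, corrections = df$correction_deg,
                 spois = spois, alpha0 = alpha0, digits = digits),
            class = "slope_table")
}

#' Write a slope grid
#'
#' `write_slope_table()` writes the rounded grid as CSV (fixed point at the
#' table's precision); `write_slope_table_json()` writes the unrounded values
#' with full precision.
#'
#' @param table a `slope_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_slope_table <- function(table, path) {
  stopifnot(inherits(table, "slope_table"))
  df <- data.frame(correction_deg = table$corrections)
  vals <- formatC(table$values, format = "f", digits = table$digits)
  for (j in seq_along(table$spois))
    df[[paste0("spoi_", format(table$spois[j], trim = TRUE))]] <- vals[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_slope_table
#' @export
write_slope_table_json <- function(table, path) {
  stopifnot(inherits(table, "slope_table"))
  obj <- list(alpha0_deg = table$alpha0,
              correction_deg = table$corrections,
              spoi_deg = table$spois,
              slope_deg = lapply(seq_along(table$spois), function(j)
                unname(table$unrounded[, j])))
  names(obj$slope_deg) <- paste0("spoi_", format(table$spois, trim = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cell-by-cell comparison of two slope grids
#'
#' @param table,reference `slope_table` objects on identical grids.
#' @return a data.frame with one row per differing cell (columns
#'   `correction_deg`, `spoi_deg`, `computed`, `reference`, `delta`);
#'   zero rows means exact reproduction.
#' @export
compare_to_reference <- function(table, reference) {
  stopifnot(inherits(table, "slope_table"), inherits(reference, "slope_table"))
  if (!isTRUE(all.equal(table$corrections, reference$corrections)) ||
      !isTRUE(all.equal(table$spois, reference$spois)))
    stop("grid mismatch: tables have different correction angles or SPOI sets")
  idx <- which(table$values != reference$values, arr.ind = TRUE)
  data.frame(
    correction_deg = table$corrections[idx[, 1]],
    spoi_deg = table$spois[idx[, 2]],
    computed = table$values[idx],
    reference = reference$values[idx],
    delta = table$values[idx] - reference$values[idx]
  )
}
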