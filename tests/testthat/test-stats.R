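test_that("mid-ranks conserve the rank sum and split ties", {
  expect_equal(ranks_with_ties(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(ranks_with_ties(c(5, 5)), c(1.5, 1.5))
  expect_equal(sum(ranks_with_ties(c(2, 2, 2, 2))), 10)
  set.seed(8)
  for (i in 1:10) {
    v <- sample(1:4, 12, replace = TRUE)
    expect_equal(sum(ranks_with_ties(v)), 12 * 13 / 2)
  }
})

test_that("the H statistic matches its definition and handles degenerate input", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kt <- kruskal_wallis(g)
  expect_equal(kt$h_statistic, bf_kw_h(g), tolerance = 1e-12)
  expect_equal(kt$df, 1)
  expect_equal(kt$group_sizes, c(3L, 3L))
  # all observations identical: H = 0, p = 1, not an error
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$h_statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1, 2)), "total n")
})

test_that("H is invariant under strictly monotone transformations", {
  set.seed(31)
  g <- list(rnorm(6), rnorm(5, 1), rnorm(7, -0.5))
  h0 <- kruskal_wallis(g)$h_statistic
  expect_equal(kruskal_wallis(lapply(g, exp))$h_statistic, h0)
  expect_equal(kruskal_wallis(lapply(g, function(x) 3 * x - 10))$h_statistic, h0)
})

test_that("for two tie-free groups H equals the squared standardized rank sum", {
  set.seed(14)
  x <- rnorm(7); y <- rnorm(9, 0.8)
  h <- kruskal_wallis(list(x, y))$h_statistic
  n1 <- 7; n2 <- 9; n <- n1 + n2
  w <- sum(rank(c(x, y))[1:n1])          # rank sum of group 1
  z <- (w - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-12)
})

test_that("the exact permutation p-value matches brute-force enumeration", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  perm <- kruskal_wallis(g, method = "permutation")
  expect_equal(perm$p_value, bf_kw_perm_p(g))
  expect_equal(perm$p_value, 2 / 20)     # only the two extreme splits
  set.seed(19)
  for (i in 1:5) {
    gg <- list(rnorm(3), rnorm(3, 1), rnorm(3))
    p_pkg <- kruskal_wallis(gg, method = "permutation")$p_value
    expect_equal(p_pkg, bf_kw_perm_p(gg), tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(rnorm(7), rnorm(7)), method = "permutation"),
               "n <= 12")
})

test_that("normality screen flags skewed cells, passes Gaussian ones, skips degenerate ones", {
  make_trials <- function(values_by_cell) {
    df <- do.call(rbind, lapply(seq_along(values_by_cell), function(i) {
      data.frame(spoi_deg = 0, correction_deg = i * 5,
                 replicate = seq_along(values_by_cell[[i]]),
                 slope_deg = values_by_cell[[i]])
    }))
    class(df) <- c("trial_table", "data.frame")
    df
  }
  set.seed(6)
  gauss <- replicate(40, rnorm(30, 10, 0.3), simplify = FALSE)
  scr <- normality_screen(make_trials(gauss))
  expect_lt(mean(scr$nonnormal), 0.2)
  skewed <- replicate(40, 10 + exp(3 * rnorm(30)), simplify = FALSE)
  scr2 <- normality_screen(make_trials(skewed))
  expect_gt(mean(scr2$nonnormal), 0.9)
  expect_warning(scr3 <- normality_screen(make_trials(list(rep(10, 10)))),
                 "constant")
  expect_true(scr3$degenerate)
})

test_that("the table analysis reproduces both test margins and rejects ragged grids", {
  trials <- simulate_experiment(n_reps = 10, noise = exact_noise())
  rep0 <- analyze_table(trials)
  # constant margin: cut parallel to the plateau
  expect_equal(rep0$per_spoi$p_value[rep0$per_spoi$spoi_deg == 10], 1)
  expect_equal(rep0$per_spoi$h_statistic[rep0$per_spoi$spoi_deg == 10], 0)
  # noise-free separated groups are significant on the other margins
  expect_true(all(rep0$per_spoi$significant[rep0$per_spoi$spoi_deg != 10]))
  expect_equal(rep0$alpha, 0.05)
  ragged <- trials[-1, ]
  class(ragged) <- c("trial_table", "data.frame")
  expect_error(analyze_table(ragged), "shape error")
})

test_that("the report renders the summary layout with both p-value margins", {
  trials <- simulate_experiment(n_reps = 5, noise = noise_model(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_analysis_report(summarize_trials(trials), analyze_table(trials), path)
  out <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(out),
               c("correction_deg", "spoi_20", "spoi_10", "spoi_0", "spoi_-10",
                 "p_value"))
  expect_equal(nrow(out), 7)             # six correction rows + p-value row
  expect_true(all(grepl("\\+-", out$spoi_20[1:6])))
  expect_equal(owhto:::format_p(c(0.0005, 0.485)), c("< 0.001", "0.485"))
})
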