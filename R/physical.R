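# Monte-Carlo emulation of the bench experiment: a coordinate digitizer
# records the two slope end-points on the rotated proximal fragment, n times
# per condition, and the slope is reconstructed from the digitized line.

#' Measurement noise model for the digitizer experiment
#'
#' Two noise sources act on each replicate:
#' * `sigma_point` (mm): independent Gaussian noise on every coordinate of
#'   every digitized point. The default 0.025 mm reads the instrument's
#'   stated +-0.05 mm accuracy as a ~2-SD bound.
#' * `sigma_mount` (degrees): a per-replicate sagittal seating tilt of the
#'   specimen-jig assembly, i.e. a small rotation of the measured points about
#'   the medial-lateral axis. Re-seating the model between measurements tilts
#'   the whole fragment in the sagittal plane and adds directly to the
#'   measured slope; point noise alone over a 50 mm baseline gives ~0.04
#'   degree scatter, an order below what replicate measurements of this kind
#'   show, so the seating term dominates the replicate SD.
#'
#' @param sigma_point per-coordinate digitization noise SD, mm (>= 0).
#' @param sigma_mount per-replicate mounting tilt SD, degrees (>= 0).
#' @param seed integer base seed for the replicate substreams.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_point = 0.025, sigma_mount = 0.25, seed = 1L) {
  if (sigma_point < 0 || sigma_mount < 0)
    stop("noise SDs must be non-negative")
  structure(list(sigma_point = sigma_point, sigma_mount = sigma_mount,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "Noise model: point SD %g mm, mounting tilt SD %g deg, seed %d\n",
    x$sigma_point, x$sigma_mount, x$seed))
  invisible(x)
}

# Deterministic 31-bit substream seed from (seed, spoi, theta, replicate) so
# any single cell/replicate is reproducible in isolation.
substream_seed <- function(seed, spoi, theta, replicate) {
  m <- 2147483647
  h <- seed %% m
  for (k in c(round(spoi * 100) + 36000, round(theta * 100) + 36000,
              replicate)) {
    h <- (h * 69069 + k) %% m
  }
  as.integer(h)
}

#' Digitize the slope end-points of one replicate
#'
#' Places point A (anterior) and point B (posterior) at the ends of the
#' top-surface midline, applies the wedge-opening rotation about the hinge
#' line, then the noise model: a sagittal seating tilt of
#' Normal(0, sigma_mount) degrees about the medial-lateral axis through the
#' hinge point, and independent Normal(0, sigma_point) mm noise on each
#' coordinate of each point. Draws from the current RNG stream; seed it (or
#' use [simulate_experiment()], which derives per-replicate substreams) for
#' reproducibility.
#'
#' @param column a [column_model()].
#' @param plan an [osteotomy_plan()].
#' @param noise a [noise_model()].
#' @param cut_height height of the hinge point on the lateral face, mm.
#' @return an object of class `slope_line`: list with `point_a`, `point_b`.
#' @export
digitize_endpoints <- function(column, plan, noise,
                               cut_height = column$height / 2) {
  stopifnot(inherits(column, "column_model"), inherits(plan, "osteotomy_plan"),
            inherits(noise, "noise_model"))
  # rigid motion of the slope line, as midpoint + rotated direction: the
  # midpoint moves with the fragment; the direction uses the reduced rotation
  # form (exact for a cut parallel to the slope). -correction matches the
  # medial-elevating fragment motion of transform_point().
  hinge_point <- c(0, 0, cut_height)
  mid <- transform_point(c(column$width_ml / 2, 0, column$height), plan,
                         hinge_point)
  dir <- if (is.null(plan$hinge_axis_override)) {
    slope_direction_reduced(column$alpha0, plan$spoi, -plan$correction)
  } else {
    a0r <- deg2rad(column$alpha0)
    rotate_about_axis(c(0, cos(a0r), sin(a0r)), plan$hinge_axis_override,
                      -plan$correction)
  }
  halflen <- column$depth_ap / (2 * cos(deg2rad(column$alpha0)))
  a <- mid + halflen * dir
  b <- mid - halflen * dir
  tilt <- stats::rnorm(1, 0, noise$sigma_mount)
  ml_axis <- c(1, 0, 0)
  a <- hinge_point + rotate_about_axis(a - hinge_point, ml_axis, tilt)
  b <- hinge_point + rotate_about_axis(b - hinge_point, ml_axis, tilt)
  a <- a + stats::rnorm(3, 0, noise$sigma_point)
  b <- b + stats::rnorm(3, 0, noise$sigma_point)
  structure(list(point_a = a, point_b = b), class = "slope_line")
}

#' Posterior slope of a digitized slope line
#'
#' Sagittal inclination of the line from point B (posterior) to point A
#' (anterior).
#'
#' @param line a `slope_line`.
#' @return slope in degrees.
#' @export
measure_slope <- function(line) {
  stopifnot(inherits(line, "slope_line"))
  d <- line$point_a - line$point_b
  if (sqrt(d[2]^2 + d[3]^2) < 1e-9)
    stop("degenerate measurement: end-points coincide in sagittal projection")
  sagittal_slope_angle(d)
}

#' Simulate the full replicated bench experiment
#'
#' For every (SPOI, correction angle) cell, runs `n_reps` independent
#' digitize/measure cycles. RNG substreams are derived from
#' (noise$seed, spoi, correction, replicate), so any cell or replicate can be
#' regenerated in isolation and the full table is reproducible.
#'
#' @param column a [column_model()].
#' @param spois osteotomy inclinations, degrees.
#' @param corrections correction angles, degrees.
#' @param n_reps replicates per cell (>= 2).
#' @param noise a [noise_model()].
#' @return a `trial_table`: data.frame with columns `spoi_deg`,
#'   `correction_deg`, `replicate`, `slope_deg`.
#' @examples
#' trials <- simulate_experiment(n_reps = 3, noise = noise_model(seed = 7))
#' head(trials)
#' @export
simulate_experiment <- function(column = column_model(),
                                spois = c(20, 10, 0, -10),
                                corrections = seq(5, 30, by = 5),
                                n_reps = 10,
                                noise = noise_model()) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  grid <- expand.grid(replicate = seq_len(n_reps), correction_deg = corrections,
                      spoi_deg = spois)[, 3:1]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  grid$slope_deg <- mapply(function(sp, th, rep) {
    set.seed(substream_seed(noise$seed, sp, th, rep))
    measure_slope(digitize_endpoints(column, osteotomy_plan(sp, th), noise))
  }, grid$spoi_deg, grid$correction_deg, grid$replicate)
  class(grid) <- c("trial_table", "data.frame")
  attr(grid, "n_reps") <- n_reps
  grid
}

#' Summarize a trial table
#'
#' Per-cell sample mean and sample standard deviation (n - 1 denominator) in
#' the usual layout: rows = correction angles, columns = SPOI.
#'
#' @param trials a `trial_table`.
#' @return a `summary_table`: list with matrices `mean` and `sd`,
#'   plus `corrections`, `spois`, `n_reps`.
#' @export
summarize_trials <- function(trials) {
  stopifnot(inherits(trials, "trial_table"), nrow(trials) > 0)
  corrections <- sort(unique(trials$correction_deg))
  spois <- unique(trials$spoi_deg)
  cell <- function(f) {
    m <- outer(corrections, spois, Vectorize(function(th, sp)
      f(trials$slope_deg[trials$correction_deg == th & trials$spoi_deg == sp])))
    dimnames(m) <- list(format(corrections, trim = TRUE),
                        format(spois, trim = TRUE))
    m
  }
  n <- length(trials$slope_deg[trials$correction_deg == corrections[1] &
                                 trials$spoi_deg == spois[1]])
  structure(list(mean = cell(mean), sd = cell(stats::sd),
                 corrections = corrections, spois = spois, n_reps = n),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, digits = 1, ...) {
  cat(sprintf("Posterior slope, mean +- SD over n = %d replicates (deg)\n",
              x$n_reps))
  m <- matrix(sprintf("%.*f +- %.*f", digits, x$mean, digits, x$sd),
              nrow = nrow(x$mean), dimnames = dimnames(x$mean))
  print(m, quote = FALSE)
  invisible(x)
}

#' Read/write trial tables as tidy CSV
#'
#' Columns: `spoi_deg`, `correction_deg`, `replicate`, `slope_deg` (full
#' precision). A written-then-read table is value-identical.
#'
#' @param trials a `trial_table`.
#' @param path CSV file path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns a `trial_table`.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  df <- as.data.frame(trials)
  df$slope_deg <- formatC(df$slope_deg, format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("spoi_deg", "correction_deg", "replicate", "slope_deg")
                %in% names(df)))
  class(df) <- c("trial_table", "data.frame")
  attr(df, "n_reps") <- max(df$replicate)
  df
}
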