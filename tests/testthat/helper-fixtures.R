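# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Minimal plate table: one plate, one replicate, `values` as the single
# feature (or a matrix of features).
make_plate_table <- function(values, plate = "plate_1", replicate = 1) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("feature_f%02d", seq_len(ncol(values)))
  }
  n <- nrow(values)
  cbind(
    data.frame(plate = plate, replicate = replicate,
               well = sprintf("A%02d", seq_len(n)),
               target = sprintf("g%02d", seq_len(n)),
               role = "library", stringsAsFactors = FALSE),
    as.data.frame(values)
  )
}

# n x p data with an exactly realized sample correlation matrix R and
# column SDs `sds` (descending SDs give a known variance ranking).
make_exact_cor <- function(n, R, sds = rev(seq_len(ncol(R))), seed = 1) {
  p <- ncol(R)
  stopifnot(n > p)
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- scale(x, center = TRUE, scale = FALSE)
  # whiten to exact identity sample covariance, then color by chol(R)
  x <- x %*% solve(chol(cov(x)))
  x <- x %*% chol(R)
  x <- sweep(x, 2, apply(x, 2, sd), "/")
  x <- sweep(x, 2, sds, "*")
  colnames(x) <- sprintf("feature_f%02d", seq_len(p))
  rownames(x) <- sprintf("t%03d", seq_len(n))
  x
}

# Dense-grid oracle for the nearest point on a quadratic curve; independent
# of the root-solving implementation.
grid_project <- function(point, model, n_grid = 20001) {
  xs <- seq(model$domain[1], model$domain[2], length.out = n_grid)
  cf <- model$coefficients
  ys <- cf[[1]] + cf[[2]] * xs + cf[[3]] * xs^2
  d2 <- (xs - point[1])^2 + (ys - point[2])^2
  i <- which.min(d2)
  list(x = xs[i], distance = sqrt(d2[i]))
}

# A bare time-curve model with given coefficients and domain (no
# calibration), for projection unit tests.
quad_model <- function(c0, c1, c2, domain) {
  structure(list(coefficients = c(c0 = c0, c1 = c1, c2 = c2),
                 domain = domain, calibration = NULL,
                 fit_days = c(NA_real_, NA_real_), rss = NA_real_),
            class = "time_curve_model")
}

# Small screen simulation used by several files.
small_screen <- function(seed = 1, ...) {
  generate_screen(screen_sim_config(
    n_targets = 60, n_plates = 2, n_replicates = 2, n_features = 12,
    seed = seed, ...))
}
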