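#' 2-D PCA embedding of expression samples
#'
#' PCA on centered log-normalized expression of the most variable genes. The
#' returned axes are swapped relative to the usual convention — x is PC2 and
#' y is PC1 — because in this assay the second component tracks reprogramming
#' time while the first carries the dominant off-time variation. Axis signs
#' are deterministic: x is oriented so that time-course day increases with
#' x, and y so that the time-course trajectory curves downward (negative
#' quadratic coefficient of y on x). The y convention matters because a
#' subsequent counter-clockwise rotation keeps x monotone along a
#' downward-opening arc but folds an upward-opening one back on itself;
#' when no time-course curvature is measurable y falls back to the
#' largest-|loading|-positive convention.
#'
#' @param lognorm Gene-by-sample log-normalized matrix.
#' @param days Numeric day label per sample column (`NA` for knockdowns);
#'   used only to orient the x axis.
#' @param n_top Number of most-variable genes for the embedding
#'   (default 200).
#' @return Object of class `embedding2d`: list with `coords` (data frame
#'   `sample`, `x`, `y`), `rotation_degrees` (0 here), `axes`
#'   (`c(x = "PC2", y = "PC1")`), `genes`, `variance_explained`.
#' @export
embed_samples <- function(lognorm, days, n_top = 200) {
  lognorm <- as.matrix(lognorm)
  if (ncol(lognorm) < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(days) != ncol(lognorm)) {
    stop("one day label (or NA) per sample is required", call. = FALSE)
  }
  genes <- top_variable_genes(lognorm, min(n_top, nrow(lognorm)))
  pc <- stats::prcomp(t(lognorm[genes, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("fewer than 2 non-degenerate principal components", call. = FALSE)
  }
  # swap: x <- PC2, y <- PC1
  x <- pc$x[, 2]
  y <- pc$x[, 1]
  ok <- is.finite(days)
  if (any(ok)) {
    if (stats::sd(x[ok]) > 0 &&
        isTRUE(stats::cor(days[ok], x[ok]) < 0)) {
      x <- -x
    }
  }
  c2 <- NA_real_
  if (sum(ok) >= 3 && length(unique(x[ok])) >= 3) {
    c2 <- stats::coef(stats::lm(y[ok] ~ x[ok] + I(x[ok]^2)))[3]
  }
  if (is.finite(c2) && abs(c2) > 1e-12) {
    if (c2 > 0) y <- -y
  } else {
    y <- fix_sign(y, pc$rotation[, 1])$scores
  }
  structure(list(
    coords = data.frame(sample = colnames(lognorm), x = unname(x),
                        y = unname(y), stringsAsFactors = FALSE),
    rotation_degrees = 0,
    axes = c(x = "PC2", y = "PC1"),
    genes = genes,
    variance_explained = pc$sdev[1:2]^2 / sum(pc$sdev^2)
  ), class = "embedding2d")
}

#' Rigid rotation of a 2-D embedding
#'
#' Rotates all coordinates about the origin by `angle_degrees`
#' (counter-clockwise positive). A rigid rotation, so all pairwise distances
#' are preserved; the cumulative angle is recorded.
#'
#' @param embedding An `embedding2d` object, or a data frame with `x`, `y`.
#' @param angle_degrees Rotation angle in degrees (default 15).
#' @return The embedding with rotated coordinates.
#' @export
rotate_embedding <- function(embedding, angle_degrees = 15) {
  coords <- if (inherits(embedding, "embedding2d")) embedding$coords
            else embedding
  th <- angle_degrees * pi / 180
  x <- coords$x * cos(th) - coords$y * sin(th)
  y <- coords$x * sin(th) + coords$y * cos(th)
  coords$x <- x
  coords$y <- y
  if (inherits(embedding, "embedding2d")) {
    embedding$coords <- coords
    embedding$rotation_degrees <- embedding$rotation_degrees + angle_degrees
    embedding
  } else {
    coords
  }
}

#' Fit the second-order time curve
#'
#' Ordinary least-squares fit of \eqn{y = c_0 + c_1 x + c_2 x^2} to the
#' replicate coordinates of time-course samples within `fit_days`, in the
#' (rotated) embedding. Also builds the day-calibration table: each fitted
#' day's mean coordinate is projected onto the curve and the projected x
#' recorded, made monotone in day by isotonic regression so that projected x
#' values can be translated back into interpolated day estimates.
#'
#' @param embedding An `embedding2d` (or data frame with `x`, `y`) covering
#'   at least the time-course samples.
#' @param days Day label per embedding row (`NA` for non-time-course
#'   samples).
#' @param fit_days Day interval used for the fit (default `c(2, 7)`; early
#'   days are excluded as the embryonic-fibroblast starting state sits off
#'   the later trajectory).
#' @return Object of class `time_curve_model`: `coefficients` (c0, c1, c2),
#'   `domain` (x-range of the fitted points), `calibration` (data frame
#'   `day`, `x`), `fit_days`, `rss`.
#' @export
fit_time_curve <- function(embedding, days, fit_days = c(2, 7)) {
  coords <- if (inherits(embedding, "embedding2d")) embedding$coords
            else embedding
  if (length(days) != nrow(coords)) {
    stop("one day label per embedding row is required", call. = FALSE)
  }
  use <- is.finite(days) & days >= min(fit_days) & days <= max(fit_days)
  if (sum(use) < 3 || length(unique(coords$x[use])) < 3) {
    stop("need at least 3 time-course points with distinct x in the fit range",
         call. = FALSE)
  }
  x <- coords$x[use]
  y <- coords$y[use]
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  model <- structure(list(
    coefficients = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
    domain = range(x),
    calibration = NULL,
    fit_days = range(fit_days),
    rss = sum(stats::residuals(fit)^2)
  ), class = "time_curve_model")

  day_f <- factor(days[use])
  mx <- tapply(x, day_f, mean)
  my <- tapply(y, day_f, mean)
  proj_x <- vapply(seq_along(mx), function(i) {
    project_onto_curve(c(mx[i], my[i]), model)$x
  }, numeric(1))
  d <- as.numeric(levels(day_f))
  ord <- order(d)
  # enforce monotone day -> x so the inverse lookup is well defined
  iso <- stats::isoreg(d[ord], proj_x[ord])
  model$calibration <- data.frame(day = d[ord], x = iso$yf)
  model
}

#' Shortest-distance projection of a point onto the fitted curve
#'
#' Finds the x on the curve \eqn{y = c_0 + c_1 x + c_2 x^2}, restricted to
#' the fit domain, that minimizes the squared Euclidean distance
#' \eqn{D(x) = (x - p_x)^2 + (f(x) - p_y)^2}. The stationary points of the
#' quartic \eqn{D} solve a cubic, found exactly via its complex roots;
#' domain endpoints are always candidates and exact ties are broken toward
#' smaller x (earlier pseudotime). The projected x is the pseudotime proxy
#' and \eqn{\sqrt{D}} the off-trajectory residual. The day estimate
#' interpolates the model's calibration table piecewise-linearly, clamped at
#' its ends.
#'
#' @param point Numeric length-2 vector `(px, py)`.
#' @param model A `time_curve_model`.
#' @return List: `x` (projected x), `y` (curve value there), `distance`,
#'   `day` (interpolated day estimate, `NA` when the model has no
#'   calibration).
#' @export
project_onto_curve <- function(point, model) {
  stopifnot(inherits(model, "time_curve_model"), length(point) == 2)
  px <- as.numeric(point[1])
  py <- as.numeric(point[2])
  cf <- model$coefficients
  c0 <- cf[[1]]; c1 <- cf[[2]]; c2 <- cf[[3]]
  f <- function(x) c0 + c1 * x + c2 * x^2
  dd <- function(x) (x - px)^2 + (f(x) - py)^2

  # D'(x)/2 = (x - px) + (f(x) - py) (c1 + 2 c2 x), a cubic in x
  a <- c0 - py
  a0 <- a * c1 - px
  a1 <- 2 * c2 * a + c1^2 + 1
  a2 <- 3 * c1 * c2
  a3 <- 2 * c2^2
  cand <- model$domain
  if (abs(a3) > 0 || abs(a2) > 0 || abs(a1) > 0) {
    coefs <- c(a0, a1, a2, a3)
    deg <- max(which(abs(coefs) > 0)) - 1L
    if (deg >= 1) {
      r <- polyroot(coefs[seq_len(deg + 1L)])
      real <- Re(r)[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))]
      real <- real[real >= model$domain[1] & real <= model$domain[2]]
      cand <- c(cand, real)
    }
  }
  vals <- dd(cand)
  best <- min(vals)
  x_star <- min(cand[vals <= best + 1e-12 * (1 + best)])
  res <- list(x = x_star, y = f(x_star), distance = sqrt(dd(x_star)),
              day = NA_real_)
  if (!is.null(model$calibration) && nrow(model$calibration) >= 2 &&
      length(unique(model$calibration$x)) >= 2) {
    res$day <- stats::approx(model$calibration$x, model$calibration$day,
                             xout = x_star, rule = 2, ties = mean)$y
  }
  res
}

#' Project every sample and report reprogramming progression
#'
#' Averages embedding coordinates per condition, projects each condition's
#' mean point onto the fitted time curve, and reports the pseudotime proxy,
#' the interpolated day estimate and the off-trajectory residual distance.
#' Knockdowns whose day estimate falls short of the reference (nt control)
#' condition's estimate by more than `delay_threshold` days are flagged
#' `delayed`.
#'
#' @param embedding An `embedding2d` (rotated) covering all samples.
#' @param model A `time_curve_model` fitted in the same frame.
#' @param conditions Condition label per embedding row.
#' @param reference Condition label of the nt control; `NULL` picks the
#'   first condition matching `"^nt"`, and when none exists the report
#'   carries no delay flags (with a warning).
#' @param delay_threshold Days short of the reference that count as delayed
#'   (default 1).
#' @return Data frame: `condition`, `x`, `y`, `pseudotime` (projected x),
#'   `day_estimate`, `distance`, `delayed`; ordered by decreasing
#'   pseudotime. The reference label is in `attr(, "reference")`.
#' @export
progression_report <- function(embedding, model, conditions,
                               reference = NULL, delay_threshold = 1) {
  coords <- if (inherits(embedding, "embedding2d")) embedding$coords
            else embedding
  if (length(conditions) != nrow(coords)) {
    stop("one condition label per embedding row is required", call. = FALSE)
  }
  f <- factor(conditions, levels = unique(conditions))
  mx <- tapply(coords$x, f, mean)
  my <- tapply(coords$y, f, mean)
  proj <- lapply(seq_along(mx), function(i) {
    project_onto_curve(c(mx[i], my[i]), model)
  })
  out <- data.frame(
    condition = levels(f),
    x = as.numeric(mx), y = as.numeric(my),
    pseudotime = vapply(proj, `[[`, numeric(1), "x"),
    day_estimate = vapply(proj, `[[`, numeric(1), "day"),
    distance = vapply(proj, `[[`, numeric(1), "distance"),
    stringsAsFactors = FALSE
  )
  if (is.null(reference)) {
    hit <- grep("^nt", out$condition, value = TRUE)
    reference <- if (length(hit) > 0) hit[1] else NULL
  }
  if (is.null(reference) || !reference %in% out$condition) {
    warning("no nt-control reference condition; delay flags not set")
    out$delayed <- NA
  } else {
    ref_day <- out$day_estimate[out$condition == reference]
    out$delayed <- out$day_estimate < ref_day - delay_threshold
    attr(out, "reference") <- reference
  }
  out[order(-out$pseudotime), , drop = FALSE]
}
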