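#' Configuration for the synthetic reprogramming time course
#'
#' Describes a CEL-seq-style UMI count experiment: a day-by-day reprogramming
#' time course of control cells plus knockdown samples whose transcriptomes
#' sit at a planted progression point along the trajectory, optionally pushed
#' off it by an orthogonal offset.
#'
#' The expression model lives in a 2-D latent space: time-course samples lie
#' on the curve \eqn{(u, v) = (t - \bar t, \alpha (t - \bar t)^2)} in day
#' units, and a knockdown with progression \eqn{p} and offset \eqn{o} lies at
#' the curve point for \eqn{p} plus \eqn{o} times the unit normal to the
#' local tangent. Latent coordinates are lifted to per-gene log-means through
#' a pair of orthonormal gene loadings scaled by `loading_scale`, added to a
#' lognormal baseline abundance, and counts are drawn from a
#' negative-binomial with the stated dispersion after scaling each sample's
#' expected total to `library_size`. Because the loadings are orthonormal the
#' latent geometry — and hence both the planted progression and the
#' orthogonal offset — is recoverable from a PCA of the log expression.
#' The default curvature makes the off-time axis carry more variance than
#' the time axis, so PC1 captures the parabola height and PC2 tracks time,
#' the configuration the progression model's axis swap expects.
#'
#' @param n_genes Number of genes (default 2000).
#' @param days Time-course days (default `0:7`, daily sampling).
#' @param replicates_per_day Replicates per day and per knockdown (default 3).
#' @param n_knockdowns Number of knockdown conditions (default 30).
#' @param knockdowns Optional knockdown labels (default `kd_01`, ...).
#' @param planted_progression Per-knockdown true progression in day units;
#'   default evenly spaced over days 2-7.
#' @param orthogonal_offset Per-knockdown non-negative offset in latent (day)
#'   units, orthogonal to the local trajectory tangent; the default cycles
#'   through 0-2.5 so offsets are uncorrelated with progression.
#' @param dispersion Negative-binomial dispersion (variance
#'   \eqn{\mu + \phi \mu^2}); 0 gives Poisson counts (default 0.1).
#' @param library_size Expected per-sample total count (default 1e6).
#' @param curvature Latent parabola coefficient \eqn{\alpha} (default 1);
#'   must be large enough that the off-time axis dominates the PCA (so the
#'   axis swap holds) yet gentle enough that the rotated arc stays a
#'   function of x over the fitted day range.
#' @param n_signal_genes Number of genes carrying the trajectory signal
#'   (default 600); the rest vary only by counting noise, as in real time
#'   courses where a limited marker programme moves while most of the
#'   transcriptome is static.
#' @param loading_scale Scale of the gene loadings: natural-log fold change
#'   per latent day unit summed in quadrature over the signal genes
#'   (default 4, chosen so signal genes stay clear of the zero-count floor
#'   and the lift into log expression remains near-isometric).
#' @param seed Integer seed.
#' @return An object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_genes = 2000, days = 0:7,
                                  replicates_per_day = 3, n_knockdowns = 30,
                                  knockdowns = NULL,
                                  planted_progression = NULL,
                                  orthogonal_offset = NULL,
                                  dispersion = 0.1, library_size = 1e6,
                                  curvature = 1.0, n_signal_genes = 600,
                                  loading_scale = 4, seed = 1) {
  n_knockdowns <- check_count(n_knockdowns, "n_knockdowns", min = 0L)
  days <- sort(as.numeric(days))
  if (length(days) < 3) stop("need at least 3 time-course days", call. = FALSE)
  if (is.null(knockdowns)) {
    knockdowns <- if (n_knockdowns > 0) sprintf("kd_%02d", seq_len(n_knockdowns))
                  else character(0)
  }
  if (length(knockdowns) != n_knockdowns) {
    stop("'knockdowns' must supply one label per knockdown", call. = FALSE)
  }
  if (is.null(planted_progression)) {
    planted_progression <- if (n_knockdowns > 0) {
      seq(2, 7, length.out = n_knockdowns)
    } else {
      numeric(0)
    }
  }
  if (is.null(orthogonal_offset)) {
    orthogonal_offset <- rep(c(0, 1.5, 0.5, 2.5, 1, 2),
                             length.out = n_knockdowns)
  }
  if (length(planted_progression) != n_knockdowns ||
      any(planted_progression < min(days)) ||
      any(planted_progression > max(days))) {
    stop("'planted_progression' must lie within the day range, one value per knockdown",
         call. = FALSE)
  }
  if (length(orthogonal_offset) != n_knockdowns || any(orthogonal_offset < 0)) {
    stop("'orthogonal_offset' must be non-negative, one value per knockdown",
         call. = FALSE)
  }
  structure(list(
    n_genes = check_count(n_genes, "n_genes", min = 10L),
    days = days,
    replicates_per_day = check_count(replicates_per_day, "replicates_per_day"),
    n_knockdowns = n_knockdowns,
    knockdowns = as.character(knockdowns),
    planted_progression = as.numeric(planted_progression),
    orthogonal_offset = as.numeric(orthogonal_offset),
    dispersion = check_positive(dispersion, "dispersion", strict = FALSE),
    library_size = check_positive(library_size, "library_size"),
    curvature = check_positive(curvature, "curvature"),
    n_signal_genes = min(check_count(n_signal_genes, "n_signal_genes",
                                     min = 2L),
                         check_count(n_genes, "n_genes", min = 10L)),
    loading_scale = check_positive(loading_scale, "loading_scale"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "trajectory_sim_config")
}

# Latent coordinates of the trajectory at time t (day units).
latent_curve <- function(t, t_center, curvature) {
  cbind(u = t - t_center, v = curvature * (t - t_center)^2)
}

#' Simulate a reprogramming time course with knockdown samples
#'
#' Draws UMI-style counts for a daily time course plus knockdown conditions
#' placed at planted progression points with orthogonal off-trajectory
#' offsets (see [trajectory_sim_config()] for the generative model).
#'
#' @param config A [trajectory_sim_config()].
#' @return A list of class `timecourse_sim` with elements
#'   \describe{
#'     \item{counts}{gene-by-sample integer matrix.}
#'     \item{samples}{sample sheet: `sample`, `condition`, `day` (NA for
#'       knockdowns), `replicate`.}
#'     \item{truth}{per-knockdown `target`, `progression`, `offset` and the
#'       latent coordinates.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- generate_timecourse(trajectory_sim_config(n_genes = 200,
#'   n_knockdowns = 4, replicates_per_day = 2, seed = 3))
#' dim(sim$counts)
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  with_seed(config$seed, {
    t_center <- mean(range(config$days))

    day_grid <- rep(config$days, each = config$replicates_per_day)
    day_latent <- latent_curve(day_grid, t_center, config$curvature)

    p <- config$planted_progression
    kd_base <- latent_curve(p, t_center, config$curvature)
    tangent <- cbind(1, 2 * config$curvature * (p - t_center))
    # unit normal on the convex side of the parabola, where the
    # shortest-distance projection is single-valued for any offset
    normal <- cbind(tangent[, 2], -tangent[, 1]) /
      sqrt(rowSums(tangent^2))
    kd_latent <- kd_base + config$orthogonal_offset * normal
    if (config$n_knockdowns > 0) {
      kd_latent <- kd_latent[rep(seq_len(config$n_knockdowns),
                                 each = config$replicates_per_day), ,
                             drop = FALSE]
    }
    latent <- rbind(day_latent, kd_latent)

    samples <- data.frame(
      sample = c(
        sprintf("day%g_r%d", day_grid,
                rep(seq_len(config$replicates_per_day), length(config$days))),
        if (config$n_knockdowns > 0) {
          sprintf("%s_r%d",
                  rep(config$knockdowns, each = config$replicates_per_day),
                  rep(seq_len(config$replicates_per_day), config$n_knockdowns))
        }
      ),
      condition = c(sprintf("day%g", day_grid),
                    if (config$n_knockdowns > 0) {
                      rep(config$knockdowns, each = config$replicates_per_day)
                    }),
      day = c(day_grid, rep(NA_real_,
                            config$n_knockdowns * config$replicates_per_day)),
      replicate = c(rep(seq_len(config$replicates_per_day), length(config$days)),
                    if (config$n_knockdowns > 0) {
                      rep(seq_len(config$replicates_per_day), config$n_knockdowns)
                    }),
      stringsAsFactors = FALSE
    )

    base_log <- stats::rnorm(config$n_genes, mean = log(5), sd = 1.5)
    # orthonormal loadings concentrated on a random signal-gene subset, so
    # the latent geometry lifts isometrically and most-variable-gene
    # selection finds both axes
    signal <- sample(config$n_genes, config$n_signal_genes)
    loadings <- matrix(0, config$n_genes, 2)
    loadings[signal, ] <- qr.Q(qr(matrix(stats::rnorm(config$n_signal_genes * 2),
                                         config$n_signal_genes, 2)))

    log_mu <- base_log + config$loading_scale * (loadings %*% t(latent))
    clipped <- log_mu > 50
    if (any(clipped)) {
      log_mu[clipped] <- 50
      warning("extreme latent offsets produced overflowing gene means; clipped")
    }
    mu <- exp(log_mu)
    mu <- sweep(mu, 2, colSums(mu), "/") * config$library_size
    mu <- pmax(mu, 1e-12)

    n <- length(mu)
    counts <- if (config$dispersion == 0) {
      stats::rpois(n, lambda = mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    counts <- matrix(counts, nrow = config$n_genes,
                     dimnames = list(sprintf("gene_%04d", seq_len(config$n_genes)),
                                     samples$sample))

    truth <- data.frame(
      target = config$knockdowns,
      progression = config$planted_progression,
      offset = config$orthogonal_offset,
      latent_u = if (config$n_knockdowns > 0) kd_base[, 1] + 0 else numeric(0),
      latent_v = if (config$n_knockdowns > 0) kd_base[, 2] + 0 else numeric(0),
      stringsAsFactors = FALSE
    )

    structure(list(counts = counts, samples = samples, truth = truth,
                   config = config),
              class = "timecourse_sim")
  })
}
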