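#' Configuration for synthetic colony-count experiments
#'
#' Single- and double-knockdown colony counts under a multiplicative
#' interaction model: the control condition has mean `control_mean`, a single
#' knockdown of gene \eqn{a} scales it by \eqn{e_a}, and a double knockdown
#' of \eqn{a} and \eqn{b} has mean
#' \eqn{control\_mean \cdot e_a \cdot e_b \cdot \gamma_{ab}}, where
#' \eqn{\gamma = 1} means the two genes act independently. Replicate noise is
#' multiplicative lognormal with coefficient of variation `cv` (mean
#' preserved), matching the positive support of colony counts.
#'
#' @param control_mean Expected colonies per well in the control (default 100).
#' @param single_effects Named vector of single-knockdown ratios
#'   \eqn{e_a \in (0, \infty)}.
#' @param interaction_gamma Named vector of pair interaction ratios, names
#'   `"a:b"` referring to entries of `single_effects`; 1 = no interaction.
#' @param cv Coefficient of variation of the lognormal replicate noise
#'   (default 0.1).
#' @param n_replicates Biological replicates per condition (default 6).
#' @param seed Integer seed.
#' @return An object of class `colony_sim_config`.
#' @export
colony_sim_config <- function(control_mean = 100,
                              single_effects = c(geneA = 0.5, geneB = 0.6),
                              interaction_gamma = c("geneA:geneB" = 1),
                              cv = 0.1, n_replicates = 6, seed = 1) {
  if (is.null(names(single_effects)) || any(!nzchar(names(single_effects)))) {
    stop("'single_effects' must be a named vector", call. = FALSE)
  }
  if (any(single_effects <= 0)) {
    stop("'single_effects' must be positive ratios", call. = FALSE)
  }
  pairs <- strsplit(names(interaction_gamma), ":", fixed = TRUE)
  if (length(interaction_gamma) > 0 &&
      (any(lengths(pairs) != 2) ||
       !all(unlist(pairs) %in% names(single_effects)))) {
    stop("every pair in 'interaction_gamma' must name two entries of 'single_effects' as \"a:b\"",
         call. = FALSE)
  }
  if (any(interaction_gamma <= 0)) {
    stop("'interaction_gamma' must be positive", call. = FALSE)
  }
  structure(list(
    control_mean = check_positive(control_mean, "control_mean"),
    single_effects = single_effects,
    interaction_gamma = interaction_gamma,
    cv = check_positive(cv, "cv", strict = FALSE),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "colony_sim_config")
}

#' Simulate colony counts for control, single and double knockdowns
#'
#' Draws replicate colony counts from the multiplicative model described in
#' [colony_sim_config()]. With `cv = 0` counts equal their expectation
#' exactly, so the product rule can be checked in closed form.
#'
#' @param config A [colony_sim_config()].
#' @return A data frame `condition`, `replicate`, `count` with conditions
#'   `control`, `single:<a>` and `double:<a>+<b>`, of class `colony_sim`.
#' @export
#' @examples
#' cfg <- colony_sim_config(cv = 0)
#' generate_colony_counts(cfg)
generate_colony_counts <- function(config) {
  stopifnot(inherits(config, "colony_sim_config"))
  with_seed(config$seed, {
    e <- config$single_effects
    means <- c(control = config$control_mean,
               stats::setNames(config$control_mean * e,
                               sprintf("single:%s", names(e))))
    if (length(config$interaction_gamma) > 0) {
      pairs <- strsplit(names(config$interaction_gamma), ":", fixed = TRUE)
      dbl <- vapply(seq_along(pairs), function(i) {
        config$control_mean * e[[pairs[[i]][1]]] * e[[pairs[[i]][2]]] *
          config$interaction_gamma[[i]]
      }, numeric(1))
      names(dbl) <- sprintf("double:%s+%s",
                            vapply(pairs, `[`, character(1), 1),
                            vapply(pairs, `[`, character(1), 2))
      means <- c(means, dbl)
    }
    n <- config$n_replicates
    # lognormal with E = mean and CV = cv: sdlog^2 = log(1 + cv^2)
    sdlog <- sqrt(log(1 + config$cv^2))
    counts <- unlist(lapply(means, function(m) {
      if (config$cv == 0) rep(m, n)
      else m * exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
    }), use.names = FALSE)
    structure(data.frame(
      condition = rep(names(means), each = n),
      replicate = rep(seq_len(n), length(means)),
      count = counts,
      stringsAsFactors = FALSE
    ), class = c("colony_sim", "data.frame"))
  })
}
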