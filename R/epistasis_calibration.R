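#' Monte-Carlo calibration of the interaction test
#'
#' Simulates many independent gene pairs from the multiplicative colony
#' model at a fixed interaction ratio `gamma` and reports how often the
#' interaction test rejects at level `alpha`. With `gamma = 1` this measures
#' the type-I error, which should sit near `alpha`; with `gamma != 1` it
#' measures power.
#'
#' @param n_pairs Number of simulated pairs (default 1000).
#' @param gamma True interaction ratio (default 1, the null).
#' @param single_effects Length-2 vector of the two single-knockdown ratios
#'   (default `c(0.5, 0.6)`).
#' @param cv Lognormal coefficient of variation (default 0.1).
#' @param n_replicates Replicates per condition (default 6).
#' @param control_mean Control colony mean (default 100).
#' @param alpha Test level (default 0.05).
#' @param method Variance treatment passed to [test_interaction()].
#' @param seed Integer seed.
#' @return List: `rejection_rate`, `n_pairs`, `gamma`, `alpha`, `method`,
#'   `p_values`.
#' @export
epistasis_calibration <- function(n_pairs = 1000, gamma = 1,
                                  single_effects = c(0.5, 0.6), cv = 0.1,
                                  n_replicates = 6, control_mean = 100,
                                  alpha = 0.05, method = "delta", seed = 1) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  stopifnot(length(single_effects) == 2)
  pair_seeds <- with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, n_pairs, replace = n_pairs > 1e6)
  })
  pvals <- vapply(seq_len(n_pairs), function(i) {
    cfg <- colony_sim_config(
      control_mean = control_mean,
      single_effects = c(a = single_effects[[1]], b = single_effects[[2]]),
      interaction_gamma = c("a:b" = gamma),
      cv = cv, n_replicates = n_replicates, seed = pair_seeds[i])
    counts <- generate_colony_counts(cfg)
    by_cond <- split(counts$count, counts$condition)
    test_interaction(by_cond[["double:a+b"]], by_cond[["single:a"]],
                     by_cond[["single:b"]], by_cond[["control"]],
                     alpha = alpha, method = method)$p_value
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), n_pairs = n_pairs,
       gamma = gamma, alpha = alpha, method = method, p_values = pvals)
}
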