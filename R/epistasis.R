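#' Per-replicate colony ratios relative to the control mean
#'
#' Divides each replicate count of a condition by the mean colony count of
#' the control condition, the normalization used for single- and
#' double-knockdown colony assays.
#'
#' @param counts Replicate colony counts of the condition.
#' @param control_counts Replicate colony counts of the control.
#' @return Numeric vector of per-replicate ratios.
#' @export
colony_ratio <- function(counts, control_counts) {
  if (any(counts < 0) || any(control_counts < 0)) {
    stop("colony counts must be non-negative", call. = FALSE)
  }
  cm <- mean(control_counts)
  if (!is.finite(cm) || cm <= 0) {
    stop("control mean must be positive", call. = FALSE)
  }
  counts / cm
}

#' Expected double-knockdown ratio under the multiplicative model
#'
#' If two genes act independently, the double-knockdown colony ratio is the
#' product of the two single-knockdown mean ratios.
#'
#' @param ratio_a,ratio_b Mean single-knockdown ratios (scalars or replicate
#'   vectors, which are averaged).
#' @return The expected double-knockdown ratio.
#' @export
expected_double_ratio <- function(ratio_a, ratio_b) {
  mean(ratio_a) * mean(ratio_b)
}

#' Test a gene pair for functional interaction
#'
#' Compares observed double-knockdown colony ratios with the ratio expected
#' from the multiplicative model via a two-tailed t-test on the mean
#' difference (observed - expected). A significant positive difference means
#' more colonies than expected — an alleviating interaction placing the two
#' genes in a shared pathway; a negative one means an aggravating
#' interaction.
#'
#' Two variance treatments are available. `"delta"` (default) propagates the
#' sampling uncertainty of the expected ratio — which is estimated from the
#' single-knockdown and shared control replicates — into the standard error
#' by the delta method, with Welch-Satterthwaite degrees of freedom; this
#' keeps the type-I error near the nominal level. `"one_sample"` treats the
#' expected ratio as a known constant and runs a plain one-sample t-test of
#' the observed ratios against it; it is anti-conservative because it
#' ignores the noise in the expected value, and is provided for comparison.
#'
#' When every relevant variance is zero the test degenerates to an exact
#' comparison, flagged in the result.
#'
#' @param double_counts Replicate colony counts of the double knockdown.
#' @param single_a_counts,single_b_counts Replicate counts of the two single
#'   knockdowns.
#' @param control_counts Replicate counts of the control.
#' @param alpha Significance level (default 0.05).
#' @param method `"delta"` or `"one_sample"`.
#' @return List of class `epistasis_result`: `observed_ratios`,
#'   `observed_mean`, `expected`, `difference`, `statistic`, `df`,
#'   `p_value`, `significant`, `method`, `degenerate`, `alpha`.
#' @export
test_interaction <- function(double_counts, single_a_counts, single_b_counts,
                             control_counts, alpha = 0.05,
                             method = c("delta", "one_sample")) {
  method <- match.arg(method)
  if (length(double_counts) < 2) {
    stop("need at least 2 double-knockdown replicates", call. = FALSE)
  }
  obs <- colony_ratio(double_counts, control_counts)
  ra <- colony_ratio(single_a_counts, control_counts)
  rb <- colony_ratio(single_b_counts, control_counts)
  expected <- expected_double_ratio(ra, rb)
  diff <- mean(obs) - expected

  var_mean <- function(x) stats::var(x) / length(x)
  c_bar <- mean(control_counts)
  d_bar <- mean(double_counts)
  a_bar <- mean(single_a_counts)
  b_bar <- mean(single_b_counts)

  if (method == "delta") {
    # gradient of d/c - a*b/c^2 in the four group means
    g <- c(d = 1 / c_bar,
           a = -b_bar / c_bar^2,
           b = -a_bar / c_bar^2,
           c = -d_bar / c_bar^2 + 2 * a_bar * b_bar / c_bar^3)
    comp <- c(d = g[["d"]]^2 * var_mean(double_counts),
              a = g[["a"]]^2 * var_mean(single_a_counts),
              b = g[["b"]]^2 * var_mean(single_b_counts),
              c = g[["c"]]^2 * var_mean(control_counts))
    se2 <- sum(comp)
    if (se2 == 0) {
      return(structure(list(
        observed_ratios = obs, observed_mean = mean(obs), expected = expected,
        difference = diff, statistic = NA_real_, df = NA_real_,
        p_value = if (abs(diff) < 1e-12) 1 else 0,
        significant = abs(diff) >= 1e-12, method = method,
        degenerate = TRUE, alpha = alpha), class = "epistasis_result"))
    }
    dfs <- c(length(double_counts), length(single_a_counts),
             length(single_b_counts), length(control_counts)) - 1
    df <- se2^2 / sum(comp^2 / dfs)
    tstat <- diff / sqrt(se2)
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    if (stats::var(obs) == 0) {
      return(structure(list(
        observed_ratios = obs, observed_mean = mean(obs), expected = expected,
        difference = diff, statistic = NA_real_, df = NA_real_,
        p_value = if (abs(diff) < 1e-12) 1 else 0,
        significant = abs(diff) >= 1e-12, method = method,
        degenerate = TRUE, alpha = alpha), class = "epistasis_result"))
    }
    tt <- stats::t.test(obs, mu = expected)
    tstat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(
    observed_ratios = obs, observed_mean = mean(obs), expected = expected,
    difference = diff, statistic = tstat, df = df, p_value = p,
    significant = p < alpha, method = method, degenerate = FALSE,
    alpha = alpha
  ), class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf(
    "epistasis test (%s): observed %.4f vs expected %.4f (diff %+.4f)\n",
    x$method, x$observed_mean, x$expected, x$difference))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.4g%s%s\n",
              x$statistic %||% NA, x$df %||% NA, x$p_value,
              if (isTRUE(x$significant)) " *" else "",
              if (isTRUE(x$degenerate)) " [degenerate: exact comparison]"
              else ""))
  invisible(x)
}

#' Epistasis analysis of a colony-count table
#'
#' Runs [test_interaction()] for every `double:<a>+<b>` condition in a
#' colony-count table that also contains `control` and the matching
#' `single:<a>`, `single:<b>` conditions.
#'
#' @param counts Data frame `condition`, `replicate`, `count` (the format
#'   written by [generate_colony_counts()]).
#' @param alpha Significance level (default 0.05).
#' @param method Variance treatment, see [test_interaction()].
#' @return Data frame with one row per pair: `pair`, `observed`, `expected`,
#'   `difference`, `statistic`, `df`, `p_value`, `significant`; the full
#'   result objects are in `attr(, "results")`.
#' @export
epistasis_analysis <- function(counts, alpha = 0.05, method = "delta") {
  need <- c("condition", "replicate", "count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns condition, replicate, count", call. = FALSE)
  }
  split_counts <- split(counts$count, counts$condition)
  if (!"control" %in% names(split_counts)) {
    stop("no 'control' condition present", call. = FALSE)
  }
  doubles <- grep("^double:", names(split_counts), value = TRUE)
  if (length(doubles) == 0) stop("no 'double:<a>+<b>' conditions present",
                                 call. = FALSE)
  res <- lapply(doubles, function(d) {
    genes <- strsplit(sub("^double:", "", d), "+", fixed = TRUE)[[1]]
    singles <- sprintf("single:%s", genes)
    if (!all(singles %in% names(split_counts))) {
      stop(sprintf("missing single knockdowns for %s", d), call. = FALSE)
    }
    test_interaction(split_counts[[d]], split_counts[[singles[1]]],
                     split_counts[[singles[2]]], split_counts[["control"]],
                     alpha = alpha, method = method)
  })
  names(res) <- sub("^double:", "", doubles)
  out <- data.frame(
    pair = names(res),
    observed = vapply(res, `[[`, numeric(1), "observed_mean"),
    expected = vapply(res, `[[`, numeric(1), "expected"),
    difference = vapply(res, `[[`, numeric(1), "difference"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    significant = vapply(res, `[[`, logical(1), "significant"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "results") <- res
  out
}
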