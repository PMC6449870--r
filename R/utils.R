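# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' package functions never perturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a random positive scores above a random negative,
#' counting ties as 1/2.
#' @noRd
rank_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  ok <- is.finite(score)
  score <- score[ok]
  label <- as.logical(label)[ok]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Assert a scalar count
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' Assert a scalar positive number
#' @noRd
check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (strict && x <= 0) ||
      (!strict && x < 0)) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  as.numeric(x)
}

#' Columns of a plate table that hold features
#' @noRd
feature_columns <- function(table) {
  grep("^feature_", names(table), value = TRUE)
}

#' Fix the sign of a PCA loading/score pair deterministically
#'
#' Flips the pair so the loading entry with the largest magnitude is positive.
#' @noRd
fix_sign <- function(scores, loading) {
  i <- which.max(abs(loading))
  if (loading[i] < 0) list(scores = -scores, loading = -loading)
  else list(scores = scores, loading = loading)
}
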