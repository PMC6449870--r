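#' Z-score feature tables per plate
#'
#' Standardizes every feature on every physical plate to mean 0, SD 1 across
#' all wells of that plate (controls included), removing additive plate batch
#' effects. The SD is the sample SD (denominator n - 1). When a `replicate`
#' column is present each replicate of a library plate is treated as its own
#' physical plate, since replicate transfections are imaged as separate
#' plates.
#'
#' Features that are constant on a plate are degenerate there: they are set
#' to 0 on that plate and a warning names them, since a feature with no
#' within-plate variation carries no phenotypic signal.
#'
#' @param table Long plate table with columns `plate`, `well`, `target`,
#'   optionally `replicate` and `role`, and `feature_*` numeric columns.
#' @return The table with every `feature_*` column Z-scored within plate.
#' @export
#' @examples
#' sim <- generate_screen(screen_sim_config(n_targets = 12, n_plates = 1,
#'                                          n_replicates = 2, seed = 1))
#' z <- zscore_by_plate(sim$tables)
#' round(colMeans(z[z$plate == "plate_1" & z$replicate == 1, -(1:5)]), 12)
zscore_by_plate <- function(table) {
  feats <- feature_columns(table)
  if (length(feats) == 0) stop("no 'feature_*' columns found", call. = FALSE)
  if (!all(c("plate", "well") %in% names(table))) {
    stop("table must have 'plate' and 'well' columns", call. = FALSE)
  }
  group <- if ("replicate" %in% names(table)) {
    interaction(table$plate, table$replicate, drop = TRUE)
  } else {
    factor(table$plate)
  }
  if (anyDuplicated(interaction(group, table$well, drop = TRUE))) {
    stop("duplicate well ids within a plate", call. = FALSE)
  }
  if (min(table(group)) < 3) {
    stop("each plate must have at least 3 wells", call. = FALSE)
  }
  degenerate <- character(0)
  for (f in feats) {
    x <- table[[f]]
    if (!is.numeric(x)) stop(sprintf("feature '%s' is not numeric", f),
                             call. = FALSE)
    m <- stats::ave(x, group, FUN = function(v) mean(v, na.rm = TRUE))
    s <- stats::ave(x, group, FUN = function(v) stats::sd(v, na.rm = TRUE))
    z <- (x - m) / s
    bad <- !is.na(s) & s == 0
    if (any(bad)) {
      degenerate <- c(degenerate, f)
      z[bad] <- 0
    }
    table[[f]] <- z
  }
  if (length(degenerate) > 0) {
    warning(sprintf("constant on at least one plate, set to 0 there: %s",
                    paste(unique(degenerate), collapse = ", ")))
  }
  table
}

#' Average replicate wells into per-target feature profiles
#'
#' Collapses Z-scored well tables to one profile per target by the
#' arithmetic mean over all wells carrying that target — across replicates
#' and, for controls present on several plates, across plates. Missing values
#' are skipped and the number of wells actually averaged is recorded per
#' target. Targets with no finite value in any replicate are dropped with a
#' warning.
#'
#' @param ztable Z-scored long table as returned by [zscore_by_plate()].
#' @return An object of class `feature_profiles`: list with `profiles`
#'   (target-by-feature matrix), `n_replicates` (wells averaged per target)
#'   and `role` (per-target role flag).
#' @export
average_replicates <- function(ztable) {
  feats <- feature_columns(ztable)
  if (!"target" %in% names(ztable)) stop("missing 'target' column",
                                         call. = FALSE)
  tgt <- factor(ztable$target, levels = unique(ztable$target))
  mat <- as.matrix(ztable[feats])
  profiles <- apply(mat, 2, function(x) {
    tapply(x, tgt, function(v) mean(v, na.rm = TRUE))
  })
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, ncol = length(feats),
                       dimnames = list(levels(tgt), feats))
  }
  n_rep <- tapply(rowSums(is.finite(mat)) > 0, tgt, sum)
  # wells with at least one finite feature count toward the replicate tally
  empty <- !is.finite(profiles)
  profiles[empty] <- NA_real_
  all_missing <- rowSums(is.finite(profiles)) == 0
  if (any(all_missing)) {
    warning(sprintf("targets with no finite values dropped: %s",
                    paste(rownames(profiles)[all_missing], collapse = ", ")))
    profiles <- profiles[!all_missing, , drop = FALSE]
    n_rep <- n_rep[!all_missing]
  }
  role <- if ("role" %in% names(ztable)) {
    vapply(split(as.character(ztable$role), tgt), `[`, character(1), 1)
  } else {
    stats::setNames(rep("library", nlevels(tgt)), levels(tgt))
  }
  structure(list(profiles = profiles,
                 n_replicates = as.integer(n_rep[rownames(profiles)]) |>
                   stats::setNames(rownames(profiles)),
                 role = role[rownames(profiles)]),
            class = "feature_profiles")
}

#' @export
print.feature_profiles <- function(x, ...) {
  cat(sprintf("feature_profiles: %d targets x %d features\n",
              nrow(x$profiles), ncol(x$profiles)))
  cat(sprintf("roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  invisible(x)
}

#' Drop redundant features by pairwise correlation
#'
#' Two features whose absolute Pearson correlation across targets exceeds
#' `threshold` are redundant; only one is kept. Features are scanned in
#' order of decreasing variance across targets (ties broken by feature name)
#' and a feature is retained only if its absolute correlation with every
#' feature already retained is at most `threshold`, so the higher-variance —
#' more informative — member of each redundant group survives. Zero-variance
#' features are dropped up front with a warning. The retained set has
#' maximum pairwise |r| <= threshold and the operation is idempotent.
#'
#' @param profiles A `feature_profiles` object or a target-by-feature matrix.
#' @param threshold Redundancy cutoff on |Pearson r|, in (0, 1] (default 0.8).
#' @return A list: `retained` (feature names in original column order) and
#'   `profiles` (input reduced to the retained features, same class as the
#'   input).
#' @export
select_features <- function(profiles, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0 ||
      threshold > 1) {
    stop("'threshold' must be in (0, 1]", call. = FALSE)
  }
  mat <- if (inherits(profiles, "feature_profiles")) profiles$profiles
         else as.matrix(profiles)
  if (ncol(mat) < 2) stop("need at least 2 features", call. = FALSE)
  v <- apply(mat, 2, stats::var, na.rm = TRUE)
  zero_var <- !is.finite(v) | v == 0
  if (any(zero_var)) {
    warning(sprintf("zero-variance features dropped: %s",
                    paste(colnames(mat)[zero_var], collapse = ", ")))
  }
  candidates <- colnames(mat)[!zero_var]
  candidates <- candidates[order(-v[candidates], candidates)]
  kept <- character(0)
  for (f in candidates) {
    if (length(kept) == 0) {
      kept <- f
      next
    }
    r <- suppressWarnings(
      abs(stats::cor(mat[, f], mat[, kept, drop = FALSE],
                     use = "pairwise.complete.obs")))
    if (all(is.na(r) | r <= threshold)) kept <- c(kept, f)
  }
  retained <- colnames(mat)[colnames(mat) %in% kept]
  out_mat <- mat[, retained, drop = FALSE]
  out <- if (inherits(profiles, "feature_profiles")) {
    structure(list(profiles = out_mat,
                   n_replicates = profiles$n_replicates,
                   role = profiles$role),
              class = "feature_profiles")
  } else {
    out_mat
  }
  list(retained = retained, profiles = out)
}
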