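#' Correlate each knockdown profile to the positive-control phenotypes
#'
#' Pearson correlation of every library target's feature Z-vector with each
#' positive control's replicate-averaged Z-vector, over the retained
#' features. A knockdown that phenocopies a control for a key reprogramming
#' gene is itself a candidate reprogramming regulator.
#'
#' @param profiles A `feature_profiles` object (controls included as rows).
#' @param controls Control target labels; default the positive controls
#'   `Trp53`, `Myc`, `Oct4`.
#' @return Data frame: `target` plus one `r_<control>` column each. Targets
#'   with a constant profile get `NA` with a warning.
#' @export
correlate_to_controls <- function(profiles,
                                  controls = c("Trp53", "Myc", "Oct4")) {
  mat <- if (inherits(profiles, "feature_profiles")) profiles$profiles
         else as.matrix(profiles)
  if (ncol(mat) < 3) stop("need at least 3 shared features", call. = FALSE)
  missing_ctrl <- setdiff(controls, rownames(mat))
  if (length(missing_ctrl) > 0) {
    stop(sprintf("control profiles absent: %s",
                 paste(missing_ctrl, collapse = ", ")), call. = FALSE)
  }
  targets <- setdiff(rownames(mat), controls)
  ctrl_mat <- t(mat[controls, , drop = FALSE])
  tgt_mat <- t(mat[targets, , drop = FALSE])
  sds <- apply(tgt_mat, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(tgt_mat, ctrl_mat,
                                   use = "pairwise.complete.obs"))
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("constant profiles, correlation undefined: %s",
                    paste(targets[sds == 0], collapse = ", ")))
  }
  out <- data.frame(target = targets, stringsAsFactors = FALSE)
  for (j in seq_along(controls)) out[[paste0("r_", controls[j])]] <- r[, j]
  out
}

#' Combine per-control correlations into one ranking score
#'
#' The single control-similarity score per knockdown is the arithmetic mean
#' of the available control correlations (`method = "mean"`, the default) or
#' their maximum. Missing correlations are skipped; if all are missing the
#' score is `NA`.
#'
#' @param correlations Data frame from [correlate_to_controls()], or a
#'   numeric matrix/vector of correlations.
#' @param method `"mean"` or `"max"`.
#' @return Numeric vector of combined scores (named by target when
#'   available), bounded in \[-1, 1\].
#' @export
combine_control_scores <- function(correlations, method = c("mean", "max")) {
  method <- match.arg(method)
  if (is.data.frame(correlations)) {
    rmat <- as.matrix(correlations[grep("^r_", names(correlations))])
    rownames(rmat) <- correlations$target
  } else {
    rmat <- if (is.matrix(correlations)) correlations
            else matrix(correlations, nrow = 1)
  }
  score <- apply(rmat, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_
    else if (method == "mean") mean(v) else max(v)
  })
  score
}

#' Train the facilitator-prediction ensemble
#'
#' Trains two independent classifier families on the high-content profiles of
#' known reprogramming facilitators — a ridge-regularized logistic model and
#' a probability random forest — treating every unlabelled library target as
#' a negative. Each model emits a score in \[0, 1\]; the ensemble score is
#' their mean. Forest scores for the training targets are out-of-bag, and the
#' logistic scores come from the regularized in-sample fit. Generalization is
#' reported as stratified k-fold cross-validated AUC of the ensemble.
#'
#' @param profiles A `feature_profiles` object or target-by-feature matrix;
#'   when roles are available only `library` targets are used.
#' @param facilitators Character vector of known facilitator target labels
#'   (at least 3 must be present in the profiles).
#' @param seed Integer seed controlling folds and forest randomness.
#' @param n_folds Cross-validation folds (default 5).
#' @param num_trees Trees in the forest (default 300).
#' @return List of class `facilitator_predictor`: `scores` (named ensemble
#'   scores for all library targets), `scores_linear`, `scores_forest`,
#'   `cv_auc` (ensemble), `cv_auc_linear`, `cv_auc_forest`, `labels`.
#' @export
train_facilitator_predictor <- function(profiles, facilitators, seed = 1,
                                        n_folds = 5, num_trees = 300) {
  mat <- if (inherits(profiles, "feature_profiles")) {
    profiles$profiles[profiles$role == "library", , drop = FALSE]
  } else {
    as.matrix(profiles)
  }
  if (anyNA(mat)) stop("profiles contain missing values", call. = FALSE)
  y <- as.integer(rownames(mat) %in% facilitators)
  if (sum(y) < 3) stop("need at least 3 known facilitators among the profiles",
                       call. = FALSE)
  if (sum(y == 0) < 3) stop("need at least 3 negative (unlabelled) targets",
                            call. = FALSE)

  fit_pair <- function(x_train, y_train, x_test, tree_seed) {
    # small positive classes are expected in a screen; glmnet warns about them
    lin <- suppressWarnings(
      glmnet::glmnet(x_train, y_train, family = "binomial", alpha = 0,
                     lambda = 0.05))
    p_lin <- as.numeric(stats::predict(lin, x_test, type = "response"))
    rf <- ranger::ranger(x = x_train, y = factor(y_train, levels = c(0, 1)),
                         probability = TRUE, num.trees = num_trees,
                         seed = tree_seed)
    p_rf <- stats::predict(rf, data = x_test)$predictions[, "1"]
    cbind(linear = p_lin, forest = p_rf)
  }

  with_seed(seed, {
    # full-data scores: regularized in-sample logistic + out-of-bag forest
    lin <- suppressWarnings(
      glmnet::glmnet(mat, y, family = "binomial", alpha = 0, lambda = 0.05))
    p_lin <- as.numeric(stats::predict(lin, mat, type = "response"))
    rf <- ranger::ranger(x = mat, y = factor(y, levels = c(0, 1)),
                         probability = TRUE, num.trees = num_trees,
                         seed = seed, oob.error = TRUE)
    p_rf <- rf$predictions[, "1"]
    # rows never OOB (tiny forests) fall back to in-bag prediction
    nas <- !is.finite(p_rf)
    if (any(nas)) {
      p_rf[nas] <- stats::predict(rf, data = mat[nas, , drop = FALSE]
                                  )$predictions[, "1"]
    }

    # stratified k-fold CV of the ensemble
    folds <- integer(length(y))
    folds[y == 1] <- sample(rep_len(seq_len(n_folds), sum(y == 1)))
    folds[y == 0] <- sample(rep_len(seq_len(n_folds), sum(y == 0)))
    cv_pred <- matrix(NA_real_, length(y), 2,
                      dimnames = list(NULL, c("linear", "forest")))
    for (f in seq_len(n_folds)) {
      test <- folds == f
      if (length(unique(y[!test])) < 2) next
      cv_pred[test, ] <- fit_pair(mat[!test, , drop = FALSE], y[!test],
                                  mat[test, , drop = FALSE],
                                  tree_seed = seed + f)
    }
    ens_cv <- rowMeans(cv_pred)

    structure(list(
      scores = stats::setNames((p_lin + p_rf) / 2, rownames(mat)),
      scores_linear = stats::setNames(p_lin, rownames(mat)),
      scores_forest = stats::setNames(p_rf, rownames(mat)),
      cv_auc = rank_auc(ens_cv, y),
      cv_auc_linear = rank_auc(cv_pred[, "linear"], y),
      cv_auc_forest = rank_auc(cv_pred[, "forest"], y),
      labels = stats::setNames(y, rownames(mat))
    ), class = "facilitator_predictor")
  })
}

#' Build the two-axis ranking table
#'
#' Combines the control-correlation axis and the machine-learning
#' facilitator axis into one table per library target.
#'
#' @param profiles A `feature_profiles` object (after feature selection).
#' @param facilitators Known facilitator labels for the ML axis; `NULL`
#'   skips the ML score.
#' @param controls Positive-control labels.
#' @param seed Integer seed for the predictor.
#' @param combine Combination rule for control correlations.
#' @return Data frame of class `ranking_table`: `target`, `r_<control>`
#'   columns, `combined_score`, `ml_score`, `selected` (all `FALSE` until
#'   [select_hits()]).
#' @export
build_ranking_table <- function(profiles, facilitators = NULL,
                                controls = c("Trp53", "Myc", "Oct4"),
                                seed = 1, combine = "mean") {
  if (inherits(profiles, "feature_profiles")) {
    # rank library knockdowns only; nt wells are controls, not candidates
    keep <- profiles$role %in% c("library") |
      names(profiles$role) %in% controls
    profiles <- structure(list(
      profiles = profiles$profiles[keep, , drop = FALSE],
      n_replicates = profiles$n_replicates[keep],
      role = profiles$role[keep]), class = "feature_profiles")
  }
  corr <- correlate_to_controls(profiles, controls)
  corr$combined_score <- combine_control_scores(corr, method = combine)
  if (!is.null(facilitators)) {
    pred <- train_facilitator_predictor(profiles, facilitators, seed = seed)
    corr$ml_score <- pred$scores[corr$target]
    attr(corr, "cv_auc") <- pred$cv_auc
  } else {
    corr$ml_score <- NA_real_
  }
  corr$selected <- FALSE
  class(corr) <- c("ranking_table", "data.frame")
  corr
}

#' Select screen hits in the two-dimensional score space
#'
#' Takes the union of (i) the `n_corr_top` targets with the highest combined
#' control-correlation score, (ii) targets at or above the `ml_quantile`
#' quantile of the ML facilitator score, and (iii) an optional user-supplied
#' inclusion list of low-ranking candidates (potential roadblocks), then
#' deduplicates and flags them.
#'
#' @param ranking A `ranking_table` from [build_ranking_table()].
#' @param n_corr_top Number of top correlation-ranked targets (default 20).
#' @param ml_quantile Quantile of the ML score above which targets are
#'   selected (default 0.95); ignored when no ML scores exist.
#' @param include Extra target labels to force into the hit list.
#' @return The ranking table with `selected` flags set; the hit labels are in
#'   `attr(, "hits")`.
#' @export
select_hits <- function(ranking, n_corr_top = 20, ml_quantile = 0.95,
                        include = NULL) {
  stopifnot(inherits(ranking, "ranking_table"))
  n_corr_top <- check_count(n_corr_top, "n_corr_top", min = 0L)
  if (n_corr_top > nrow(ranking)) {
    stop("'n_corr_top' exceeds the number of targets", call. = FALSE)
  }
  by_corr <- ranking$target[order(-ranking$combined_score)][
    seq_len(n_corr_top)]
  by_ml <- character(0)
  if (any(is.finite(ranking$ml_score))) {
    cut <- stats::quantile(ranking$ml_score, ml_quantile, na.rm = TRUE,
                           names = FALSE)
    by_ml <- ranking$target[is.finite(ranking$ml_score) &
                              ranking$ml_score >= cut]
  }
  hits <- unique(c(by_corr, by_ml, intersect(include, ranking$target)))
  ranking$selected <- ranking$target %in% hits
  attr(ranking, "hits") <- hits
  attr(ranking, "hits_by_correlation") <- by_corr
  attr(ranking, "hits_by_ml") <- by_ml
  ranking
}
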