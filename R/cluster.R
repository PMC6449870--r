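#' K-means clustering of knockdown phenotype profiles
#'
#' Partitions per-target feature Z-profiles into `k` phenotype classes with
#' K-means (Euclidean metric, multiple random restarts, deterministic given
#' `seed`). Rows with missing values are not allowed; filter or impute
#' upstream.
#'
#' @param profiles A `feature_profiles` object or target-by-feature matrix.
#' @param k Number of clusters (default 5, the number of major colony
#'   phenotypes the method is designed around).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts (default 25).
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector), `k`, `centers` (k-by-feature matrix),
#'   `withinss` and `tot_withinss`.
#' @export
cluster_knockdowns <- function(profiles, k = 5, seed = 1, nstart = 25) {
  mat <- if (inherits(profiles, "feature_profiles")) profiles$profiles
         else as.matrix(profiles)
  k <- check_count(k, "k", min = 2L)
  if (k >= nrow(mat)) stop("'k' must be smaller than the number of targets",
                           call. = FALSE)
  if (anyNA(mat)) stop("profiles contain missing values; filter features first",
                       call. = FALSE)
  fit <- with_seed(seed, stats::kmeans(mat, centers = k, nstart = nstart,
                                       iter.max = 100))
  structure(list(cluster = stats::setNames(fit$cluster, rownames(mat)),
                 k = k,
                 centers = fit$centers,
                 withinss = fit$withinss,
                 tot_withinss = fit$tot.withinss),
            class = "cluster_assignment")
}

#' Hierarchical clustering of features for display ordering
#'
#' Clusters feature columns by Euclidean distance with average linkage and
#' returns the merge tree plus the leaf order used to arrange heatmap
#' columns. Display-only: downstream scores do not depend on this ordering.
#'
#' @param profiles A `feature_profiles` object or target-by-feature matrix.
#' @return List with `hclust` (the merge tree) and `order` (feature names in
#'   leaf order).
#' @export
cluster_features <- function(profiles) {
  mat <- if (inherits(profiles, "feature_profiles")) profiles$profiles
         else as.matrix(profiles)
  if (ncol(mat) < 2) stop("need at least 2 features", call. = FALSE)
  d <- stats::dist(t(mat), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = colnames(mat)[hc$order])
}

#' Summarize phenotype clusters against control identities
#'
#' Reports, per cluster, its size, mean feature Z-vector and how many nt and
#' positive-control wellsets it absorbed, and flags the cluster holding the
#' majority of nt controls as the reference ("normal reprogramming")
#' phenotype.
#'
#' @param assignment A `cluster_assignment` from [cluster_knockdowns()].
#' @param profiles The `feature_profiles` the assignment was computed on
#'   (supplies the per-target role flags).
#' @return List with `table` (per-cluster data frame: `cluster`, `size`,
#'   `n_nt`, one column per positive control, `is_reference`) and `centers`
#'   (mean Z-vectors).
#' @export
summarize_clusters <- function(assignment, profiles) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  role <- if (inherits(profiles, "feature_profiles")) profiles$role
          else stop("'profiles' must be a feature_profiles object",
                    call. = FALSE)
  cl <- assignment$cluster
  role <- role[names(cl)]
  nt_targets <- names(cl)[role == "nt"]
  pc_targets <- names(cl)[role == "positive"]

  sizes <- tabulate(cl, nbins = assignment$k)
  tab <- data.frame(cluster = seq_len(assignment$k), size = sizes,
                    n_nt = vapply(seq_len(assignment$k), function(i) {
                      sum(cl[nt_targets] == i)
                    }, integer(1)))
  for (p in pc_targets) tab[[p]] <- as.integer(cl[p] == tab$cluster)

  if (length(nt_targets) == 0) {
    warning("no nt controls present; reference cluster not flagged")
    tab$is_reference <- FALSE
  } else {
    ref <- which.max(tab$n_nt)
    tab$is_reference <- tab$cluster == ref
  }
  list(table = tab, centers = assignment$centers)
}

#' Adjusted Rand index against planted class labels
#'
#' Chance-corrected agreement between a cluster assignment and ground-truth
#' labels, for parameter-recovery evaluation of synthetic screens.
#'
#' @param assignment A `cluster_assignment`, or a vector of labels.
#' @param truth Named vector of true class labels, or a `screen_sim` truth
#'   data frame with `target` and `class` columns.
#' @return The adjusted Rand index.
#' @export
cluster_recovery_ari <- function(assignment, truth) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
            else assignment
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$class, truth$target)
  }
  shared <- intersect(names(labels), names(truth))
  if (length(shared) < 2) stop("no shared targets between assignment and truth",
                               call. = FALSE)
  mclust::adjustedRandIndex(labels[shared], truth[shared])
}
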