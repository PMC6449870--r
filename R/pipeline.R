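#' Run the high-content screen stage
#'
#' Chains the screen analysis end to end: per-plate Z-scoring, replicate
#' averaging, redundant-feature elimination, K-means phenotype clustering and
#' two-axis hit ranking. Intermediate objects are returned (and optionally
#' written) so each step can be audited.
#'
#' @param tables Long plate table (from [generate_screen()] or
#'   [read_plate_tables()]).
#' @param facilitators Known facilitator labels for the ML axis (optional).
#' @param zscore_threshold Redundancy cutoff on |r| (default 0.8).
#' @param k Number of phenotype clusters (default 5).
#' @param n_corr_top Top correlation-ranked hits (default 20).
#' @param ml_quantile ML-score selection quantile (default 0.95).
#' @param controls Positive-control labels.
#' @param seed Integer seed.
#' @param out_dir Optional directory for the stage's delimited-text outputs.
#' @return List: `profiles` (reduced `feature_profiles`), `retained`,
#'   `assignment`, `cluster_summary`, `ranking` (with hit flags).
#' @export
run_screen_stage <- function(tables, facilitators = NULL,
                             zscore_threshold = 0.8, k = 5, n_corr_top = 20,
                             ml_quantile = 0.95,
                             controls = c("Trp53", "Myc", "Oct4"), seed = 1,
                             out_dir = NULL) {
  validate_plate_table(tables)
  z <- zscore_by_plate(tables)
  profiles <- average_replicates(z)
  sel <- select_features(profiles, threshold = zscore_threshold)
  assignment <- cluster_knockdowns(sel$profiles, k = k, seed = seed)
  cluster_summary <- summarize_clusters(assignment, sel$profiles)
  ranking <- build_ranking_table(sel$profiles, facilitators = facilitators,
                                 controls = controls, seed = seed)
  ranking <- select_hits(ranking, n_corr_top = n_corr_top,
                         ml_quantile = ml_quantile)
  out <- list(profiles = sel$profiles, retained = sel$retained,
              assignment = assignment, cluster_summary = cluster_summary,
              ranking = ranking)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(target = names(assignment$cluster),
                                cluster = assignment$cluster,
                                row.names = NULL),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ranking),
                     file.path(out_dir, "ranking.csv"), row.names = FALSE)
    utils::write.csv(data.frame(feature = sel$retained),
                     file.path(out_dir, "retained_features.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the transcriptome stage
#'
#' Chains log-CPM normalization, most-variable-gene selection,
#' knockdown-to-knockdown correlation, the rotated 2-D embedding with the
#' second-order time-curve fit, shortest-distance projection into a
#' progression report, and — when high-content profiles are supplied —
#' cross-modal concordance.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample sheet with `sample`, `condition`, `day` (`NA` for
#'   knockdowns).
#' @param profiles Optional `feature_profiles` for cross-modal concordance.
#' @param n_top Number of most variable genes (default 200).
#' @param angle Rotation angle in degrees (default 15).
#' @param fit_days Day interval for the curve fit (default `c(2, 7)`).
#' @param reference Reference (nt control) condition label for delay calls.
#' @param delay_threshold Days behind the reference flagged as delayed.
#' @param out_dir Optional output directory.
#' @return List: `lognorm`, `genes`, `expr_corr`, `embedding` (rotated),
#'   `model`, `report`, `concordance` (`NULL` without profiles).
#' @export
run_txome_stage <- function(counts, samples, profiles = NULL, n_top = 200,
                            angle = 15, fit_days = c(2, 7), reference = NULL,
                            delay_threshold = 1, out_dir = NULL) {
  if (!all(colnames(counts) == samples$sample)) {
    counts <- counts[, samples$sample, drop = FALSE]
  }
  if (!"day" %in% names(samples)) {
    stop("sample sheet is missing the 'day' column needed for the curve fit",
         call. = FALSE)
  }
  if (!any(is.finite(samples$day) & samples$day >= min(fit_days) &
             samples$day <= max(fit_days))) {
    stop("no time-course samples labelled within the fit range", call. = FALSE)
  }
  lognorm <- normalize_counts(counts)
  genes <- top_variable_genes(lognorm, min(n_top, nrow(lognorm)))
  expr_corr <- condition_correlation(lognorm, samples$condition, genes = genes)
  emb <- embed_samples(lognorm, samples$day, n_top = n_top)
  emb <- rotate_embedding(emb, angle)
  model <- fit_time_curve(emb, samples$day, fit_days = fit_days)
  report <- progression_report(emb, model, samples$condition,
                               reference = reference,
                               delay_threshold = delay_threshold)
  concordance <- NULL
  if (!is.null(profiles)) {
    feat_corr <- profile_correlation(profiles)
    concordance <- crossmodal_concordance(expr_corr, feat_corr)
  }
  out <- list(lognorm = lognorm, genes = genes, expr_corr = expr_corr,
              embedding = emb, model = model, report = report,
              concordance = concordance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "progression.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(expr_corr)),
                     file.path(out_dir, "expression_correlation.csv"))
    if (!is.null(concordance)) {
      utils::write.csv(concordance, file.path(out_dir, "concordance.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' Recovery metrics of the progression model on a simulated time course
#'
#' Runs the full projection pipeline on a [generate_timecourse()] simulation
#' and compares the result with the planted truth: Spearman correlation of
#' the pseudotime proxy with the planted progression and Pearson correlation
#' of the residual distance with the planted orthogonal offset.
#'
#' @param sim A `timecourse_sim`.
#' @param n_top,angle,fit_days Passed to [run_txome_stage()].
#' @return List: `pseudotime_spearman`, `offset_pearson`, `report`, `stage`.
#' @export
evaluate_timecourse_recovery <- function(sim, n_top = 200, angle = 15,
                                         fit_days = c(2, 7)) {
  stopifnot(inherits(sim, "timecourse_sim"))
  stage <- suppressWarnings(
    run_txome_stage(sim$counts, sim$samples, n_top = n_top, angle = angle,
                    fit_days = fit_days))
  rep_kd <- stage$report[match(sim$truth$target, stage$report$condition), ]
  list(
    pseudotime_spearman = stats::cor(rep_kd$pseudotime, sim$truth$progression,
                                     method = "spearman"),
    offset_pearson = stats::cor(rep_kd$distance, sim$truth$offset),
    report = stage$report,
    stage = stage
  )
}

#' One-command synthetic demonstration of the whole pipeline
#'
#' Generates a synthetic screen, time course and colony-count experiment
#' from a single seed, runs every stage, and summarizes how well the planted
#' ground truth is recovered: cluster ARI, facilitator cross-validated AUC,
#' recall of control-like targets in the top score decile, pseudotime and
#' offset recovery, interaction-test results on planted interacting and
#' non-interacting pairs, and a small null-calibration estimate of the
#' interaction test's type-I error.
#'
#' @param seed Integer seed driving every stage (default 1).
#' @param out_dir Optional directory; when given, all inputs, intermediate
#'   tables and the JSON summary are written there.
#' @param n_null_pairs Pairs for the demo-scale null calibration
#'   (default 2000).
#' @return List with `summary` (named metrics), `screen`, `txome`,
#'   `epistasis` and the simulation objects.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_null_pairs = 2000) {
  seed <- check_count(seed, "seed", min = 0L)

  # --- screen ---------------------------------------------------------
  scr_cfg <- screen_sim_config(seed = seed)
  scr <- generate_screen(scr_cfg)
  facil <- scr$truth$target[scr$truth$role == "facilitator" &
                              !scr$truth$is_control]
  screen <- run_screen_stage(scr$tables, facilitators = facil, seed = seed)
  ari <- cluster_recovery_ari(screen$assignment, scr$truth)

  ranking <- screen$ranking
  n_lib <- nrow(ranking)
  top_decile <- ranking$target[order(-ranking$combined_score)][
    seq_len(ceiling(n_lib / 10))]
  control_like <- intersect(facil, ranking$target)
  recall <- length(intersect(control_like, top_decile)) / length(control_like)

  # --- transcriptome + progression -----------------------------------
  kd_names <- utils::head(attr(ranking, "hits"), 30)
  tc_cfg <- trajectory_sim_config(n_knockdowns = length(kd_names),
                                  knockdowns = kd_names, seed = seed)
  tc <- generate_timecourse(tc_cfg)
  recovery <- evaluate_timecourse_recovery(tc)
  txome <- suppressWarnings(
    run_txome_stage(tc$counts, tc$samples,
                    profiles = screen$profiles$profiles[
                      intersect(kd_names, rownames(screen$profiles$profiles)), ,
                      drop = FALSE]))

  # --- epistasis ------------------------------------------------------
  col_cfg <- colony_sim_config(
    single_effects = c(Wdr5 = 0.4, Brca1 = 0.35, Bard1 = 0.45),
    interaction_gamma = c("Brca1:Bard1" = 2, "Wdr5:Brca1" = 2,
                          "Wdr5:Bard1" = 1),
    seed = seed)
  colonies <- generate_colony_counts(col_cfg)
  epi <- epistasis_analysis(colonies)
  calib <- epistasis_calibration(n_pairs = n_null_pairs, gamma = 1,
                                 seed = seed)

  summary <- list(
    seed = seed,
    cluster_ari = ari,
    facilitator_cv_auc = attr(ranking, "cv_auc"),
    control_like_recall_top_decile = recall,
    n_hits = length(attr(ranking, "hits")),
    pseudotime_spearman = recovery$pseudotime_spearman,
    offset_pearson = recovery$offset_pearson,
    epistasis_null_rejection_rate = calib$rejection_rate,
    epistasis_pairs_significant =
      stats::setNames(epi$significant, epi$pair)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_plate_tables(scr$tables, file.path(out_dir, "plate_tables.csv"))
    write_count_matrix(tc$counts, file.path(out_dir, "counts.tsv"))
    write_sample_sheet(tc$samples, file.path(out_dir, "samples.csv"))
    write_colony_counts(colonies, file.path(out_dir, "colony_counts.csv"))
    utils::write.csv(recovery$report, file.path(out_dir, "progression.csv"),
                     row.names = FALSE)
    utils::write.csv(epi, file.path(out_dir, "epistasis.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(summary = summary, screen = screen, txome = txome, epistasis = epi,
       screen_sim = scr, timecourse_sim = tc, colony_sim = colonies)
}
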