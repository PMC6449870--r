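make_profiles <- function(mat, role = NULL) {
  if (is.null(role)) role <- setNames(rep("library", nrow(mat)), rownames(mat))
  structure(list(profiles = mat,
                 n_replicates = setNames(rep(4L, nrow(mat)), rownames(mat)),
                 role = role),
            class = "feature_profiles")
}

test_that("control correlations hit the Pearson identities", {
  ctrl <- c(1, 2, 3, 4, 5)
  mat <- rbind(Trp53 = ctrl, Myc = rev(ctrl), Oct4 = ctrl * 2 - 1,
               same = ctrl, neg = -ctrl, other = c(1, 2, 4, 2, 1))
  colnames(mat) <- sprintf("feature_f%02d", 1:5)
  r <- correlate_to_controls(mat)
  expect_equal(r$r_Trp53[r$target == "same"], 1)
  expect_equal(r$r_Trp53[r$target == "neg"], -1)
  expect_equal(r$r_Oct4[r$target == "same"], 1)  # affine control, same r

  # hand-computed Pearson value for (1,2,3) vs (1,2,4)
  mat2 <- rbind(Trp53 = c(1, 2, 4), Myc = c(1, 2, 4), Oct4 = c(1, 2, 4),
                t1 = c(1, 2, 3))
  colnames(mat2) <- sprintf("feature_f%02d", 1:3)
  r2 <- correlate_to_controls(mat2)
  expect_equal(r2$r_Trp53, 3 / sqrt(2 * 14 / 3), tolerance = 1e-9)
  expect_equal(r2$r_Trp53, 0.981980506, tolerance = 1e-7)
})

test_that("constant profiles give NA correlations with a warning", {
  mat <- rbind(Trp53 = c(1, 2, 3), Myc = c(3, 2, 1), Oct4 = c(1, 3, 2),
               flat = c(2, 2, 2))
  colnames(mat) <- sprintf("feature_f%02d", 1:3)
  expect_warning(r <- correlate_to_controls(mat), "flat")
  expect_true(all(is.na(unlist(r[r$target == "flat", -1]))))
})

test_that("combined scores average the available correlations", {
  df <- data.frame(target = c("a", "b", "c"),
                   r_Trp53 = c(0.6, 1, 0.4),
                   r_Myc = c(0.3, 1, NA),
                   r_Oct4 = c(0.0, 1, 0.8))
  s <- combine_control_scores(df)
  expect_equal(unname(s), c(0.3, 1, 0.6))
  expect_equal(unname(combine_control_scores(df, method = "max")),
               c(0.6, 1, 0.8))
  df$r_Trp53[1] <- NA; df$r_Myc[1] <- NA; df$r_Oct4[1] <- NA
  expect_true(is.na(combine_control_scores(df)[1]))
  expect_true(all(abs(s) <= 1, na.rm = TRUE))
})

test_that("the facilitator ensemble separates a planted signature", {
  set.seed(5)
  n <- 120
  mat <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("t%03d", 1:n),
                                sprintf("feature_f%02d", 1:10)))
  pos <- sprintf("t%03d", 1:15)
  mat[pos, 1:3] <- mat[pos, 1:3] - 3  # linearly separable signature
  fit <- train_facilitator_predictor(make_profiles(mat), pos, seed = 2)
  expect_gte(fit$cv_auc, 0.95)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  # a duplicate of a positive example scores at least the ensemble median
  dup <- rbind(mat, t_dup = mat[pos[1], ])
  rownames(dup)[n + 1] <- "t_dup"
  fit2 <- train_facilitator_predictor(make_profiles(dup), pos, seed = 2)
  expect_gte(fit2$scores["t_dup"], median(fit2$scores))
})

test_that("degenerate training sets are rejected", {
  mat <- matrix(rnorm(40), 10, 4,
                dimnames = list(sprintf("t%02d", 1:10),
                                sprintf("feature_f%02d", 1:4)))
  expect_error(train_facilitator_predictor(make_profiles(mat),
                                           facilitators = "t01"),
               "at least 3")
  expect_error(train_facilitator_predictor(make_profiles(mat),
                                           facilitators = rownames(mat)),
               "negative")
})

test_that("the rank AUC agrees with an independent implementation", {
  set.seed(7)
  score <- c(rnorm(40, 1), rnorm(60))
  label <- rep(c(1, 0), c(40, 60))
  mine <- reprophen:::rank_auc(score, label)
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("hit selection unions the two axes and deduplicates", {
  set.seed(9)
  n <- 50
  mat <- matrix(rnorm((n + 3) * 8), n + 3, 8,
                dimnames = list(c(sprintf("t%03d", 1:n),
                                  c("Trp53", "Myc", "Oct4")),
                                sprintf("feature_f%02d", 1:8)))
  prof <- make_profiles(mat, role = setNames(
    c(rep("library", n), rep("positive", 3)), rownames(mat)))
  rk <- build_ranking_table(prof, facilitators = sprintf("t%03d", 1:5),
                            seed = 1)
  sel <- select_hits(rk, n_corr_top = 10, ml_quantile = 0.9)
  expect_length(attr(sel, "hits_by_correlation"), 10)
  hits <- attr(sel, "hits")
  expect_equal(anyDuplicated(hits), 0L)
  expect_setequal(hits, union(attr(sel, "hits_by_correlation"),
                              attr(sel, "hits_by_ml")))
  expect_equal(sum(sel$selected), length(hits))
  expect_error(select_hits(rk, n_corr_top = n + 1), "exceeds")
  # forced inclusion of a low-ranking roadblock candidate
  low <- rk$target[which.min(rk$combined_score)]
  sel2 <- select_hits(rk, n_corr_top = 5, include = low)
  expect_true(low %in% attr(sel2, "hits"))
})

test_that("ranking by combined score ignores redundant features", {
  sim <- small_screen(seed = 10)
  tables2 <- sim$tables
  tables2$feature_dup_01 <- tables2$feature_intensity_01  # exact copy
  base <- run_screen_stage(sim$tables, seed = 1)
  with_dup <- run_screen_stage(tables2, seed = 1)
  expect_equal(sum(c("feature_dup_01", "feature_intensity_01") %in%
                     with_dup$retained), 1L)
  o1 <- base$ranking$target[order(-base$ranking$combined_score)]
  o2 <- with_dup$ranking$target[order(-with_dup$ranking$combined_score)]
  expect_identical(o1, o2)
})
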