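test_that("plate Z-scores match the sample-SD identity on small cases", {
  tab <- make_plate_table(c(1, 2, 3))
  z <- zscore_by_plate(tab)
  expect_equal(z$feature_f01, c(-1, 0, 1))

  # idempotence: re-normalizing Z-scores changes nothing
  z2 <- zscore_by_plate(z)
  expect_equal(z2$feature_f01, z$feature_f01, tolerance = 1e-12)
})

test_that("constant features are zeroed with a warning", {
  tab <- make_plate_table(cbind(c(5, 5, 5), c(1, 2, 3)))
  expect_warning(z <- zscore_by_plate(tab), "constant")
  expect_equal(z$feature_f01, c(0, 0, 0))
  expect_equal(z$feature_f02, c(-1, 0, 1))
})

test_that("each replicate of a plate is normalized as its own plate", {
  tab <- rbind(make_plate_table(c(1, 2, 3), replicate = 1),
               make_plate_table(c(10, 20, 60), replicate = 2))
  z <- zscore_by_plate(tab)
  for (r in 1:2) {
    v <- z$feature_f01[z$replicate == r]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})

test_that("normalization yields exact per-plate moments on simulated screens", {
  sim <- small_screen(seed = 3)
  z <- zscore_by_plate(sim$tables)
  feats <- grep("^feature_", names(z), value = TRUE)
  grp <- interaction(z$plate, z$replicate, drop = TRUE)
  for (f in feats) {
    m <- tapply(z[[f]], grp, mean)
    s <- tapply(z[[f]], grp, sd)
    expect_true(all(abs(m) < 1e-9))
    expect_true(all(abs(s - 1) < 1e-9))
  }
  expect_error(zscore_by_plate(make_plate_table(c(1, 2))), "at least 3")
  dup <- make_plate_table(c(1, 2, 3))
  dup$well[2] <- dup$well[1]
  expect_error(zscore_by_plate(dup), "duplicate well")
})

test_that("replicate averaging is the arithmetic mean with NA skipping", {
  tab <- rbind(make_plate_table(c(1, 5, 7), replicate = 1),
               make_plate_table(c(3, 5, NA), replicate = 2))
  prof <- average_replicates(tab)
  expect_equal(unname(prof$profiles["g01", ]), 2)     # mean(1, 3)
  expect_equal(unname(prof$profiles["g02", ]), 5)     # identical replicates
  expect_equal(unname(prof$profiles["g03", ]), 7)     # missing skipped
  expect_equal(unname(prof$n_replicates[c("g01", "g03")]), c(2L, 1L))
})

test_that("targets missing from all replicates are dropped with a warning", {
  tab <- make_plate_table(cbind(c(NA, 1, 2), c(NA, 4, 9)))
  expect_warning(prof <- average_replicates(tab), "g01")
  expect_false("g01" %in% rownames(prof$profiles))
})

test_that("redundant duplicates are eliminated, keeping the high-variance copy", {
  set.seed(1)
  f1 <- rnorm(50, sd = 3)
  f3 <- rnorm(50)
  mat <- cbind(feature_a = f1, feature_b = f1, feature_c = f3)
  sel <- select_features(mat, threshold = 0.8)
  expect_setequal(sel$retained, c("feature_a", "feature_c"))

  # threshold 1 keeps every non-constant feature
  sel_all <- select_features(mat, threshold = 1)
  expect_setequal(sel_all$retained, colnames(mat))
})

test_that("greedy scan keeps the transitive ends of a correlated chain", {
  # r(f1,f2) = r(f2,f3) = 0.9 with r(f1,f3) = 0.65 (a feasible correlation
  # structure) and variances f1 > f2 > f3: f2 is dropped against f1, f3 kept
  R <- rbind(c(1, 0.9, 0.65), c(0.9, 1, 0.9), c(0.65, 0.9, 1))
  mat <- make_exact_cor(40, R, sds = c(3, 2, 1))
  expect_equal(unname(abs(cor(mat))[upper.tri(R)]),
               R[upper.tri(R)], tolerance = 1e-10)
  sel <- select_features(mat, threshold = 0.8)
  expect_setequal(sel$retained, c("feature_f01", "feature_f03"))
})

test_that("feature selection is idempotent and respects the threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    base <- matrix(rnorm(n * 3), n, 3)
    mix <- matrix(runif(3 * 8, -1, 1), 3, 8)
    mat <- base %*% mix + matrix(rnorm(n * 8, sd = 0.3), n, 8)
    colnames(mat) <- sprintf("feature_f%02d", 1:8)
    sel <- select_features(mat, threshold = 0.8)
    red <- sel$profiles
    if (length(sel$retained) >= 2) {
      expect_lte(max(abs(cor(red))[upper.tri(diag(ncol(red)))]), 0.8)
      sel2 <- select_features(red, threshold = 0.8)
      expect_identical(sel2$retained, sel$retained)
    }
    # maximality: every dropped feature conflicts with something retained
    dropped <- setdiff(colnames(mat), sel$retained)
    for (d in dropped) {
      expect_gt(max(abs(cor(mat[, d], mat[, sel$retained]))), 0.8)
    }
  }
})

test_that("zero-variance features are dropped first with a warning", {
  mat <- cbind(feature_a = rep(2, 10), feature_b = rnorm(10))
  expect_warning(sel <- select_features(mat), "zero-variance")
  expect_identical(sel$retained, "feature_b")
  expect_error(select_features(mat, threshold = 0), "threshold")
})
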