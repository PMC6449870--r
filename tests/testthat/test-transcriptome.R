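test_that("CPM normalization follows the definition and its invariances", {
  m <- cbind(s1 = c(10, 90), s2 = c(50, 50))
  rownames(m) <- c("g1", "g2")
  cpm <- normalize_counts(m, log = FALSE)
  expect_equal(unname(cpm[, "s1"]), c(1e5, 9e5))
  # zero counts log to zero; doubling a library changes nothing
  m2 <- m; m2[, "s1"] <- m2[, "s1"] * 2
  expect_equal(normalize_counts(m), normalize_counts(m2))
  m3 <- cbind(s1 = c(0, 100))
  expect_equal(unname(normalize_counts(m3)[1, 1]), 0)
  expect_error(normalize_counts(cbind(s1 = c(0, 0))), "zero-sum")
  expect_error(normalize_counts(cbind(s1 = c(-1, 2))), "non-negative")
})

test_that("most-variable-gene selection is deterministic and order invariant", {
  m <- rbind(flat = rep(3, 4), wiggly = c(0, 9, 0, 9), mild = c(1, 2, 1, 2))
  colnames(m) <- sprintf("s%d", 1:4)
  expect_equal(top_variable_genes(m, 2), c("wiggly", "mild"))
  expect_equal(top_variable_genes(m, 1), "wiggly")
  expect_setequal(top_variable_genes(m, 3), rownames(m))
  expect_equal(top_variable_genes(m[, c(3, 1, 4, 2)], 2),
               top_variable_genes(m, 2))
  expect_error(top_variable_genes(m, 9), "exceeds")
})

test_that("condition correlations are symmetric with unit diagonal", {
  set.seed(4)
  m <- matrix(rpois(200 * 9, 40), 200, 9,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:9)))
  cond <- rep(c("a", "b", "a_copy"), each = 3)
  m[, cond == "a_copy"] <- m[, cond == "a"]  # duplicated condition
  ln <- normalize_counts(m)
  cc <- condition_correlation(ln, cond)
  expect_equal(unclass(cc), t(unclass(cc)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["a", "a_copy"], 1)
  expect_true(all(cc >= -1 & cc <= 1))
})

test_that("replicate averaging precedes correlation", {
  m <- cbind(a_r1 = c(1, 5, 3), a_r2 = c(3, 1, 5), b_r1 = c(2, 3, 4))
  rownames(m) <- c("g1", "g2", "g3")
  avg <- average_condition_replicates(m, c("a", "a", "b"))
  expect_equal(unname(avg[, "a"]), c(2, 3, 4))
  cc <- condition_correlation(m, c("a", "a", "b"))
  expect_equal(cc["a", "b"], 1)  # averaged a equals b exactly
})

test_that("a planted co-regulated triple forms the top correlation block", {
  triple <- c("kd_a", "kd_b", "kd_c")
  others <- sprintf("kd_x%d", 1:6)
  cfg <- trajectory_sim_config(
    n_genes = 1000, n_knockdowns = 9, knockdowns = c(triple, others),
    planted_progression = c(rep(3, 3), seq(2.2, 6.8, length.out = 6)),
    orthogonal_offset = c(rep(2, 3), c(0, 0.5, 1, 1.5, 2.5, 3)),
    seed = 21)
  sim <- generate_timecourse(cfg)
  ln <- normalize_counts(sim$counts)
  genes <- top_variable_genes(ln, 200)
  kd <- sim$samples$condition %in% c(triple, others)
  cc <- condition_correlation(ln[, kd], sim$samples$condition[kd],
                              genes = genes)
  pairs <- t(combn(c(triple, others), 2))
  vals <- cc[pairs]
  in_triple <- pairs[, 1] %in% triple & pairs[, 2] %in% triple
  expect_setequal(rank(-vals)[in_triple], 1:3)
})

test_that("cross-modal concordance flags pairs similar in both modalities", {
  set.seed(6)
  conds <- sprintf("kd%02d", 1:8)
  base <- matrix(rnorm(8 * 20), 8, 20,
                 dimnames = list(conds, sprintf("feature_f%02d", 1:20)))
  base["kd02", ] <- base["kd01", ] + rnorm(20, sd = 0.1)  # similar in features
  expr <- matrix(rnorm(8 * 50), 8, 50, dimnames = list(conds, NULL))
  expr["kd02", ] <- expr["kd01", ] + rnorm(50, sd = 0.1)  # and in expression
  expr["kd04", ] <- expr["kd03", ] + rnorm(50, sd = 0.1)  # expression only
  ec <- structure(cor(t(expr)), modality = "expression")
  fc <- profile_correlation(base)
  tab <- crossmodal_concordance(ec, fc, expr_threshold = 0.5,
                                feature_threshold = 0.5)
  expect_equal(nrow(tab), choose(8, 2))
  flagged <- tab[tab$flagged, c("a", "b")]
  expect_true(any(flagged$a == "kd01" & flagged$b == "kd02"))
  expect_false(any(flagged$a == "kd03" & flagged$b == "kd04"))
  # symmetric in pair order: same unordered pairs whichever matrix order
  tab2 <- crossmodal_concordance(ec[rev(conds), rev(conds)], fc)
  key <- function(d) sort(paste(pmin(d$a, d$b), pmax(d$a, d$b)))
  expect_identical(key(tab), key(tab2))
  expect_error(crossmodal_concordance(ec[1:2, 1:2],
                                      fc[c("kd05", "kd06"), c("kd05", "kd06")]),
               "share")
})
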