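test_that("rotation follows the cos/sin identities and is an isometry", {
  df <- data.frame(x = c(1, 0, 3), y = c(0, 0, -2))
  rot <- rotate_embedding(df, 15)
  expect_equal(rot$x[1], cos(15 * pi / 180), tolerance = 1e-9)
  expect_equal(rot$y[1], sin(15 * pi / 180), tolerance = 1e-9)
  expect_equal(rot$x[1], 0.96593, tolerance = 1e-5)
  expect_equal(rot$y[1], 0.25882, tolerance = 1e-5)
  expect_equal(unlist(rot[2, ]), c(x = 0, y = 0))
  d0 <- dist(df)
  d1 <- dist(rot)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # 15 then -15 degrees is the identity
  back <- rotate_embedding(rot, -15)
  expect_equal(back$x, df$x, tolerance = 1e-12)
})

test_that("the quadratic fit interpolates exact data and degenerates sanely", {
  x <- seq(-2, 3, by = 0.5)
  coords <- data.frame(x = x, y = 1 + 2 * x + 0.5 * x^2)
  days <- seq(2, 7, length.out = length(x))
  model <- fit_time_curve(coords, days, fit_days = c(2, 7))
  expect_equal(unname(model$coefficients), c(1, 2, 0.5), tolerance = 1e-9)
  expect_equal(model$domain, range(x))

  lin <- data.frame(x = x, y = 3 - x)
  m2 <- fit_time_curve(lin, days)
  expect_equal(unname(m2$coefficients[3]), 0, tolerance = 1e-9)

  degen <- data.frame(x = rep(1, 5), y = 1:5)
  expect_error(fit_time_curve(degen, rep(3, 5)), "distinct x")
})

test_that("least squares beats every coefficient triple on a search grid", {
  set.seed(13)
  x <- runif(20, -3, 3)
  y <- 0.5 - 1.2 * x + 0.8 * x^2 + rnorm(20, sd = 0.4)
  model <- fit_time_curve(data.frame(x = x, y = y),
                          days = rep(2:6, 4), fit_days = c(2, 6))
  rss <- function(cf) sum((y - cf[1] - cf[2] * x - cf[3] * x^2)^2)
  grid <- as.matrix(expand.grid(c0 = seq(-1, 2, length.out = 50),
                                c1 = seq(-3, 1, length.out = 50),
                                c2 = seq(0, 2, length.out = 50)))
  grid_best <- min(apply(grid, 1, rss))
  expect_lte(model$rss, grid_best + 1e-9)
})

test_that("projection solves the worked quartic cases exactly", {
  flat <- quad_model(0, 0, 0, c(-5, 5))
  p <- project_onto_curve(c(2, 3), flat)
  expect_equal(p$x, 2)
  expect_equal(p$distance, 3)

  par <- quad_model(0, 0, 1, c(-2, 2))
  on_curve <- project_onto_curve(c(1.5, 1.5^2), par)
  expect_equal(on_curve$x, 1.5, tolerance = 1e-9)
  expect_equal(on_curve$distance, 0, tolerance = 1e-9)

  # point (0, 1) above y = x^2: two symmetric minima; tie broken low
  tie <- project_onto_curve(c(0, 1), par)
  expect_equal(tie$x, -1 / sqrt(2), tolerance = 1e-6)
  expect_equal(tie$distance, sqrt(3) / 2, tolerance = 1e-6)
  oracle <- grid_project(c(0, 1), par, n_grid = 400001)
  expect_equal(tie$distance, oracle$distance, tolerance = 1e-6)
})

test_that("the solver never loses to a dense-grid oracle", {
  set.seed(17)
  for (i in 1:200) {
    model <- quad_model(runif(1, -3, 3), runif(1, -2, 2), runif(1, -1.5, 1.5),
                        sort(runif(2, -6, 6)))
    pt <- c(runif(1, -8, 8), runif(1, -8, 8))
    sol <- project_onto_curve(pt, model)
    orc <- grid_project(pt, model, n_grid = 4001)
    expect_lte(sol$distance, orc$distance + 1e-6)
    expect_gte(sol$x, model$domain[1])
    expect_lte(sol$x, model$domain[2])
  }
})

test_that("embedding swaps axes and orients x along time", {
  sim <- generate_timecourse(trajectory_sim_config(
    n_genes = 800, n_knockdowns = 6, seed = 2))
  ln <- normalize_counts(sim$counts)
  emb <- embed_samples(ln, sim$samples$day)
  expect_identical(emb$axes, c(x = "PC2", y = "PC1"))
  ok <- is.finite(sim$samples$day)
  expect_gt(cor(emb$coords$x[ok], sim$samples$day[ok]), 0)
  # duplicated samples get identical coordinates
  ln2 <- cbind(ln, dup = ln[, 1])
  emb2 <- embed_samples(ln2, c(sim$samples$day, sim$samples$day[1]))
  last <- nrow(emb2$coords)
  expect_equal(emb2$coords$x[last], emb2$coords$x[1], tolerance = 1e-8)
  expect_equal(emb2$coords$y[last], emb2$coords$y[1], tolerance = 1e-8)
})

test_that("rotating the frame does not change residual distances", {
  # noise-free geometry: points on/off an exact parabola
  x <- seq(-2, 3, by = 0.25)
  coords <- data.frame(x = x, y = -0.4 * x^2 + 0.3 * x + 1)
  days <- rep(seq(2, 7, length.out = 7), length.out = length(x))
  model <- fit_time_curve(coords, days, fit_days = c(2, 7))
  pt <- c(1, 3)
  d0 <- project_onto_curve(pt, model)$distance
  rot <- rotate_embedding(coords, 15)
  model_r <- fit_time_curve(rot, days, fit_days = c(2, 7))
  pt_r <- unlist(rotate_embedding(data.frame(x = pt[1], y = pt[2]), 15))
  d1 <- project_onto_curve(pt_r, model_r)$distance
  expect_equal(d1, d0, tolerance = 0.05)
})

test_that("day estimates track true day and delays are flagged", {
  sim <- generate_timecourse(trajectory_sim_config(
    n_genes = 1500, n_knockdowns = 4,
    planted_progression = c(3, 3.5, 5.5, 6), orthogonal_offset = rep(0.5, 4),
    dispersion = 0.01, seed = 6))
  st <- suppressWarnings(run_txome_stage(sim$counts, sim$samples,
                                         reference = "day6"))
  rep_tc <- st$report[grepl("^day", st$report$condition), ]
  d <- as.numeric(sub("day", "", rep_tc$condition))
  in_fit <- d >= 2 & d <= 7
  expect_true(all(diff(rep_tc$day_estimate[in_fit][order(d[in_fit])]) >= 0))

  # a knockdown 3 days behind the reference is delayed at threshold 1
  rp <- progression_report(st$embedding, st$model, sim$samples$condition,
                           reference = "day6", delay_threshold = 1)
  expect_true(rp$delayed[rp$condition == "kd_01"])
  expect_false(rp$delayed[rp$condition == "kd_04"])
  expect_warning(
    progression_report(st$embedding, st$model, sim$samples$condition,
                       reference = "not_there"),
    "reference")
})
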