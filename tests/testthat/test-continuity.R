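test_that("the single-clade statistic at k = 1 always holds", {
  cfg <- validate_config(constant_model(200), sampling_scheme(10, 3, 1000))
  est <- estimate_probability(cfg, k = 1, reps = 300, seed = 2,
                              statistic = "single")
  expect_equal(est$p_hat, 1)
  expect_equal(est$standard_error, 0)
})

test_that("independent runs agree within combined Monte-Carlo error", {
  cfg <- validate_config(constant_model(50), sampling_scheme(3, 3, 1000))
  a <- estimate_probability(cfg, k = 2, reps = 20000, seed = 1,
                            statistic = "single")
  b <- estimate_probability(cfg, k = 2, reps = 20000, seed = 2,
                            statistic = "single")
  se <- sqrt(a$standard_error^2 + b$standard_error^2)
  expect_lt(abs(a$p_hat - b$p_hat), 4 * se)
  # add-one estimator shifts the raw proportion as documented
  c1 <- estimate_probability(cfg, k = 2, reps = 1000, seed = 3,
                             estimator = "add_one")
  expect_equal(c1$p_hat, (c1$hits + 1) / (c1$reps + 1))
})

test_that("exclusivity probability decreases with effective size and with k", {
  samp <- sampling_scheme()
  ts <- time_scale(3)
  grid <- c(500, 2000, 8000)
  p <- se <- numeric(3)
  for (i in 1:3) {
    est <- estimate_probability(validate_config(constant_model(grid[i]), samp, ts),
                                reps = 15000, seed = 4, stream_offset = (i - 1) * 15000)
    p[i] <- est$p_hat
    se[i] <- est$standard_error
  }
  expect_lt(p[2], p[1] + 4 * sqrt(se[1]^2 + se[2]^2))
  expect_lt(p[3], p[2] + 4 * sqrt(se[2]^2 + se[3]^2))
  expect_gt(p[1], p[3])  # wide separation must be strict

  # same seed: per-replicate indicators are monotone in k, hence so is p_hat
  cfg <- validate_config(constant_model(2000), samp, ts)
  p8 <- estimate_probability(cfg, k = 8, reps = 4000, seed = 5)$p_hat
  p13 <- estimate_probability(cfg, k = 13, reps = 4000, seed = 5)$p_hat
  expect_gte(p8, p13)
})

test_that("threshold scans report the largest non-rejected value and flags", {
  samp <- sampling_scheme(40, 8, 1000)
  sc <- rejection_threshold("constant", grid = seq(200, 3200, 500), k = 5,
                            reps = 2500, seed = 6, sampling = samp,
                            timescale = time_scale(2))
  expect_true(sc$threshold %in% sc$trace$parameter)
  above <- sc$trace$parameter > sc$threshold
  expect_true(all(sc$trace$p_hat[above] < sc$alpha))
  expect_gte(sc$trace$p_hat[sc$trace$parameter == sc$threshold], sc$alpha)

  # absurd alpha rejects everything and flags the boundary
  all_rej <- rejection_threshold("constant", grid = c(4000, 6000), k = 8,
                                 alpha = 0.999, reps = 200, seed = 7)
  expect_true(is.na(all_rej$threshold))
  expect_equal(all_rej$boundary, "below_range")

  # minuscule alpha rejects nothing (every point has p_hat >= alpha > 0 here)
  none_rej <- rejection_threshold("constant", grid = c(200, 400), k = 2,
                                  sampling = sampling_scheme(5, 3, 1000),
                                  alpha = 1e-9, reps = 400, seed = 8,
                                  statistic = "single")
  expect_equal(none_rej$threshold, 400)
  expect_equal(none_rej$boundary, "above_range")
})

test_that("admixture limits decrease in c and are seed-stable to a grid step", {
  lim1 <- admixture_upper_limit(ne = 500, c_grid = seq(0, 1, 0.05),
                                reps = 3000, seed = 10,
                                sampling = sampling_scheme(60, 13, 1000))
  lim2 <- admixture_upper_limit(ne = 500, c_grid = seq(0, 1, 0.05),
                                reps = 3000, seed = 11,
                                sampling = sampling_scheme(60, 13, 1000))
  expect_lte(abs(lim1$c_limit - lim2$c_limit), 0.05 + 1e-9)
  # exclusivity probability declines in c (coarse grid, allow MC slack)
  tr <- lim1$trace
  coarse <- tr[tr$c %in% c(0, 0.3, 0.6, 0.9), ]
  expect_true(all(diff(coarse$p_hat) < 4 * sqrt(2) * max(coarse$se) + 1e-12))
})

test_that("a degenerate limit curve equals the direct upper-limit call", {
  curve <- limit_curve(ne_grid = 800, timescales = list(time_scale(2)),
                       c_grid = seq(0, 0.6, 0.1), reps = 1500, seed = 20,
                       sampling = sampling_scheme(40, 13, 1000))
  expect_equal(nrow(curve), 1)
  direct <- admixture_upper_limit(ne = 800, timescale = time_scale(2),
                                  c_grid = seq(0, 0.6, 0.1), reps = 1500,
                                  seed = 21,
                                  sampling = sampling_scheme(40, 13, 1000))
  expect_equal(curve$c_limit, direct$c_limit)
  expect_true(all(curve$c_limit >= 0 & curve$c_limit <= 1, na.rm = TRUE))
})
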