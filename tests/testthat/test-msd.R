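test_that("MSD of a stationary track is zero at every lag", {
  tr <- data.frame(frame = 0:5, t_s = 0:5, x_um = 2, y_um = -1)
  cv <- compute_msd(tr)
  expect_equal(cv$msd_um2, rep(0, 5))
})

test_that("MSD of a ballistic track is exactly (v*lag)^2", {
  tr <- data.frame(frame = 0:4, t_s = 0:4, x_um = 0:4, y_um = 0)
  cv <- compute_msd(tr)
  expect_equal(cv$msd_um2, (1:4)^2)
})

test_that("the worked 4-point example matches the all-pairs oracle", {
  tr <- data.frame(track_id = 1, frame = 0:3, t_s = 0:3,
                   x_um = c(0, 1, 1, 3), y_um = c(0, 0, 1, 1))
  cv <- compute_msd(tr)
  orc <- msd_oracle(tr)
  expect_equal(cv$msd_um2, orc$msd_um2)
  expect_equal(cv$msd_um2, c((1 + 1 + 4) / 3, (2 + 5) / 2, 10))
  expect_identical(cv$n_pairs, c(3L, 2L, 1L))
})

test_that("compute_msd equals the brute-force oracle on random gapped tracks", {
  set.seed(99)
  for (i in 1:200) {
    tr <- random_track(10)
    cv <- compute_msd(tr)
    orc <- msd_oracle(tr)
    expect_equal(cv$lag_s, orc$lag_s)
    expect_equal(cv$msd_um2, orc$msd_um2, tolerance = 1e-12)
    expect_equal(cv$n_pairs, orc$n_pairs)
  }
})

test_that("compute_msd rejects degenerate input", {
  expect_error(compute_msd(data.frame(frame = 0, t_s = 0, x_um = 0,
                                      y_um = 0)), "at least 2")
})

test_that("a pure linear curve returns (D, v = 0) exactly", {
  cv <- data.frame(lag_s = 1:20, msd_um2 = 0.4 * (1:20))
  f <- fit_diffusion_ballistic(cv)
  expect_equal(f$D, 0.1, tolerance = 1e-9)
  expect_equal(f$v, 0, tolerance = 1e-9)
  expect_false(f$directed_flag)
})

test_that("a pure quadratic curve returns (v, D = 0) exactly", {
  cv <- data.frame(lag_s = 1:20, msd_um2 = 0.25 * (1:20)^2)
  f <- fit_diffusion_ballistic(cv)
  expect_equal(f$v, 0.5, tolerance = 1e-9)
  expect_equal(f$D, 0, tolerance = 1e-9)
  expect_true(f$directed_flag)
})

test_that("an all-zero curve fits D = 0, v = 0 without error", {
  cv <- data.frame(lag_s = 1:10, msd_um2 = 0, n_pairs = 10:1)
  f <- fit_diffusion_ballistic(cv)
  expect_identical(c(f$D, f$v), c(0, 0))
  expect_false(f$directed_flag)
  expect_error(fit_diffusion_ballistic(data.frame(lag_s = 1:2,
                                                  msd_um2 = 1:2)),
               "at least 3 lags")
})

test_that("optional offset term recovers a localization-error intercept", {
  cv <- data.frame(lag_s = 1:20, msd_um2 = 0.016 + 0.4 * (1:20))
  f <- fit_diffusion_ballistic(cv, include_offset = TRUE)
  expect_equal(f$offset, 0.016, tolerance = 1e-9)
  expect_equal(f$D, 0.1, tolerance = 1e-9)
})

test_that("log-log slope is exact for power-law curves", {
  lin <- data.frame(lag_s = 1:20, msd_um2 = 3 * (1:20))
  quad <- data.frame(lag_s = 1:20, msd_um2 = 3 * (1:20)^2)
  expect_equal(fit_alpha_loglog(lin), 1, tolerance = 1e-12)
  expect_equal(fit_alpha_loglog(quad), 2, tolerance = 1e-12)
})

test_that("plateauing curves give alpha < 1, matching an OLS oracle", {
  lag <- 1:20
  cv <- data.frame(lag_s = lag, msd_um2 = 0.25 * (1 - exp(-lag / 3)))
  a <- fit_alpha_loglog(cv, lag_fraction = 1)
  fit <- stats::lm(log(msd_um2) ~ log(lag_s), data = cv)
  expect_equal(a, unname(coef(fit)[2]), tolerance = 1e-9)
  expect_lt(a, 1)
})

test_that("an immobile track yields an undefined exponent, classed constrained", {
  cv <- data.frame(lag_s = 1:10, msd_um2 = 0)
  expect_warning(a <- fit_alpha_loglog(cv), "undefined")
  expect_true(is.na(a))
  expect_identical(classify_motion(a), "constrained")
})

test_that("anchor slopes classify to their motion classes", {
  expect_identical(classify_motion(1.0), "diffusive")
  expect_identical(classify_motion(2.0), "transported")
  expect_identical(classify_motion(0.4), "constrained")
  expect_identical(classify_motion(c(0.79, 0.8, 1.49, 1.5)),
                   c("constrained", "diffusive", "diffusive", "transported"))
  expect_error(classify_motion(1, bins = c(2, 1)))
})

test_that("motion summaries are normalized compositions", {
  fits <- data.frame(motion_class = rep("diffusive", 5),
                     v = runif(5), directed_flag = FALSE)
  s <- summarize_motion(fits)
  expect_equal(unname(s$fractions), c(0, 1, 0))
  set.seed(8)
  fits2 <- data.frame(
    motion_class = sample(c("constrained", "diffusive", "transported"),
                          50, TRUE),
    v = runif(50), directed_flag = sample(c(TRUE, FALSE), 50, TRUE))
  expect_equal(sum(summarize_motion(fits2)$fractions), 1)
  expect_error(summarize_motion(fits2[0, ]), "no motion fits")
})

test_that("fitted velocity is invariant under rotation and translation", {
  sim <- simulate_ensemble(motion_model("directed", D = 0.01,
                                        v = c(0.3, 0)),
                           5, 40, 1, seed = 31)
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sim$tracks
  xy <- as.matrix(rot[, c("x_um", "y_um")]) %*% t(R)
  rot$x_um <- xy[, 1] + 7; rot$y_um <- xy[, 2] - 3
  f0 <- analyze_motion(sim$tracks)
  f1 <- analyze_motion(rot)
  expect_equal(f1$v, f0$v, tolerance = 1e-9)
  expect_equal(f1$D, f0$D, tolerance = 1e-9)
})
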