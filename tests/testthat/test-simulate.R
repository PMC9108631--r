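test_that("zero-variance Brownian motion stays at the origin", {
  m <- motion_model("brownian", D = 0)
  sim <- simulate_trajectory(m, 10, 1, seed = 1)
  expect_equal(sim$track$x_um, rep(0, 10))
  expect_equal(sim$track$y_um, rep(0, 10))
})

test_that("noise-free directed motion drifts exactly v*dt per frame", {
  m <- motion_model("directed", D = 0, v = c(0.5, 0))
  sim <- simulate_trajectory(m, 5, 1, seed = 1)
  expect_equal(sim$track$x_um, c(0, 0.5, 1.0, 1.5, 2.0))
  expect_equal(sim$track$y_um, rep(0, 5))
})

test_that("Brownian step variance matches the analytic moment 4*D*dt", {
  m <- motion_model("brownian", D = 0.05)
  steps2 <- unlist(lapply(1:200, function(i) {
    tr <- simulate_trajectory(m, 51, 1, seed = 42, particle_id = i)$track
    diff(tr$x_um)^2 + diff(tr$y_um)^2
  }))
  expect_gt(length(steps2), 9999)
  expect_lt(abs(mean(steps2) - 4 * 0.05 * 1) / (4 * 0.05), 0.05)
})

test_that("ensemble MSD of Brownian tracks matches 4*D*dt + 4*sigma_loc^2", {
  D <- 0.05; sl <- 0.02
  sim <- simulate_ensemble(motion_model("brownian", D = D, sigma_loc = sl),
                           150, 30, 1, seed = 7)
  for (lag in c(1, 3, 5)) {
    ms <- mean(vapply(split(sim$tracks, sim$tracks$track_id), function(tr) {
      cv <- compute_msd(tr)
      cv$msd_um2[cv$lag_s == lag]
    }, 0))
    expected <- 4 * D * lag + 4 * sl^2
    expect_lt(abs(ms - expected) / expected, 0.1)
  }
})

test_that("confined trajectories never leave the corral", {
  for (seed in 1:10) {
    m <- motion_model("confined", D = 0.1, R = 0.5)
    tr <- simulate_trajectory(m, 100, 1, seed = seed)$truth
    d <- sqrt((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2)
    expect_lte(max(d), 0.5 + 1e-9)
  }
})

test_that("long-time confined MSD plateaus near R^2", {
  R <- 0.5
  sim <- simulate_ensemble(motion_model("confined", D = 0.1, R = R),
                           200, 80, 1, seed = 13)
  plateau <- mean(vapply(split(sim$tracks, sim$tracks$track_id),
                         function(tr) {
    cv <- compute_msd(tr)
    mean(cv$msd_um2[cv$lag_s >= 40 & cv$lag_s <= 60])
  }, 0))
  # mean squared distance of two uniform points in a disc of radius R = R^2
  expect_lt(abs(plateau - R^2) / R^2, 0.25)
})

test_that("simulation is seed-deterministic and seeds decorrelate", {
  m <- motion_model("brownian", D = 0.05)
  a <- simulate_trajectory(m, 20, 1, seed = 5)
  b <- simulate_trajectory(m, 20, 1, seed = 5)
  c <- simulate_trajectory(m, 20, 1, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$track$x_um, c$track$x_um)))
})

test_that("invalid simulation parameters are rejected", {
  m <- motion_model("brownian", D = 0.05)
  expect_error(simulate_trajectory(m, 1, 1), "n_frames")
  expect_error(simulate_trajectory(m, 10, 0), "dt")
  expect_error(motion_model("directed", v = c(0, 0)), "non-zero")
  expect_error(motion_model("confined"), "R > 0")
  expect_error(motion_model("brownian", D = -1))
  expect_error(optics_model(psf_sigma = 0.01), "pixel_size / 4")
})

test_that("background-only rendering gives the expected Poisson mean", {
  truth <- data.frame(particle_id = 1L, frame = 0L, x_um = -50, y_um = -50)
  opt <- optics_model(background = 100, read_noise_sd = 0,
                      photons_per_particle = 0)
  mov <- render_movie(truth, opt, shape = c(256, 256), seed = 2)
  expect_lt(abs(mean(mov$channels[[1]]) - 100) / 100, 0.01)
})

test_that("a bright particle renders with its brightest pixel at the truth", {
  opt <- optics_model(photons_per_particle = 5000)
  px <- opt$pixel_size
  truth <- data.frame(particle_id = 1L, frame = 0L,
                      x_um = 30.4 * px, y_um = 17.8 * px)
  mov <- render_movie(truth, opt, shape = c(64, 64), seed = 3)
  fr <- mov$channels[[1]][, , 1]
  ij <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_lte(abs(ij[2] - 1 - 30.4), 1)
  expect_lte(abs(ij[1] - 1 - 17.8), 1)
})

test_that("zero-photon particles render as background only", {
  opt0 <- optics_model(photons_per_particle = 0, read_noise_sd = 0)
  truth <- data.frame(particle_id = 1L, frame = 0L, x_um = 5, y_um = 5)
  mov <- render_movie(truth, opt0, shape = c(128, 128), seed = 4)
  expect_lt(abs(mean(mov$channels[[1]]) - opt0$background) /
              opt0$background, 0.01)
})

test_that("rendering is deterministic under a fixed seed", {
  opt <- optics_model()
  truth <- data.frame(particle_id = 1L, frame = 0:2,
                      x_um = c(5, 5.2, 5.4), y_um = 5)
  a <- render_movie(truth, opt, shape = c(64, 64), seed = 9)
  b <- render_movie(truth, opt, shape = c(64, 64), seed = 9)
  expect_identical(a, b)
})

test_that("two-channel simulation honours the colocalized fraction", {
  two0 <- simulate_two_channel(10, 0, n_frames = 3, shape = c(128, 128),
                               seed = 1)
  per_obj <- two0$truth[!duplicated(two0$truth$particle_id), ]
  expect_true(all(per_obj$coloc_label == "NCL"))
  # channel 2 is background-only: mean close to background
  opt <- optics_model()
  expect_lt(abs(mean(two0$movie$channels[[2]]) - opt$background) /
              opt$background, 0.02)

  two1 <- simulate_two_channel(10, 1, n_frames = 3, shape = c(128, 128),
                               seed = 1)
  per_obj <- two1$truth[!duplicated(two1$truth$particle_id), ]
  expect_true(all(per_obj$coloc_label == "CL"))

  two <- simulate_two_channel(50, 0.4, n_frames = 2, shape = c(256, 256),
                              seed = 1)
  per_obj <- two$truth[!duplicated(two$truth$particle_id), ]
  expect_identical(sum(per_obj$coloc_label == "CL"), 20L)
})
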