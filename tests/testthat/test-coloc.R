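# Two labelled squares in channel 1; channel 2 gets a bright blob covering
# a controlled fraction of each object's pixels.
make_coloc_fixture <- function(fracs) {
  ch1 <- matrix(0L, 40, 80)
  ch2 <- matrix(10, 40, 80)
  for (i in seq_along(fracs)) {
    rows <- 11:20; cols <- (40 * (i - 1) + 11):(40 * (i - 1) + 20)
    ch1[rows, cols] <- i
    n_cov <- round(fracs[i] * 100)
    if (n_cov > 0) {
      px <- expand.grid(r = rows, c = cols)[seq_len(n_cov), ]
      ch2[as.matrix(px)] <- 250
    }
  }
  list(ch1 = ch1, ch2 = ch2)
}

test_that("an empty second channel labels every object NCL", {
  fx <- make_coloc_fixture(c(0, 0))
  out <- split_colocalized(fx$ch1, matrix(10, 40, 80))
  expect_identical(out$coloc_label, c("NCL", "NCL"))
  expect_equal(out$overlap_fraction, c(0, 0))
})

test_that("an identical mask labels every object CL with full overlap", {
  fx <- make_coloc_fixture(c(1, 1))
  out <- split_colocalized(fx$ch1, fx$ch2, smoothing = 0)
  expect_identical(out$coloc_label, c("CL", "CL"))
  expect_equal(out$overlap_fraction, c(1, 1))
})

test_that("overlap fractions threshold at the configured boundary", {
  fx <- make_coloc_fixture(c(0.1, 0.5))
  out <- split_colocalized(fx$ch1, fx$ch2, overlap_threshold = 0.3,
                           smoothing = 0)
  expect_identical(out$coloc_label, c("NCL", "CL"))
  expect_equal(out$overlap_fraction, c(0.1, 0.5), tolerance = 0.05)
  expect_gt(out$membership[2], out$membership[1])
  expect_error(split_colocalized(fx$ch1, matrix(0, 4, 4)), "shapes differ")
})

test_that("coloc labels are invariant to object ordering", {
  fx <- make_coloc_fixture(c(0.1, 0.6))
  out1 <- split_colocalized(fx$ch1, fx$ch2, smoothing = 0)
  relab <- fx$ch1
  relab[fx$ch1 == 1L] <- 2L; relab[fx$ch1 == 2L] <- 1L
  out2 <- split_colocalized(relab, fx$ch2, smoothing = 0)
  expect_identical(out1$coloc_label,
                   out2$coloc_label[match(c(2, 1), out2$label)])
})

test_that("a static object tracks with zero displacement", {
  fr <- lapply(1:4, function(i)
    data.frame(x_um = 3, y_um = 3, area_um2 = 0.5, coloc_label = "NCL"))
  out <- track_objects(fr, dt = 1)
  expect_identical(nrow(out$summary), 1L)
  expect_equal(out$summary$displacement_um, 0)
  expect_equal(out$summary$speed_um_s, 0)
})

test_that("uniform motion yields speed 1 and net displacement 4", {
  fr <- lapply(0:4, function(i)
    data.frame(x_um = 1 + i, y_um = 2, area_um2 = 0.5))
  out <- track_objects(fr, linking_config(linking_max_distance = 1.5),
                       dt = 1)
  expect_identical(nrow(out$summary), 1L)
  expect_equal(out$summary$speed_um_s, 1)
  expect_equal(out$summary$displacement_um, 4)
})

test_that("a zigzag path separates mean speed from net displacement", {
  xs <- c(0, 1, 1, 0); ys <- c(0, 0, 1, 1)
  fr <- lapply(1:4, function(i)
    data.frame(x_um = xs[i], y_um = ys[i], area_um2 = 1))
  out <- track_objects(fr, linking_config(linking_max_distance = 1.5),
                       dt = 1)
  expect_equal(out$summary$speed_um_s, 1)
  expect_equal(out$summary$displacement_um, 1)
})

test_that("majority labels resolve ties to CL and flag them", {
  fr <- lapply(1:4, function(i)
    data.frame(x_um = 3, y_um = 3, area_um2 = 0.5,
               coloc_label = if (i <= 2) "CL" else "NCL"))
  out <- track_objects(fr, dt = 1)
  expect_identical(out$summary$label, "CL")
  expect_true(out$summary$label_tie)
})

test_that("the Welch statistic matches the textbook formula and t.test", {
  s <- data.frame(label = rep(c("CL", "NCL"), each = 3),
                  speed_um_s = c(1, 2, 3, 2, 3, 4),
                  displacement_um = c(1, 2, 3, 2, 3, 4),
                  size_um2 = c(1, 2, 3, 2, 3, 4))
  cmp <- compare_populations(s, "speed")
  # hand computation: means 2 and 3, var 1 each, n 3: t = -1/sqrt(2/3)
  expect_equal(cmp$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(cmp$df, unname(ref$parameter), tolerance = 1e-9)

  set.seed(77)
  for (i in 1:10) {
    s2 <- data.frame(label = rep(c("CL", "NCL"), c(8, 11)),
                     speed_um_s = rnorm(19, 2),
                     displacement_um = 1, size_um2 = 1)
    cmp2 <- compare_populations(s2, "speed")
    ref2 <- stats::t.test(s2$speed_um_s[s2$label == "CL"],
                          s2$speed_um_s[s2$label == "NCL"])
    expect_equal(cmp2$t, unname(ref2$statistic), tolerance = 1e-9)
    expect_equal(cmp2$p_value, ref2$p.value, tolerance = 1e-9)
  }
})

test_that("identical groups compare with zero difference and |t| = 0", {
  s <- data.frame(label = rep(c("CL", "NCL"), each = 4),
                  speed_um_s = rep(c(1, 2, 3, 4), 2),
                  displacement_um = 1, size_um2 = 1)
  cmp <- compare_populations(s, "speed")
  expect_equal(cmp$difference, 0)
  expect_equal(abs(cmp$t), 0)
})

test_that("undersized populations are rejected", {
  s <- data.frame(label = c("CL", "NCL", "NCL"),
                  speed_um_s = 1:3, displacement_um = 1:3, size_um2 = 1:3)
  expect_error(compare_populations(s, "speed"), "at least 2")
})
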