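test_that("empty and saturated scenes hit their analytic limits", {
  bg <- render_frame(scene_params("none", noise_sd = 0))
  expect_true(all(bg$pixels == 13))
  # at 0.1 m the standing ellipse envelops the whole grid
  full <- render_frame(scene_params("standing", distance = 0.1,
                                    noise_sd = 0))
  expect_true(all(full$pixels == 31))
})

test_that("noiseless frame mean equals the coverage-sum prediction", {
  sc <- scene_params("standing", distance = 0.5, background_temp = 13,
                     body_temp = 31, noise_sd = 0, seed = 42)
  fr <- render_frame(sc)
  cov <- oracle_coverage(3.2, 1.4, 4, 4)
  expect_equal(mean(fr$pixels), 13 + cov * (31 - 13), tolerance = 1e-12)
  sit <- render_frame(scene_params("sitting", noise_sd = 0))
  cov_sit <- oracle_coverage(1.25, 0.8, 4, 4)
  expect_equal(mean(sit$pixels), 13 + cov_sit * (31 - 13),
               tolerance = 1e-12)
})

test_that("rendering is deterministic under a fixed seed", {
  a <- render_frame(scene_params("standing", seed = 42))
  b <- render_frame(scene_params("standing", seed = 42))
  expect_identical(a$pixels, b$pixels)
  s1 <- simulate_sequence(make_trajectory(1.0, 0.2, 8, seed = 5))
  s2 <- simulate_sequence(make_trajectory(1.0, 0.2, 8, seed = 5))
  expect_identical(lapply(s1$frames, `[[`, "pixels"),
                   lapply(s2$frames, `[[`, "pixels"))
})

test_that("silhouette coverage shrinks with distance and with sitting", {
  area <- function(posture, d) sum(thermogrid:::coverage_matrix(posture, d))
  ds <- c(0.3, 0.5, 0.8, 1.2)
  st <- vapply(ds, area, numeric(1), posture = "standing")
  expect_true(all(diff(st) <= 0))
  for (d in ds) {
    expect_gt(area("standing", d), area("sitting", d))
  }
})

test_that("noiseless approach yields strictly increasing frame means", {
  seqs <- simulate_sequence(make_trajectory(1.0, 0.1, 10, noise_sd = 0))
  expect_identical(seqs$motion, "approaching")
  means <- vapply(seqs$frames, function(f) mean(f$pixels), numeric(1))
  expect_true(all(diff(means) > 0))
  # constant distance, no noise: identical frames
  still <- simulate_sequence(make_trajectory(0.5, 0.5, 5, noise_sd = 0))
  expect_identical(still$motion, "still")
  px <- lapply(still$frames, `[[`, "pixels")
  for (i in 2:5) expect_identical(px[[i]], px[[1]])
})

test_that("emitted frames satisfy the sensor-range invariants", {
  set.seed(30)
  for (p in c("standing", "sitting", "none")) {
    fr <- render_frame(scene_params(p, noise_sd = 2))
    expect_true(all(fr$pixels >= -20 & fr$pixels <= 80))
    expect_s3_class(fr, "thermal_frame")
  }
})

test_that("default parameters separate the postures at the 0.8t threshold", {
  st <- render_frame(scene_params("standing", noise_sd = 0))
  si <- render_frame(scene_params("sitting", noise_sd = 0))
  expect_gt(mean(st$pixels), 14.4)
  expect_lt(mean(si$pixels), 14.4)
  # and on the detector's actual statistic, the interpolated mean
  expect_gt(mean(bilinear_interpolate(st$pixels, 10)), 14.4)
  expect_lt(mean(bilinear_interpolate(si$pixels, 10)), 14.4)
})

test_that("scene invariants are enforced", {
  expect_error(scene_params(distance = 0), "distance")
  expect_error(scene_params(distance = 2), "distance")
  expect_error(scene_params(body_temp = 12, background_temp = 13),
               "exceed")
  expect_error(scene_params(noise_sd = -1), "noise_sd")
})

test_that("generated datasets have the canonical shape and determinism", {
  d <- generate_dataset(376, c("standing", "sitting"), seed = 1)
  expect_identical(dim(d), c(752L, 65L))
  expect_identical(names(d)[65], "state")
  expect_identical(sort(unique(d$state)), c("sitting", "standing"))

  one <- generate_dataset(1, "standing", noise_sd = 0, seed = 2)
  fr <- render_frame(scene_params("standing", noise_sd = 0))
  expect_equal(as.numeric(one[1, 1:64]), as.vector(t(fr$pixels)))

  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_frames(generate_dataset(5, seed = 7), p1)
  write_frames(generate_dataset(5, seed = 7), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(generate_dataset(3, "levitating"), "unknown state")
})

test_that("swing states are rendered and distinct from still postures", {
  d <- generate_dataset(16, c("swingfb", "swinglr"), noise_sd = 0,
                        seed = 3)
  fb <- as.matrix(d[d$state == "swingfb", 1:64])
  lr <- as.matrix(d[d$state == "swinglr", 1:64])
  # forward-backward sway modulates apparent size, hence the frame mean
  expect_gt(diff(range(rowMeans(fb))), 0.1)
  # lateral sway moves the centroid column
  col_centroid <- function(row) {
    m <- matrix(row, 8, 8, byrow = TRUE)
    w <- m - min(m)
    sum(colSums(w) * (1:8)) / sum(w)
  }
  cents <- apply(lr, 1, col_centroid)
  expect_gt(diff(range(cents)), 1)
})
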