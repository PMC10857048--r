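test_that("A1 and the difference factor follow their definitions", {
  expect_equal(average_raw(const_frame(20)), 20)
  half <- thermal_frame(matrix(c(rep(10, 32), rep(30, 32)), 8, 8), 18)
  expect_equal(average_raw(half), 20)
  fr <- render_frame(scene_params("standing", seed = 3))
  expect_equal(average_raw(fr), sum(fr$pixels) / 64)

  expect_equal(difference_factor(20, 20), 1.0)
  expect_equal(difference_factor(18, 20), 0.9)
  expect_equal(difference_factor(14.56, 18), 14.56 / 18)
  expect_error(difference_factor(15, 0), "undefined")
})

test_that("A2 normalizations match hand arithmetic on a constant grid", {
  grid <- bilinear_interpolate(matrix(20, 8, 8), ipf = 10)  # 80x80 of 20
  expect_equal(average_interpolated(grid, df = 1.0, mode = "alg1"),
               6400 * 20 / 80)           # 1600
  expect_equal(average_interpolated(grid, df = 1.0, mode = "eq6"),
               128000 / 640)             # 200
  expect_equal(average_interpolated(grid, df = 0, mode = "alg1"), 0)
  expect_error(average_interpolated(grid, 1, mode = "bogus"))
})

test_that("posture rule reduces to a mean threshold and ties fall to sitting", {
  # at ipf = 10 and t = 18 the alg1 rule reduces to mean > 0.8*18 = 14.4
  st <- detector_state(ipf = 10)
  expect_identical(detect_step(st, const_frame(15, 18))$result$posture,
                   "standing")
  expect_identical(detect_step(st, const_frame(14, 18))$result$posture,
                   "sitting")
  expect_identical(classify_posture(a2 = 64 * 18 * 1, t = 18, df = 1),
                   "sitting")  # exact tie
})

test_that("motion rule tracks the df trend with unknown on the first frame", {
  expect_identical(classify_motion(0.95, 0.97), "approaching")
  expect_identical(classify_motion(0.97, 0.95), "receding")
  expect_identical(classify_motion(NA, 0.95), "unknown")
  expect_identical(classify_motion(0.95, 0.95), "receding")  # strict >
  expect_identical(classify_motion(0.95, 0.97, epsilon = 0.05), "receding")
})

test_that("detect_step composes the pipeline and threads state", {
  st <- detector_state(ipf = 10)
  out1 <- detect_step(st, const_frame(20, 18))
  expect_identical(out1$result$posture, "standing")
  expect_identical(out1$result$motion, "unknown")
  expect_equal(out1$result$A1, 20)
  expect_equal(out1$result$df, 20 / 18)
  expect_equal(out1$result$threshold, 64 * 18 * 20 / 18)
  out2 <- detect_step(out1$state, const_frame(20, 18))
  expect_identical(out2$result$motion, "receding")  # equal df, strict rule
  # determinism
  rerun <- detect_step(st, const_frame(20, 18))
  expect_identical(rerun$result, out1$result)
})

test_that("posture via step() agrees exactly with the reduced inequality", {
  set.seed(202)
  n_checked <- 0L
  for (ipf in c(1L, 2L, 5L, 10L)) {
    for (i in 1:250) {
      t_amb <- runif(1, 10, 30)
      fr <- random_frame(thermistor = t_amb)
      got <- detect_step(detector_state(ipf = ipf), fr)$result$posture
      interp_mean <- oracle_interp_mean(fr$pixels, ipf)
      want <- if (interp_mean > (64 / (8 * ipf)) * t_amb) "standing"
              else "sitting"
      expect_identical(got, want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("df is strictly increasing in A1 at fixed ambient temperature", {
  a1 <- sort(runif(50, 5, 35))
  df <- vapply(a1, difference_factor, numeric(1), t = 18)
  expect_true(all(diff(df) > 0))
})

test_that("every processed frame gets exactly one posture and motion label", {
  seqs <- simulate_sequence(make_trajectory(0.9, 0.4, 15, seed = 5))
  log <- detect_frames(seqs$frames)
  expect_identical(nrow(log), 15L)
  expect_true(all(log$posture %in% c("standing", "sitting")))
  expect_true(all(log$motion %in% c("approaching", "receding", "unknown")))
  expect_identical(log$motion[1], "unknown")
})

test_that("malformed frames are skipped, not fatal", {
  frames <- list(const_frame(20), "not a frame", const_frame(21))
  log <- detect_frames(frames)
  expect_identical(nrow(log), 2L)
  expect_error(detect_frames(list("junk")), "no valid frames")
})

test_that("sweep_ipf reports per-factor accuracy matching a re-execution", {
  d <- generate_dataset(20, c("standing", "sitting"), noise_sd = 0,
                        seed = 9)
  frames <- dataset_to_frames(d)
  labels <- attr(frames, "labels")
  tab <- sweep_ipf(frames, labels, c(10, 1, 2))
  expect_identical(tab$ipf, c(1L, 2L, 10L))
  # the reduced threshold (px/(8*ipf))*t separates the default scenes at
  # the operating factor 10; at small factors it sits above both class
  # means, so only the sitting half is labelled correctly
  expect_equal(tab$accuracy[tab$ipf == 10L], 1)
  expect_equal(tab$accuracy[tab$ipf == 1L], 0.5)
  # re-execution oracle on a noisy set
  dn <- generate_dataset(15, c("standing", "sitting"), noise_sd = 1.5,
                         seed = 10)
  fn <- dataset_to_frames(dn)
  tn <- sweep_ipf(fn, attr(fn, "labels"), c(1, 2, 10))
  for (i in seq_len(nrow(tn))) {
    log <- detect_frames(fn, detector_state(ipf = tn$ipf[i]))
    expect_equal(tn$accuracy[i], mean(log$posture == attr(fn, "labels")))
  }
  expect_error(sweep_ipf(list(), character(0), 1), "empty")
})
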