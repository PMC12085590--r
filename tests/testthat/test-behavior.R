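flat_traces <- function(nf = 100, fr = 60) {
  tt <- seq(0, by = 1 / fr, length.out = nf)
  cfg <- synthetic_config(n_units = c(vS1 = 1), behavior_noise_sd = 0, seed = 1)
  trl <- data.frame(trial_id = integer(0), context = character(0),
                    choice = character(0), t_stop_s = numeric(0))
  tr <- data.frame(time_s = tt)
  pos <- socialtouch:::label_rest_positions()
  for (lab in rownames(pos)) {
    tr[[paste0(lab, "_x")]] <- pos[lab, "x"]
    tr[[paste0(lab, "_y")]] <- pos[lab, "y"]
  }
  tr$ball_motion <- 0; tr$ball_direction <- 1; tr$excluded <- FALSE
  tr
}

test_that("motion energy is the two-frame displacement and honors the mask", {
  tr <- flat_traces(10)
  expect_equal(label_motion_energy(tr, "nose1"), rep(0, 10))
  # marker stepping d pixels every 2 frames has energy d
  tr$nose1_x <- tr$nose1_x + rep(c(0, 0, 3), length.out = 10) * 0
  tr$nose1_x <- 100 + 1.5 * floor(seq_len(10) / 2) * 2  # +3 px every 2 frames
  e <- label_motion_energy(tr, "nose1")
  expect_true(all(abs(e[3:10] - 3) < 1e-9))
  # masked frames propagate NA, never interpolation
  tr2 <- exclude_frames(tr, seq_len(10) == 5)
  e2 <- label_motion_energy(tr2, "nose1")
  expect_true(all(is.na(e2[c(5, 7)])))
  expect_false(anyNA(e2[c(3, 4, 8:10)]))
  expect_error(label_motion_energy(tr, "nostril9"), "unknown")
})

test_that("eye area is the shoelace polygon area with scale homogeneity", {
  tr <- flat_traces(3)
  sq <- c("eye1", "eye2", "eye3", "eye4")
  tr[paste0(sq, "_x")] <- rep(list(c(0, 0, 0)), 4)
  tr$eye1_x <- 0; tr$eye2_x <- 2; tr$eye3_x <- 2; tr$eye4_x <- 0
  tr$eye1_y <- 0; tr$eye2_y <- 0; tr$eye3_y <- 2; tr$eye4_y <- 2
  a <- eye_area_trace(tr, sq)
  expect_equal(a, rep(4, 3))
  tr2 <- tr
  for (l in sq) {
    tr2[[paste0(l, "_x")]] <- 2 * tr[[paste0(l, "_x")]]
    tr2[[paste0(l, "_y")]] <- 2 * tr[[paste0(l, "_y")]]
  }
  expect_equal(eye_area_trace(tr2, sq), 4 * a)
  expect_error(eye_area_trace(tr, c("eye1", "eye2")), "3")
})

test_that("features are invariant to rigid translation of all labels", {
  cfg <- synthetic_config(n_units = c(vS1 = 1), n_bouts = 5, frame_rate = 60,
                          afe_prob = c(social = 1, object = 1), seed = 21)
  trl <- generate_trials(cfg)
  b <- generate_behavior_traces(trl, cfg)
  shifted <- b$traces
  for (nm in names(shifted))
    if (grepl("_x$", nm)) shifted[[nm]] <- shifted[[nm]] + 37
    else if (grepl("_y$", nm)) shifted[[nm]] <- shifted[[nm]] - 11
  expect_equal(label_motion_energy(shifted, "whisker1"),
               label_motion_energy(b$traces, "whisker1"))
  expect_equal(eye_area_trace(shifted), eye_area_trace(b$traces))
  expect_equal(nrow(detect_saccades(shifted)), nrow(detect_saccades(b$traces)))
})

test_that("saccade detection is x-axis specific with signed direction", {
  tr <- flat_traces(200, fr = 60)
  # slow drift below threshold
  for (l in paste0("pupil", 1:4))
    tr[[paste0(l, "_x")]] <- tr[[paste0(l, "_x")]] + seq(0, 1, length.out = 200)
  expect_equal(nrow(detect_saccades(tr)), 0)
  # fast +x jump at frame 100 -> one nasal event
  tr2 <- flat_traces(200, fr = 60)
  for (l in paste0("pupil", 1:4))
    tr2[[paste0(l, "_x")]][100:200] <- tr2[[paste0(l, "_x")]][100:200] + 8
  ev <- detect_saccades(tr2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "nasal")
  # pure y movement never triggers
  tr3 <- flat_traces(200, fr = 60)
  for (l in paste0("pupil", 1:4))
    tr3[[paste0(l, "_y")]][100:200] <- tr3[[paste0(l, "_y")]][100:200] + 8
  expect_equal(nrow(detect_saccades(tr3)), 0)
})

test_that("AFE bout detection applies min-duration and merge-gap rules", {
  fr <- 60
  tt <- seq(0, 10, by = 1 / fr)
  f <- rep(0, length(tt))
  expect_equal(detect_afe_bouts(tt, f, "whisker_protraction", threshold = 1)$n_bouts, 0)
  # one planted 2 s supra-threshold epoch
  f1 <- f; f1[tt >= 2 & tt < 4] <- 5
  b1 <- detect_afe_bouts(tt, f1, "whisker_protraction", threshold = 1,
                         min_duration = 0.5)
  expect_equal(b1$n_bouts, 1)
  expect_equal(b1$bouts$t_on_s, 2, tolerance = 2 / fr)
  # two epochs separated by less than the merge gap fuse into one
  f2 <- f; f2[tt >= 2 & tt < 3] <- 5; f2[tt >= 3.1 & tt < 4] <- 5
  expect_equal(detect_afe_bouts(tt, f2, "whisker_protraction", threshold = 1,
                                merge_gap = 0.25)$n_bouts, 1)
  expect_equal(detect_afe_bouts(tt, f2, "whisker_protraction", threshold = 1,
                                merge_gap = 0.05)$n_bouts, 2)
  # masked frames split a bout only when the gap is >= merge_gap
  f3 <- f1; f3[tt >= 2.9 & tt < 3.0] <- NA
  expect_equal(detect_afe_bouts(tt, f3, "whisker_protraction", threshold = 1,
                                merge_gap = 0.25)$n_bouts, 1)
})

test_that("detectors recover planted aversive events at generator defaults", {
  cfg <- synthetic_config(n_units = c(vS1 = 1), n_bouts = 20, frame_rate = 60,
                          afe_prob = c(social = 0.6, object = 0.6), seed = 11)
  trl <- generate_trials(cfg)
  b <- generate_behavior_traces(trl, cfg)
  n_planted <- nrow(b$events)
  expect_gt(n_planted, 5)
  ea <- eye_area_trace(b$traces)
  orb <- detect_afe_bouts(b$traces$time_s, ea, "orbital_tightening")
  wp <- detect_afe_bouts(b$traces$time_s,
                         whisker_protraction_trace(b$traces),
                         "whisker_protraction")
  sc <- detect_saccades(b$traces)
  expect_gte(orb$n_bouts, ceiling(0.95 * n_planted))
  expect_gte(wp$n_bouts, ceiling(0.95 * n_planted))
  expect_gte(nrow(sc), ceiling(0.95 * n_planted))
})

test_that("running-avoidance fraction handles all/none/missing running", {
  tr <- flat_traces(100, fr = 60)
  tr$ball_motion <- 5
  tr$ball_direction <- -1
  w <- c(0, 1)
  expect_equal(running_avoidance_fraction(tr, w), 1)
  tr$ball_direction <- 1
  expect_equal(running_avoidance_fraction(tr, w), 0)
  tr$ball_direction <- rep(c(1, -1), 50)
  expect_equal(running_avoidance_fraction(tr, w), 0.5)
  tr$ball_motion <- 0
  expect_true(is.na(running_avoidance_fraction(tr, w)))
})

test_that("frame exclusion OR-combines and an all-frame mask blanks features", {
  tr <- flat_traces(50)
  tr1 <- exclude_frames(tr, rep(FALSE, 50))
  expect_equal(tr1$excluded, rep(FALSE, 50))
  tr2 <- exclude_frames(tr, rep(TRUE, 50))
  expect_true(all(is.na(eye_area_trace(tr2))))
  expect_true(all(is.na(label_motion_energy(tr2, "nose1"))))
  expect_error(exclude_frames(tr, rep(TRUE, 10)), "length")
})
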