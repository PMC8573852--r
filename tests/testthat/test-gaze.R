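# Gaze QC: visual-angle geometry, exclusion criteria, AOI assignment.

test_that("visual angle conversion matches the set-up constants", {
  expect_equal(round(visual_angle_to_cm(2, 60), 1), 2.1)
  expect_equal(round(visual_angle_to_cm(1.5, 60), 2), 1.57)
  expect_equal(visual_angle_to_cm(0, 60), 0)
  expect_error(visual_angle_to_cm(190, 60), "180")
  expect_error(visual_angle_to_cm(2, 0), "positive")
  # strictly increasing in both arguments
  a <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(visual_angle_to_cm(a, 60)) > 0))
  d <- seq(30, 120, by = 10)
  expect_true(all(diff(visual_angle_to_cm(2, d)) > 0))
  # inverse round trip
  expect_equal(cm_to_visual_angle(visual_angle_to_cm(a, 57), 57), a,
               tolerance = 1e-9)
})

test_that("pixel/centimetre conversion uses the image scale", {
  g <- screen_geometry()
  expect_equal(px_to_cm(1920, g), 49.92)
  expect_equal(cm_to_px(px_to_cm(c(0, 960, 1920), g), g), c(0, 960, 1920))
})

test_that("geometry validation enforces the minimum AOI size", {
  expect_error(screen_geometry(aoi_width_cm = 1.0), "minimum")
  g <- screen_geometry()
  va <- valid_area_rect(g)
  expect_equal(unname(va["x1"] - va["x0"]), g$valid_width_cm)
  expect_equal(unname((va["x0"] + va["x1"]) / 2), g$image_width_cm / 2)
  aois <- aoi_rects(g)
  expect_equal(nrow(aois), 3)
  expect_equal(aois$bar, 2:4)
  expect_true(all(aois$x0 >= va["x0"] & aois$x1 <= va["x1"]))
  # overlapping AOIs are rejected
  expect_error(aoi_rects(screen_geometry(aoi_width_cm = 7)), "overlap")
})

test_that("trial exclusions flag every violated criterion", {
  g <- screen_geometry()
  cx <- g$image_width_cm / 2
  trials <- rbind(
    fixation_trial("few", rep(cx, 3), duration_ms = 2000),
    fixation_trial("ok", cx + seq(-8, 8, length.out = 10),
                   duration_ms = 500),
    fixation_trial("long", cx + seq(-8, 8, length.out = 10),
                   duration_ms = 1400),
    fixation_trial("outside", c(rep(cx, 4), rep(1, 6)), duration_ms = 500)
  )
  res <- apply_trial_exclusions(trials, g)
  res <- res[match(c("few", "ok", "long", "outside"), res$trial_id), ]
  expect_true(res$excluded[res$trial_id == "few"])
  expect_match(res$exclusion_reasons[res$trial_id == "few"],
               "too_few_fixations")
  expect_false(res$excluded[res$trial_id == "ok"])
  expect_true(res$excluded[res$trial_id == "long"])       # 14000 ms > 13714
  expect_match(res$exclusion_reasons[res$trial_id == "long"], "gaze_too_long")
  expect_true(res$excluded[res$trial_id == "outside"])    # 6 outside > 5
  expect_match(res$exclusion_reasons[res$trial_id == "outside"],
               "too_many_outside")
  # a negative externally-recorded outside count marks a corrupt trial
  res2 <- apply_trial_exclusions(
    fixation_trial("bad", rep(cx, 10), duration_ms = 500), g,
    n_outside = list(bad = -1))
  expect_true(res2$excluded)
  expect_match(res2$exclusion_reasons, "corrupt")
})

test_that("exclusion flags are independent of criterion order", {
  g <- screen_geometry()
  cx <- g$image_width_cm / 2
  set.seed(9)
  trials <- do.call(rbind, lapply(1:30, function(i) {
    n <- sample(2:12, 1)
    fixation_trial(paste0("t", i),
                   cx + runif(n, -20, 20),
                   duration_ms = runif(1, 200, 1600))
  }))
  base <- apply_trial_exclusions(trials, g)
  # re-evaluate with trials presented in a different order
  shuffled <- trials[sample(nrow(trials)), ]
  again <- apply_trial_exclusions(shuffled, g)
  again <- again[match(base$trial_id, again$trial_id), ]
  expect_equal(again$excluded, base$excluded)
  # reasons contain the same criterion sets regardless of order
  canon <- function(x) vapply(strsplit(x, ";"), function(v)
    paste(sort(v), collapse = ";"), character(1))
  expect_equal(canon(again$exclusion_reasons), canon(base$exclusion_reasons))
})

test_that("data-point exclusions blank saccade measures only", {
  fx <- rbind(
    fixation_trial("a", seq(10, 40, length.out = 10), duration_ms = 500),
    fixation_trial("b", seq(10, 40, length.out = 10), duration_ms = 500)
  )
  sacc <- tibble::tibble(
    trial_id = c(rep("a", 2), rep("b", 8)),
    onset_ms = 0,
    amplitude_cm = c(10, 10, rep(2.5, 8)),
    direction = "progressive"
  )
  summary <- merge(summarize_fixations(fx), summarize_saccades(sacc),
                   by = "trial_id")
  res <- apply_datapoint_exclusions(summary)
  a <- res[res$trial_id == "a", ]
  b <- res[res$trial_id == "b", ]
  # trial a: 2 saccades < 3 -> saccade measures missing, fixations kept
  expect_true(is.na(a$n_saccades))
  expect_true(is.na(a$dist_progressive_cm))
  expect_equal(a$n_fixations, 10)
  expect_match(a$saccade_exclusion_reasons, "too_few_saccades")
  # trial b: 8 saccades spanning 20 cm > 13 cm, |10 - 8| <= 8 -> clean
  expect_equal(b$n_saccades, 8)
  expect_equal(b$saccade_exclusion_reasons, "")
})

test_that("AOI assignment decomposes fixations into passes", {
  g <- screen_geometry()
  aois <- aoi_rects(g)
  a1 <- aois[1, ]
  inside_x <- (a1$x0 + a1$x1) / 2
  outside_x <- a1$x1 + 3
  # visit (2 fixations), leave (1), return (1)
  fx <- fixation_trial("t", c(inside_x, inside_x, outside_x, inside_x),
                       duration_ms = c(300, 200, 400, 250))
  met <- assign_fixations_to_aois(fx, aois)
  m1 <- met[met$aoi_index == 1, ]
  expect_equal(m1$n_fixations, 3)
  expect_equal(m1$n_first_pass, 2)
  expect_equal(m1$n_second_pass, 1)
  expect_equal(m1$gaze_duration_ms, 750)
  expect_equal(m1$first_pass_duration_ms, 500)
  expect_equal(m1$second_pass_duration_ms, 250)
  expect_false(m1$missing)
  # an AOI never fixated is missing
  m3 <- met[met$aoi_index == 3, ]
  expect_true(m3$missing)
  expect_equal(m3$n_fixations, 0)
  # pass decomposition conserves counts and durations
  expect_equal(m1$n_first_pass + m1$n_second_pass + m1$n_later_pass,
               m1$n_fixations)
  expect_equal(m1$first_pass_duration_ms + m1$second_pass_duration_ms,
               m1$gaze_duration_ms)
})

test_that("AOI boundary membership is left/top inclusive only", {
  g <- screen_geometry()
  aois <- aoi_rects(g)
  a1 <- aois[1, ]
  fx <- rbind(
    fixation_trial("edge", c(a1$x0, a1$x1))  # left edge in, right edge out
  )
  met <- assign_fixations_to_aois(fx, aois)
  expect_equal(met$n_fixations[met$aoi_index == 1], 1)
})

test_that("noisy AOI records are blanked and marked missing", {
  g <- screen_geometry()
  aois <- aoi_rects(g)
  inside_x <- (aois$x0[1] + aois$x1[1]) / 2
  fx <- fixation_trial("noisy", rep(inside_x, 7), duration_ms = 300)
  met <- assign_fixations_to_aois(fx, aois)
  res <- apply_aoi_exclusions(met)
  r1 <- res[res$aoi_index == 1, ]
  expect_true(is.na(r1$n_fixations))  # 7 fixations > 6
  expect_true(r1$missing)
  expect_match(r1$aoi_exclusion_reasons, "too_many_fixations")
  # long gaze duration also blanks the record
  fx2 <- fixation_trial("long", rep(inside_x, 4), duration_ms = 1200)
  res2 <- apply_aoi_exclusions(assign_fixations_to_aois(fx2, aois))
  expect_true(res2$missing[res2$aoi_index == 1])  # 4800 ms > 4000
})
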