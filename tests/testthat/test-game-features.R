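test_that("registry counts match the published per-game inventory", {
  reg <- feature_registry()
  counts <- table(reg$game)
  expect_equal(unname(counts[["boxes"]]), 29)
  expect_equal(unname(counts[["sharing"]]), 44)
  expect_equal(unname(counts[["pinwheel"]]), 41)
  expect_equal(unname(counts[["creativity"]]), 41)
  expect_equal(unname(counts[["catdog"]]), 27)
  # per-game totals sum to 182 (the source's grand total of 181 conflicts
  # with its own per-game counts; the registry follows the per-game counts)
  expect_equal(nrow(reg), 182)
  expect_false(anyDuplicated(paste(reg$game, reg$name)) > 0)
  expect_true(all(reg$source %in% c("flow", "touch", "inertial")))
})

test_that("every extractor emits exactly its registry slice", {
  co <- simulate_cohort(small_cohort_config(n_children = 2, seed = 8))
  for (rec in co$sessions[[1]]$recordings) {
    fv <- extract_features(rec)
    expect_identical(names(fv$values), feature_registry(rec$game_id)$name)
  }
})

test_that("extractors are deterministic and respect bounds", {
  co <- simulate_cohort(small_cohort_config(n_children = 2, seed = 21))
  reg <- feature_registry()
  for (rec in co$sessions[[1]]$recordings) {
    v1 <- extract_features(rec)$values
    v2 <- extract_features(rec)$values
    expect_identical(v1, v2)
    rates <- grep("_rate", names(v1), value = TRUE)
    expect_true(all(v1[rates] >= 0, na.rm = TRUE))
    fracs <- grep("^(pct_|tilt_fraction|exceed_frac)", names(v1),
                  value = TRUE)
    expect_true(all(v1[fracs] >= 0 & v1[fracs] <= 1, na.rm = TRUE))
    eff <- grep("efficiency", names(v1), value = TRUE)
    expect_true(all(v1[eff] >= 0 & v1[eff] <= 1 + 1e-9, na.rm = TRUE))
  }
})

test_that("time dilation halves rates and preserves fractions", {
  rec <- tiny_boxes()
  v1 <- extract_boxes(rec)$values
  rec2 <- rec
  rec2$duration <- rec$duration * 2
  rec2$touches$t <- rec$touches$t * 2
  rec2$events$t <- rec$events$t * 2
  v2 <- extract_boxes(rec2)$values
  for (f in c("successful_move_rate", "unsuccessful_move_rate",
              "total_move_rate"))
    expect_equal(v2[[f]], v1[[f]] / 2)
  # counts and efficiencies unchanged
  expect_equal(v2[["n_ball_moves"]], v1[["n_ball_moves"]])
  expect_equal(v2[["path_efficiency_avg_all"]],
               v1[["path_efficiency_avg_all"]])
})

test_that("boxes: hand-checked fixture and scripted perfect play", {
  v <- extract_boxes(tiny_boxes())$values
  expect_equal(v[["total_time"]], 10)
  expect_equal(v[["n_ball_moves"]], 2)
  expect_equal(v[["success_placements_red"]], 1)
  expect_equal(v[["unsuccess_placements_blue"]], 1)
  expect_equal(v[["successful_move_rate"]], 0.1)
  expect_equal(v[["path_efficiency_avg_all"]], 1)  # both straight

  # scripted perfect play: four rounds, each ball placed correctly 4 times
  rec <- simulate_game_recording("boxes", setNames(rep(50, 10),
                                                   playprogress:::AREAS),
                                 90, cohort_config(), seed = 5,
                                 scripted = TRUE)
  v <- extract_boxes(rec)$values
  for (col in c("red", "blue", "green", "yellow", "purple")) {
    expect_equal(v[[paste0("success_placements_", col)]], 4)
    expect_equal(v[[paste0("unsuccess_placements_", col)]], 0)
  }
})

test_that("boxes: 20 successful moves in 100 s gives rate 0.2", {
  touches <- do.call(rbind, lapply(1:20, function(i)
    straight_path(i, 2 * i, 1, 0.1, 0.2, 0.5, 0.9)))
  events <- data.frame(t = 2 * (1:20) + 1, kind = "ball_drop",
                       ball_colour = "red", box_colour = "red",
                       path_id = 1:20, stringsAsFactors = FALSE)
  rec <- game_recording("boxes", 100, touches, empty_motion_df(), events)
  expect_equal(extract_boxes(rec)$values[["successful_move_rate"]], 0.2)
})

test_that("sharing: distractor rates and perfect drags", {
  taps <- data.frame(t = c(10, 20, 30), kind = "distractor_tap",
                     group = "lamps", object = NA_character_,
                     source = NA_character_, target_character = NA_integer_,
                     path_id = NA_integer_, stringsAsFactors = FALSE)
  drags <- do.call(rbind, lapply(1:4, function(k)
    data.frame(t = 40 + k, kind = "food_drag", group = NA_character_,
               object = "food", source = "table", target_character = k,
               path_id = k, stringsAsFactors = FALSE)))
  touches <- do.call(rbind, lapply(1:4, function(k)
    straight_path(k, 39 + k, 1, 0.5, 0.85, 0.2 * k, 0.25)))
  rec <- game_recording("sharing", 60, touches, empty_motion_df(),
                        rbind(taps, drags))
  v <- extract_sharing(rec)$values
  expect_equal(v[["distractor_rate_lamps"]], 0.05)
  expect_equal(v[["distractor_rate_bird"]], 0)
  expect_equal(v[["distractor_rate_all"]], 0.05)
  expect_equal(v[["food_table_plate_rate"]], 4 / 60)
  for (ch in paste0("char", 1:4))
    expect_equal(v[[paste0("drag_efficiency_avg_", ch)]], 1)
})

test_that("pinwheel: rates, reaction times and level-tablet tilts", {
  v <- extract_pinwheel(tiny_pinwheel())$values
  expect_equal(v[["successful_hit_rate"]], 0.1)
  expect_equal(v[["unsuccessful_hit_rate"]], 0.1)
  expect_equal(v[["ball_fall_rate"]], 0.1)
  expect_equal(v[["rt_successful_mean"]], 1)    # hit at 2, round at 1
  expect_equal(v[["rt_unsuccessful_mean"]], 1.5)
  expect_equal(v[["rt_all_mean"]], 1.25)
  for (d in c("forward", "backward", "left", "right"))
    expect_equal(v[[paste0("tilt_fraction_", d)]], 0)
  # motion stream is mandatory
  bad <- tiny_pinwheel(); bad$motion <- empty_motion_df()
  expect_error(extract_pinwheel(bad), "motion")
})

test_that("creativity: path classification, fill stats, quiet sensors", {
  events <- data.frame(
    t = c(1, 4, 4.2, 9),
    kind = c("image_selected", "outline_completed", "fill_started",
             "colour_change"), stringsAsFactors = FALSE)
  touches <- rbind(
    straight_path(1, 2, 1, 0.3, 0.5, 0.5, 0.5),    # contour
    straight_path(2, 5, 1, 0.3, 0.4, 0.4, 0.4),    # fill, len 0.1
    straight_path(3, 7, 1, 0.3, 0.6, 0.5, 0.6))    # fill, len 0.2
  rec <- game_recording("creativity", 12, touches, flat_motion(12), events)
  v <- extract_creativity(rec)$values
  expect_equal(v[["n_images_selected"]], 1)
  expect_equal(v[["n_images_fill_started"]], 1)
  expect_equal(v[["fill_len_mean"]], 0.15)
  expect_equal(v[["colour_changes_per_image"]], 1)
  expect_equal(v[["exceed_frac_x"]], 0)
  expect_equal(v[["exceed_frac_y"]], 0)
  expect_equal(v[["exceed_frac_z"]], 0)
  expect_equal(v[["draw_speed_mean_fill"]],
               mean(c(0.1, 0.2)))  # 0.1 and 0.2 units over 1 s each
})

test_that("catdog: answers, restrain percentage and reaction times", {
  n <- 10
  onsets <- 2.5 * (1:n)
  stim <- data.frame(t = onsets, kind = "stimulus_onset",
                     modality = "image", target = TRUE,
                     region = NA_character_, stringsAsFactors = FALSE)
  taps <- data.frame(t = onsets + 0.4, kind = "response_tap",
                     modality = NA_character_, target = NA,
                     region = "expected", stringsAsFactors = FALSE)
  touches <- do.call(rbind, lapply(1:n, function(i)
    data.frame(path_id = i, t = c(onsets[i] + 0.4, onsets[i] + 0.45),
               x = 0.5, y = 0.5, phase = c("began", "ended"),
               stringsAsFactors = FALSE)))
  rec <- game_recording("catdog", 30, touches, empty_motion_df(),
                        rbind(stim, taps))
  v <- extract_catdog(rec)$values
  expect_equal(v[["rt_mean_correct_image"]], 0.4)
  expect_equal(v[["pct_touch_answers"]], 1)
  expect_equal(v[["pct_restrain"]], 0)
  expect_equal(v[["correct_answer_rate"]], n / 30)

  # no taps at all: all-restrain session
  rec2 <- game_recording("catdog", 30, empty_touches_df(),
                         empty_motion_df(), stim)
  v2 <- extract_catdog(rec2)$values
  expect_equal(v2[["pct_restrain"]], 1)
  expect_equal(v2[["pct_touch_answers"]], 0)
  expect_equal(v2[["correct_answer_rate"]], 0)
  expect_true(is.na(v2[["rt_mean_all"]]))  # explicit not-available
})

test_that("wrong game id and zero duration are rejected", {
  expect_error(extract_sharing(tiny_boxes()), "sharing")
  expect_error(game_recording("boxes", 0), "duration")
})
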