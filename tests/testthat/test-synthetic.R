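test_that("simulation is deterministic given the master seed", {
  cfg <- small_cohort_config(n_children = 2, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$skills, c2$skills)
  expect_identical(c1$sessions[[1]]$questionnaire,
                   c2$sessions[[1]]$questionnaire)
  expect_identical(c1$sessions[[2]]$recordings$boxes$touches,
                   c2$sessions[[2]]$recordings$boxes$touches)
})

test_that("session counts respect the configured range", {
  co <- simulate_cohort(small_cohort_config(n_children = 8, seed = 2))
  per_child <- table(vapply(co$sessions, function(s) s$child_id,
                            character(1)))
  expect_true(all(per_child >= 2 & per_child <= 3))
})

test_that("zero drift and zero rating noise yields no progress labels", {
  cfg <- small_cohort_config(n_children = 4, seed = 9, drift = 0,
                             latent_sd = 0, rating_noise = 0)
  co <- simulate_cohort(cfg)
  sc <- cohort_area_scores(co$sessions)
  f <- extract_cohort_features(co$sessions)
  d <- build_diff_samples(f, sc, "boxes", "fine_motor", "consecutive")
  expect_true(all(d$label == "no_progress"))  # strict-increase rule
})

test_that("null cohort progress frequency is near one half", {
  # drift 0 with rating noise: label is the sign of a symmetric noise
  # delta; estimate over many children at questionnaire level only
  cfg <- cohort_config(n_children = 200, sessions_range = c(2, 2),
                      drift = 0, latent_sd = 0, rating_noise = 0.6,
                      seed = 123)
  ins <- default_instrument()
  with_seed <- playprogress:::with_seed
  freqs <- with_seed(99, {
    labs <- replicate(200, {
      s <- setNames(runif(10, 30, 70), playprogress:::AREAS)
      q1 <- simulate_questionnaire(s, ins, 0.6)
      q2 <- simulate_questionnaire(s, ins, 0.6)
      a1 <- area_scores(q1, ins); a2 <- area_scores(q2, ins)
      progress_label(a1[["fine_motor"]], a2[["fine_motor"]]) == "progress"
    })
    mean(labs)
  })
  expect_lt(abs(freqs - 0.5), 0.08)
})

test_that("scripted perfect play fixtures are deterministic and perfect", {
  skills <- setNames(rep(50, 10), playprogress:::AREAS)
  cfg <- cohort_config()
  r1 <- simulate_game_recording("boxes", skills, 90, cfg, seed = 4,
                                scripted = TRUE)
  r2 <- simulate_game_recording("boxes", skills, 90, cfg, seed = 4,
                                scripted = TRUE)
  expect_identical(r1$events, r2$events)
  drops <- r1$events[r1$events$kind == "ball_drop", ]
  expect_equal(nrow(drops), 20)  # 4 rounds x 5 balls
  expect_true(all(drops$ball_colour == drops$box_colour))
  expect_error(simulate_game_recording("boxes", skills, 0, cfg), "duration")
  expect_error(simulate_game_recording("tennis", skills, 10, cfg),
               "unknown")
})

test_that("higher fine-motor skill raises mean path efficiency", {
  cfg <- small_cohort_config(seed = 1)
  eff_at <- function(skill, seeds = 12) {
    skills <- setNames(rep(50, 10), playprogress:::AREAS)
    skills["fine_motor"] <- skill
    mean(vapply(seq_len(seeds), function(s) {
      rec <- simulate_game_recording("boxes", skills, 50, cfg, seed = 100 + s)
      extract_boxes(rec)$values[["path_efficiency_avg_all"]]
    }, numeric(1)))
  }
  e <- c(eff_at(20), eff_at(50), eff_at(80))
  expect_true(e[1] < e[2] && e[2] < e[3])
})

test_that("questionnaire simulation maps skill monotonically to ratings", {
  ins <- default_instrument()
  mid <- simulate_questionnaire(setNames(rep(50, 10),
                                         playprogress:::AREAS),
                                ins, noise_sd = 0, seed = 1)
  expect_true(all(mid == 3L))  # skill 50 -> mid-scale exactly
  lo <- simulate_questionnaire(setNames(rep(20, 10), playprogress:::AREAS),
                               ins, noise_sd = 0, seed = 1)
  hi <- simulate_questionnaire(setNames(rep(80, 10), playprogress:::AREAS),
                               ins, noise_sd = 0, seed = 1)
  expect_true(all(area_scores(lo, ins) <= area_scores(hi, ins)))
  noisy <- simulate_questionnaire(setNames(rep(50, 10),
                                           playprogress:::AREAS),
                                  ins, noise_sd = 3, seed = 2)
  expect_true(all(noisy >= 1L & noisy <= 5L))  # clipped to scale
})

test_that("cohort writes to disk and reads back", {
  co <- simulate_cohort(small_cohort_config(n_children = 2, seed = 44))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back$sessions, length(co$sessions))
  expect_equal(back$skills$fine_motor, co$skills$fine_motor)
  expect_length(validate_cohort(back$sessions), 0)
})
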