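## Synthetic cohort simulator -----------------------------------------------
##
## Generates cohorts of simulated children: latent developmental skills
## drifting month to month, per-game event/touch/motion streams whose
## kinematics are monotone readouts of the linked skills, and therapist
## questionnaires that are noisy discretized readouts of the same skills.
## Latent skills live on a 0-100 scale.  Behavioural control parameters are
## logistic in skill ("abilities" in (0,1)); with an empty effect map every
## ability is 0.5 and gameplay carries no skill signal (a null cohort).

#' Default effect map linking areas to game behaviour parameters
#'
#' Each row makes one behavioural control parameter of one game monotone
#' in one area's latent skill with the given strength.
#'
#' @return Data frame with columns `area`, `game`, `param`, `strength`.
#' @export
default_effect_map <- function() {
  m <- rbind(
    c("fine_motor", "boxes", "motor", 1),
    c("following_instructions", "boxes", "accuracy", 1),
    c("communication", "boxes", "accuracy", 0.5),
    c("attention", "boxes", "focus", 1),
    c("fine_motor", "sharing", "motor", 1),
    c("following_instructions", "sharing", "compliance", 1),
    c("attention", "sharing", "focus", 1),
    c("gross_motor", "pinwheel", "control", 1),
    c("attention", "pinwheel", "focus", 0.5),
    c("stimulation_reaction", "pinwheel", "tempo", 1),
    c("stereotypical", "pinwheel", "control", 0.5),
    c("fine_motor", "creativity", "motor", 1),
    c("attention", "creativity", "focus", 1),
    c("challenging", "creativity", "calm", 1),
    c("stimulation_reaction", "creativity", "calm", 0.5),
    c("attention", "catdog", "focus", 1),
    c("communication", "catdog", "focus", 0.5),
    c("stimulation_reaction", "catdog", "tempo", 1),
    c("social_emotional", "catdog", "restraint", 1))
  data.frame(area = m[, 1], game = m[, 2], param = m[, 3],
             strength = as.numeric(m[, 4]), stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' Defaults state the emulated study conditions: 40 children aged 37-83
#' months, 2-7 monthly sessions each (children with a single session would
#' be excluded downstream anyway), ten latent skill areas drifting by
#' `drift` points per month on the 0-100 scale.
#'
#' @param n_children Number of children, default 40.
#' @param sessions_range Inclusive range of sessions per child, default
#'   `c(2, 7)`.
#' @param age_range Age range in months at enrolment, default `c(37, 83)`.
#' @param drift Mean monthly latent-skill change (0-100 scale), default 2.
#' @param latent_sd SD of the monthly latent-skill innovation, default 3.
#' @param rating_noise SD of the therapist rating noise on the 1-5 item
#'   scale, default 0.4.
#' @param effect_map Data frame as [default_effect_map()]; an empty data
#'   frame yields a null cohort.
#' @param games Games recorded each session.
#' @param durations Named game durations in seconds.
#' @param touch_hz,motion_hz Sensor sampling rates (the study hardware's
#'   rates are unpublished; these are typical tablet rates).
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_children = 40L, sessions_range = c(2L, 7L),
                          age_range = c(37, 83), drift = 2,
                          latent_sd = 3, rating_noise = 0.4,
                          effect_map = default_effect_map(),
                          games = GAME_IDS,
                          durations = c(boxes = 90, sharing = 300,
                                        pinwheel = 150, creativity = 180,
                                        catdog = 120),
                          touch_hz = 60, motion_hz = 100, seed = 1L) {
  if (n_children < 1) stop("n_children must be >= 1")
  if (latent_sd < 0 || rating_noise < 0) stop("noise sds must be >= 0")
  structure(list(n_children = as.integer(n_children),
                 sessions_range = as.integer(sessions_range),
                 age_range = age_range, drift = drift,
                 latent_sd = latent_sd, rating_noise = rating_noise,
                 effect_map = effect_map, games = games,
                 durations = durations, touch_hz = touch_hz,
                 motion_hz = motion_hz, seed = as.integer(seed)),
            class = "cohort_config")
}

## ability in (0,1): logistic in the strength-weighted skill deviations
ability <- function(skills, effect_map, game, param) {
  rows <- effect_map[effect_map$game == game & effect_map$param == param, ,
                     drop = FALSE]
  if (!nrow(rows)) return(0.5)
  stats::plogis(sum(rows$strength * (skills[rows$area] - 50) / 15))
}

clip01 <- function(v) pmin(1, pmax(0, v))

## A drag path: straight line plus perpendicular jitter, sampled at hz.
sim_path <- function(path_id, t0, from, to, speed, jitter, hz) {
  d <- sqrt(sum((to - from)^2))
  dur <- max(d / max(speed, 1e-3), 2.5 / hz)
  tt <- seq(0, dur, by = 1 / hz)
  if (length(tt) < 3) tt <- seq(0, dur, length.out = 3)
  frac <- tt / dur
  perp <- c(-(to - from)[2], (to - from)[1]) / max(d, 1e-9)
  wob <- jitter * sin(frac * pi * stats::runif(1, 1, 3)) +
    stats::rnorm(length(tt), 0, jitter / 3)
  x <- clip01(from[1] + frac * (to[1] - from[1]) + perp[1] * wob)
  y <- clip01(from[2] + frac * (to[2] - from[2]) + perp[2] * wob)
  n <- length(tt)
  data.frame(path_id = as.integer(path_id), t = t0 + tt, x = x, y = y,
             phase = c("began", rep("moved", n - 2), "ended"),
             stringsAsFactors = FALSE)
}

sim_tap <- function(path_id, t0, x, y) {
  data.frame(path_id = as.integer(path_id), t = c(t0, t0 + 0.05),
             x = clip01(c(x, x)), y = clip01(c(y, y)),
             phase = c("began", "ended"), stringsAsFactors = FALSE)
}

baseline_motion <- function(duration, hz, accel_sd = 0.05) {
  tt <- seq(0, duration, by = 1 / hz)
  ar <- function(sd) as.numeric(stats::filter(stats::rnorm(length(tt), 0,
                                                           sd),
                                              0.9, "recursive"))
  data.frame(t = tt, ax = ar(accel_sd), ay = ar(accel_sd),
             az = ar(accel_sd), roll = ar(0.01), pitch = ar(0.01),
             stringsAsFactors = FALSE)
}

sim_boxes <- function(skills, duration, cfg, scripted = FALSE) {
  motor <- if (scripted) 1 else ability(skills, cfg$effect_map, "boxes",
                                        "motor")
  acc <- if (scripted) 1 else ability(skills, cfg$effect_map, "boxes",
                                      "accuracy")
  focus <- if (scripted) 1 else ability(skills, cfg$effect_map, "boxes",
                                        "focus")
  speed <- 0.25 + 0.55 * motor
  jitter <- if (scripted) 0 else 0.005 + 0.10 * (1 - motor)
  p_correct <- 0.35 + 0.63 * acc
  boxes_x <- seq(0.1, 0.9, length.out = 5)
  touches <- list(); events <- list()
  t <- 1; pid <- 0L
  for (round in 1:4) {
    events[[length(events) + 1L]] <-
      data.frame(t = t, kind = "round_start", stringsAsFactors = FALSE)
    for (ball in 1:5) {
      if (t > duration - 3) break
      colour <- BALL_COLOURS[ball]
      from <- c(if (scripted) 0.1 + 0.2 * (ball - 1)
                else stats::runif(1, 0.05, 0.95),
                if (scripted) 0.2 else stats::runif(1, 0.1, 0.3))
      ## occasional aimless move that reaches no box
      if (!scripted && stats::runif(1) > 0.3 + 0.7 * focus) {
        pid <- pid + 1L
        mid <- clip01(from + stats::runif(2, -0.3, 0.3))
        touches[[length(touches) + 1L]] <-
          sim_path(pid, t, from, mid, speed, jitter * 2, cfg$touch_hz)
        t <- t + (touches[[length(touches)]]$t[1] -
                    t) + diff(range(touches[[length(touches)]]$t)) + 0.3
      }
      correct <- scripted || stats::runif(1) < p_correct
      target <- if (correct) ball else
        sample(setdiff(1:5, ball), 1)
      to <- c(boxes_x[target], 0.88)
      pid <- pid + 1L
      pth <- sim_path(pid, t, from, to, speed, jitter, cfg$touch_hz)
      touches[[length(touches) + 1L]] <- pth
      t_end <- max(pth$t)
      events[[length(events) + 1L]] <-
        data.frame(t = t_end, kind = "ball_drop", ball_colour = colour,
                   box_colour = BALL_COLOURS[target], path_id = pid,
                   stringsAsFactors = FALSE)
      t <- t_end + if (scripted) 0.5 else stats::rexp(1, 2) + 0.3
    }
    if (t > duration - 3) break
  }
  ev <- do.call(rbind, lapply(events, function(e) {
    e$ball_colour <- if (is.null(e$ball_colour)) NA_character_ else
      e$ball_colour
    e$box_colour <- if (is.null(e$box_colour)) NA_character_ else
      e$box_colour
    e$path_id <- if (is.null(e$path_id)) NA_integer_ else e$path_id
    e[, c("t", "kind", "ball_colour", "box_colour", "path_id")]
  }))
  game_recording("boxes", duration, do.call(rbind, touches),
                 empty_motion(), ev)
}

sim_sharing <- function(skills, duration, cfg, scripted = FALSE) {
  motor <- if (scripted) 1 else ability(skills, cfg$effect_map, "sharing",
                                        "motor")
  comp <- if (scripted) 1 else ability(skills, cfg$effect_map, "sharing",
                                       "compliance")
  focus <- if (scripted) 1 else ability(skills, cfg$effect_map, "sharing",
                                        "focus")
  speed <- 0.25 + 0.55 * motor
  jitter <- if (scripted) 0 else 0.005 + 0.10 * (1 - motor)
  plates <- cbind(seq(0.15, 0.85, length.out = 4), 0.25)
  table_pos <- c(0.5, 0.85)
  touches <- list(); events <- list()
  events[[1]] <- data.frame(t = 0.5, kind = "round_start",
                            stringsAsFactors = FALSE)
  events[[2]] <- data.frame(t = duration / 2, kind = "round_start",
                            stringsAsFactors = FALSE)
  t <- 1; pid <- 0L; k <- 0L
  while (t < duration - 3) {
    if (!scripted && stats::runif(1) > 0.25 + 0.75 * focus) {
      grp <- sample(DISTRACTOR_GROUPS[1:4], 1)
      pid <- pid + 1L
      touches[[length(touches) + 1L]] <-
        sim_tap(pid, t, stats::runif(1), stats::runif(1, 0, 0.2))
      events[[length(events) + 1L]] <-
        data.frame(t = t, kind = "distractor_tap", group = grp,
                   stringsAsFactors = FALSE)
      t <- t + stats::rexp(1, 1) + 0.5
      next
    }
    k <- k + 1L
    target <- (k - 1L) %% 4L + 1L
    is_food <- scripted || stats::runif(1) < 0.4 + 0.58 * comp
    from_table <- scripted || stats::runif(1) < 0.3 + 0.68 * comp
    from <- if (from_table) table_pos else
      plates[sample(4, 1), ] + stats::runif(2, -0.03, 0.03)
    pid <- pid + 1L
    pth <- sim_path(pid, t, from, plates[target, ], speed, jitter,
                    cfg$touch_hz)
    touches[[length(touches) + 1L]] <- pth
    events[[length(events) + 1L]] <-
      data.frame(t = max(pth$t), kind = "food_drag",
                 object = if (is_food) "food" else "other",
                 source = if (from_table) "table" else "plate",
                 target_character = target, path_id = pid,
                 stringsAsFactors = FALSE)
    t <- max(pth$t) + if (scripted) 0.8 else stats::rexp(1, 1.2) + 0.4
  }
  ev <- do.call(rbind, lapply(events, function(e) {
    for (cn in c("group", "object", "source"))
      if (is.null(e[[cn]])) e[[cn]] <- NA_character_
    for (cn in c("target_character", "path_id"))
      if (is.null(e[[cn]])) e[[cn]] <- NA_integer_
    e[, c("t", "kind", "group", "object", "source", "target_character",
          "path_id")]
  }))
  game_recording("sharing", duration, do.call(rbind, touches),
                 empty_motion(), ev)
}

sim_pinwheel <- function(skills, duration, cfg, scripted = FALSE) {
  control <- if (scripted) 1 else ability(skills, cfg$effect_map,
                                          "pinwheel", "control")
  focus <- if (scripted) 1 else ability(skills, cfg$effect_map, "pinwheel",
                                        "focus")
  tempo <- if (scripted) 1 else ability(skills, cfg$effect_map, "pinwheel",
                                        "tempo")
  mm <- baseline_motion(duration, cfg$motion_hz)
  p_hit <- 0.25 + 0.7 * (0.6 * control + 0.4 * focus)
  touches <- list(); events <- list()
  t <- 1; pid <- 0L
  while (t < duration - 4) {
    events[[length(events) + 1L]] <-
      data.frame(t = t, kind = "round_start", success = NA,
                 stringsAsFactors = FALSE)
    latency <- if (scripted) 1.5 else 0.8 + 3 * (1 - tempo) +
      stats::rexp(1, 2)
    t_hit <- min(t + latency, duration - 0.1)
    ## tilt bump toward a random direction during the attempt
    dir <- sample(c("pitch", "roll"), 1)
    sgn <- sample(c(-1, 1), 1)
    amp <- 0.2 + 0.35 * (1 - 0.7 * control)
    unsteady <- 1 - control
    sel <- mm$t >= t & mm$t <= t_hit
    phase <- (mm$t[sel] - t) / max(t_hit - t, 0.1)
    bump <- sgn * amp * sin(pi * phase) *
      (1 + 0.5 * unsteady * sin(2 * pi * 4 * phase))
    mm[[dir]][sel] <- mm[[dir]][sel] + bump
    hit <- stats::runif(1) < p_hit
    fell <- !hit && stats::runif(1) < 0.5
    if (fell) {
      events[[length(events) + 1L]] <-
        data.frame(t = t_hit, kind = "ball_fall", success = NA,
                   stringsAsFactors = FALSE)
    } else {
      events[[length(events) + 1L]] <-
        data.frame(t = t_hit, kind = "petal_hit", success = hit,
                   stringsAsFactors = FALSE)
    }
    if (!scripted && stats::runif(1) > focus) {
      pid <- pid + 1L
      touches[[length(touches) + 1L]] <-
        sim_tap(pid, min(t + 0.3, duration - 0.1), stats::runif(1),
                stats::runif(1))
    }
    t <- t_hit + if (scripted) 1 else stats::rexp(1, 1) + 0.8
  }
  ev <- do.call(rbind, events)
  tt <- if (length(touches)) do.call(rbind, touches) else empty_touches()
  game_recording("pinwheel", duration, tt, mm, ev)
}

sim_creativity <- function(skills, duration, cfg, scripted = FALSE) {
  motor <- if (scripted) 1 else ability(skills, cfg$effect_map,
                                        "creativity", "motor")
  focus <- if (scripted) 1 else ability(skills, cfg$effect_map,
                                        "creativity", "focus")
  calm <- if (scripted) 1 else ability(skills, cfg$effect_map, "creativity",
                                       "calm")
  mm <- baseline_motion(duration, cfg$motion_hz,
                        accel_sd = 0.04 + 0.18 * (1 - calm))
  speed <- 0.2 + 0.5 * motor
  jitter <- if (scripted) 0 else 0.004 + 0.08 * (1 - motor)
  touches <- list(); events <- list()
  t <- 1; pid <- 0L
  while (t < duration - 8) {
    events[[length(events) + 1L]] <-
      data.frame(t = t, kind = "image_selected", stringsAsFactors = FALSE)
    t <- t + 1
    centre <- stats::runif(2, 0.3, 0.7)
    for (seg in seq_len(3 + stats::rpois(1, 2))) {  # contour strokes
      if (t > duration - 4) break
      a <- centre + 0.2 * c(cos(seg), sin(seg))
      b <- centre + 0.2 * c(cos(seg + 1), sin(seg + 1))
      pid <- pid + 1L
      pth <- sim_path(pid, t, clip01(a), clip01(b), speed, jitter,
                      cfg$touch_hz)
      touches[[length(touches) + 1L]] <- pth
      t <- max(pth$t) + 0.4
    }
    outlined <- scripted || stats::runif(1) < 0.3 + 0.68 * focus
    if (outlined && t < duration - 3) {
      events[[length(events) + 1L]] <-
        data.frame(t = t, kind = "outline_completed",
                   stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <-
        data.frame(t = t + 0.2, kind = "fill_started",
                   stringsAsFactors = FALSE)
      t <- t + 0.4
      for (stroke in seq_len(2 + stats::rpois(1, 2))) {  # fill strokes
        if (t > duration - 2) break
        horiz <- stats::runif(1) < 0.5
        len <- stats::runif(1, 0.1, 0.35)
        a <- clip01(centre + stats::runif(2, -0.15, 0.15))
        b <- clip01(a + if (horiz) c(len, stats::runif(1, 0, 0.04))
                    else c(stats::runif(1, 0, 0.04), len))
        pid <- pid + 1L
        pth <- sim_path(pid, t, a, b, speed, jitter, cfg$touch_hz)
        touches[[length(touches) + 1L]] <- pth
        t <- max(pth$t) + 0.3
      }
      for (cc in seq_len(stats::rpois(1, 1.5)))
        events[[length(events) + 1L]] <-
          data.frame(t = min(t + 0.1 * cc, duration),
                     kind = "colour_change", stringsAsFactors = FALSE)
    }
    t <- t + 1.5
  }
  ev <- do.call(rbind, events)
  game_recording("creativity", duration, do.call(rbind, touches), mm, ev)
}

sim_catdog <- function(skills, duration, cfg, scripted = FALSE) {
  focus <- if (scripted) 1 else ability(skills, cfg$effect_map, "catdog",
                                        "focus")
  tempo <- if (scripted) 1 else ability(skills, cfg$effect_map, "catdog",
                                        "tempo")
  restraint <- if (scripted) 1 else ability(skills, cfg$effect_map,
                                            "catdog", "restraint")
  p_answer <- 0.3 + 0.68 * focus
  p_impulse <- if (scripted) 0 else 0.75 * (1 - restraint)
  touches <- list(); events <- list()
  t <- 1.5; pid <- 0L
  while (t < duration - 3) {
    modality <- sample(c("image", "sound"), 1)
    target <- scripted || stats::runif(1) < 0.5
    events[[length(events) + 1L]] <-
      data.frame(t = t, kind = "stimulus_onset", modality = modality,
                 target = target, region = NA_character_,
                 stringsAsFactors = FALSE)
    tapped <- if (target) scripted || stats::runif(1) < p_answer
              else stats::runif(1) < p_impulse
    if (tapped) {
      rt <- if (scripted) 0.4 else
        min(0.25 + 1.2 * (1 - tempo) + stats::rexp(1, 4), 1.9)
      pid <- pid + 1L
      touches[[length(touches) + 1L]] <-
        sim_tap(pid, t + rt, 0.5, 0.5)
      events[[length(events) + 1L]] <-
        data.frame(t = t + rt, kind = "response_tap", modality = NA,
                   target = NA, region = "expected",
                   stringsAsFactors = FALSE)
    }
    if (!scripted && stats::runif(1) < 0.3 * (1 - focus)) {
      pid <- pid + 1L
      touches[[length(touches) + 1L]] <- sim_tap(pid, t + 2.2, 0.1, 0.1)
      events[[length(events) + 1L]] <-
        data.frame(t = t + 2.2, kind = "response_tap", modality = NA,
                   target = NA, region = "unexpected",
                   stringsAsFactors = FALSE)
    }
    t <- t + if (scripted) 2.5 else stats::runif(1, 2.2, 3.2)
  }
  ev <- do.call(rbind, events)
  tt <- if (length(touches)) do.call(rbind, touches) else empty_touches()
  game_recording("catdog", duration, tt, empty_motion(), ev)
}

#' Simulate a single game recording
#'
#' @param game_id Game to simulate.
#' @param skills Named latent-skill vector over the ten areas (0-100).
#' @param duration Game duration in seconds (> 0).
#' @param config A [cohort_config()] (effect map and sampling rates are
#'   taken from it).
#' @param seed Optional seed for this recording alone.
#' @param scripted When TRUE, produce deterministic perfect play (all
#'   rounds completed, straight paths, fixed reaction times) for use as a
#'   fixture.
#' @return A valid `game_recording`.
#' @export
simulate_game_recording <- function(game_id, skills, duration,
                                    config = cohort_config(), seed = NULL,
                                    scripted = FALSE) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0")
  if (any(!is.finite(skills))) stop("skills must be finite")
  fun <- switch(game_id, boxes = sim_boxes, sharing = sim_sharing,
                pinwheel = sim_pinwheel, creativity = sim_creativity,
                catdog = sim_catdog, stop("unknown game: ", game_id))
  if (is.null(seed)) fun(skills, duration, config, scripted)
  else with_seed(seed, fun(skills, duration, config, scripted))
}

#' Simulate a therapist questionnaire response
#'
#' Each item rating is a clipped, rounded monotone map of its area's
#' latent skill plus Gaussian noise: skill 0 maps to the scale minimum,
#' 100 to the maximum, 50 to mid-scale exactly.
#'
#' @param skills Named latent-skill vector (0-100 scale).
#' @param instrument Instrument definition from [default_instrument()].
#' @param noise_sd Rating noise SD in rating points.
#' @param seed Optional seed.
#' @return Named integer vector of ratings (an item-id keyed
#'   questionnaire).
#' @export
simulate_questionnaire <- function(skills, instrument = default_instrument(),
                                   noise_sd = 0.4, seed = NULL) {
  gen <- function() {
    mid <- instrument$scale_min +
      (instrument$scale_max - instrument$scale_min) *
        pmin(pmax(skills[instrument$area], 0), 100) / 100
    r <- round(mid + stats::rnorm(nrow(instrument), 0, noise_sd))
    r <- pmin(pmax(r, instrument$scale_min), instrument$scale_max)
    stats::setNames(as.integer(r), instrument$item_id)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a full cohort
#'
#' Skills evolve as `s[t+1] = s[t] + drift + N(0, latent_sd)` (clipped to
#' 0-100); each session yields one recording per configured game and one
#' questionnaire.  Re-running with the same config reproduces the cohort
#' exactly.
#'
#' @param config A [cohort_config()].
#' @param instrument Instrument definition.
#' @return List with `sessions` (session_records), `skills` (ground-truth
#'   data frame: child_id, session_index, one column per area), `ages`
#'   (months at enrolment) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            instrument = default_instrument()) {
  if (!inherits(config, "cohort_config")) stop("invalid config")
  with_seed(config$seed, {
    sessions <- list()
    skill_rows <- list()
    ages <- numeric(config$n_children)
    for (i in seq_len(config$n_children)) {
      cid <- sprintf("child_%03d", i)
      ages[i] <- stats::runif(1, config$age_range[1], config$age_range[2])
      n_s <- sample(seq(config$sessions_range[1], config$sessions_range[2]),
                    1)
      s <- pmin(pmax(stats::rnorm(length(AREAS), 50, 10), 5), 95)
      names(s) <- AREAS
      for (k in seq_len(n_s)) {
        if (k > 1)
          s <- pmin(pmax(s + config$drift +
                           stats::rnorm(length(AREAS), 0,
                                        config$latent_sd), 0), 100)
        recs <- lapply(config$games, function(g)
          simulate_game_recording(g, s, config$durations[[g]], config))
        q <- simulate_questionnaire(s, instrument, config$rating_noise)
        sessions[[length(sessions) + 1L]] <-
          session_record(cid, k, recs, q)
        skill_rows[[length(skill_rows) + 1L]] <-
          c(list(child_id = cid, session_index = k), as.list(s))
      }
    }
    skills <- as.data.frame(
      lapply(stats::setNames(nm = c("child_id", "session_index", AREAS)),
             function(cn) unlist(lapply(skill_rows, `[[`, cn),
                                 use.names = FALSE)),
      stringsAsFactors = FALSE)
    list(sessions = sessions, skills = skills, ages = ages,
         config = config)
  })
}

#' Write a simulated cohort to disk
#'
#' Produces one session JSONL file per (child, session), a cohort manifest
#' CSV, the questionnaire responses CSV and the ground-truth skills CSV.
#'
#' @param cohort From [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(child_id = character(), session_index = integer(),
                         file = character(), stringsAsFactors = FALSE)
  responses <- list()
  for (s in cohort$sessions) {
    fn <- sprintf("%s_s%02d.jsonl", s$child_id, s$session_index)
    write_session(s, file.path(dir, fn))
    manifest[nrow(manifest) + 1L, ] <- list(s$child_id, s$session_index, fn)
    if (!is.null(s$questionnaire))
      responses[[length(responses) + 1L]] <-
        data.frame(child_id = s$child_id, session_index = s$session_index,
                   item_id = names(s$questionnaire),
                   rating = unname(s$questionnaire),
                   stringsAsFactors = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (length(responses))
    utils::write.csv(do.call(rbind, responses),
                     file.path(dir, "responses.csv"), row.names = FALSE)
  utils::write.csv(cohort$skills, file.path(dir, "skills.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory containing `manifest.csv`.
#' @return List with `sessions` and (if present) `skills`.
#' @export
read_cohort <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  sessions <- lapply(mf$file, function(f) read_session(file.path(dir, f)))
  skills_path <- file.path(dir, "skills.csv")
  skills <- if (file.exists(skills_path))
    utils::read.csv(skills_path, stringsAsFactors = FALSE) else NULL
  list(sessions = sessions, skills = skills)
}
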