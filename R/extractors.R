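## Per-game feature extractors ----------------------------------------------
##
## Every extractor returns a `feature_vector` whose value names equal the
## registry slice for its game, in registry order.  Statistics over empty
## sets (e.g. reaction times when no hit occurred) are emitted as NA — an
## explicit not-available marker, never a silent zero.  Percentages are
## stored as fractions in [0, 1]; dataset-level min-max scaling makes the
## convention immaterial downstream.

feature_vector <- function(game_id, values, config) {
  reg <- feature_registry(game_id)
  if (!identical(sort(names(values)), sort(reg$name)))
    stop("internal error: extractor keys do not match registry for ", game_id)
  structure(list(game_id = game_id, values = values[reg$name],
                 config = config),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>", x$game_id, "-", length(x$values), "features (",
      sum(is.na(x$values)), "not available )\n")
  invisible(x)
}

check_recording <- function(recording, game_id, need_motion = FALSE) {
  if (!inherits(recording, "game_recording"))
    stop("not a game_recording")
  if (recording$game_id != game_id)
    stop("expected a ", game_id, " recording, got ", recording$game_id)
  if (recording$duration <= 0) stop("zero or negative duration")
  if (need_motion && nrow(recording$motion) == 0)
    stop(game_id, " requires a motion stream")
}

## Split touches into per-path (t, x, y) data frames, in path order.
touch_paths <- function(touches) {
  if (!nrow(touches)) return(list())
  lapply(split(touches, touches$path_id), function(p)
    p[order(p$t), c("t", "x", "y")])
}

## Per-path scalar descriptors used by several games.
path_summaries <- function(paths) {
  if (!length(paths))
    return(data.frame(path_id = integer(), length = numeric(),
                      efficiency = numeric(), speed = numeric(),
                      t_start = numeric(), t_end = numeric(),
                      hrange = numeric(), vrange = numeric()))
  data.frame(
    path_id = as.integer(names(paths)),
    length = vapply(paths, function(p) path_length(p$x, p$y), numeric(1)),
    efficiency = vapply(paths, function(p) path_efficiency(p$x, p$y),
                        numeric(1)),
    speed = vapply(paths, function(p) {
      dt <- p$t[nrow(p)] - p$t[1]
      if (dt > 0) path_length(p$x, p$y) / dt else NA_real_
    }, numeric(1)),
    t_start = vapply(paths, function(p) p$t[1], numeric(1)),
    t_end = vapply(paths, function(p) p$t[nrow(p)], numeric(1)),
    hrange = vapply(paths, function(p) diff(range(p$x)), numeric(1)),
    vrange = vapply(paths, function(p) diff(range(p$y)), numeric(1)),
    row.names = NULL)
}

stat3_of <- function(prefix, x, suffix) {
  x <- x[is.finite(x)]
  v <- if (length(x)) c(mean(x), min(x), max(x)) else rep(NA_real_, 3)
  stats::setNames(v, cross_names(prefix, stat3, suffix))
}

stat4_of <- function(prefix, x, suffix) {
  x <- x[is.finite(x)]
  v <- if (length(x)) c(mean(x), min(x), max(x), stats::median(x))
       else rep(NA_real_, 4)
  stats::setNames(v, cross_names(prefix, stat4, suffix))
}

stat5_of <- function(prefix, x, suffix = NULL) {
  s <- summary_stats(x)
  nm <- if (is.null(suffix)) cross_names(prefix, stat5)
        else cross_names(prefix, stat5, suffix)
  stats::setNames(s[stat5], nm)
}

events_of <- function(recording, kind) {
  ee <- recording$events
  ee[ee$kind == kind, , drop = FALSE]
}

#' Extract features from a Boxes recording
#'
#' Boxes is a colour-matching drag-and-drop game: four planned rounds of
#' five balls each.  Flow features count placements per ball colour and
#' move rates; touch features summarize efficiency and speed of the ball
#' moves that end in a box, for all such paths and for the short subset
#' (traversed length below `short_path_threshold` of the screen diagonal).
#'
#' @param recording A `game_recording` with `game_id = "boxes"`.
#' @param config An [extraction_config()].
#' @return A `feature_vector` with 29 features.
#' @export
extract_boxes <- function(recording, config = extraction_config()) {
  check_recording(recording, "boxes")
  dur <- recording$duration
  paths <- touch_paths(recording$touches)
  ps <- path_summaries(paths)
  drops <- events_of(recording, "ball_drop")
  succ <- drops[drops$ball_colour == drops$box_colour, , drop = FALSE]
  fail <- drops[drops$ball_colour != drops$box_colour, , drop = FALSE]
  vals <- c(total_time = dur, n_ball_moves = length(paths))
  for (col in BALL_COLOURS)
    vals[paste0("success_placements_", col)] <- sum(succ$ball_colour == col)
  for (col in BALL_COLOURS)
    vals[paste0("unsuccess_placements_", col)] <- sum(fail$ball_colour == col)
  vals <- c(vals, successful_move_rate = nrow(succ) / dur,
            unsuccessful_move_rate = nrow(fail) / dur,
            total_move_rate = length(paths) / dur)
  ## touch statistics over ball moves ending in a box (successful or not)
  inbox <- ps[ps$path_id %in% drops$path_id, , drop = FALSE]
  short_cut <- config$short_path_threshold * sqrt(2)  # fraction of diagonal
  subsets <- list(all = inbox,
                  short = inbox[inbox$length < short_cut, , drop = FALSE])
  for (sub in names(subsets)) {
    q <- subsets[[sub]]
    vals[paste0("n_paths_", sub)] <- nrow(q)
    vals <- c(vals, stat3_of("path_efficiency", q$efficiency, sub),
              stat3_of("speed", q$speed, sub))
  }
  feature_vector("boxes", vals, config)
}

#' Extract features from a Sharing recording
#'
#' Sharing asks the child to drag food to four animated characters while
#' clickable distractors compete for attention.  Flow features are action
#' and rule-compliance rates plus distractor-use rates per group; drag
#' features summarize efficiency and speed of table-to-plate food drags per
#' character.
#'
#' @param recording A `game_recording` with `game_id = "sharing"`.
#' @inheritParams extract_boxes
#' @return A `feature_vector` with 44 features.
#' @export
extract_sharing <- function(recording, config = extraction_config()) {
  check_recording(recording, "sharing")
  dur <- recording$duration
  drags <- events_of(recording, "food_drag")
  taps <- events_of(recording, "distractor_tap")
  rounds <- events_of(recording, "round_start")
  food <- drags[drags$object == "food", , drop = FALSE]
  other <- drags[drags$object == "other", , drop = FALSE]
  round_len <- if (nrow(rounds)) diff(c(sort(rounds$t), dur)) else numeric()
  vals <- c(
    total_time = dur,
    action_rate = (nrow(drags) + nrow(taps)) / dur,
    successful_action_rate = nrow(food) / dur,
    avg_round_length = if (length(round_len)) mean(round_len) else NA_real_,
    food_table_plate_rate = sum(food$source == "table") / dur,
    other_table_plate_rate = sum(other$source == "table") / dur,
    other_plate_plate_rate = sum(other$source == "plate") / dur)
  for (g in DISTRACTOR_GROUPS[1:4])
    vals[paste0("distractor_rate_", g)] <- sum(taps$group == g) / dur
  vals["distractor_rate_all"] <- nrow(taps) / dur
  ps <- path_summaries(touch_paths(recording$touches))
  tofood <- food[food$source == "table", , drop = FALSE]
  for (k in seq_along(SHARING_CHARACTERS)) {
    ch <- SHARING_CHARACTERS[k]
    ids <- tofood$path_id[tofood$target_character == k]
    q <- ps[ps$path_id %in% ids, , drop = FALSE]
    vals <- c(vals, stat4_of("drag_efficiency", q$efficiency, ch),
              stat4_of("drag_speed", q$speed, ch))
  }
  feature_vector("sharing", vals, config)
}

#' Extract features from a Pinwheel recording
#'
#' Pinwheel is controlled by tilting the tablet to roll a ball into the
#' matching petal.  Flow features are hit/fall/round rates; reaction times
#' measure the delay from round start to the petal hit; inertial features
#' summarize tilt episodes per direction (forward, backward, left, right).
#'
#' @param recording A `game_recording` with `game_id = "pinwheel"` and a
#'   motion stream.
#' @inheritParams extract_boxes
#' @return A `feature_vector` with 41 features.
#' @export
extract_pinwheel <- function(recording, config = extraction_config()) {
  check_recording(recording, "pinwheel", need_motion = TRUE)
  dur <- recording$duration
  hits <- events_of(recording, "petal_hit")
  falls <- events_of(recording, "ball_fall")
  rounds <- events_of(recording, "round_start")
  succ <- hits[as.logical(hits$success), , drop = FALSE]
  fail <- hits[!as.logical(hits$success), , drop = FALSE]
  ## reaction time of a hit = delay since the most recent round start
  hit_rt <- function(h) {
    if (!nrow(h) || !nrow(rounds)) return(numeric())
    starts <- sort(rounds$t)
    vapply(h$t, function(tt) {
      prev <- starts[starts <= tt]
      if (length(prev)) tt - max(prev) else NA_real_
    }, numeric(1))
  }
  mean_na <- function(x) { x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_ }
  vals <- c(
    total_time = dur,
    successful_hit_rate = nrow(succ) / dur,
    unsuccessful_hit_rate = nrow(fail) / dur,
    ball_fall_rate = nrow(falls) / dur,
    round_rate = nrow(rounds) / dur,
    touch_rate = length(unique(recording$touches$path_id)) / dur,
    rt_successful_mean = mean_na(hit_rt(succ)),
    rt_unsuccessful_mean = mean_na(hit_rt(fail)),
    rt_all_mean = mean_na(hit_rt(hits)))
  mm <- recording$motion
  for (d in TILT_DIRECTIONS) {
    ang <- if (d %in% c("forward", "backward")) mm$pitch else mm$roll
    ep <- detect_tilt_episodes(mm$t, ang, d, config$tilt_threshold)
    tf <- tilt_features(ep, dur)
    names(tf) <- paste(c("tilt_fraction", "tilt_rate", "tilt_peak_mean",
                         "tilt_peak_sd", "tilt_peak_median", "tilt_osc_mean",
                         "tilt_osc_sd", "tilt_osc_median"), d, sep = "_")
    vals <- c(vals, tf)
  }
  feature_vector("pinwheel", vals, config)
}

## Classify each creativity path as contour or fill: a path is a fill path
## when a fill_started event for the image selected most recently before the
## path began precedes the path.  Without image bookkeeping (degenerate
## logs) paths default to contour.
creativity_path_kind <- function(ps, events) {
  sel <- events[events$kind == "image_selected", , drop = FALSE]
  fil <- events[events$kind == "fill_started", , drop = FALSE]
  vapply(ps$t_start, function(t0) {
    prev_sel <- sel$t[sel$t <= t0]
    if (!length(prev_sel)) return("contour")
    t_img <- max(prev_sel)
    if (any(fil$t >= t_img & fil$t <= t0)) "fill" else "contour"
  }, character(1))
}

#' Extract features from a Creativity recording
#'
#' Creativity is a guided drawing and colouring game.  Flow features count
#' images selected, outlined and filled; touch features summarize drawing
#' speed (contour, fill and all paths), fill-path length and extent; the
#' inertial features measure drawing/pressure intensity as acceleration
#' sign-change rates (X over horizontal paths, Y over vertical paths, Z over
#' all paths) and threshold-exceedance fractions per axis.
#'
#' @param recording A `game_recording` with `game_id = "creativity"` and a
#'   motion stream.
#' @inheritParams extract_boxes
#' @return A `feature_vector` with 41 features.
#' @export
extract_creativity <- function(recording, config = extraction_config()) {
  check_recording(recording, "creativity", need_motion = TRUE)
  dur <- recording$duration
  ee <- recording$events
  ps <- path_summaries(touch_paths(recording$touches))
  ps$kind <- if (nrow(ps)) creativity_path_kind(ps, ee) else character()
  n_sel <- sum(ee$kind == "image_selected")
  fill <- ps[ps$kind == "fill", , drop = FALSE]
  vals <- c(total_time = dur,
            n_images_selected = n_sel,
            n_images_outlined = sum(ee$kind == "outline_completed"),
            n_images_fill_started = sum(ee$kind == "fill_started"))
  for (kind in c("contour", "fill")) {
    q <- ps[ps$kind == kind, , drop = FALSE]
    vals <- c(vals, stat5_of("draw_speed", q$speed, kind))
  }
  vals <- c(vals, stat5_of("draw_speed", ps$speed, "all"),
            stat5_of("fill_len", fill$length),
            stat5_of("fill_hrange", fill$hrange),
            stat5_of("fill_vrange", fill$vrange))
  vals["colour_changes_per_image"] <-
    if (n_sel > 0) sum(ee$kind == "colour_change") / n_sel else NA_real_
  ## inertial: sign-change intensity within paths of matching orientation
  mm <- recording$motion
  horizontal <- ps$hrange >= ps$vrange
  axis_rate <- function(axis, mask) {
    q <- ps[mask, , drop = FALSE]
    total <- sum(pmax(q$t_end - q$t_start, 0))
    if (total <= 0) return(NA_real_)
    flips <- 0
    for (i in seq_len(nrow(q))) {
      seg <- mm[[axis]][mm$t >= q$t_start[i] & mm$t <= q$t_end[i]]
      s <- sign(seg); s <- s[s != 0]
      if (length(s) > 1) flips <- flips + sum(diff(s) != 0)
    }
    flips / total
  }
  vals["sign_change_x"] <- axis_rate("ax", horizontal)
  vals["sign_change_y"] <- axis_rate("ay", !horizontal)
  vals["sign_change_z"] <- axis_rate("az", rep(TRUE, nrow(ps)))
  for (axis in c("x", "y", "z"))
    vals[paste0("exceed_frac_", axis)] <-
      if (nrow(mm) >= 2)
        exceedance_fraction(mm$t, mm[[paste0("a", axis)]],
                            config$accel_threshold)
      else NA_real_
  feature_vector("creativity", vals, config)
}

#' Extract features from a Cat and Dog recording
#'
#' A go/no-go task: the child must tap for target stimuli (dog image or
#' bark) and withhold the tap otherwise.  Taps over the expected region
#' within the response window answer the most recent unanswered stimulus;
#' expected-region taps outside any window are missed touches; taps over an
#' unexpected region are counted separately.  Restrain events are stimuli
#' left unanswered (correctly for non-targets, incorrectly for targets).
#'
#' @param recording A `game_recording` with `game_id = "catdog"`.
#' @inheritParams extract_boxes
#' @return A `feature_vector` with 27 features.
#' @export
extract_catdog <- function(recording, config = extraction_config()) {
  check_recording(recording, "catdog")
  dur <- recording$duration
  stim <- events_of(recording, "stimulus_onset")
  stim <- stim[order(stim$t), , drop = FALSE]
  tapev <- events_of(recording, "response_tap")
  expected <- sort(tapev$t[tapev$region == "expected"])
  unexpected <- tapev$t[tapev$region == "unexpected"]
  m <- reaction_times(stim$t, expected, config$response_window)
  answered <- !m$missed
  target <- as.logical(stim$target)
  modality <- stim$modality
  n_stim <- nrow(stim)
  n_missed_touch <- length(expected) - sum(answered)
  vals <- c(
    total_time = dur,
    correct_answer_rate = sum(answered & target) / dur,
    incorrect_answer_rate = sum(answered & !target) / dur,
    unexpected_touch_rate = length(unexpected) / dur,
    missed_touch_rate = n_missed_touch / dur,
    pct_touch_answers = if (n_stim) sum(answered) / n_stim else NA_real_,
    pct_restrain = if (n_stim) sum(!answered) / n_stim else NA_real_)
  groups <- list(correct_image = answered & target & modality == "image",
                 correct_sound = answered & target & modality == "sound",
                 incorrect_image = answered & !target & modality == "image",
                 incorrect_sound = answered & !target & modality == "sound",
                 all = answered)
  for (g in names(groups)) {
    s <- summary_stats(m$rt[groups[[g]]])
    vals <- c(vals, stats::setNames(s[c("mean", "sd", "min", "max")],
                                    cross_names("rt",
                                                c("mean", "sd", "min", "max"),
                                                g)))
  }
  feature_vector("catdog", vals, config)
}

#' Extract features from any game recording
#'
#' Dispatches to the per-game extractor by `game_id`.
#'
#' @param recording A `game_recording`.
#' @inheritParams extract_boxes
#' @return A `feature_vector`.
#' @export
extract_features <- function(recording, config = extraction_config()) {
  switch(recording$game_id,
         boxes = extract_boxes(recording, config),
         sharing = extract_sharing(recording, config),
         pinwheel = extract_pinwheel(recording, config),
         creativity = extract_creativity(recording, config),
         catdog = extract_catdog(recording, config),
         stop("unknown game_id: ", recording$game_id))
}

#' Extract a cohort feature table
#'
#' @param sessions List of `session_record`s.
#' @param config An [extraction_config()].
#' @return Data frame with columns `child_id`, `session_index`, `game` and
#'   one column per registry feature of that game (long over games; feature
#'   columns not belonging to a row's game are NA).
#' @export
extract_cohort_features <- function(sessions, config = extraction_config()) {
  reg <- feature_registry()
  rows <- list()
  for (s in sessions) {
    for (rec in s$recordings) {
      fv <- extract_features(rec, config)
      row <- c(list(child_id = s$child_id, session_index = s$session_index,
                    game = rec$game_id), as.list(fv$values))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("no recordings in cohort")
  cols <- c("child_id", "session_index", "game", unique(reg$name))
  out <- lapply(cols, function(cn)
    unlist(lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]]),
           use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
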