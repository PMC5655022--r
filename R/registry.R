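## Canonical feature registry ----------------------------------------------
##
## The registry is normative: every extractor must emit exactly its slice,
## in order.  Per-game counts are boxes 29, sharing 44, pinwheel 41,
## creativity 41, catdog 27 (total 182).  The published per-game counts sum
## to 182 although the accompanying text gives a grand total of 181; the
## registry follows the per-game counts and the discrepancy is documented
## rather than silently resolved.

BALL_COLOURS <- c("red", "blue", "green", "yellow", "purple")
SHARING_CHARACTERS <- c("char1", "char2", "char3", "char4")
DISTRACTOR_GROUPS <- c("lamps", "shelf", "bird", "pinwheel", "all")
TILT_DIRECTIONS <- c("forward", "backward", "left", "right")

stat3 <- c("avg", "min", "max")
stat4 <- c("avg", "min", "max", "median")
stat5 <- c("mean", "sd", "min", "max", "median")

cross_names <- function(prefix, stats, suffix = NULL) {
  out <- paste(prefix, stats, sep = "_")
  if (!is.null(suffix)) out <- paste(out, suffix, sep = "_")
  out
}

registry_boxes <- function() {
  flow <- c("total_time", "n_ball_moves",
            paste0("success_placements_", BALL_COLOURS),
            paste0("unsuccess_placements_", BALL_COLOURS),
            "successful_move_rate", "unsuccessful_move_rate",
            "total_move_rate")
  touch <- c(unlist(lapply(c("all", "short"), function(sub)
    c(paste0("n_paths_", sub),
      cross_names("path_efficiency", stat3, sub),
      cross_names("speed", stat3, sub)))))
  data.frame(game = "boxes", name = c(flow, touch),
             source = c(rep("flow", length(flow)),
                        rep("touch", length(touch))),
             stringsAsFactors = FALSE)
}

registry_sharing <- function() {
  flow <- c("total_time", "action_rate", "successful_action_rate",
            "avg_round_length", "food_table_plate_rate",
            "other_table_plate_rate", "other_plate_plate_rate",
            paste0("distractor_rate_", DISTRACTOR_GROUPS))
  drag <- unlist(lapply(SHARING_CHARACTERS, function(ch)
    c(cross_names("drag_efficiency", stat4, ch),
      cross_names("drag_speed", stat4, ch))))
  data.frame(game = "sharing", name = c(flow, drag),
             source = c(rep("flow", length(flow)),
                        rep("touch", length(drag))),
             stringsAsFactors = FALSE)
}

registry_pinwheel <- function() {
  flow <- c("total_time", "successful_hit_rate", "unsuccessful_hit_rate",
            "ball_fall_rate", "round_rate")
  touch <- c("touch_rate", "rt_successful_mean", "rt_unsuccessful_mean",
             "rt_all_mean")
  inertial <- unlist(lapply(TILT_DIRECTIONS, function(d)
    paste(c("tilt_fraction", "tilt_rate",
            cross_names("tilt_peak", c("mean", "sd", "median")),
            cross_names("tilt_osc", c("mean", "sd", "median"))), d,
          sep = "_")))
  data.frame(game = "pinwheel", name = c(flow, touch, inertial),
             source = c(rep("flow", length(flow)),
                        rep("touch", length(touch)),
                        rep("inertial", length(inertial))),
             stringsAsFactors = FALSE)
}

registry_creativity <- function() {
  flow <- c("total_time", "n_images_selected", "n_images_outlined",
            "n_images_fill_started")
  touch <- c(unlist(lapply(c("contour", "fill", "all"), function(kind)
    cross_names("draw_speed", stat5, kind))),
    cross_names("fill_len", stat5),
    cross_names("fill_hrange", stat5),
    cross_names("fill_vrange", stat5),
    "colour_changes_per_image")
  inertial <- c("sign_change_x", "sign_change_y", "sign_change_z",
                "exceed_frac_x", "exceed_frac_y", "exceed_frac_z")
  data.frame(game = "creativity", name = c(flow, touch, inertial),
             source = c(rep("flow", length(flow)),
                        rep("touch", length(touch)),
                        rep("inertial", length(inertial))),
             stringsAsFactors = FALSE)
}

registry_catdog <- function() {
  flow <- c("total_time", "correct_answer_rate", "incorrect_answer_rate",
            "unexpected_touch_rate", "missed_touch_rate",
            "pct_touch_answers", "pct_restrain")
  groups <- c("correct_image", "correct_sound", "incorrect_image",
              "incorrect_sound", "all")
  reaction <- unlist(lapply(groups, function(g)
    cross_names("rt", c("mean", "sd", "min", "max"), g)))
  data.frame(game = "catdog", name = c(flow, reaction),
             source = c(rep("flow", length(flow)),
                        rep("touch", length(reaction))),
             stringsAsFactors = FALSE)
}

## Short human-readable definition for a feature name, by family prefix.
DEFINITION_REFS <- c(
  total_time = "total game time in seconds",
  n_ball_moves = "all ball moves, including those reaching no box",
  success_placements = "successful placements per ball colour",
  unsuccess_placements = "wrong-box placements per ball colour",
  successful_move_rate = "successful moves per second",
  unsuccessful_move_rate = "unsuccessful moves per second",
  total_move_rate = "all moves per second",
  n_paths = "count of box-reaching drag paths (all / short subset)",
  path_efficiency = "shortest-to-actual path length ratio",
  speed = "drag speed over box-reaching paths",
  action_rate = "all actions (drags and distractor taps) per second",
  successful_action_rate = "food drags reaching a plate per second",
  avg_round_length = "mean round duration in seconds",
  food_table_plate_rate = "food moves table to plate per second",
  other_table_plate_rate = "other-object moves table to plate per second",
  other_plate_plate_rate = "other-object moves plate to plate per second",
  distractor_rate = "distractor uses per second, by group",
  drag_efficiency = "table-to-plate drag straightness per character",
  drag_speed = "table-to-plate drag speed per character",
  successful_hit_rate = "successful petal hits per second",
  unsuccessful_hit_rate = "unsuccessful petal hits per second",
  ball_fall_rate = "ball falls per second",
  round_rate = "rounds (balls) per second",
  touch_rate = "screen touches per second",
  rt_successful = "mean delay from round start to successful hit",
  rt_unsuccessful = "mean delay from round start to unsuccessful hit",
  rt_all = "mean delay from round start to any hit",
  tilt_fraction = "share of time tilted in the direction",
  tilt_rate = "tilt episodes per second in the direction",
  tilt_peak = "per-episode maximum tilt statistics",
  tilt_osc = "per-episode tilt oscillation (local extrema) statistics",
  n_images_selected = "images selected",
  n_images_outlined = "images completely outlined",
  n_images_fill_started = "images with colour filling begun",
  draw_speed = "path drawing speed (contour / fill / all paths)",
  fill_len = "colour-filling path length statistics",
  fill_hrange = "horizontal extent of colour-filling paths",
  fill_vrange = "vertical extent of colour-filling paths",
  colour_changes_per_image = "colour changes per selected image",
  sign_change = "acceleration sign changes per second of drawing",
  exceed_frac = "share of time acceleration magnitude above threshold",
  correct_answer_rate = "correct touch answers per second",
  incorrect_answer_rate = "incorrect touch answers per second",
  unexpected_touch_rate = "unexpected-region touches per second",
  missed_touch_rate = "expected-region touches answering nothing, per second",
  pct_touch_answers = "share of stimuli answered by touch",
  pct_restrain = "share of stimuli with withheld touch",
  rt = "reaction time statistics by answer type and modality")

definition_ref_for <- function(name) {
  keys <- names(DEFINITION_REFS)[order(-nchar(names(DEFINITION_REFS)))]
  for (k in keys)
    if (startsWith(name, k)) return(DEFINITION_REFS[[k]])
  ""
}

#' The canonical feature registry
#'
#' One row per (game, feature) pair, in extractor output order, with the
#' information source of each feature (`flow`, `touch` or `inertial`) and
#' a short definition.  Per-game counts: boxes 29, sharing 44, pinwheel
#' 41, creativity 41, catdog 27 (182 in total).
#'
#' @param game Optional game id to return a single game's slice.
#' @return Data frame with columns `game`, `name`, `source`,
#'   `definition_ref`.
#' @export
feature_registry <- function(game = NULL) {
  reg <- rbind(registry_boxes(), registry_sharing(), registry_pinwheel(),
               registry_creativity(), registry_catdog())
  reg$definition_ref <- vapply(reg$name, definition_ref_for, character(1),
                               USE.NAMES = FALSE)
  if (!is.null(game)) {
    if (!game %in% GAME_IDS) stop("unknown game_id: ", game)
    reg <- reg[reg$game == game, , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Write the feature manifest shipped with the package
#'
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(path) {
  utils::write.table(feature_registry(), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
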