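## Questionnaire scoring and progress labels --------------------------------
##
## The therapist instrument has 74 items over ten developmental areas.
## Item ratings on small ordinal scales are rescaled to [0, 100]; the
## unweighted mean of an area's items is its evaluation; progress between
## two sessions is a strict increase of that evaluation.

INSTRUMENT_ITEMS <- list(
  communication = c("spontaneous eye contact", "speech understanding",
    "reacting to name", "indicating", "imitating adults or other children",
    "adequate gestures", "alternative communication skills",
    "ability to use speech", "greeting and saying good bye",
    "asking and answering questions",
    "spontaneously starting to communicate",
    "expressing physiological needs",
    "expressing other needs and preferences", "maintaining a conversation"),
  fine_motor = c("holding pencil", "colouring", "tracing a drawing",
    "cutting", "grabbing small objects", "building a tower of blocks",
    "putting beads onto a necklace", "fastening buttons"),
  gross_motor = c("standing on one leg", "jumping on one or both legs",
    "squats", "climbing stairs", "throwing a ball at a target",
    "kicking a ball", "running", "riding a bike", "climbing a chair or sofa"),
  following_instructions = c("simple instructions", "complex instructions"),
  self_reliance = c("dressing", "eating", "cleaning up", "using a toilet",
    "washing hands", "tooth brushing"),
  social_emotional = c("reciprocal smile",
    "contacting adults or other children",
    "sharing with adults or other children", "recognizing others' emotions",
    "understanding own emotions", "joining other children spontaneously",
    "asking for help", "empathic reactions to others' emotions",
    "taking part in a symbolic play"),
  stereotypical = c("motor stereotypes", "echolalia", "routine behaviours",
    "reaction to change in routine", "reaction to novelty"),
  stimulation_reaction = c("reaction to motion stimuli",
    "reaction to visual stimuli", "reaction to auditory stimuli",
    "reaction to taste stimuli", "reaction to smell stimuli",
    "reaction to touch stimuli"),
  attention = c("following others' indication", "indicating attention",
    "focusing on a given task", "focusing on a talking therapist",
    "moving from one activity to another"),
  challenging = c("aggressive or autoaggressive behaviours", "crying",
    "screaming", "apathy", "inadequate laugh", "escaping",
    "emotional lability", "not accepting refusals",
    "stimulating behaviours", "problems with calming down"))

#' The default therapist instrument
#'
#' 74 items over ten developmental areas, each rated on a small ordinal
#' scale (default 1-5; the item-level scale widths of the original
#' instrument are not published, so they are configurable).
#'
#' @param scale_min,scale_max Integer rating bounds applied to every item.
#' @return Data frame with columns `item_id`, `area`, `scale_min`,
#'   `scale_max`, `description`.
#' @export
default_instrument <- function(scale_min = 1L, scale_max = 5L) {
  stopifnot(scale_max > scale_min)
  rows <- lapply(names(INSTRUMENT_ITEMS), function(area) {
    d <- INSTRUMENT_ITEMS[[area]]
    data.frame(item_id = sprintf("%s_%02d", area, seq_along(d)),
               area = area, scale_min = as.integer(scale_min),
               scale_max = as.integer(scale_max), description = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rescale an ordinal rating to the [0, 100] evaluation scale
#'
#' `100 * (rating - scale_min) / (scale_max - scale_min)`, so the scale
#' endpoints map to exactly 0 and 100 for every scale width.
#'
#' @param rating Integer rating(s).
#' @param scale_min,scale_max Scale bounds, `scale_max > scale_min`.
#' @return Numeric in `[0, 100]`.
#' @export
scale_rating <- function(rating, scale_min, scale_max) {
  if (any(scale_max <= scale_min)) stop("scale_max must exceed scale_min")
  if (any(rating < scale_min | rating > scale_max))
    stop("rating outside scale bounds")
  100 * (rating - scale_min) / (scale_max - scale_min)
}

#' Score a questionnaire response into ten area evaluations
#'
#' Each area score is the unweighted mean of its items' rescaled ratings.
#'
#' @param ratings Named integer vector, names are instrument item ids.
#' @param instrument Instrument definition as from [default_instrument()].
#' @return Named numeric vector over all ten areas, values in `[0, 100]`.
#' @export
area_scores <- function(ratings, instrument = default_instrument()) {
  unknown <- setdiff(names(ratings), instrument$item_id)
  if (length(unknown))
    stop("rated items not in instrument: ", paste(unknown, collapse = ", "))
  out <- stats::setNames(numeric(length(AREAS)), AREAS)
  for (a in AREAS) {
    items <- instrument[instrument$area == a, , drop = FALSE]
    r <- ratings[items$item_id]
    ok <- !is.na(r)
    if (!any(ok)) stop("area with zero rated items: ", a)
    out[a] <- mean(scale_rating(r[ok], items$scale_min[ok],
                                items$scale_max[ok]))
  }
  out
}

#' Binary progress label between two sessions
#'
#' Progress iff the area evaluation strictly increased; ties and decreases
#' are no_progress.
#'
#' @param score_from,score_to Area scores in `[0, 100]`.
#' @return `"progress"` or `"no_progress"`.
#' @export
progress_label <- function(score_from, score_to) {
  ifelse(score_to > score_from, "progress", "no_progress")
}

#' Score a cohort's questionnaires
#'
#' @param sessions List of `session_record`s carrying questionnaires.
#' @param instrument Instrument definition.
#' @return Data frame with `child_id`, `session_index` and one column per
#'   area.
#' @export
cohort_area_scores <- function(sessions, instrument = default_instrument()) {
  keep <- Filter(function(s) !is.null(s$questionnaire), sessions)
  if (!length(keep)) stop("no questionnaires in cohort")
  rows <- lapply(keep, function(s)
    c(list(child_id = s$child_id, session_index = s$session_index),
      as.list(area_scores(s$questionnaire, instrument))))
  out <- lapply(c("child_id", "session_index", AREAS), function(cn)
    unlist(lapply(rows, `[[`, cn), use.names = FALSE))
  names(out) <- c("child_id", "session_index", AREAS)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write the instrument definition to CSV
#' @param instrument Instrument data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  utils::write.csv(instrument, path, row.names = FALSE)
  invisible(path)
}
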