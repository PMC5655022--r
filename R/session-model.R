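#' @keywords internal
"_PACKAGE"

## Session data model -------------------------------------------------------
##
## A session is one child's visit: up to one recording per game plus a
## therapist questionnaire.  Coordinates are normalized to [0,1] with the
## origin at the top-left corner (x rightward, y downward); times are seconds
## from game start.  Sign convention for device attitude: positive pitch =
## top edge lifted (tilt backward), negative pitch = tilt forward; positive
## roll = right edge lifted (tilt left), negative roll = tilt right.

GAME_IDS <- c("boxes", "sharing", "pinwheel", "creativity", "catdog")
MOTION_GAMES <- c("pinwheel", "creativity")
TOUCH_PHASES <- c("began", "moved", "ended")
AREAS <- c("communication", "fine_motor", "gross_motor",
           "following_instructions", "self_reliance", "social_emotional",
           "stereotypical", "stimulation_reaction", "attention",
           "challenging")

#' Extraction configuration
#'
#' Thresholds used by the feature extractors.  None of these is dictated by
#' the measurement hardware; results must always be reported together with
#' the configuration used.
#'
#' @param tilt_threshold Tilt detection threshold in radians. The tablet
#'   counts as tilted in a direction when the direction-signed roll or pitch
#'   exceeds this value. Default 0.175 (about 10 degrees).
#' @param accel_threshold Acceleration exceedance threshold in g units.
#'   Default 0.15.
#' @param short_path_threshold Boundary between "short" and other drag paths,
#'   as a fraction of the screen diagonal. Default 0.25.
#' @param response_window Seconds after a stimulus onset during which a tap
#'   counts as an answer to it. Default 2.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(tilt_threshold = 0.175,
                              accel_threshold = 0.15,
                              short_path_threshold = 0.25,
                              response_window = 2.0) {
  vals <- c(tilt_threshold = tilt_threshold,
            accel_threshold = accel_threshold,
            short_path_threshold = short_path_threshold,
            response_window = response_window)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all extraction_config thresholds must be strictly positive")
  structure(as.list(vals), class = "extraction_config")
}

empty_touches <- function() {
  data.frame(path_id = integer(), t = numeric(), x = numeric(),
             y = numeric(), phase = character(), stringsAsFactors = FALSE)
}

empty_motion <- function() {
  data.frame(t = numeric(), ax = numeric(), ay = numeric(), az = numeric(),
             roll = numeric(), pitch = numeric(), stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(t = numeric(), kind = character(), stringsAsFactors = FALSE)
}

## Event vocabulary per game; payload columns are free-form beyond `t, kind`.
EVENT_VOCAB <- list(
  boxes      = c("round_start", "ball_drop"),
  sharing    = c("round_start", "food_drag", "distractor_tap"),
  pinwheel   = c("round_start", "petal_hit", "ball_fall"),
  creativity = c("image_selected", "outline_completed", "fill_started",
                 "colour_change"),
  catdog     = c("stimulus_onset", "response_tap")
)

#' Construct a single-game recording
#'
#' @param game_id One of `"boxes"`, `"sharing"`, `"pinwheel"`,
#'   `"creativity"`, `"catdog"`.
#' @param duration Game duration in seconds (> 0).
#' @param touches Data frame with columns `path_id`, `t`, `x`, `y`, `phase`.
#' @param motion Data frame with columns `t`, `ax`, `ay`, `az`, `roll`,
#'   `pitch` (required for pinwheel and creativity).
#' @param events Data frame with columns `t`, `kind` plus event-specific
#'   payload columns.
#' @return A `game_recording` object.
#' @export
game_recording <- function(game_id, duration, touches = empty_touches(),
                           motion = empty_motion(), events = empty_events()) {
  if (!game_id %in% GAME_IDS)
    stop("unknown game_id: ", game_id)
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0)
    stop("duration must be a single positive number")
  rec <- structure(list(game_id = game_id, duration = as.numeric(duration),
                        touches = touches, motion = motion, events = events),
                   class = "game_recording")
  rec
}

#' Construct a session record
#'
#' @param child_id Opaque child identifier.
#' @param session_index Session number, integer >= 1 (sessions are monthly).
#' @param recordings Named list of [game_recording()] objects (names are
#'   game ids), at most one per game.
#' @param questionnaire Optional named integer vector of item ratings
#'   (names are instrument item ids).
#' @return A `session_record` object.
#' @export
session_record <- function(child_id, session_index, recordings = list(),
                           questionnaire = NULL) {
  if (length(recordings)) {
    ids <- vapply(recordings, function(r) r$game_id, character(1))
    names(recordings) <- ids
    if (anyDuplicated(ids)) stop("at most one recording per game")
  }
  structure(list(child_id = as.character(child_id),
                 session_index = as.integer(session_index),
                 recordings = recordings,
                 questionnaire = questionnaire),
            class = "session_record")
}

#' Validate a session record
#'
#' Checks every documented invariant and returns the violations as data,
#' not as conditions: an empty character vector means the record is valid.
#'
#' @param record A `session_record`.
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_session <- function(record) {
  v <- character()
  if (!inherits(record, "session_record"))
    return("not a session_record")
  if (is.na(record$session_index) || record$session_index < 1)
    v <- c(v, "session_index must be >= 1")
  for (rec in record$recordings) {
    g <- rec$game_id
    if (!g %in% GAME_IDS) {
      v <- c(v, paste0("unknown game_id: ", g))
      next
    }
    if (rec$duration <= 0)
      v <- c(v, paste0(g, ": duration must be > 0"))
    tt <- rec$touches
    if (nrow(tt)) {
      if (any(tt$t < 0)) v <- c(v, paste0(g, ": touch t < 0"))
      if (any(tt$t > rec$duration + 1e-9))
        v <- c(v, paste0(g, ": touch t exceeds duration"))
      if (!all(tt$phase %in% TOUCH_PHASES))
        v <- c(v, paste0(g, ": invalid touch phase"))
      for (pid in unique(tt$path_id)) {
        p <- tt[tt$path_id == pid, , drop = FALSE]
        if (is.unsorted(p$t))
          v <- c(v, paste0(g, ": touch t decreasing within path ", pid))
        if (p$phase[1] != "began" || p$phase[nrow(p)] != "ended")
          v <- c(v, paste0(g, ": path ", pid,
                           " must start with 'began' and end with 'ended'"))
      }
    }
    mm <- rec$motion
    if (nrow(mm)) {
      if (is.unsorted(mm$t)) v <- c(v, paste0(g, ": motion t not sorted"))
      if (any(mm$t > rec$duration + 1e-9))
        v <- c(v, paste0(g, ": motion t exceeds duration"))
    } else if (g %in% MOTION_GAMES) {
      v <- c(v, paste0(g, ": motion stream required but absent"))
    }
    ee <- rec$events
    if (nrow(ee)) {
      if (any(ee$t > rec$duration + 1e-9))
        v <- c(v, paste0(g, ": event t exceeds duration"))
      bad <- setdiff(unique(ee$kind), EVENT_VOCAB[[g]])
      if (length(bad))
        v <- c(v, paste0(g, ": event kind(s) outside vocabulary: ",
                         paste(bad, collapse = ", ")))
    }
  }
  v
}

#' Validate a cohort of sessions
#'
#' In addition to per-session checks, verifies that `session_index` is
#' unique within each child.
#'
#' @param sessions List of `session_record`s.
#' @return Character vector of violation messages.
#' @export
validate_cohort <- function(sessions) {
  v <- unlist(lapply(sessions, validate_session), use.names = FALSE)
  key <- vapply(sessions, function(s)
    paste(s$child_id, s$session_index, sep = "\r"), character(1))
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    v <- c(v, paste0("duplicate (child_id, session_index): ",
                     gsub("\r", "/", dup)))
  if (is.null(v)) character() else v
}

json_line <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null",
                   na = "null")
}

df_records <- function(df, stream, game) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    row <- row[!vapply(row, function(z) is.na(z) && !is.nan(z), logical(1))]
    c(list(stream = stream, game = game), row)
  })
}

#' Write a session to a JSON Lines file
#'
#' The format is one JSON object per line: a header
#' `{"stream":"header", ...}` first, then an optional questionnaire line,
#' then one line per touch sample, motion sample and game event, each
#' carrying a `stream` discriminator and the owning `game`.  Numbers are
#' serialized with 17 significant digits so that
#' `read_session(write_session(r))` is bit-exact.
#'
#' @param record A valid `session_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  v <- validate_session(record)
  if (length(v)) stop("invalid session: ", paste(v, collapse = "; "))
  games <- lapply(unname(record$recordings), function(r)
    list(game_id = r$game_id, duration = r$duration))
  lines <- json_line(list(stream = "header", child_id = record$child_id,
                          session_index = record$session_index,
                          games = games))
  if (!is.null(record$questionnaire)) {
    q <- record$questionnaire
    lines <- c(lines, json_line(list(stream = "questionnaire",
                                     items = names(q),
                                     ratings = unname(as.integer(q)))))
  }
  for (rec in record$recordings) {
    g <- rec$game_id
    recs <- c(df_records(rec$touches, "touch", g),
              df_records(rec$motion, "motion", g),
              df_records(rec$events, "event", g))
    lines <- c(lines, vapply(recs, json_line, character(1)))
  }
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

rebind_rows <- function(rows, proto) {
  if (!length(rows)) return(proto)
  cols <- unique(c(names(proto), unlist(lapply(rows, names))))
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]])
    v <- unlist(vals, use.names = FALSE)
    if (cn %in% names(proto)) {
      storage <- proto[[cn]]
      if (is.numeric(storage)) v <- as.numeric(v)
      if (is.character(storage)) v <- as.character(v)
      if (is.integer(storage)) v <- as.integer(v)
    }
    v
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a session from a JSON Lines file
#'
#' @param path Path to a `.jsonl` session file written by [write_session()].
#' @return A `session_record` satisfying all type invariants.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no session header: ", path, " is empty")
  objs <- lapply(seq_along(lines), function(i) {
    o <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e) NULL)
    if (is.null(o) || is.null(o$stream))
      stop("schema error at line ", i, ": not a tagged JSON object")
    o
  })
  hdr <- objs[[1]]
  if (!identical(hdr$stream, "header"))
    stop("no session header: first line must have stream=\"header\"")
  questionnaire <- NULL
  streams <- list()
  for (i in seq_along(objs)[-1]) {
    o <- objs[[i]]
    if (identical(o$stream, "questionnaire")) {
      questionnaire <- stats::setNames(as.integer(unlist(o$ratings)),
                                       unlist(o$items))
      next
    }
    if (!o$stream %in% c("touch", "motion", "event"))
      stop("schema error at line ", i, ": unknown stream '", o$stream, "'")
    g <- o$game
    if (is.null(g)) stop("schema error at line ", i, ": missing game")
    key <- paste(g, o$stream, sep = ".")
    row <- o[setdiff(names(o), c("stream", "game"))]
    streams[[key]] <- c(streams[[key]], list(row))
  }
  recordings <- list()
  for (gi in hdr$games) {
    g <- gi$game_id
    if (is.null(g) || !g %in% GAME_IDS)
      stop("vocabulary error: unknown game_id '", g, "'")
    touches <- rebind_rows(streams[[paste0(g, ".touch")]], empty_touches())
    motion <- rebind_rows(streams[[paste0(g, ".motion")]], empty_motion())
    events <- rebind_rows(streams[[paste0(g, ".event")]], empty_events())
    touches$path_id <- as.integer(touches$path_id)
    recordings[[g]] <- game_recording(g, gi$duration, touches, motion, events)
  }
  rec <- session_record(hdr$child_id, hdr$session_index, recordings,
                        questionnaire)
  v <- validate_session(rec)
  if (length(v)) stop("schema error in ", path, ": ",
                      paste(v, collapse = "; "))
  rec
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> child", x$child_id, "session", x$session_index, "\n")
  for (r in x$recordings)
    cat(sprintf("  %-10s %6.1f s  %4d touch  %4d motion  %4d events\n",
                r$game_id, r$duration, nrow(r$touches), nrow(r$motion),
                nrow(r$events)))
  if (!is.null(x$questionnaire))
    cat("  questionnaire:", length(x$questionnaire), "items\n")
  invisible(x)
}
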