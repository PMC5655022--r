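# Fixtures are built in code: tiny hand-written recordings with known
# feature values, and scaled-down simulated cohorts (short games, few
# children) to keep the suite fast.

touch_df <- function(path_id, t, x, y) {
  n <- length(t)
  data.frame(path_id = as.integer(path_id), t = t, x = x, y = y,
             phase = c("began", rep("moved", max(0, n - 2)),
                       if (n > 1) "ended"),
             stringsAsFactors = FALSE)
}

# one straight drag from (x0,y0) to (x1,y1) over [t0, t0+dur], k samples
straight_path <- function(path_id, t0, dur, x0, y0, x1, y1, k = 5) {
  frac <- seq(0, 1, length.out = k)
  touch_df(path_id, t0 + frac * dur, x0 + frac * (x1 - x0),
           y0 + frac * (y1 - y0))
}

flat_motion <- function(duration, hz = 20) {
  tt <- seq(0, duration, by = 1 / hz)
  data.frame(t = tt, ax = 0, ay = 0, az = 0, roll = 0, pitch = 0,
             stringsAsFactors = FALSE)
}

# minimal valid boxes recording: two drops (one correct, one wrong)
tiny_boxes <- function() {
  touches <- rbind(straight_path(1, 1, 1, 0.2, 0.2, 0.2, 0.9),
                   straight_path(2, 3, 1, 0.5, 0.2, 0.5, 0.9))
  events <- data.frame(
    t = c(0.5, 2, 4),
    kind = c("round_start", "ball_drop", "ball_drop"),
    ball_colour = c(NA, "red", "blue"),
    box_colour = c(NA, "red", "green"),
    path_id = c(NA, 1L, 2L), stringsAsFactors = FALSE)
  game_recording("boxes", 10, touches, empty_motion_df(), events)
}

empty_motion_df <- function() {
  data.frame(t = numeric(), ax = numeric(), ay = numeric(),
             az = numeric(), roll = numeric(), pitch = numeric(),
             stringsAsFactors = FALSE)
}

tiny_pinwheel <- function(duration = 10) {
  events <- data.frame(
    t = c(1, 2, 5, 6.5, 8),
    kind = c("round_start", "petal_hit", "round_start", "petal_hit",
             "ball_fall"),
    success = c(NA, TRUE, NA, FALSE, NA), stringsAsFactors = FALSE)
  game_recording("pinwheel", duration, empty_touches_df(),
                 flat_motion(duration), events)
}

empty_touches_df <- function() {
  data.frame(path_id = integer(), t = numeric(), x = numeric(),
             y = numeric(), phase = character(), stringsAsFactors = FALSE)
}

small_cohort_config <- function(n_children = 6, seed = 11,
                                sessions_range = c(2, 3), ...) {
  cohort_config(n_children = n_children, sessions_range = sessions_range,
                durations = c(boxes = 50, sharing = 60, pinwheel = 50,
                              creativity = 70, catdog = 60),
                seed = seed, ...)
}

# design matrix with the stated injected signal: n rows, 5 informative
# features with class-mean separation `sep` (in pooled-sd units) among
# `p` total features
separable_matrix <- function(n = 60, p = 12, sep = 1.5, seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  y <- factor(rep(c("no_progress", "progress"), each = n / 2),
              levels = c("no_progress", "progress"))
  x[y == "progress", 1:5] <- x[y == "progress", 1:5] + sep
  list(x = x, y = y)
}
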