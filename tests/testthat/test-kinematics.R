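test_that("path_length sums Euclidean segments", {
  expect_equal(path_length(c(0, 3), c(0, 4)), 5)
  expect_equal(path_length(0.5, 0.5), 0)
  expect_equal(path_length(c(0, 1, 1, 2), c(0, 0, 1, 1)), 3)
  expect_error(path_length(numeric(), numeric()), "empty")
})

test_that("path_efficiency is endpoint distance over traversed length", {
  expect_equal(path_efficiency(c(0, 1), c(0, 1)), 1)
  expect_equal(path_efficiency(c(0, 2, 1), c(0, 0, 0)), 1 / 3)
  expect_equal(path_efficiency(c(0, 0, 5), c(0, 5, 5)), sqrt(50) / 10)
  expect_equal(path_efficiency(0.3, 0.3), 1)  # stationary touch
})

test_that("path_efficiency is in [0,1]; 1 iff collinear-forward (property)", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    x <- runif(n); y <- runif(n)
    e <- path_efficiency(x, y)
    expect_gte(e, 0); expect_lte(e, 1 + 1e-12)
  }
  # collinear forward path has efficiency exactly 1
  frac <- sort(runif(6))
  expect_equal(path_efficiency(frac * 0.7, frac * 0.2), 1)
})

test_that("segment_speed_stats matches a brute-force loop oracle", {
  expect_equal(
    unname(segment_speed_stats(c(0, 1, 2), c(0, 1, 4), c(0, 0, 0))[
      c("mean", "min", "max", "median")]),
    c(2, 1, 3, 2))
  s <- segment_speed_stats(c(0, 1, 2, 3), c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_equal(unname(s["mean"]), unname(s["min"]))
  expect_equal(unname(s["max"]), unname(s["median"]))

  set.seed(1)
  for (rep in 1:20) {
    n <- 100
    t <- cumsum(runif(n, 0.01, 0.1))
    x <- runif(n); y <- runif(n)
    # independent oracle: explicit loop over segments
    sp <- c()
    for (i in 2:n) {
      dt <- t[i] - t[i - 1]
      if (dt > 0)
        sp <- c(sp, sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / dt)
    }
    got <- segment_speed_stats(t, x, y)
    expect_equal(unname(got[c("mean", "min", "max", "median")]),
                 c(mean(sp), min(sp), max(sp), median(sp)))
  }
})

# brute-force per-sample scan used as the oracle for tilt episodes
oracle_tilt <- function(t, angle, direction, threshold) {
  s <- switch(direction, forward = -angle, backward = angle,
              left = angle, right = -angle)
  above <- s > threshold
  eps <- list(); cur <- NULL
  for (i in seq_along(above)) {
    if (above[i]) {
      if (is.null(cur)) cur <- i else cur <- c(cur[1], i)
    } else if (!is.null(cur)) {
      eps[[length(eps) + 1L]] <- range(cur); cur <- NULL
    }
  }
  if (!is.null(cur)) eps[[length(eps) + 1L]] <- range(cur)
  data.frame(t_start = vapply(eps, function(e) t[e[1]], 0),
             t_end = vapply(eps, function(e) t[e[2]], 0))
}

test_that("detect_tilt_episodes: stated examples", {
  tt <- seq(0, 2, by = 0.01)
  expect_equal(nrow(detect_tilt_episodes(tt, rep(0, length(tt)),
                                         "forward", 0.175)), 0)

  ep <- detect_tilt_episodes(tt, rep(-0.3, length(tt)), "forward", 0.175)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$t_start, 0); expect_equal(ep$t_end, 2)
  expect_equal(ep$peak, 0.3)

  # -0.4 sin(2 pi t): forward-signed angle 0.4 sin(2 pi t) > 0.2 twice
  ang <- -0.4 * sin(2 * pi * tt)
  ep <- detect_tilt_episodes(tt, ang, "forward", 0.2)
  expect_equal(nrow(ep), 2)
  dense <- seq(0, 2, by = 0.001)
  ref <- oracle_tilt(dense, -0.4 * sin(2 * pi * dense), "forward", 0.2)
  expect_equal(ep$t_start, ref$t_start, tolerance = 0.02)
  expect_equal(ep$t_end, ref$t_end, tolerance = 0.02)
})

test_that("tilt episodes match the brute-force scan on random series", {
  set.seed(99)
  for (rep in 1:250) {
    n <- sample(20:80, 1)
    t <- cumsum(runif(n, 0.005, 0.05))
    ang <- as.numeric(filter(rnorm(n, 0, 0.2), 0.8, "recursive"))
    dir <- sample(c("forward", "backward", "left", "right"), 1)
    got <- detect_tilt_episodes(t, ang, dir, 0.175)
    ref <- oracle_tilt(t, ang, dir, 0.175)
    expect_equal(got$t_start, ref$t_start)
    expect_equal(got$t_end, ref$t_end)
    # episodes disjoint, union within observation span
    if (nrow(got) > 1)
      expect_true(all(got$t_start[-1] > got$t_end[-nrow(got)]))
    expect_lte(sum(got$t_end - got$t_start), max(t) - min(t))
  }
})

test_that("tilt_features summarizes episodes", {
  expect_equal(unname(tilt_features(
    data.frame(t_start = numeric(), t_end = numeric(), peak = numeric(),
               oscillations = integer()), 10)),
    rep(0, 8))
  one <- data.frame(t_start = 0, t_end = 10, peak = 0.3, oscillations = 2L)
  expect_equal(tilt_features(one, 10)[["fraction"]], 1)
  three <- data.frame(t_start = c(0, 3, 6), t_end = c(1, 4, 7),
                      peak = 0.3, oscillations = 1L)
  tf <- tilt_features(three, 10)
  expect_equal(tf[["fraction"]], 0.3)
  expect_equal(tf[["rate"]], 0.3)
  expect_error(tilt_features(one, 0), "duration")
})

test_that("oscillation_count: examples, oracle, monotone invariance", {
  expect_equal(oscillation_count(1:10), 0L)
  expect_equal(oscillation_count(c(0, 1, 0, 1, 0)), 3L)
  expect_equal(oscillation_count(c(5)), 0L)
  expect_equal(oscillation_count(c(0, 1, 1, 0)), 1L)  # plateau collapses

  oracle <- function(v) {
    w <- v[c(TRUE, diff(v) != 0)]
    cnt <- 0L
    for (i in seq_along(w)[-c(1, length(w))])
      if ((w[i] > w[i - 1] && w[i] > w[i + 1]) ||
          (w[i] < w[i - 1] && w[i] < w[i + 1])) cnt <- cnt + 1L
    cnt
  }
  set.seed(3)
  for (rep in 1:50) {
    v <- cumsum(sample(c(-1, 0, 1), 200, replace = TRUE))
    expect_equal(oscillation_count(v), oracle(v))
    # invariant under strictly monotone transforms
    expect_equal(oscillation_count(exp(v / 10)), oscillation_count(v))
  }
})

test_that("sign_change_rate: zero-skip rule and scale invariance", {
  expect_equal(sign_change_rate(c(1, 2, 3), 2), 0)
  expect_equal(sign_change_rate(c(1, -1, 1, -1, 1), 2), 2)
  expect_equal(sign_change_rate(c(1, 0, -1), 1), 1)
  set.seed(4)
  v <- rnorm(100)
  expect_equal(sign_change_rate(v, 7), sign_change_rate(13.7 * v, 7))
  expect_error(sign_change_rate(v, 0), "duration")
})

test_that("exceedance_fraction is time-weighted", {
  tt <- seq(0, 10, by = 0.1)
  expect_equal(exceedance_fraction(tt, rep(0.1, length(tt)), 0.15), 0)
  expect_equal(exceedance_fraction(tt, rep(-0.9, length(tt)), 0.15), 1)
  # square wave above threshold exactly half the time
  v <- ifelse(tt %% 2 < 1, 0.5, 0)
  frac <- exceedance_fraction(tt, v, 0.15)
  expect_equal(frac, 0.5, tolerance = 0.02)
  expect_error(exceedance_fraction(1, 1, 0.5), "samples")
})

test_that("reaction_times matches greedily and reports misses", {
  m <- reaction_times(1.0, 1.35, 2)
  expect_equal(m$rt, 0.35)
  expect_true(reaction_times(1.0, 5.0, 2)$missed)
  m <- reaction_times(c(1, 3), c(1.2, 3.5), 2)
  expect_equal(m$rt, c(0.2, 0.5))
  # consumed tap cannot answer a second stimulus
  m <- reaction_times(c(1, 1.1), 1.2, 2)
  expect_equal(m$missed, c(FALSE, TRUE))
  expect_error(reaction_times(1, 2, -1), "window")
})
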