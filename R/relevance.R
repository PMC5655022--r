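## Feature relevance --------------------------------------------------------
##
## Features are ranked as progress indicators two ways: by correlating
## per-session-pair feature deltas with the therapist evaluation deltas
## (Pearson and Spearman), and by the information gain of the discretized
## feature delta about the binary progress label.

#' Sample Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (>= 3 pairs after removing
#'   incomplete ones).
#' @return Correlation in `[-1, 1]`, or NA when either side has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Spearman rank correlation (mid-ranks for ties)
#'
#' @inheritParams pearson_r
#' @return Correlation in `[-1, 1]`, or NA when either side's ranks have
#'   zero variance.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  pearson_r(rank(x, ties.method = "average"),
            rank(y, ties.method = "average"))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a discretized feature about a binary label
#'
#' `H(label) - sum_b p(b) H(label | bin b)` with base-2 entropy over
#' equal-frequency bins of the feature values (duplicated quantiles
#' collapse bins, reducing the effective bin count).
#'
#' @param values Numeric feature values.
#' @param labels Factor or vector with the class labels.
#' @param bins Target number of equal-frequency bins, default 5.
#' @return Information gain in bits (>= 0); 0 when only one label class is
#'   present.
#' @export
information_gain <- function(values, labels, bins = 5L) {
  labels <- as.factor(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- droplevels(labels[ok])
  if (length(values) < 2) stop("need >= 2 samples")
  if (nlevels(labels) < 2) return(0)
  breaks <- equal_freq_breaks(values, bins)
  b <- findInterval(values, breaks)
  h <- entropy_bits(table(labels))
  cond <- 0
  for (bin in unique(b)) {
    sel <- b == bin
    cond <- cond + mean(sel) * entropy_bits(table(labels[sel]))
  }
  max(0, h - cond)
}

#' Relevance records for every feature of one (game, area) dataset
#'
#' @param diff A difference-sample set from [build_diff_samples()] (built
#'   in `consecutive` mode to maximize the number of pairs).
#' @param bins Bins for the information gain.
#' @return Data frame with one row per feature: `game`, `area`, `feature`,
#'   `source`, `pearson_r`, `spearman_rho`, `info_gain_bits`, `n_pairs`.
#' @export
relevance_records <- function(diff, bins = 5L) {
  reg <- feature_registry(diff$game_id)
  out <- lapply(seq_len(nrow(reg)), function(i) {
    v <- diff$x[, reg$name[i]]
    ok <- is.finite(v)
    r <- rho <- ig <- NA_real_
    if (sum(ok) >= 3) {
      r <- pearson_r(v, diff$score_delta)
      rho <- spearman_rho(v, diff$score_delta)
    }
    if (sum(ok) >= 2 && nlevels(droplevels(diff$label[ok])) == 2)
      ig <- information_gain(v[ok], diff$label[ok], bins)
    data.frame(game = diff$game_id, area = diff$area,
               feature = reg$name[i], source = reg$source[i],
               pearson_r = r, spearman_rho = rho, info_gain_bits = ig,
               n_pairs = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank the best progress indicators per area
#'
#' For each area, takes the union of the top-k features by absolute
#' Pearson correlation, absolute Spearman correlation and information
#' gain, and orders the union by each feature's best (smallest) rank over
#' the three criteria.
#'
#' @param records Relevance records over all games for one or more areas
#'   (rows as from [relevance_records()], possibly concatenated).
#' @param top_k Features admitted per criterion, default 5.
#' @return Data frame: `area`, `rank`, `feature`, `source`, `game` and the
#'   criterion values.
#' @export
rank_indicators <- function(records, top_k = 5L) {
  out <- list()
  for (a in unique(records$area)) {
    rr <- records[records$area == a, , drop = FALSE]
    crit <- cbind(abs(rr$pearson_r), abs(rr$spearman_rho),
                  rr$info_gain_bits)
    ranks <- apply(-crit, 2, rank, ties.method = "min", na.last = "keep")
    sel <- sort(unique(unlist(lapply(1:3, function(j)
      which(ranks[, j] <= top_k)))))
    if (!length(sel)) next
    best <- apply(ranks[sel, , drop = FALSE], 1, min, na.rm = TRUE)
    ord <- sel[order(best)]
    out[[a]] <- data.frame(area = a, rank = seq_along(ord),
                           feature = rr$feature[ord],
                           source = rr$source[ord], game = rr$game[ord],
                           pearson_r = rr$pearson_r[ord],
                           spearman_rho = rr$spearman_rho[ord],
                           info_gain_bits = rr$info_gain_bits[ord],
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(area = character(), rank = integer(),
                      feature = character(), source = character(),
                      game = character(), pearson_r = numeric(),
                      spearman_rho = numeric(), info_gain_bits = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
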