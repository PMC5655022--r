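## Labelled difference-vector datasets --------------------------------------
##
## Classification inputs are per-feature differences between two sessions
## of the same child, labelled by whether the therapist evaluation of one
## area strictly increased over the same pair.  Two pairing modes exist:
## first_last (one sample per child) and consecutive (one per adjacent
## session pair).  Children with fewer than two usable sessions are
## excluded.

#' Build labelled difference samples for one (game, area)
#'
#' @param features Feature table as from [extract_cohort_features()].
#' @param scores Area-score table as from [cohort_area_scores()].
#' @param game_id Game to use.
#' @param area Developmental area providing the label.
#' @param mode `"first_last"` (last minus first session per child) or
#'   `"consecutive"` (every adjacent session pair).
#' @return List with `x` (numeric matrix of feature deltas, may contain
#'   NA), `label` (factor progress/no_progress), `child_id`, `from_session`,
#'   `to_session`, `score_delta`, `game_id`, `area`.
#' @export
build_diff_samples <- function(features, scores, game_id, area,
                               mode = c("first_last", "consecutive")) {
  mode <- match.arg(mode)
  if (!area %in% AREAS) stop("unknown area: ", area)
  feat_names <- feature_registry(game_id)$name
  ff <- features[features$game == game_id, , drop = FALSE]
  if (!nrow(ff)) stop("empty cohort for game ", game_id)
  merged <- merge(ff, scores[, c("child_id", "session_index", area)],
                  by = c("child_id", "session_index"))
  merged <- merged[order(merged$child_id, merged$session_index), ,
                   drop = FALSE]
  rows <- list()
  for (cid in unique(merged$child_id)) {
    m <- merged[merged$child_id == cid, , drop = FALSE]
    if (nrow(m) < 2) next  # at least two sessions required
    pairs <- if (mode == "first_last") cbind(1L, nrow(m))
             else cbind(seq_len(nrow(m) - 1L), seq_len(nrow(m) - 1L) + 1L)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      dx <- as.numeric(m[j, feat_names]) - as.numeric(m[i, feat_names])
      rows[[length(rows) + 1L]] <- list(
        child_id = cid, from_session = m$session_index[i],
        to_session = m$session_index[j],
        score_delta = m[[area]][j] - m[[area]][i],
        label = progress_label(m[[area]][i], m[[area]][j]), dx = dx)
    }
  }
  if (!length(rows)) stop("no children with >= 2 sessions for ", game_id)
  x <- do.call(rbind, lapply(rows, `[[`, "dx"))
  colnames(x) <- feat_names
  list(x = x,
       label = factor(vapply(rows, `[[`, character(1), "label"),
                      levels = c("no_progress", "progress")),
       child_id = vapply(rows, `[[`, character(1), "child_id"),
       from_session = vapply(rows, `[[`, numeric(1), "from_session"),
       to_session = vapply(rows, `[[`, numeric(1), "to_session"),
       score_delta = vapply(rows, `[[`, numeric(1), "score_delta"),
       game_id = game_id, area = area, mode = mode)
}

#' Write a difference dataset to CSV with a preprocessing sidecar
#'
#' The CSV holds `child_id`, `label` and one column per feature (or
#' `pc_1..pc_k` after PCA); the sidecar JSON records the preprocessing
#' recipe (variant, imputation medians, normalization bounds, PCA model)
#' so held-out rows can be transformed identically.
#'
#' @param diff From [build_diff_samples()].
#' @param path Output CSV path; the sidecar is `<path>.recipe.json`.
#' @param variant Preprocessing variant applied before writing.
#' @return `path`, invisibly.
#' @export
write_diff_dataset <- function(diff, path, variant = "raw") {
  fp <- fit_preprocess(diff$x, variant)
  out <- data.frame(child_id = diff$child_id,
                    label = as.character(diff$label),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fp$x))
  utils::write.csv(out, path, row.names = FALSE)
  recipe <- fp$recipe
  if (!is.null(recipe$pca))
    recipe$pca <- list(center = recipe$pca$center,
                       rotation = recipe$pca$rotation,
                       var_ratio = recipe$pca$var_ratio, k = recipe$pca$k)
  jsonlite::write_json(recipe, paste0(path, ".recipe.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Min-max normalization to [0, 1]
#'
#' Fitted bounds are returned for reuse on held-out rows (with clipping to
#' `[0, 1]`); constant features map to 0 by convention.
#'
#' @param x Numeric matrix.
#' @param bounds Optional previously fitted bounds (list with `min`,
#'   `max`); when `NULL`, bounds are fitted on `x`.
#' @return List with `x` (normalized matrix) and `bounds`.
#' @export
minmax_normalize <- function(x, bounds = NULL) {
  if (!nrow(x)) stop("need >= 1 row")
  if (is.null(bounds)) {
    bounds <- list(min = apply(x, 2, function(c) min(c, na.rm = TRUE)),
                   max = apply(x, 2, function(c) max(c, na.rm = TRUE)))
    bounds$min[!is.finite(bounds$min)] <- 0
    bounds$max[!is.finite(bounds$max)] <- 0
  }
  rng <- bounds$max - bounds$min
  out <- sweep(x, 2, bounds$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng <= 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  list(x = out, bounds = bounds)
}

#' PCA reduction retaining a cumulative explained-variance share
#'
#' Retains the smallest leading set of principal components whose
#' cumulative explained-variance ratio reaches `variance_threshold`, and
#' projects the centered data on them.
#'
#' @param x Numeric matrix without NA, >= 2 rows.
#' @param variance_threshold In `(0, 1]`; default 0.95.
#' @return List with `model` (class `pca_model`: `center`, `rotation`,
#'   `var_ratio`, `k`) and `x` (scores matrix, columns `pc_1..pc_k`).
#' @export
pca_reduce <- function(x, variance_threshold = 0.95) {
  if (nrow(x) < 2) stop("need >= 2 rows for PCA")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vr <- p$sdev^2 / sum(p$sdev^2)
  nz <- p$sdev^2 > 1e-12 * max(p$sdev^2)
  if (!any(nz)) stop("rank-0 matrix: no variance to decompose")
  k <- which(cumsum(vr) >= variance_threshold - 1e-12)[1]
  k <- min(k, sum(nz))
  model <- structure(list(center = p$center,
                          rotation = p$rotation[, seq_len(k), drop = FALSE],
                          var_ratio = vr, k = k,
                          variance_threshold = variance_threshold),
                     class = "pca_model")
  scores <- p$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("pc_", seq_len(k))
  list(model = model, x = scores)
}

#' Project new rows with a fitted PCA model
#' @param model A `pca_model` from [pca_reduce()].
#' @param x Numeric matrix with the training feature columns.
#' @return Scores matrix `pc_1..pc_k`.
#' @export
pca_project <- function(model, x) {
  scores <- sweep(x, 2, model$center) %*% model$rotation
  colnames(scores) <- paste0("pc_", seq_len(model$k))
  scores
}

#' Impute or drop not-available entries
#'
#' @param x Numeric matrix possibly containing NA.
#' @param policy `"median"` (replace by the feature's median; features
#'   missing everywhere are dropped with a warning) or `"drop_feature"`
#'   (drop any feature with a missing entry).
#' @param medians Optional previously fitted medians (named vector) for
#'   held-out rows.
#' @return List with `x` (complete matrix), `dropped` (feature names) and
#'   `medians`.
#' @export
impute_missing <- function(x, policy = c("median", "drop_feature"),
                           medians = NULL) {
  policy <- match.arg(policy)
  all_na <- apply(x, 2, function(c) all(is.na(c)))
  any_na <- apply(x, 2, function(c) anyNA(c))
  if (policy == "drop_feature") {
    dropped <- colnames(x)[any_na]
    if (!is.null(medians)) dropped <- union(dropped, names(medians))
    return(list(x = x[, !colnames(x) %in% dropped, drop = FALSE],
                dropped = dropped, medians = NULL))
  }
  dropped <- colnames(x)[all_na]
  if (is.null(medians)) {
    if (length(dropped))
      warning("features missing in all rows dropped: ",
              paste(dropped, collapse = ", "))
    keep <- !colnames(x) %in% dropped
    x <- x[, keep, drop = FALSE]
    medians <- apply(x, 2, function(c) stats::median(c, na.rm = TRUE))
  } else {
    x <- x[, names(medians), drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- medians[[j]]
  }
  list(x = x, dropped = dropped, medians = medians)
}

#' Fit the preprocessing pipeline on training rows
#'
#' Variants mirror the four evaluated conditions: raw, raw + PCA,
#' normalized, normalized + PCA.  Imputation (median policy) always runs
#' first so that no NA reaches the models.
#'
#' @param x Training matrix (may contain NA).
#' @param variant One of `"raw"`, `"raw_pca"`, `"norm"`, `"norm_pca"`.
#' @param variance_threshold PCA threshold, default 0.95.
#' @return List with `x` (transformed training matrix) and `recipe` used by
#'   [apply_preprocess()].
#' @export
fit_preprocess <- function(x, variant = c("raw", "raw_pca", "norm",
                                          "norm_pca"),
                           variance_threshold = 0.95) {
  variant <- match.arg(variant)
  imp <- suppressWarnings(impute_missing(x, "median"))
  x <- imp$x
  recipe <- list(variant = variant, medians = imp$medians, bounds = NULL,
                 pca = NULL)
  if (variant %in% c("norm", "norm_pca")) {
    nm <- minmax_normalize(x)
    x <- nm$x
    recipe$bounds <- nm$bounds
  }
  if (variant %in% c("raw_pca", "norm_pca")) {
    pr <- pca_reduce(x, variance_threshold)
    x <- pr$x
    recipe$pca <- pr$model
  }
  list(x = x, recipe = recipe)
}

#' Apply a fitted preprocessing recipe to held-out rows
#' @param recipe From [fit_preprocess()].
#' @param x Matrix of held-out rows.
#' @return Transformed matrix.
#' @export
apply_preprocess <- function(recipe, x) {
  x <- impute_missing(x, "median", medians = recipe$medians)$x
  if (!is.null(recipe$bounds)) x <- minmax_normalize(x, recipe$bounds)$x
  if (!is.null(recipe$pca)) x <- pca_project(recipe$pca, x)
  x
}
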