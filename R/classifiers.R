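## Classifier suite ---------------------------------------------------------
##
## Self-contained implementations of the evaluated model families: CART
## decision tree (Gini, weighted), Gaussian naive Bayes, tree-augmented
## naive Bayes over equal-frequency-discretized features, a one-hidden-layer
## feedforward neural network, and tree ensembles (bagging, random forest,
## AdaBoost, rotation forest).  All take a numeric matrix `x` and a
## two-level factor `y`; all are deterministic given the spec seed.

MODEL_NAMES <- c("decision_tree", "naive_bayes", "bayes_net", "neural_net",
                 "random_forest", "bagging_trees", "adaboost_trees",
                 "rotation_forest")

#' Describe a model to train
#'
#' @param name One of `r paste(MODEL_NAMES, collapse = ", ")`.
#' @param hyper Named list of hyperparameter overrides (see the fitter
#'   defaults in the package source / methods vignette).
#' @param seed Integer seed controlling every random element of the fit.
#' @return A `model_spec`.
#' @export
model_spec <- function(name, hyper = list(), seed = 1L) {
  name <- match.arg(name, MODEL_NAMES)
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "model_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

## --- CART (weighted Gini) -------------------------------------------------

## Weighted Gini impurity decrease of every candidate cut of one ordered
## feature, vectorized over cuts.  `cw` is the cumulative per-class weight
## matrix (cuts x classes).
gini_gains <- function(cw, tot) {
  tl <- rowSums(cw)
  tr <- sum(tot) - tl
  parent <- 1 - sum((tot / sum(tot))^2)
  wr <- -sweep(cw, 2, tot)
  gl <- 1 - rowSums((cw / ifelse(tl > 0, tl, 1))^2 * (tl > 0))
  gr <- 1 - rowSums((wr / ifelse(tr > 0, tr, 1))^2 * (tr > 0))
  parent - (tl * gl + tr * gr) / sum(tot)
}

cart_grow <- function(x, yi, w, depth, maxdepth, minsplit, nclass) {
  wcls <- vapply(seq_len(nclass), function(k) sum(w[yi == k]), numeric(1))
  leaf <- list(leaf = TRUE, pred = which.max(wcls), w = wcls)
  if (depth >= maxdepth || length(yi) < minsplit ||
      length(unique(yi)) == 1L)
    return(leaf)
  best <- list(gain = 1e-12, j = NA, cut = NA)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    o <- order(v)
    vs <- v[o]; ys <- yi[o]; ws <- w[o]
    distinct <- which(diff(vs) > 0)
    if (!length(distinct)) next
    ## cumulative class-weight totals below each candidate cut
    cw <- vapply(seq_len(nclass), function(k) cumsum(ws * (ys == k)),
                 numeric(length(ys)))
    tot <- cw[length(ys), ]
    gains <- gini_gains(cw[distinct, , drop = FALSE], tot)
    i_best <- which.max(gains)
    if (gains[i_best] > best$gain + 1e-12) {
      i <- distinct[i_best]
      best <- list(gain = gains[i_best], j = j,
                   cut = (vs[i] + vs[i + 1]) / 2)
    }
  }
  if (is.na(best$j)) return(leaf)
  left <- x[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut,
       left = cart_grow(x[left, , drop = FALSE], yi[left], w[left],
                        depth + 1, maxdepth, minsplit, nclass),
       right = cart_grow(x[!left, , drop = FALSE], yi[!left], w[!left],
                         depth + 1, maxdepth, minsplit, nclass))
}

cart_fit <- function(x, y, w = NULL, maxdepth = 10L, minsplit = 5L) {
  if (is.null(w)) w <- rep(1, nrow(x))
  tree <- cart_grow(x, as.integer(y), w / sum(w), 0L, maxdepth, minsplit,
                    nlevels(y))
  structure(list(tree = tree, levels = levels(y)), class = "pp_cart")
}

cart_node_predict <- function(node, xrow) {
  while (!node$leaf)
    node <- if (xrow[node$j] <= node$cut) node$left else node$right
  node$pred
}

#' @export
predict.pp_cart <- function(object, newdata, ...) {
  idx <- apply(newdata, 1, function(r) cart_node_predict(object$tree, r))
  factor(object$levels[idx], levels = object$levels)
}

## --- Gaussian naive Bayes -------------------------------------------------

nb_fit <- function(x, y) {
  lv <- levels(y)
  stats_by <- lapply(lv, function(l) {
    xi <- x[y == l, , drop = FALSE]
    list(mu = colMeans(xi),
         sd = pmax(apply(xi, 2, stats::sd), 1e-6),
         prior = mean(y == l))
  })
  names(stats_by) <- lv
  structure(list(stats = stats_by, levels = lv), class = "pp_nb")
}

#' @export
predict.pp_nb <- function(object, newdata, ...) {
  ll <- sapply(object$stats, function(s) {
    s$sd[is.na(s$sd)] <- 1e-6
    rowSums(sapply(seq_len(ncol(newdata)), function(j)
      stats::dnorm(newdata[, j], s$mu[j], s$sd[j], log = TRUE))) +
      log(max(s$prior, 1e-12))
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  factor(object$levels[max.col(ll, ties.method = "first")],
         levels = object$levels)
}

## --- Tree-augmented naive Bayes ------------------------------------------

equal_freq_breaks <- function(v, bins) {
  ## interior cut points at the 1/bins .. (bins-1)/bins quantiles;
  ## duplicated quantiles collapse bins (heavily tied features get fewer)
  unique(stats::quantile(v, probs = seq_len(bins - 1) / bins,
                         na.rm = TRUE, names = FALSE, type = 7))
}

discretize_train <- function(x, bins) {
  breaks <- lapply(seq_len(ncol(x)), function(j)
    equal_freq_breaks(x[, j], bins))
  z <- sapply(seq_len(ncol(x)), function(j)
    findInterval(x[, j], breaks[[j]]) + 1L)
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(x))
  list(z = z, breaks = breaks,
       nbin = vapply(breaks, function(b) length(b) + 1L, integer(1)))
}

cond_mutual_info <- function(zi, zj, yi, ni, nj, ny) {
  n <- length(yi)
  mi <- 0
  for (y in seq_len(ny)) {
    sel <- yi == y
    py <- sum(sel) / n
    if (py == 0) next
    tab <- table(factor(zi[sel], levels = seq_len(ni)),
                 factor(zj[sel], levels = seq_len(nj))) / sum(sel)
    pi_ <- rowSums(tab); pj_ <- colSums(tab)
    nzr <- tab > 0
    mi <- mi + py * sum(tab[nzr] * log2(tab[nzr] /
                                          outer(pi_, pj_)[nzr]))
  }
  mi
}

tan_fit <- function(x, y, bins = 5L) {
  d <- discretize_train(x, bins)
  z <- d$z; yi <- as.integer(y); ny <- nlevels(y); p <- ncol(z)
  parent <- rep(0L, p)
  if (p > 1) {
    ## Chow-Liu maximum spanning tree on conditional mutual information
    mi <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      mi[i, j] <- mi[j, i] <- cond_mutual_info(z[, i], z[, j], yi,
                                               d$nbin[i], d$nbin[j], ny)
    in_tree <- c(TRUE, rep(FALSE, p - 1))
    while (!all(in_tree)) {
      cand <- which(!in_tree)
      best <- c(-1, 0, 0)
      for (j in cand) for (i in which(in_tree))
        if (mi[i, j] > best[1]) best <- c(mi[i, j], i, j)
      parent[best[3]] <- best[2]
      in_tree[best[3]] <- TRUE
    }
  }
  ## CPTs with Laplace smoothing
  prior <- (tabulate(yi, ny) + 1) / (length(yi) + ny)
  cpt <- vector("list", p)
  for (j in seq_len(p)) {
    nj <- d$nbin[j]
    if (parent[j] == 0L) {
      tab <- array(1, dim = c(nj, ny))
      for (r in seq_along(yi)) tab[z[r, j], yi[r]] <- tab[z[r, j], yi[r]] + 1
      cpt[[j]] <- sweep(tab, 2, colSums(tab), "/")
    } else {
      np <- d$nbin[parent[j]]
      tab <- array(1, dim = c(nj, np, ny))
      for (r in seq_along(yi)) {
        idx <- cbind(z[r, j], z[r, parent[j]], yi[r])
        tab[idx] <- tab[idx] + 1
      }
      tot <- apply(tab, c(2, 3), sum)
      for (b in seq_len(nj)) tab[b, , ] <- tab[b, , ] / tot
      cpt[[j]] <- tab
    }
  }
  structure(list(breaks = d$breaks, nbin = d$nbin, parent = parent,
                 prior = prior, cpt = cpt, levels = levels(y)),
            class = "pp_tan")
}

#' @export
predict.pp_tan <- function(object, newdata, ...) {
  p <- length(object$cpt); ny <- length(object$prior)
  z <- sapply(seq_len(p), function(j)
    pmin(findInterval(newdata[, j], object$breaks[[j]]) + 1L,
         object$nbin[j]))
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(newdata))
  ll <- matrix(rep(log(object$prior), each = nrow(z)), nrow = nrow(z))
  for (j in seq_len(p)) {
    for (y in seq_len(ny)) {
      pj <- if (object$parent[j] == 0L) object$cpt[[j]][z[, j], y]
            else object$cpt[[j]][cbind(z[, j], z[, object$parent[j]], y)]
      ll[, y] <- ll[, y] + log(pj)
    }
  }
  factor(object$levels[max.col(ll, ties.method = "first")],
         levels = object$levels)
}

## --- One-hidden-layer neural network --------------------------------------

nnet_fit <- function(x, y, hidden = 10L, decay = 1e-3, maxit = 200L) {
  ## logistic activations, cross-entropy loss, BFGS with analytic gradient
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x); sdv <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  t01 <- as.numeric(y) - 1
  npar <- p * hidden + hidden + hidden + 1
  unpack <- function(th) {
    W1 <- matrix(th[seq_len(p * hidden)], p, hidden)
    b1 <- th[p * hidden + seq_len(hidden)]
    w2 <- th[p * hidden + hidden + seq_len(hidden)]
    b2 <- th[npar]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  sig <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  fwd <- function(th) {
    pp <- unpack(th)
    a1 <- sig(sweep(xs %*% pp$W1, 2, pp$b1, "+"))
    list(pp = pp, a1 = a1, out = sig(drop(a1 %*% pp$w2) + pp$b2))
  }
  fn <- function(th) {
    f <- fwd(th)
    eps <- 1e-12
    -mean(t01 * log(f$out + eps) + (1 - t01) * log(1 - f$out + eps)) +
      decay * sum(th^2)
  }
  gr <- function(th) {
    f <- fwd(th)
    d2 <- (f$out - t01) / n
    gw2 <- drop(crossprod(f$a1, d2))
    gb2 <- sum(d2)
    d1 <- (d2 %o% f$pp$w2) * f$a1 * (1 - f$a1)
    gW1 <- crossprod(xs, d1)
    gb1 <- colSums(d1)
    c(as.numeric(gW1), gb1, gw2, gb2) + 2 * decay * th
  }
  th0 <- stats::runif(npar, -0.5, 0.5)
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  structure(list(theta = opt$par, p = p, hidden = hidden, mu = mu, sd = sdv,
                 levels = levels(y)), class = "pp_nnet")
}

#' @export
predict.pp_nnet <- function(object, newdata, ...) {
  p <- object$p; hidden <- object$hidden; th <- object$theta
  xs <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  W1 <- matrix(th[seq_len(p * hidden)], p, hidden)
  b1 <- th[p * hidden + seq_len(hidden)]
  w2 <- th[p * hidden + hidden + seq_len(hidden)]
  b2 <- th[length(th)]
  sig <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  out <- sig(drop(sig(sweep(xs %*% W1, 2, b1, "+")) %*% w2) + b2)
  factor(object$levels[ifelse(out > 0.5, 2L, 1L)], levels = object$levels)
}

## --- Tree ensembles -------------------------------------------------------

bag_fit <- function(x, y, ntree = 25L, mtry = NULL, maxdepth = 10L) {
  ## mtry = NULL: plain bagging; otherwise a random feature subspace per
  ## tree (random-forest flavour at tree granularity)
  n <- nrow(x)
  trees <- lapply(seq_len(ntree), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    feats <- if (is.null(mtry)) seq_len(ncol(x))
             else sort(sample.int(ncol(x), min(mtry, ncol(x))))
    list(fit = cart_fit(x[idx, feats, drop = FALSE], y[idx],
                        maxdepth = maxdepth), feats = feats)
  })
  structure(list(trees = trees, levels = levels(y)), class = "pp_bag")
}

#' @export
predict.pp_bag <- function(object, newdata, ...) {
  votes <- sapply(object$trees, function(tr)
    as.integer(predict(tr$fit, newdata[, tr$feats, drop = FALSE])))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  idx <- apply(votes, 1, function(v)
    which.max(tabulate(v, length(object$levels))))
  factor(object$levels[idx], levels = object$levels)
}

ada_fit <- function(x, y, rounds = 30L, maxdepth = 2L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  fits <- list(); alphas <- numeric()
  for (m in seq_len(rounds)) {
    fit <- cart_fit(x, y, w = w, maxdepth = maxdepth, minsplit = 2L)
    pred <- predict(fit, x)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    fits[[length(fits) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  if (!length(fits)) {  # degenerate: fall back to a single tree
    fits <- list(cart_fit(x, y, maxdepth = maxdepth))
    alphas <- 1
  }
  structure(list(fits = fits, alphas = alphas, levels = levels(y)),
            class = "pp_ada")
}

#' @export
predict.pp_ada <- function(object, newdata, ...) {
  score <- rep(0, nrow(newdata))
  for (m in seq_along(object$fits)) {
    pm <- predict(object$fits[[m]], newdata)
    score <- score + object$alphas[m] * ifelse(as.integer(pm) == 2L, 1, -1)
  }
  factor(object$levels[ifelse(score > 0, 2L, 1L)], levels = object$levels)
}

rot_fit <- function(x, y, ntree = 10L, group_size = 3L,
                    sample_frac = 0.75, maxdepth = 10L) {
  n <- nrow(x); p <- ncol(x)
  trees <- lapply(seq_len(ntree), function(l) {
    groups <- split(sample.int(p), ceiling(seq_len(p) / group_size))
    R <- matrix(0, p, p)
    for (g in groups) {
      idx <- sample.int(n, max(2L, round(sample_frac * n)), replace = TRUE)
      sub <- x[idx, g, drop = FALSE]
      ## eigen of the covariance always yields a full square rotation,
      ## even when the bootstrap sample is rank-deficient
      ev <- tryCatch(eigen(stats::cov(sub), symmetric = TRUE)$vectors,
                     error = function(e) NULL)
      R[g, g] <- if (is.null(ev) || anyNA(ev)) diag(length(g)) else ev
    }
    center <- colMeans(x)
    xr <- sweep(x, 2, center) %*% R
    list(fit = cart_fit(xr, y, maxdepth = maxdepth), R = R, center = center)
  })
  structure(list(trees = trees, levels = levels(y)), class = "pp_rot")
}

#' @export
predict.pp_rot <- function(object, newdata, ...) {
  votes <- sapply(object$trees, function(tr)
    as.integer(predict(tr$fit,
                       sweep(newdata, 2, tr$center) %*% tr$R)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  idx <- apply(votes, 1, function(v)
    which.max(tabulate(v, length(object$levels))))
  factor(object$levels[idx], levels = object$levels)
}

## --- Dispatcher -----------------------------------------------------------

#' Train a classifier from a model spec
#'
#' @param spec A [model_spec()].
#' @param x Numeric matrix (no NA), >= 2 rows.
#' @param y Two-level factor with both classes present.
#' @return A fitted model with a `predict` method returning a factor over
#'   the training levels.
#' @export
train_model <- function(spec, x, y) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  if (nrow(x) < 2) stop("need >= 2 training rows")
  if (anyNA(x)) stop("x must be complete; impute first")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("single-class training set")
  h <- spec$hyper
  gv <- function(name, default) if (is.null(h[[name]])) default else h[[name]]
  with_seed(spec$seed, switch(
    spec$name,
    decision_tree = cart_fit(x, y, maxdepth = gv("maxdepth", 10L),
                             minsplit = gv("minsplit", 5L)),
    naive_bayes = nb_fit(x, y),
    bayes_net = tan_fit(x, y, bins = gv("bins", 5L)),
    neural_net = nnet_fit(x, y, hidden = gv("hidden", 10L),
                          decay = gv("decay", 1e-3),
                          maxit = gv("maxit", 200L)),
    random_forest = bag_fit(x, y, ntree = gv("ntree", 50L),
                            mtry = gv("mtry",
                                      max(1L, floor(sqrt(ncol(x))))),
                            maxdepth = gv("maxdepth", 10L)),
    bagging_trees = bag_fit(x, y, ntree = gv("ntree", 25L), mtry = NULL,
                            maxdepth = gv("maxdepth", 10L)),
    adaboost_trees = ada_fit(x, y, rounds = gv("rounds", 30L),
                             maxdepth = gv("maxdepth", 2L)),
    rotation_forest = rot_fit(x, y, ntree = gv("ntree", 10L),
                              group_size = gv("group_size", 3L),
                              sample_frac = gv("sample_frac", 0.75),
                              maxdepth = gv("maxdepth", 10L))))
}
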