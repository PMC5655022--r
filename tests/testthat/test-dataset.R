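make_cohort_tables <- function(seed = 31, n_children = 6) {
  co <- simulate_cohort(small_cohort_config(n_children = n_children,
                                            seed = seed))
  list(features = extract_cohort_features(co$sessions),
       scores = cohort_area_scores(co$sessions),
       sessions = co$sessions)
}

test_that("pairing modes yield the documented sample counts", {
  tabs <- make_cohort_tables()
  sess_per_child <- table(tabs$scores$child_id)
  d_cons <- build_diff_samples(tabs$features, tabs$scores, "boxes",
                               "fine_motor", "consecutive")
  expect_equal(nrow(d_cons$x), sum(sess_per_child - 1))
  d_fl <- build_diff_samples(tabs$features, tabs$scores, "boxes",
                             "fine_motor", "first_last")
  expect_equal(nrow(d_fl$x), sum(sess_per_child >= 2))
  # first_last difference is last minus first
  cid <- names(sess_per_child)[1]
  f <- tabs$features
  f <- f[f$game == "boxes" & f$child_id == cid, ]
  f <- f[order(f$session_index), ]
  expect_equal(unname(d_fl$x[d_fl$child_id == cid, "total_time"]),
               f$total_time[nrow(f)] - f$total_time[1])
  # labels agree with score deltas under the strict rule
  expect_equal(unname(d_cons$label == "progress"),
               unname(d_cons$score_delta > 0))
})

test_that("children with fewer than two sessions are excluded", {
  tabs <- make_cohort_tables()
  # forge a child with a single session
  f1 <- tabs$features[tabs$features$child_id ==
                        tabs$features$child_id[1], ][1, ]
  f1$child_id <- "single"
  s1 <- tabs$scores[1, ]; s1$child_id <- "single"
  d <- build_diff_samples(rbind(tabs$features, f1), rbind(tabs$scores, s1),
                          "boxes", "fine_motor", "consecutive")
  expect_false("single" %in% d$child_id)
})

test_that("minmax_normalize maps to [0,1] with recorded bounds", {
  m <- matrix(c(2, 4, 6, 5, 5, 5), ncol = 2)
  colnames(m) <- c("a", "b")
  nm <- minmax_normalize(m)
  expect_equal(nm$x[, "a"], c(0, 0.5, 1))
  expect_equal(nm$x[, "b"], c(0, 0, 0))  # constant column convention
  # held-out rows reuse bounds and clip
  held <- matrix(c(0, 8, 5, 5), ncol = 2, dimnames = list(NULL, c("a", "b")))
  hx <- minmax_normalize(held, nm$bounds)$x
  expect_equal(hx[, "a"], c(0, 1))
  set.seed(2)
  r <- matrix(rnorm(60), 10)
  expect_true(all(minmax_normalize(r)$x >= 0 &
                    minmax_normalize(r)$x <= 1))
})

test_that("pca_reduce matches an independent eigendecomposition", {
  set.seed(8)
  x <- matrix(rnorm(20 * 8), 20, 8)
  pr <- pca_reduce(x, 1.0)
  # oracle: eigen of the sample covariance
  ev <- eigen(cov(x), symmetric = TRUE)
  k <- pr$model$k
  for (j in seq_len(k)) {
    a <- pr$model$rotation[, j]; b <- ev$vectors[, j]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)  # sign-aligned
  }
  expect_equal(pr$model$var_ratio[seq_len(k)],
               (ev$values / sum(ev$values))[seq_len(k)], tolerance = 1e-8)
  # components orthonormal; ratios non-increasing
  expect_equal(crossprod(pr$model$rotation), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pr$model$var_ratio) <= 1e-12))
})

test_that("pca_reduce keeps the smallest sufficient component set", {
  line <- cbind(1:10, 2 * (1:10) + rnorm(10, 0, 1e-8))
  expect_equal(pca_reduce(line, 0.95)$model$k, 1)
  set.seed(9)
  x <- matrix(rnorm(30 * 5), 30, 5)
  expect_equal(pca_reduce(x, 1.0)$model$k, 5)
  expect_error(pca_reduce(x[1, , drop = FALSE], 0.9), "rows")
})

test_that("PCA reconstruction error is non-increasing in components", {
  set.seed(10)
  x <- matrix(rnorm(25 * 6), 25, 6)
  p <- prcomp(x)
  errs <- vapply(1:6, function(k) {
    recon <- p$x[, 1:k, drop = FALSE] %*% t(p$rotation[, 1:k, drop = FALSE])
    sum((sweep(x, 2, colMeans(x)) - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("impute_missing honours both policies", {
  m <- matrix(c(1, NA, 3, 4, 5, 6, NA, NA, NA), ncol = 3)
  colnames(m) <- c("a", "b", "c")
  expect_warning(out <- impute_missing(m, "median"), "dropped")
  expect_equal(colnames(out$x), c("a", "b"))
  expect_equal(unname(out$x[2, "a"]), 2)  # median of 1, 3
  out2 <- impute_missing(m, "drop_feature")
  expect_equal(colnames(out2$x), "b")
  full <- matrix(1:6, 2); colnames(full) <- c("x", "y", "z")
  expect_identical(impute_missing(full, "median")$x, full)
})

test_that("write_diff_dataset emits CSV plus a usable recipe sidecar", {
  tabs <- make_cohort_tables(seed = 77)
  d <- build_diff_samples(tabs$features, tabs$scores, "catdog",
                          "attention", "consecutive")
  path <- withr::local_tempfile(fileext = ".csv")
  write_diff_dataset(d, path, variant = "norm")
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(d$x))
  expect_true(all(c("child_id", "label") %in% names(back)))
  vals <- as.matrix(back[, setdiff(names(back), c("child_id", "label"))])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(file.exists(paste0(path, ".recipe.json")))
})

test_that("fitted preprocessing applied to training rows reproduces them", {
  tabs <- make_cohort_tables(seed = 55)
  d <- build_diff_samples(tabs$features, tabs$scores, "pinwheel",
                          "gross_motor", "consecutive")
  for (variant in c("raw", "raw_pca", "norm", "norm_pca")) {
    fp <- fit_preprocess(d$x, variant)
    expect_false(anyNA(fp$x))
    expect_equal(apply_preprocess(fp$recipe, d$x), fp$x,
                 ignore_attr = TRUE)
  }
})
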