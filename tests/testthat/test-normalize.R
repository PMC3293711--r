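methods_all <- c("lowess", "quantile", "vsn", "tquantile", "tbw", "peng")

test_that("LOWESS detrending leaves flat data alone and removes constants", {
  n <- 200
  set.seed(1)
  A <- matrix(rnorm(n, 10, 1), ncol = 1)
  zero <- ma_matrix(matrix(0, n, 1), A)
  out <- lowess_normalize(zero)
  expect_lt(max(abs(out$M)), 1e-8)

  const <- ma_matrix(matrix(0.7, n, 1), A)
  out2 <- lowess_normalize(const)
  expect_lt(max(abs(out2$M)), 1e-6)

  expect_error(lowess_normalize(ma_matrix(matrix(0, 5, 1),
                                          matrix(1:5, 5, 1))), "10 probes")
  expect_error(lowess_normalize(zero, span = 0), "span")
})

test_that("rank-mean quantile normalization matches the sort/average oracle", {
  X <- cbind(c(2, 4, 6), c(3, 5, 7))
  # independent oracle: sort each channel, average same-rank values, remap
  sorted_mean <- rowMeans(apply(X, 2, sort))
  oracle <- apply(X, 2, function(col) sorted_mean[rank(col)])
  got <- quantile_normalize_matrix(X)
  expect_equal(got, oracle, ignore_attr = TRUE)
  expect_equal(got[, 1], c(2.5, 4.5, 6.5), ignore_attr = TRUE)
})

test_that("quantile normalization equalizes pooled channels and is idempotent", {
  exp3 <- random_experiment(n = 400, n_arrays = 3)
  res <- quantile_normalize(exp3)
  chan <- ma_to_intensities(res)
  X <- log2(cbind(chan$green, chan$red))
  sorted <- apply(X, 2, sort)
  expect_lt(max(abs(sorted - rowMeans(sorted))), 1e-12)

  # idempotence: renormalizing the normalized channels changes nothing
  arrays2 <- lapply(seq_len(3), function(j)
    two_channel_array(paste0("b", j), chan$green[, j], chan$red[, j]))
  res2 <- quantile_normalize(experiment_set(exp3$annotation, arrays2))
  expect_lt(max(abs(res2$M - res$M)), 1e-12)

  # two identical channels are left unchanged
  ann <- toy_annotation(5)
  x <- c(3, 1, 4, 1.5, 9)
  same <- experiment_set(ann, two_channel_array("s", x, x))
  expect_lt(max(abs(quantile_normalize(same)$M)), 1e-12)
})

test_that("T-quantile equalizes within channel groups and preserves ranks", {
  exp3 <- random_experiment(n = 400, n_arrays = 3)
  res <- tquantile_normalize(exp3)
  chan <- ma_to_intensities(res)
  gs <- apply(log2(chan$green), 2, sort)
  rs <- apply(log2(chan$red), 2, sort)
  expect_lt(max(abs(gs - rowMeans(gs))), 1e-12)
  expect_lt(max(abs(rs - rowMeans(rs))), 1e-12)
  # red and green distributions remain distinct (unlike pooled quantile)
  expect_gt(max(abs(gs[, 1] - rs[, 1])), 0.1)
  # within-array, within-channel ranks preserved exactly
  for (j in seq_along(exp3$arrays)) {
    expect_identical(order(chan$green[, j]),
                     order(exp3$arrays[[j]]$green))
    expect_identical(order(chan$red[, j]), order(exp3$arrays[[j]]$red))
  }
  # idempotence
  arrays2 <- lapply(seq_len(3), function(j)
    two_channel_array(paste0("b", j), chan$green[, j], chan$red[, j]))
  res2 <- tquantile_normalize(experiment_set(exp3$annotation, arrays2))
  expect_lt(max(abs(res2$M - res$M)), 1e-12)

  expect_error(tquantile_normalize(
    experiment_set(toy_annotation(3),
                   two_channel_array("one", 1:3, 4:6))), ">= 2 arrays")
})

test_that("pooled quantile can reorder M where T-quantile cannot", {
  exp3 <- random_experiment(n = 300, n_arrays = 2, seed = 3)
  raw_M <- compute_ma(exp3)$M
  q <- quantile_normalize(exp3)
  tq <- tquantile_normalize(exp3)
  # pooling red and green changes the M ordering of this experiment
  expect_false(identical(order(q$M[, 1]), order(raw_M[, 1])))
  # per-array T-quantile M ranks can change too, but within-channel ranks
  # never do (asserted above); here the scaled-array identity instead:
  ann <- toy_annotation(50)
  set.seed(8)
  g <- 2^rnorm(50, 10, 1)
  r <- 2^(rnorm(50, 10, 1))
  sc <- experiment_set(ann, list(two_channel_array("a1", g, r),
                                 two_channel_array("a2", g, 3 * r)))
  out <- tquantile_normalize(sc)
  chan <- ma_to_intensities(out)
  # red channels equalized across arrays
  expect_lt(max(abs(chan$red[, 1] - chan$red[, 2])), 1e-9)
})

test_that("T-quantile on rescaled replicates preserves the raw array's AUC", {
  set.seed(21)
  n <- 400
  ann <- probe_annotation(sprintf("p%03d", 1:n), "chr1", (1:n - 1) * 100,
                          50L, rep(c("NEGATIVE_CONTROL", "PROMOTER"),
                                   each = n / 2))
  g <- 2^rnorm(n, 10, 0.8)
  r <- g * 2^c(rnorm(n / 2, 0, 0.4), rnorm(n / 2, 1, 0.4))
  k <- c(1, 2.5, 0.6)
  arrays <- lapply(seq_along(k), function(j)
    two_channel_array(paste0("a", j), g, k[j] * r))
  expt <- experiment_set(ann, arrays)
  res <- tquantile_normalize(expt)
  neg <- ann$category == "NEGATIVE_CONTROL"
  auc_raw_single <- roc_auc(log2(r / g)[neg], log2(r / g)[!neg])$auc
  auc_norm_combined <- roc_auc(as.vector(res$M[neg, ]),
                               as.vector(res$M[!neg, ]))$auc
  expect_equal(auc_norm_combined, auc_raw_single, tolerance = 1e-12)
})

test_that("glog transform has its defining identities", {
  expect_identical(glog2(0), 0)
  x <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(glog2(x)) > 0))
  expect_equal(inv_glog2(glog2(x)), x, tolerance = 1e-12)
  # approaches plain log2(2x) for large arguments
  expect_equal(glog2(1e6), log2(2e6), tolerance = 1e-10)
})

test_that("VSN-style calibration absorbs a pure scale factor", {
  set.seed(5)
  x <- 2^runif(50, 4, 12)
  ann <- toy_annotation(50)
  expt <- experiment_set(ann, two_channel_array("a", x, 3 * x))
  res <- vsn_normalize(expt)
  # grid-search oracle: with channel 1 fixed at (a=0, b=median), the
  # agreement objective over (a2, b2) is minimized at a2 = 0, b2 = 3 * b1
  b1 <- median(x)
  h1 <- glog2(x / b1)
  grid <- expand.grid(a2 = seq(-50, 50, length.out = 21),
                      b2 = b1 * 3 * exp(seq(-0.5, 0.5, length.out = 21)))
  ss <- mapply(function(a2, b2) sum((glog2((3 * x - a2) / b2) - h1)^2),
               grid$a2, grid$b2)
  best <- grid[which.min(ss), ]
  expect_equal(best$a2, 0, tolerance = 1e-8)
  expect_equal(best$b2, 3 * b1, tolerance = 1e-8)
  # the fitted transform equalizes the channels to the same precision
  expect_lt(max(abs(res$M)), 1e-6)
  expect_equal(unname(res$diagnostics$b[2] / res$diagnostics$b[1]), 3,
               tolerance = 1e-3)
})

test_that("VSN-style transform stabilizes additive-multiplicative noise", {
  set.seed(17)
  n <- 3000
  mu <- runif(n, 3, 12)
  s <- 2^mu
  make_channel <- function() pmax(s * 2^rnorm(n, 0, 0.2) + rnorm(n, 0, 5),
                                  0.25)
  x1 <- make_channel(); x2 <- make_channel()
  ann <- toy_annotation(n)
  res <- vsn_normalize(experiment_set(ann, two_channel_array("a", x1, x2)))
  strata <- cut(mu, quantile(mu, 0:5 / 5), include.lowest = TRUE)
  sd_glog <- tapply(res$M[, 1], strata, sd)
  sd_log <- tapply(log2(x2) - log2(x1), strata, sd)
  expect_lt((max(sd_glog) - min(sd_glog)) / mean(sd_glog), 0.25)
  expect_gt((max(sd_log) - min(sd_log)) / mean(sd_log), 1.0)
})

test_that("Tukey biweight matches hand-iterated bisquare weighting", {
  expect_identical(tukey_biweight(c(5, 5, 5)), 5)
  expect_identical(tukey_biweight(c(1, 2, 3)), 2)

  x <- c(1, 2, 3, 4, 100)
  # oracle: direct arithmetic of the weighting formula
  biweight_step <- function(center, x, c, mad0) {
    u <- (x - center) / (c * mad0)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    sum(w * x) / sum(w)
  }
  mad0 <- median(abs(x - median(x)))
  expect_identical(mad0, 1)
  first <- biweight_step(median(x), x, 5, mad0)
  expect_equal(first, 2.6024, tolerance = 1e-4)
  expect_equal(tukey_biweight(x, c = 5, max_iter = 1), first,
               tolerance = 1e-12)
  # oracle fixed point
  est <- median(x)
  for (i in 1:100) est <- biweight_step(est, x, 5, mad0)
  expect_equal(tukey_biweight(x, c = 5, max_iter = 200, tol = 1e-12), est,
               tolerance = 1e-8)
})

test_that("TBW scaling centers arrays by a rank-preserving constant", {
  set.seed(4)
  M <- matrix(rnorm(600, 0.7, 0.5), ncol = 2)
  A <- matrix(rnorm(600, 10, 1), ncol = 2)
  res <- tbw_scale(ma_matrix(M, A))
  expect_lt(max(abs(colMeans(res$M))), 0.1)
  # difference to raw is constant per array
  d <- M - res$M
  expect_lt(max(apply(d, 2, function(col) diff(range(col)))), 1e-12)
  expect_equal(res$diagnostics$shift, d[1, ], ignore_attr = TRUE)
  # ranks untouched
  for (j in 1:2) expect_identical(order(res$M[, j]), order(M[, j]))
  # identical arrays get identical constants
  res2 <- tbw_scale(ma_matrix(cbind(M[, 1], M[, 1]), A))
  expect_identical(res2$diagnostics$shift[1], res2$diagnostics$shift[2])
})

test_that("Peng rotation flattens the major axis and reduces to LOWESS", {
  set.seed(6)
  n <- 2000
  A <- matrix(rnorm(n, 10, 1), ncol = 1)
  # trended cloud: M = 0.5 * A + small noise
  M <- 0.5 * A + matrix(rnorm(n, 0, 0.05), ncol = 1)
  res <- peng_normalize(ma_matrix(M, A))
  expect_equal(res$diagnostics$slope[1], 0.5, tolerance = 0.01)
  # oracle: principal direction of the rotated cloud is horizontal
  cx <- A[, 1] - mean(A); cy <- M[, 1] - mean(M)
  th <- res$diagnostics$angle[1]
  xr <- cos(th) * cx + sin(th) * cy
  yr <- -sin(th) * cx + cos(th) * cy
  v <- eigen(crossprod(cbind(xr, yr)) / (n - 1), symmetric = TRUE)$vectors[, 1]
  expect_lt(abs(v[2] / v[1]), 0.01)
  # rotation is an isometry of the centered cloud
  idx <- sample(n, 50)
  d_before <- dist(cbind(cx, cy)[idx, ])
  d_after <- dist(cbind(xr, yr)[idx, ])
  expect_lt(max(abs(d_before - d_after)), 1e-10)

  # no-trend limit: rotation angle ~ 0 and result ~ plain LOWESS
  M0 <- matrix(rnorm(n, 0, 0.3), ncol = 1)
  p0 <- peng_normalize(ma_matrix(M0, A))
  l0 <- lowess_normalize(ma_matrix(M0, A))
  expect_lt(abs(p0$diagnostics$angle[1]), 0.02)
  expect_gt(cor(p0$M[, 1], l0$M[, 1]), 0.999)

  expect_error(peng_normalize(ma_matrix(M0, matrix(10, n, 1))),
               "zero-variance")
})

test_that("all six methods preserve shape and produce finite output", {
  sim <- simulate_experiment(quick_config(seed = 30L))
  for (m in methods_all) {
    res <- normalize_experiment(sim$experiment, m)
    expect_identical(dim(res$M), dim(compute_ma(sim$experiment)$M))
    expect_true(all(is.finite(res$M)), info = m)
    expect_true(all(is.finite(res$A)), info = m)
    expect_identical(res$method, m)
  }
})
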