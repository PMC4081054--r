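test_that("normalization equalizes aggregate counts and leaves the test sample alone", {
  set.seed(11)
  counts <- matrix(rpois(50 * 10, 100), 50, 10,
                   dimnames = list(NULL, paste0("S", 1:10)))
  storage.mode(counts) <- "integer"
  norm <- normalize_to_sample(counts, "S3")
  expect_equal(unname(colSums(norm)), rep(sum(counts[, "S3"]), 10))
  expect_equal(norm[, "S3"], as.numeric(counts[, "S3"]),
               ignore_attr = TRUE)

  # already-equal totals: scale factor 1 everywhere
  eq <- counts
  eq[] <- 2L
  expect_equal(normalize_to_sample(eq, "S1"), eq + 0,
               ignore_attr = TRUE)

  # a reference with half the total gets doubled
  half <- cbind(a = c(10L, 10L), b = c(5L, 5L))
  expect_equal(normalize_to_sample(half, "a")[, "b"], c(10, 10),
               ignore_attr = TRUE)

  zero <- cbind(a = c(10L, 10L), b = c(0L, 0L), d = c(9L, 8L))
  expect_warning(out <- normalize_to_sample(zero, "a"), "zero-total")
  expect_false("b" %in% colnames(out))
})

test_that("NNLS weights are non-negative, normalized, and match a brute-force QP oracle", {
  set.seed(21)
  base <- rlnorm(20, log(100), 0.4)
  X <- sapply(1:4, function(i) rpois(20, base * runif(1, 0.8, 1.2)))
  y <- rpois(20, base)
  norm <- cbind(X, y)
  colnames(norm) <- c(paste0("R", 1:4), "T")
  norm <- normalize_to_sample(round(norm), "T")
  w <- nnls_weights(norm, "T")
  expect_true(all(w$weights >= 0))
  expect_equal(sum(w$weights), 1)
  expect_gte(w$effective_n, 1)
  expect_lte(w$effective_n, 4)

  # fitted vector agrees with the exhaustive active-set oracle
  oracle <- nnls_oracle(norm[, paste0("R", 1:4)], norm[, "T"])
  raw <- pracma::lsqnonneg(norm[, paste0("R", 1:4)], norm[, "T"])$x
  fit_pkg <- norm[, paste0("R", 1:4)] %*% raw
  fit_orc <- norm[, paste0("R", 1:4)] %*% oracle$coef
  expect_equal(as.numeric(fit_pkg), as.numeric(fit_orc), tolerance = 1e-6)

  # an exact-duplicate reference takes all the weight
  dup <- cbind(A = y, B = rpois(20, base), C = rpois(20, base), T = y)
  dup <- normalize_to_sample(dup, "T")
  wd <- nnls_weights(dup, "T")
  expect_equal(unname(wd$weights["A"]), 1, tolerance = 1e-8)
  expect_equal(wd$effective_n, 1, tolerance = 1e-6)

  expect_error(nnls_weights(norm[, c("R1", "T")], "T"), "at least 2")
})

test_that("weighted moments reduce to classical estimators and match hand computation", {
  set.seed(31)
  x <- rnorm(15, 50, 8)
  w_eq <- rep(1 / 15, 15)
  m <- weighted_moments(x, w_eq)
  expect_equal(m[["mean"]], mean(x))
  expect_equal(m[["var"]], var(x))

  # hand-computed oracle: w = (.5, .3, .2), x = (10, 20, 30)
  # mu = 17; var = (0.5*49 + 0.3*9 + 0.2*169) / (1 - 0.38) = 61 / 0.62
  m2 <- weighted_moments(c(10, 20, 30), c(0.5, 0.3, 0.2))
  expect_equal(m2[["mean"]], 17)
  expect_equal(m2[["var"]], 61 / 0.62)

  # constant data: zero variance regardless of weights
  expect_equal(weighted_moments(c(5, 5, 5), c(0.2, 0.2, 0.6))[["var"]], 0)

  # single effective sample: variance undefined
  expect_true(is.na(weighted_moments(c(1, 2), c(1, 0))[["var"]]))

  # matrix form agrees with row-wise evaluation
  X <- matrix(rnorm(30, 100, 10), 10, 3)
  w <- c(0.5, 0.3, 0.2)
  mm <- weighted_moments(X, w)
  row4 <- weighted_moments(X[4, ], w)
  expect_equal(mm$mean[4], row4[["mean"]])
  expect_equal(mm$var[4], row4[["var"]])

  expect_error(weighted_moments(x, rep(0.1, 15)), "sum to 1")
})

test_that("variance trend fit recovers simulated mean-variance relationships", {
  set.seed(41)
  n <- 1000
  mu <- rlnorm(n, log(80), 0.8)
  gc <- rbeta(n, 9, 11)

  # Poisson-like data: predictions track var = mean in the mid-range
  raw_pois <- vapply(mu, function(m) var(rpois(40, m)), 0)
  tr <- fit_variance_trend(mu, gc, raw_pois)
  mid <- mu > quantile(mu, 0.25) & mu < quantile(mu, 0.75)
  pred <- predict(tr, mu[mid], gc[mid])
  expect_lt(median(abs(pred - mu[mid]) / mu[mid]), 0.15)

  # overdispersed data, var = mu + mu^2/50: predictions increase and are
  # convex in the mean on a grid
  raw_nb <- vapply(mu, function(m) var(rnbinom(40, mu = m, size = 50)), 0)
  tr2 <- fit_variance_trend(mu, gc, raw_nb)
  grid <- seq(quantile(mu, 0.1), quantile(mu, 0.9), length.out = 30)
  pg <- predict(tr2, grid, rep(median(gc), 30))
  expect_true(all(diff(pg) > 0))
  expect_gt(pg[30] - pg[16], pg[15] - pg[1])  # accelerating growth

  # constant variance: approximately flat predictions
  raw_const <- rnorm(n, 400, 20)
  tr3 <- fit_variance_trend(mu, gc, raw_const)
  pf <- predict(tr3, grid, rep(median(gc), 30))
  expect_lt(max(pf) / min(pf), 1.35)

  expect_error(fit_variance_trend(mu[1:50], gc[1:50], raw_pois[1:50]),
               "at least")
})

test_that("final variance applies the max-of-three floor", {
  expect_equal(final_variance(50, 100, 80), 100)
  expect_equal(final_variance(300, 100, 80), 300)
  expect_equal(final_variance(50, 100, 150), 150)
  expect_equal(final_variance(NA, 100, 150), 150)
  expect_equal(final_variance(c(50, 300), c(100, 100), c(80, 80)),
               c(100, 300))
})

test_that("moment estimation recovers simulated NB parameters", {
  sim <- tiny_cohort(n_samples = 30, n_targets = 400, seed = 5,
                     batch_sd = 0, libsize_sd = 0, size = 70)
  mom <- estimate_moments(sim$counts, sim$targets, "S001",
                          min_targets_trend = 200)
  truth_mu <- sim$truth$rate
  expect_lt(median(abs(mom$mu - truth_mu) / truth_mu), 0.05)
  truth_var <- truth_mu + truth_mu^2 / 70
  expect_lt(median(abs(mom$var - truth_var) / truth_var), 0.25)

  # invariants: floored variance never below the mean; size positive or Inf
  expect_true(all(mom$var >= mom$mu - 1e-9))
  fin <- is.finite(mom$size)
  expect_true(all(mom$size[fin] > 0))
  expect_equal(mom$size[fin], mom$mu[fin]^2 / (mom$var[fin] - mom$mu[fin]))

  # z = mu^2 / (var - mu) spot values
  expect_equal(100^2 / (200 - 100), 100)
  expect_equal(10^2 / (110 - 10), 1)
})
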