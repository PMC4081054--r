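# Independent brute-force oracles used to check the HMM, the NNLS
# weighting and BAM counting on tiny instances.

# All 3^n state paths of an n-target chain, their log-scores, the best
# path and the total log-likelihood. Independent of the package's
# forward/Viterbi code: only transition_matrix() (closed-form, itself
# checked against hand substitution) is reused.
enumerate_chain <- function(emissions, distances, params) {
  n <- nrow(emissions)
  logpi <- log(c(params$p, 1 - 2 * params$p, params$p))
  logA <- lapply(seq_along(distances), function(i) {
    log(transition_matrix(distances[i], params))
  })
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  scores <- apply(paths, 1L, function(pp) {
    s <- logpi[pp[1L]] + emissions[1L, pp[1L]]
    for (t in seq_len(n - 1L)) {
      s <- s + logA[[t]][pp[t], pp[t + 1L]] + emissions[t + 1L, pp[t + 1L]]
    }
    s
  })
  m <- max(scores)
  list(paths = paths, scores = scores,
       best_path = paths[which.max(scores), ],
       best_score = m,
       total_loglik = m + log(sum(exp(scores - m))))
}

# Brute-force P(no target in [first, last] occupies `forbidden`)
enumerate_p_none <- function(emissions, distances, params, first, last,
                             forbidden) {
  enum <- enumerate_chain(emissions, distances, params)
  hit <- apply(enum$paths[, first:last, drop = FALSE], 1L,
               function(pp) any(pp == forbidden))
  m <- max(enum$scores)
  p <- exp(enum$scores - m)
  sum(p[!hit]) / sum(p)
}

# Exhaustive active-set NNLS oracle: the optimum's support solves the
# unconstrained LS problem on that support with non-negative coefficients,
# so enumerate all supports and keep the feasible minimum-RSS solution.
nnls_oracle <- function(X, y) {
  p <- ncol(X)
  best <- list(rss = sum(y^2), coef = rep(0, p))  # empty support
  for (sz in 1:p) {
    combs <- utils::combn(p, sz)
    for (ci in seq_len(ncol(combs))) {
      S <- combs[, ci]
      b <- tryCatch(qr.solve(X[, S, drop = FALSE], y),
                    error = function(e) NULL)
      if (is.null(b) || any(b < 0)) next
      rss <- sum((y - X[, S, drop = FALSE] %*% b)^2)
      if (rss < best$rss - 1e-12) {
        coef <- rep(0, p); coef[S] <- b
        best <- list(rss = rss, coef = coef)
      }
    }
  }
  best
}

# Per-read interval-overlap counter (0-based half-open targets,
# 1-based inclusive read spans)
overlap_count_oracle <- function(read_start1, read_end1, targets) {
  vapply(seq_len(nrow(targets)), function(i) {
    sum(read_start1 <= targets$end[i] & read_end1 >= targets$start[i] + 1L)
  }, integer(1))
}

random_chain <- function(n, seed_emissions_sd = 3) {
  em <- matrix(stats::rnorm(n * 3, sd = seed_emissions_sd), n, 3)
  em <- em - apply(em, 1L, max)  # keep log-densities <= 0
  d <- stats::runif(n - 1, 0, 2e5)
  list(emissions = em, distances = d)
}

# Small deterministic cohort used across tests; spiking optional.
tiny_cohort <- function(n_samples = 20, n_targets = 300, seed = 42, ...) {
  simulate_cohort(n_samples = n_samples, n_targets = n_targets,
                  seed = seed, ...)
}

quiet_fit <- function(counts, targets, ...) {
  suppressWarnings(suppressMessages(
    nbcnv(counts, targets,
          config = nbcnv_config(min_targets_trend = 100, ...))))
}
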