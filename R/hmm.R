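# Three-state HMM over exome targets: states DEL (copy 1), DIP (copy 2),
# DUP (copy 3), in that index order throughout.

STATE_NAMES <- c("DEL", "DIP", "DUP")
STATE_COPY <- c(DEL = 1, DIP = 2, DUP = 3)

#' HMM transition parameters
#'
#' @param p Average rate of CNV occurrence per target (default `1e-8`).
#' @param T Expected number of targets in a CNV (default 6).
#' @param D Expected distance in bases between consecutive targets within a
#'   CNV (default 70000); transitions relax toward the stationary diploid
#'   row as inter-target distance grows on this scale.
#' @return Object of class `nbcnv_hmm_params`.
#' @export
hmm_params <- function(p = 1e-8, T = 6, D = 70000) {
  stopifnot(p > 0, p < 0.5, T > 1, D > 0)
  structure(list(p = p, T = T, D = D), class = "nbcnv_hmm_params")
}

#' @export
print.nbcnv_hmm_params <- function(x, ...) {
  cat("HMM parameters: p =", x$p, ", T =", x$T, ", D =", x$D, "bases\n")
  invisible(x)
}

#' Negative binomial emission log-likelihood for a copy-number state
#'
#' Under copy number `c` the diploid NB mean and size are both scaled by
#' `c/2`: states DEL/DIP/DUP use multipliers 1/2, 1 and 3/2. Targets
#' flagged with infinite size use the Poisson limit. Means of zero are
#' lifted to a small epsilon so log-likelihoods stay finite.
#'
#' @param k Observed read count(s), non-negative integers.
#' @param state `"DEL"`, `"DIP"` or `"DUP"` (or copy multiplier index
#'   1, 2, 3).
#' @param mu,size Diploid NB mean and size per target (`size = Inf` selects
#'   the Poisson model).
#' @param eps_mu Floor applied to scaled means (default `1e-3`).
#' @return Log-density vector, one entry per target.
#' @export
emission_loglik <- function(k, state, mu, size, eps_mu = 1e-3) {
  if (any(k < 0)) stop("negative read count")
  cc <- if (is.character(state)) STATE_COPY[[state]] else as.numeric(state)
  m <- pmax(cc * mu / 2, eps_mu)
  z <- cc * size / 2
  out <- numeric(length(k))
  pois <- !is.finite(z)
  if (any(pois)) {
    out[pois] <- stats::dpois(k[pois], lambda = m[pois], log = TRUE)
  }
  if (any(!pois)) {
    out[!pois] <- stats::dnbinom(k[!pois], mu = m[!pois], size = z[!pois],
                                 log = TRUE)
  }
  out
}

#' @keywords internal
emission_matrix <- function(k, mu, size, eps_mu = 1e-3) {
  e <- vapply(1:3, function(s) emission_loglik(k, s, mu, size, eps_mu),
              numeric(length(k)))
  e <- matrix(e, ncol = 3L,
              dimnames = list(NULL, STATE_NAMES))
  if (any(!is.finite(e))) {
    bad <- which(rowSums(!is.finite(e)) > 0)[1L]
    stop("non-finite emission log-likelihood at target ", bad)
  }
  e
}

#' Distance-attenuated transition matrix
#'
#' With `f = exp(-d / D)` and `q = 1 / T`, a CNV state persists with
#' probability `f * (1 - q)` and otherwise relaxes toward the stationary
#' diploid-centred row `(p, 1 - 2p, p)`:
#' \itemize{
#'   \item DIP row: `(p, 1 - 2p, p)` regardless of distance;
#'   \item DEL row: `(f(1-q) + (1-f)p, f q + (1-f)(1-2p), (1-f)p)`;
#'   \item DUP row: mirror image of the DEL row.
#' }
#' Rows sum to 1 for every `d >= 0`; as `d -> Inf` every row tends to the
#' stationary row.
#'
#' @param d Distance in bases between consecutive targets
#'   (`start[i+1] - end[i]`, floored at 0).
#' @param params [hmm_params()].
#' @return 3x3 row-stochastic matrix in DEL, DIP, DUP order.
#' @export
transition_matrix <- function(d, params = hmm_params()) {
  stopifnot(d >= 0)
  p <- params$p
  q <- 1 / params$T
  f <- exp(-d / params$D)
  dip <- c(p, 1 - 2 * p, p)
  del <- c(f * (1 - q) + (1 - f) * p,
           f * q + (1 - f) * (1 - 2 * p),
           (1 - f) * p)
  dup <- rev(del)
  matrix(c(del, dip, dup), nrow = 3L, byrow = TRUE,
         dimnames = list(STATE_NAMES, STATE_NAMES))
}

#' @keywords internal
log_transition_array <- function(distances, params) {
  n <- length(distances)
  arr <- array(NA_real_, dim = c(3L, 3L, n))
  for (i in seq_len(n)) arr[, , i] <- log(transition_matrix(distances[i], params))
  arr
}

#' @keywords internal
log_initial <- function(params) {
  log(c(params$p, 1 - 2 * params$p, params$p))
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Inter-target distances within a chromosome block
#'
#' @keywords internal
target_distances <- function(targets, idx) {
  if (length(idx) < 2L) return(numeric(0))
  pmax(targets$start[idx[-1L]] - targets$end[idx[-length(idx)]], 0)
}

#' Most probable copy-state path (Viterbi)
#'
#' Dynamic-programming maximum a posteriori path under the initial
#' distribution `(p, 1-2p, p)` and the distance-attenuated transition
#' model. Ties are broken deterministically toward DIP, then DEL, then
#' DUP. Chromosomes must be processed independently (pass one chromosome's
#' emissions at a time).
#'
#' @param emissions Matrix (targets x 3) of emission log-likelihoods in
#'   DEL, DIP, DUP column order.
#' @param distances Inter-target distances, length `nrow(emissions) - 1`.
#' @param params [hmm_params()].
#' @return Integer vector of states (1 = DEL, 2 = DIP, 3 = DUP).
#' @export
viterbi_path <- function(emissions, distances, params = hmm_params()) {
  n <- nrow(emissions)
  stopifnot(n >= 1L, ncol(emissions) == 3L, length(distances) == n - 1L)
  if (any(!is.finite(emissions))) {
    stop("non-finite emission at target ",
         which(rowSums(!is.finite(emissions)) > 0)[1L])
  }
  pref <- c(2L, 1L, 3L)  # tie-break preference: DIP, DEL, DUP
  logA <- log_transition_array(distances, params)
  delta <- matrix(-Inf, n, 3L)
  back <- matrix(0L, n, 3L)
  delta[1L, ] <- log_initial(params) + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      A <- logA[, , t - 1L]
      for (j in 1:3) {
        cand <- delta[t - 1L, ] + A[, j]
        best <- pref[which.max(cand[pref])]
        back[t, j] <- best
        delta[t, j] <- cand[best] + emissions[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- pref[which.max(delta[n, pref])]
  if (n > 1L) {
    for (t in (n - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  }
  path
}

#' Forward-backward posteriors and total log-likelihood
#'
#' @inheritParams viterbi_path
#' @return List with `posterior` (targets x 3 matrix of state
#'   probabilities, rows summing to 1) and `loglik` (log of the sum over
#'   all state paths).
#' @export
forward_backward <- function(emissions, distances, params = hmm_params()) {
  n <- nrow(emissions)
  stopifnot(n >= 1L, ncol(emissions) == 3L, length(distances) == n - 1L)
  if (any(!is.finite(emissions))) {
    stop("non-finite emission at target ",
         which(rowSums(!is.finite(emissions)) > 0)[1L])
  }
  logA <- log_transition_array(distances, params)
  alpha <- matrix(-Inf, n, 3L)
  beta <- matrix(0, n, 3L)
  alpha[1L, ] <- log_initial(params) + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      A <- logA[, , t - 1L]
      for (j in 1:3) {
        alpha[t, j] <- logsumexp(alpha[t - 1L, ] + A[, j]) + emissions[t, j]
      }
    }
    for (t in (n - 1L):1L) {
      A <- logA[, , t]
      for (i in 1:3) {
        beta[t, i] <- logsumexp(A[i, ] + emissions[t + 1L, ] + beta[t + 1L, ])
      }
    }
  }
  ll <- logsumexp(alpha[n, ])
  post <- exp(alpha + beta - ll)
  post <- post / rowSums(post)
  colnames(post) <- STATE_NAMES
  list(posterior = post, loglik = ll)
}

#' Forward log-likelihood with one state forbidden inside a region
#'
#' Runs the forward recursion zeroing (in probability space) the given
#' state at every target inside `[first, last]`; the ratio of this
#' restricted likelihood to the unrestricted one is the probability that
#' no target in the region occupies that state.
#'
#' @keywords internal
restricted_loglik <- function(emissions, distances, params, first, last,
                              forbidden) {
  n <- nrow(emissions)
  stopifnot(first >= 1L, last <= n, first <= last)
  logA <- log_transition_array(distances, params)
  alpha <- log_initial(params) + emissions[1L, ]
  if (first == 1L) alpha[forbidden] <- -Inf
  if (n > 1L) {
    for (t in 2:n) {
      A <- logA[, , t - 1L]
      nxt <- vapply(1:3, function(j) logsumexp(alpha + A[, j]), 0)
      nxt <- nxt + emissions[t, ]
      if (t >= first && t <= last) nxt[forbidden] <- -Inf
      alpha <- nxt
    }
  }
  logsumexp(alpha)
}

#' Segment a state path into CNV calls
#'
#' Maximal runs of consecutive non-diploid targets in the same state (and
#' on the same chromosome) become calls; a run is split at a chromosome
#' boundary. Quality scores and copy numbers are not attached here.
#'
#' @param path Integer state path (1 = DEL, 2 = DIP, 3 = DUP), one entry
#'   per target.
#' @param targets Target table aligned with `path`.
#' @param sample Sample id recorded on each call.
#' @return `data.frame` with one row per call: `sample`, `type`, `chrom`,
#'   `start`, `end` (0-based half-open genomic span), `first_target`,
#'   `last_target` (row indices into `targets`), `n_targets`.
#' @export
segment_path <- function(path, targets, sample) {
  stopifnot(length(path) == nrow(targets))
  n <- length(path)
  if (n == 0L) return(empty_calls())
  newrun <- c(TRUE, path[-1L] != path[-n] |
                targets$chrom[-1L] != targets$chrom[-n])
  run_id <- cumsum(newrun)
  firsts <- which(newrun)
  lasts <- c(firsts[-1L] - 1L, n)
  st <- path[firsts]
  keep <- st != 2L
  if (!any(keep)) return(empty_calls())
  firsts <- firsts[keep]; lasts <- lasts[keep]; st <- st[keep]
  data.frame(
    sample = sample,
    type = STATE_NAMES[st],
    chrom = targets$chrom[firsts],
    start = targets$start[firsts],
    end = targets$end[lasts],
    first_target = firsts,
    last_target = lasts,
    n_targets = lasts - firsts + 1L,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
empty_calls <- function() {
  data.frame(sample = character(), type = character(), chrom = character(),
             start = integer(), end = integer(), first_target = integer(),
             last_target = integer(), n_targets = integer(),
             stringsAsFactors = FALSE)
}
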