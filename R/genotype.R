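#' Phred-scaled interval qualities (SQ / NQ) for a region
#'
#' For a candidate event of a given type (DEL or DUP) spanning a run of
#' targets, the probability that the sample carries *no* target in that
#' state anywhere in the region is the ratio of a restricted chain
#' likelihood (forward pass with the state zeroed inside the region) to
#' the unrestricted likelihood, both computed over the region's whole
#' chromosome. Then
#' \deqn{SQ = -10 \log_{10} P_{none}, \quad NQ = -10 \log_{10}(1 - P_{none})}
#' so that before capping `10^(-SQ/10) + 10^(-NQ/10) = 1`. A high SQ is
#' evidence that some target in the region carries the event; a high NQ is
#' evidence that none does. Both scores are capped (default 99).
#'
#' @param moments `nbcnv_moments` for the sample (see [estimate_moments()]).
#' @param counts Integer vector of the sample's read counts, aligned with
#'   `targets`.
#' @param targets Target table.
#' @param region Length-2 integer vector `(first_target, last_target)`,
#'   row indices into `targets`; must lie on one chromosome.
#' @param type `"DEL"` or `"DUP"`.
#' @param params [hmm_params()].
#' @param cap Phred cap (default 99).
#' @return List with `SQ`, `NQ`, `p_none`, plus the region descriptors.
#' @export
interval_qualities <- function(moments, counts, targets, region,
                               type = c("DEL", "DUP"),
                               params = hmm_params(), cap = 99) {
  type <- match.arg(type)
  first <- as.integer(region[1L]); last <- as.integer(region[2L])
  if (is.na(first) || is.na(last) || first > last || first < 1L ||
      last > nrow(targets)) {
    stop("invalid or empty region")
  }
  chrom <- targets$chrom[first]
  if (!all(targets$chrom[first:last] == chrom)) {
    stop("region spans more than one chromosome")
  }
  idx <- which(targets$chrom == chrom)
  em <- emission_matrix(counts[idx], moments$mu[idx], moments$size[idx])
  dists <- target_distances(targets, idx)
  lf <- match(first, idx); ll <- match(last, idx)
  total <- forward_backward(em, dists, params)$loglik
  forbidden <- match(type, STATE_NAMES)
  restr <- restricted_loglik(em, dists, params, lf, ll, forbidden)
  scores <- phred_pair(restr - total, cap)
  c(list(sample = moments$sample, chrom = chrom, first_target = first,
         last_target = last, type = type), scores)
}

# delta = log P_none (<= 0 up to rounding); returns capped SQ/NQ
#' @keywords internal
phred_pair <- function(delta, cap = 99) {
  delta <- min(delta, 0)
  p_none <- exp(delta)
  sq <- -10 * delta / log(10)
  p_some <- -expm1(delta)
  nq <- if (p_some <= 0) Inf else -10 * log10(p_some)
  list(SQ = min(sq, cap), NQ = min(nq, cap), p_none = p_none)
}

#' Integer copy number for a CNV call
#'
#' Candidate copy numbers are 0 and 1 for deletions and 3, 4, 5 and 6 for
#' duplications. For copies `c >= 1` the log-likelihood over the call's
#' targets is the NB log-pmf with mean and size both scaled by `c/2`; the
#' homozygous-deletion state (`c = 0`) instead uses a flat Poisson
#' background with mean `lambda0` per target (default 0.2, the residual
#' read level observed at truly zero-copy loci; platform-specific).
#' Because homozygous deletions and multi-copy duplications are rare, a
#' non-baseline candidate (0, 4, 5 or 6) is chosen over the single-copy
#' event (1 or 3) only if its likelihood ratio exceeds `lr_threshold`
#' (default 1000). Copy 2 is never a candidate for a made call.
#'
#' @param call One-row call `data.frame` (see [segment_path()]) with
#'   `type`, `first_target`, `last_target`.
#' @param counts Integer vector of the sample's read counts.
#' @param moments `nbcnv_moments` for the sample.
#' @param lambda0 Poisson mean for the zero-copy state (default 0.2).
#' @param lr_threshold Likelihood-ratio threshold for non-baseline copy
#'   numbers (default 1000).
#' @return Object of class `nbcnv_copynumber`: list with `copy_number`,
#'   `loglik` (named vector over candidates) and `lr_vs_baseline`.
#' @export
copy_number_estimate <- function(call, counts, moments, lambda0 = 0.2,
                                 lr_threshold = 1000) {
  stopifnot(nrow(call) == 1L, call$type %in% c("DEL", "DUP"))
  idx <- call$first_target:call$last_target
  k <- counts[idx]
  mu <- moments$mu[idx]
  size <- moments$size[idx]
  ll_copy <- function(cc) {
    if (cc == 0) return(sum(stats::dpois(k, lambda = lambda0, log = TRUE)))
    m <- pmax(cc * mu / 2, 1e-3)
    z <- cc * size / 2
    pois <- !is.finite(z)
    sum(ifelse(pois,
               stats::dpois(k, lambda = m, log = TRUE),
               stats::dnbinom(k, mu = m, size = ifelse(pois, 1, z),
                              log = TRUE)))
  }
  if (call$type == "DEL") {
    cands <- c(0, 1); baseline <- 1
  } else {
    cands <- c(3, 4, 5, 6); baseline <- 3
  }
  ll <- vapply(cands, ll_copy, 0)
  names(ll) <- as.character(cands)
  base_ll <- ll[[as.character(baseline)]]
  alt <- cands[cands != baseline]
  chosen <- baseline
  if (length(alt) > 0L) {
    alt_ll <- ll[as.character(alt)]
    best <- alt[which.max(alt_ll)]
    if (max(alt_ll) - base_ll > log(lr_threshold)) chosen <- best
  }
  structure(
    list(copy_number = as.integer(chosen), loglik = ll,
         lr_vs_baseline = exp(ll - base_ll), baseline = baseline),
    class = "nbcnv_copynumber"
  )
}

#' @export
print.nbcnv_copynumber <- function(x, ...) {
  cat("Copy number:", x$copy_number, "(baseline", x$baseline, ")\n")
  print(round(x$loglik, 2))
  invisible(x)
}
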