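#' Normalize reference samples to a test sample's aggregate read count
#'
#' Scales each reference column so that its total read count (over all
#' targets) equals that of the test sample `sample`. The test sample's own
#' column is left unchanged. Reference samples with zero total count carry
#' no usable information and are dropped with a warning.
#'
#' @param counts Integer count matrix (targets x samples), sample ids as
#'   column names.
#' @param sample Column name of the test sample.
#' @return Real-valued matrix with the same shape (minus any dropped
#'   zero-total references); every column sums to the test sample's total.
#' @export
normalize_to_sample <- function(counts, sample) {
  validate_counts(counts)
  if (!sample %in% colnames(counts)) stop("unknown sample: ", sample)
  totals <- colSums(counts)
  if (totals[sample] <= 0) stop("test sample ", sample, " has zero total count")
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0L) {
    warning("dropping zero-total reference sample(s): ",
            paste(zero, collapse = ", "))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  sweep(counts, 2L, totals[sample] / totals, `*`)
}

#' Non-negative least squares weights for reference samples
#'
#' Regresses the test sample's read-count vector on the (aggregate-count
#' normalized) reference samples' vectors with non-negative least squares.
#' Because all columns share the test sample's aggregate count the
#' coefficients approximately sum to 1 already; they are renormalized to
#' sum to exactly 1. The effective number of references is `1 / sum(w^2)`.
#'
#' @param normalized Normalized matrix from [normalize_to_sample()].
#' @param sample Column name of the test sample (excluded from its own
#'   reference set).
#' @return An object of class `nbcnv_weights`: list with `sample`,
#'   `weights` (named, non-negative, summing to 1) and `effective_n`.
#' @export
nnls_weights <- function(normalized, sample) {
  if (!sample %in% colnames(normalized)) stop("unknown sample: ", sample)
  refs <- setdiff(colnames(normalized), sample)
  if (length(refs) < 2L) {
    stop("need at least 2 reference samples, have ", length(refs))
  }
  y <- normalized[, sample]
  X <- normalized[, refs, drop = FALSE]
  w <- nnls_lawson_hanson(crossprod(X), crossprod(X, y))
  s <- sum(w)
  if (s <= 0) {
    warning("degenerate NNLS solution (all-zero weights) for ", sample,
            "; falling back to uniform weights")
    w <- rep(1 / length(refs), length(refs))
  } else {
    if (abs(s - 1) > 0.05) {
      message("NNLS weight sum for ", sample, " was ",
              format(s, digits = 4), "; renormalizing to 1")
    }
    w <- w / s
  }
  names(w) <- refs
  structure(
    list(sample = sample, weights = w, effective_n = 1 / sum(w^2)),
    class = "nbcnv_weights"
  )
}

# Lawson-Hanson active-set NNLS on the normal equations. Operating on the
# p x p Gram matrix instead of the tall design makes each iteration O(p^2)
# and the whole solve independent of the number of targets; the solution
# is the same as lsqnonneg's up to solver tie-breaking among collinear
# columns (only the fitted vector is contract-tested).
#' @keywords internal
nnls_lawson_hanson <- function(XtX, Xty, tol = NULL, max_iter = NULL) {
  p <- length(Xty)
  if (is.null(tol)) tol <- 1e-10 * max(abs(Xty))
  if (is.null(max_iter)) max_iter <- 10L * p
  w <- numeric(p)
  passive <- logical(p)
  banned <- logical(p)  # columns that made no numerical progress
  grad <- Xty
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive & !banned & grad > tol)
    if (length(cand) == 0L) break
    entering <- cand[which.max(grad[cand])]
    passive[entering] <- TRUE
    repeat {
      P <- which(passive)
      if (length(P) == 0L) {  # entering column was degenerate
        banned[entering] <- TRUE
        break
      }
      s <- numeric(p)
      sol <- tryCatch(
        solve(XtX[P, P, drop = FALSE], Xty[P]),
        error = function(e) NULL)
      if (is.null(sol)) {  # rank deficiency: ridge-regularized fallback
        sol <- solve(XtX[P, P, drop = FALSE] +
                       diag(1e-10 * mean(diag(XtX)[P]), length(P)),
                     Xty[P])
      }
      s[P] <- sol
      if (all(s[P] > 0)) {
        w <- s
        break
      }
      neg <- P[s[P] <= 0]
      alpha <- min(w[neg] / (w[neg] - s[neg]))
      w <- w + alpha * (s - w)
      # drop columns driven (numerically) to zero; tol here is a weight
      # scale, not the gradient scale
      passive[P[w[P] <= 1e-12 * max(w)]] <- FALSE
      w[!passive] <- 0
    }
    grad <- Xty - XtX %*% w
  }
  w
}

#' @export
print.nbcnv_weights <- function(x, ...) {
  cat("Reference weights for sample", x$sample, "\n")
  cat("  references:", length(x$weights),
      " effective n:", format(x$effective_n, digits = 4), "\n")
  nz <- sort(x$weights[x$weights > 1e-6], decreasing = TRUE)
  cat("  top weights:\n")
  print(utils::head(round(nz, 4)))
  invisible(x)
}

#' Weighted mean and reliability-weighted unbiased variance
#'
#' For normalized weights `w` (summing to 1), the mean is `sum(w * x)` and
#' the variance is `sum(w * (x - mu)^2) / (1 - sum(w^2))`, the unbiased
#' estimator under reliability weights. With equal weights both reduce to
#' the classical unbiased estimators. When `sum(w^2)` approaches 1 a single
#' sample carries all the weight and the variance is undefined (`NA`);
#' downstream the variance floor alone is used in that case.
#'
#' @param x Numeric vector of (normalized) reference counts at one target,
#'   or a matrix with one row per target and one column per reference.
#' @param w Weights aligned with `x` (or with the columns of `x`).
#' @param eps Degeneracy guard: variance is `NA` when `sum(w^2) >= 1 - eps`.
#' @return For vector `x`, `c(mean, var)`; for matrix `x`, a list with
#'   vectors `mean` and `var`.
#' @export
weighted_moments <- function(x, w, eps = 1e-8) {
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  sw2 <- sum(w^2)
  denom <- 1 - sw2
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(w))
    mu <- drop(x %*% w)
    if (denom < eps) return(list(mean = mu, var = rep(NA_real_, nrow(x))))
    v <- drop(((x - mu)^2) %*% w) / denom
    return(list(mean = mu, var = v))
  }
  stopifnot(length(x) == length(w))
  mu <- sum(w * x)
  v <- if (denom < eps) NA_real_ else sum(w * (x - mu)^2) / denom
  c(mean = mu, var = v)
}

#' Fit the variance-vs-(mean, GC) trend across targets
#'
#' The across-reference variance of read count grows curvilinearly with
#' mean depth and rises at both GC extremes. The trend is captured with an
#' additive penalized-spline model (via \pkg{mgcv}) fitted on
#' `log(variance + 1)` against `log(mean + 1)` and the GC fraction, then
#' back-transformed for prediction. Predictions serve as a floor on
#' per-target variance estimates, pooling information across targets of
#' similar depth and GC.
#'
#' @param mu Per-target mean read counts.
#' @param gc Per-target GC fractions (`NA`s are imputed with the median).
#' @param raw_var Per-target raw weighted variances (may contain `NA`).
#' @param k Basis dimension per smooth term (default 10).
#' @param min_targets Minimum number of targets with defined variance
#'   (default 200).
#' @return An object of class `nbcnv_vartrend` with a `predict()` method
#'   mapping (mu, gc) to a positive predicted variance.
#' @export
fit_variance_trend <- function(mu, gc, raw_var, k = 10, min_targets = 200) {
  ok <- is.finite(mu) & is.finite(raw_var)
  if (sum(ok) < min_targets) {
    stop("only ", sum(ok), " targets with defined variance; at least ",
         min_targets, " are required -- use a larger cohort or target set")
  }
  gc_med <- stats::median(gc[is.finite(gc)], na.rm = TRUE)
  if (!is.finite(gc_med)) gc_med <- 0.5
  gc_filled <- ifelse(is.finite(gc), gc, gc_med)
  idx <- which(ok)
  # a 2-term smooth needs a few thousand points at most; thin large
  # target sets deterministically (evenly spaced) to bound the fit cost
  if (length(idx) > 5000L) {
    idx <- idx[unique(round(seq(1L, length(idx), length.out = 5000L)))]
  }
  dat <- data.frame(lv = log(raw_var[idx] + 1),
                    lm = log(mu[idx] + 1),
                    gc = gc_filled[idx])
  # penalized splines; k is capped by the number of unique covariate values
  k_lm <- min(k, max(3L, length(unique(dat$lm)) - 1L))
  k_gc <- min(k, max(3L, length(unique(dat$gc)) - 1L))
  fit <- mgcv::gam(lv ~ s(lm, k = k_lm) + s(gc, k = k_gc), data = dat)
  structure(
    list(fit = fit, gc_median = gc_med,
         df = sum(fit$edf), sigma = sqrt(fit$sig2),
         range_lm = range(dat$lm), range_gc = range(dat$gc)),
    class = "nbcnv_vartrend"
  )
}

#' @param object An `nbcnv_vartrend` model.
#' @param mu,gc Vectors of means and GC fractions to predict at.
#' @param ... Unused.
#' @rdname fit_variance_trend
#' @export
predict.nbcnv_vartrend <- function(object, mu, gc, ...) {
  gc_filled <- ifelse(is.finite(gc), gc, object$gc_median)
  nd <- data.frame(lm = log(pmax(mu, 0) + 1), gc = gc_filled)
  # clamp to the training hull so extrapolation cannot run away
  nd$lm <- pmin(pmax(nd$lm, object$range_lm[1]), object$range_lm[2])
  nd$gc <- pmin(pmax(nd$gc, object$range_gc[1]), object$range_gc[2])
  pred <- exp(as.numeric(mgcv::predict.gam(object$fit, newdata = nd))) - 1
  pmax(pred, .Machine$double.eps)
}

#' @export
print.nbcnv_vartrend <- function(x, ...) {
  cat("Variance trend fit: log(var+1) ~ s(log(mean+1)) + s(gc)\n")
  cat("  effective df:", format(x$df, digits = 4),
      " residual sd (log scale):", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Final per-target variance with Poisson and smooth-trend floors
#'
#' The variance used downstream is the highest of the raw weighted
#' variance, the mean (Poisson floor) and the smooth-trend prediction.
#' Where the raw variance is undefined the floor alone applies.
#'
#' @param raw_var Raw weighted variance (may be `NA`).
#' @param mu Mean read count.
#' @param smooth_var Predicted variance from the trend fit.
#' @return Floored variance, `pmax(raw_var, mu, smooth_var)`.
#' @export
final_variance <- function(raw_var, mu, smooth_var) {
  raw <- ifelse(is.finite(raw_var), raw_var, -Inf)
  pmax(raw, mu, smooth_var)
}

#' Negative binomial moment estimates for one test sample
#'
#' Composes the reference model for a single test sample: aggregate-count
#' normalization of the references, NNLS reference weighting, per-target
#' weighted mean and variance, the smooth variance floor, and conversion to
#' the NB size parameter `z = mu^2 / (var - mu)`. Targets whose floored
#' variance equals the mean are flagged with `size = Inf` (the Poisson
#' limit); downstream emissions then use a Poisson model.
#'
#' @param counts Integer count matrix (targets x samples).
#' @param targets Target table aligned with `counts`; the `gc` column feeds
#'   the variance-trend fit (missing values are imputed with the median).
#' @param sample Column name of the test sample.
#' @param exclude_self Exclude the test sample from its own reference set
#'   (default `TRUE`; including it would leak the signal being tested).
#' @param exclude_refs Further samples to drop from this sample's
#'   reference panel (e.g. first-degree relatives, who share the very
#'   CNVs being tested about half the time and would otherwise
#'   contaminate the variance estimate at event regions).
#' @param min_targets_trend Minimum targets required for the trend fit.
#' @return Object of class `nbcnv_moments`: list with `sample`, per-target
#'   vectors `mu`, `var`, `smooth_var`, `size`, the `weights`
#'   (`nbcnv_weights`) and the `trend` (`nbcnv_vartrend`).
#' @export
estimate_moments <- function(counts, targets, sample, exclude_self = TRUE,
                             exclude_refs = NULL,
                             min_targets_trend = 200) {
  validate_counts(counts, targets)
  if (!is.null(exclude_refs)) {
    drop <- setdiff(intersect(exclude_refs, colnames(counts)), sample)
    if (length(drop)) counts <- counts[, setdiff(colnames(counts), drop),
                                       drop = FALSE]
  }
  norm <- normalize_to_sample(counts, sample)
  if (!exclude_self) {
    # keep self in the regression design by aliasing it under a shadow name
    shadow <- paste0(".self.", sample)
    norm2 <- cbind(norm, stats::setNames(data.frame(norm[, sample]), shadow))
    norm <- as.matrix(norm2)
  }
  w <- nnls_weights(norm, sample)
  refs <- names(w$weights)
  mom <- weighted_moments(norm[, refs, drop = FALSE], w$weights)
  trend <- fit_variance_trend(mom$mean, targets$gc, mom$var,
                              min_targets = min_targets_trend)
  s2 <- predict(trend, mom$mean, targets$gc)
  v <- final_variance(mom$var, mom$mean, s2)
  size <- ifelse(v > mom$mean, mom$mean^2 / (v - mom$mean), Inf)
  structure(
    list(sample = sample, mu = mom$mean, raw_var = mom$var, var = v,
         smooth_var = s2, size = size, weights = w, trend = trend),
    class = "nbcnv_moments"
  )
}

#' @export
print.nbcnv_moments <- function(x, ...) {
  cat("NB moment estimates for sample", x$sample, "over", length(x$mu),
      "targets\n")
  cat("  mean depth:", format(mean(x$mu), digits = 4),
      " median var/mean:",
      format(stats::median(x$var / pmax(x$mu, 1e-9)), digits = 4), "\n")
  cat("  effective reference n:",
      format(x$weights$effective_n, digits = 4), "\n")
  invisible(x)
}
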