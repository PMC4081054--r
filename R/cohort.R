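#' Configuration for a cohort CNV-calling run
#'
#' @param params HMM transition parameters, see [hmm_params()].
#' @param n_max Per-sample call-count filter: a sample with more than
#'   `n_max` calls has all its calls excluded (default 50).
#' @param lambda0 Poisson mean of the zero-copy background (default 0.2).
#' @param lr_threshold Likelihood-ratio threshold for copy numbers 0, 4,
#'   5, 6 (default 1000).
#' @param phred_cap Cap on SQ/NQ scores (default 99).
#' @param sq_threshold Minimum SQ for a call to be reported (default 0,
#'   i.e. report everything).
#' @param exclude_self Exclude each sample from its own reference set
#'   (default `TRUE`).
#' @param include_sex_chrom Keep targets on X/Y chromosomes (default
#'   `FALSE`; mixed-sex cohorts violate the diploid baseline there, so
#'   autosomes only unless the caller opts in).
#' @param min_targets_trend Minimum targets for the variance-trend fit.
#' @return Object of class `nbcnv_config`.
#' @export
nbcnv_config <- function(params = hmm_params(), n_max = 50, lambda0 = 0.2,
                         lr_threshold = 1000, phred_cap = 99,
                         sq_threshold = 0, exclude_self = TRUE,
                         include_sex_chrom = FALSE,
                         min_targets_trend = 200) {
  stopifnot(inherits(params, "nbcnv_hmm_params"), n_max >= 1,
            lambda0 > 0, lr_threshold >= 0, phred_cap > 0,
            sq_threshold >= 0)
  structure(
    list(params = params, n_max = n_max, lambda0 = lambda0,
         lr_threshold = lr_threshold, phred_cap = phred_cap,
         sq_threshold = sq_threshold, exclude_self = exclude_self,
         include_sex_chrom = include_sex_chrom,
         min_targets_trend = min_targets_trend),
    class = "nbcnv_config"
  )
}

#' @export
print.nbcnv_config <- function(x, ...) {
  cat("nbcnv configuration\n")
  print(x$params)
  cat("  N_max =", x$n_max, " lambda0 =", x$lambda0,
      " LR threshold =", x$lr_threshold, "\n")
  cat("  Phred cap =", x$phred_cap, " SQ reporting threshold =",
      x$sq_threshold, "\n")
  invisible(x)
}

#' @keywords internal
is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

#' Call rare CNVs across a cohort of exome samples
#'
#' The main fitting function. For every sample in the count matrix it
#' estimates per-target negative binomial moments from NNLS-weighted
#' reference samples ([estimate_moments()]), segments the targets with the
#' three-state HMM ([viterbi_path()]), scores each resulting call with
#' Phred-scaled SQ/NQ interval qualities ([interval_qualities()]) and an
#' integer copy number ([copy_number_estimate()]), and finally removes all
#' calls from samples exceeding the `n_max` call-count filter
#' ([filter_noisy_samples()]). The run is deterministic given its inputs
#' and configuration.
#'
#' @param counts Integer count matrix (targets x samples) with unique
#'   sample ids as column names.
#' @param targets Target table aligned with `counts` (see
#'   [read_targets()]); a `gc` column improves the variance floor.
#' @param config [nbcnv_config()].
#' @param samples Samples to call (default: all). References are drawn
#'   from the full cohort minus any per-sample exclusions.
#' @param exclude_references Optional named list mapping a sample id to
#'   the sample ids to drop from its reference panel. Family members
#'   share rare CNVs about half the time, so leaving them in a relative's
#'   panel inflates the variance estimate exactly at event regions; for
#'   trio cohorts pass [pedigree_exclusions()].
#' @param verbose Emit per-sample progress messages.
#' @return Object of class `nbcnv`; see [calls()], [summary.nbcnv()],
#'   [plot.nbcnv()], [coef.nbcnv()], [residuals.nbcnv()].
#' @examples
#' sim <- simulate_cohort(n_samples = 20, n_targets = 300, seed = 7)
#' fit <- nbcnv(sim$counts, sim$targets,
#'              config = nbcnv_config(min_targets_trend = 100))
#' fit
#' head(calls(fit))
#' @export
nbcnv <- function(counts, targets, config = nbcnv_config(),
                  samples = colnames(counts), exclude_references = NULL,
                  verbose = FALSE) {
  validate_counts(counts, targets)
  validate_targets(targets)
  stopifnot(inherits(config, "nbcnv_config"))
  if (ncol(counts) < 2L) {
    stop("cohort of 1: at least one reference sample is required")
  }
  if (ncol(counts) < 16L) {
    warning("cohort has ", ncol(counts),
            " samples; at least 16 are recommended for stable reference ",
            "weighting")
  }
  if (!config$include_sex_chrom && any(is_sex_chrom(targets$chrom))) {
    keep <- !is_sex_chrom(targets$chrom)
    message("excluding ", sum(!keep), " sex-chromosome target(s); set ",
            "include_sex_chrom = TRUE to keep them")
    targets <- targets[keep, , drop = FALSE]
    rownames(targets) <- NULL
    counts <- counts[keep, , drop = FALSE]
  }
  chroms <- unique(targets$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(targets$chrom == ch))
  names(chrom_idx) <- chroms

  moments <- list()
  emissions <- list()
  all_calls <- list()
  for (j in samples) {
    if (verbose) message("sample ", j)
    mom <- estimate_moments(counts, targets, j,
                            exclude_self = config$exclude_self,
                            exclude_refs = exclude_references[[j]],
                            min_targets_trend = config$min_targets_trend)
    em <- emission_matrix(counts[, j], mom$mu, mom$size)
    path <- integer(nrow(targets))
    for (ch in chroms) {
      idx <- chrom_idx[[ch]]
      path[idx] <- viterbi_path(em[idx, , drop = FALSE],
                                target_distances(targets, idx),
                                config$params)
    }
    segs <- segment_path(path, targets, j)
    if (nrow(segs) > 0L) {
      sq <- nq <- cn <- numeric(nrow(segs))
      for (r in seq_len(nrow(segs))) {
        iq <- interval_qualities(mom, counts[, j], targets,
                                 c(segs$first_target[r],
                                   segs$last_target[r]),
                                 segs$type[r], config$params,
                                 config$phred_cap)
        sq[r] <- iq$SQ; nq[r] <- iq$NQ
        cn[r] <- copy_number_estimate(segs[r, , drop = FALSE], counts[, j],
                                      mom, config$lambda0,
                                      config$lr_threshold)$copy_number
      }
      segs$SQ <- sq; segs$NQ <- nq; segs$copy_number <- as.integer(cn)
      segs <- segs[segs$SQ >= config$sq_threshold, , drop = FALSE]
    } else {
      segs$SQ <- numeric(0); segs$NQ <- numeric(0)
      segs$copy_number <- integer(0)
    }
    mom$trend$fit <- strip_gam(mom$trend$fit)
    moments[[j]] <- mom
    emissions[[j]] <- em
    all_calls[[j]] <- segs
  }
  all_calls <- do.call(rbind, c(all_calls, list(make.row.names = FALSE)))
  flt <- filter_noisy_samples(all_calls, config$n_max)
  structure(
    list(call = match.call(), config = config, targets = targets,
         counts = counts, samples = samples, moments = moments,
         emissions = emissions, chrom_idx = chrom_idx,
         calls = flt$calls, unfiltered_calls = all_calls,
         excluded_samples = flt$excluded, n_calls = flt$n_calls,
         ll_cache = new.env(parent = emptyenv())),
    class = "nbcnv"
  )
}

# drop heavyweight pieces of a gam fit that prediction does not need
#' @keywords internal
strip_gam <- function(fit) {
  for (f in c("y", "residuals", "fitted.values", "weights",
              "prior.weights", "linear.predictors", "hat", "offset")) {
    fit[[f]] <- NULL
  }
  fit$model <- fit$model[0, , drop = FALSE]
  fit
}

#' Exclude samples with excessive call counts
#'
#' Samples whose read-count profile is poorly matched by the available
#' references accumulate large numbers of spurious calls. Any sample with
#' strictly more than `n_max` calls has all of its calls removed and is
#' reported as excluded.
#'
#' @param calls Calls table (see [nbcnv()]).
#' @param n_max Threshold (default 50); a sample with exactly `n_max`
#'   calls is retained.
#' @return List with `calls` (kept rows), `excluded` (character vector of
#'   sample ids) and `n_calls` (named per-sample call counts, pre-filter).
#' @export
filter_noisy_samples <- function(calls, n_max = 50) {
  n_calls <- table(calls$sample)
  excluded <- names(n_calls)[n_calls > n_max]
  kept <- calls[!(calls$sample %in% excluded), , drop = FALSE]
  rownames(kept) <- NULL
  list(calls = kept, excluded = excluded,
       n_calls = stats::setNames(as.integer(n_calls), names(n_calls)))
}

#' Batch-structure diagnostic by multidimensional scaling
#'
#' Samples processed together share systematic read-count biases and form
#' tight clusters. This diagnostic applies classical multidimensional
#' scaling to a dissimilarity derived from the inverse of the
#' sample-by-sample covariance matrix of the count vectors: the inverse
#' covariance is normalized to partial correlations (removing the
#' per-sample precision scale that would otherwise dominate) and the
#' dissimilarity is `1 - |partial correlation|`, symmetrized with a zero
#' diagonal, so samples sharing a batch embed close together. Samples
#' whose maximum pairwise correlation with any other sample is low are
#' poor candidates for reference-based calling and are worth inspecting
#' before a run.
#'
#' @param counts Integer count matrix (targets x samples), at least 3
#'   samples.
#' @return List with `points` (samples x 2 coordinate matrix) and
#'   `max_correlation` (per sample, the largest Pearson correlation with
#'   any other sample).
#' @export
mds_batches <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) < 3L) stop("need at least 3 samples")
  S <- stats::cov(counts)
  inv <- tryCatch(solve(S), error = function(e) {
    warning("sample covariance is singular; using the pseudo-inverse")
    MASS::ginv(S)
  })
  pcor <- -stats::cov2cor(inv)
  M <- 1 - abs(pcor)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M[M < 0] <- 0
  pts <- stats::cmdscale(stats::as.dist(M), k = 2)
  colnames(pts) <- c("dim1", "dim2")
  cors <- stats::cor(counts)
  diag(cors) <- NA
  list(points = pts,
       max_correlation = apply(cors, 2L, max, na.rm = TRUE))
}

#' Extract the filtered calls table from a fit
#'
#' @param fit An `nbcnv` object.
#' @return `data.frame` of calls: `sample`, `type`, `chrom`, `start`,
#'   `end` (0-based half-open), `first_target`, `last_target`,
#'   `n_targets`, `SQ`, `NQ`, `copy_number`.
#' @export
calls <- function(fit) {
  stopifnot(inherits(fit, "nbcnv"))
  fit$calls
}

#' @export
print.nbcnv <- function(x, ...) {
  cat("Cohort CNV calls (negative binomial HMM)\n")
  cat("  samples:", length(x$samples), "  targets:", nrow(x$targets), "\n")
  cat("  calls:", nrow(x$calls),
      sprintf("(%d DEL, %d DUP)", sum(x$calls$type == "DEL"),
              sum(x$calls$type == "DUP")), "\n")
  if (length(x$excluded_samples) > 0L) {
    cat("  excluded (>", x$config$n_max, "calls):",
        paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.nbcnv <- function(object, ...) {
  cl <- object$calls
  per_sample <- stats::setNames(integer(length(object$samples)),
                                object$samples)
  tb <- table(cl$sample)
  per_sample[names(tb)] <- as.integer(tb)
  structure(
    list(n_samples = length(object$samples),
         n_targets = nrow(object$targets),
         n_calls = nrow(cl),
         n_del = sum(cl$type == "DEL"),
         n_dup = sum(cl$type == "DUP"),
         per_sample = per_sample,
         size_dist = if (nrow(cl)) summary(cl$n_targets) else NULL,
         sq_dist = if (nrow(cl)) summary(cl$SQ) else NULL,
         excluded = object$excluded_samples,
         effective_n = vapply(object$moments,
                              function(m) m$weights$effective_n, 0)),
    class = "summary.nbcnv"
  )
}

#' @export
print.summary.nbcnv <- function(x, ...) {
  cat("Cohort CNV calling summary\n")
  cat("  ", x$n_samples, "samples,", x$n_targets, "targets\n")
  cat("  ", x$n_calls, "calls:", x$n_del, "deletions,", x$n_dup,
      "duplications\n")
  cat("  calls per sample: median",
      stats::median(x$per_sample), ", max", max(x$per_sample), "\n")
  if (!is.null(x$size_dist)) {
    cat("  call size (targets):\n"); print(x$size_dist)
    cat("  SQ:\n"); print(x$sq_dist)
  }
  cat("  effective reference n: median",
      format(stats::median(x$effective_n), digits = 4), "\n")
  if (length(x$excluded)) {
    cat("  excluded samples:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.nbcnv <- function(object, ...) {
  refs <- object$samples
  W <- matrix(0, length(object$moments), length(refs),
              dimnames = list(names(object$moments), refs))
  for (j in names(object$moments)) {
    w <- object$moments[[j]]$weights$weights
    W[j, names(w)[names(w) %in% refs]] <- w[names(w) %in% refs]
  }
  W
}

#' @export
fitted.nbcnv <- function(object, ...) {
  vapply(object$moments, function(m) m$mu, numeric(nrow(object$targets)))
}

#' Pearson residuals of observed counts against the reference model
#'
#' @param object An `nbcnv` fit.
#' @param ... Unused.
#' @return Matrix (targets x samples) of `(k - mu) / sqrt(var)`.
#' @export
residuals.nbcnv <- function(object, ...) {
  mu <- fitted(object)
  v <- vapply(object$moments, function(m) m$var,
              numeric(nrow(object$targets)))
  (object$counts[, colnames(mu), drop = FALSE] - mu) / sqrt(pmax(v, 1e-12))
}

#' Plot the batch-structure diagnostic for a fitted cohort
#'
#' @param x An `nbcnv` fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [mds_batches()] result.
#' @export
plot.nbcnv <- function(x, ...) {
  mds <- mds_batches(x$counts)
  lowcor <- mds$max_correlation < 0.9
  graphics::plot(mds$points, pch = 19,
                 col = ifelse(lowcor, "red", "black"),
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = "Batch structure (inverse-covariance MDS)", ...)
  if (any(lowcor)) {
    graphics::text(mds$points[lowcor, , drop = FALSE],
                   labels = rownames(mds$points)[lowcor], pos = 3,
                   cex = 0.7, col = "red")
  }
  invisible(mds)
}

#' Interval qualities for an arbitrary region in a fitted cohort
#'
#' Scores any (sample, region, type) triple against a fitted cohort, e.g.
#' to genotype one sample's call in another sample. Unrestricted chain
#' likelihoods are cached per (sample, chromosome).
#'
#' @param fit An `nbcnv` fit.
#' @param sample Sample id.
#' @param region `(first_target, last_target)` row indices into the fit's
#'   target table (one chromosome).
#' @param type `"DEL"` or `"DUP"`.
#' @return As [interval_qualities()].
#' @export
score_region <- function(fit, sample, region, type) {
  stopifnot(inherits(fit, "nbcnv"))
  if (!sample %in% names(fit$moments)) stop("sample not in fit: ", sample)
  first <- as.integer(region[1L]); last <- as.integer(region[2L])
  chrom <- fit$targets$chrom[first]
  if (!all(fit$targets$chrom[first:last] == chrom)) {
    stop("region spans more than one chromosome")
  }
  idx <- fit$chrom_idx[[chrom]]
  em <- fit$emissions[[sample]][idx, , drop = FALSE]
  dists <- target_distances(fit$targets, idx)
  key <- paste0(sample, "\r", chrom)
  total <- fit$ll_cache[[key]]
  if (is.null(total)) {
    total <- forward_backward(em, dists, fit$config$params)$loglik
    fit$ll_cache[[key]] <- total
  }
  restr <- restricted_loglik(em, dists, fit$config$params,
                             match(first, idx), match(last, idx),
                             match(type, STATE_NAMES))
  scores <- phred_pair(restr - total, fit$config$phred_cap)
  c(list(sample = sample, chrom = chrom, first_target = first,
         last_target = last, type = type), scores)
}

#' Write CNV calls to disk
#'
#' TSV columns: `SAMPLE`, `CNV` (DEL/DUP), `INTERVAL`
#' (`chrom:start-end`, 1-based inclusive for display), `KB`,
#' `NUM_TARGETS`, `SQ`, `NQ`, `COPY_NUMBER`. The VCF 4.2 output uses
#' symbolic alleles `<DEL>`/`<DUP>` with `END`/`SVTYPE`/`NTARGETS` INFO
#' fields and per-sample `CN:SQ` genotype fields; records are sorted by
#' (chrom, start).
#'
#' @param calls Calls table (see [calls()]).
#' @param path Output file path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_calls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (nrow(calls) == 0L) {
      writeLines(paste(c("SAMPLE", "CNV", "INTERVAL", "KB", "NUM_TARGETS",
                         "SQ", "NQ", "COPY_NUMBER"), collapse = "\t"),
                 path)
      return(invisible(path))
    }
    out <- data.frame(
      SAMPLE = calls$sample,
      CNV = calls$type,
      INTERVAL = paste0(calls$chrom, ":", calls$start + 1L, "-", calls$end),
      KB = round((calls$end - calls$start) / 1000, 3),
      NUM_TARGETS = calls$n_targets,
      SQ = round(calls$SQ, 3),
      NQ = round(calls$NQ, 3),
      COPY_NUMBER = calls$copy_number,
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_calls_vcf(calls, path)
  }
  invisible(path)
}

#' @keywords internal
write_calls_vcf <- function(calls, path) {
  samples <- sort(unique(calls$sample))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nbcnv",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=NTARGETS,Number=1,Type=Integer,Description=\"Number of exome targets spanned\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Integer copy number\">",
    "##FORMAT=<ID=SQ,Number=1,Type=Float,Description=\"Phred-scaled quality that some target carries the event\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- character(0)
  if (nrow(calls) > 0L) {
    ord <- order(calls$chrom, calls$start, calls$end)
    calls <- calls[ord, , drop = FALSE]
    lines <- vapply(seq_len(nrow(calls)), function(i) {
      cl <- calls[i, ]
      gts <- rep(".:.", length(samples))
      gts[match(cl$sample, samples)] <-
        paste0(cl$copy_number, ":", round(cl$SQ, 2))
      paste(c(cl$chrom, cl$start + 1L, ".", "N",
              paste0("<", cl$type, ">"), round(cl$SQ, 2), "PASS",
              paste0("END=", cl$end, ";SVTYPE=", cl$type,
                     ";NTARGETS=", cl$n_targets),
              "CN:SQ", gts), collapse = "\t")
    }, "")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a TSV calls table written by [write_calls()]
#'
#' @param path Path to a TSV calls file.
#' @return Calls `data.frame` with `sample`, `type`, `chrom`, `start`,
#'   `end` (0-based half-open), `n_targets`, `SQ`, `NQ`, `copy_number`.
#' @export
read_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- regmatches(tab$INTERVAL,
                  regexec("^(.+):([0-9]+)-([0-9]+)$", tab$INTERVAL))
  data.frame(
    sample = tab$SAMPLE,
    type = tab$CNV,
    chrom = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)) - 1L,
    end = as.integer(vapply(m, `[[`, "", 4L)),
    n_targets = tab$NUM_TARGETS,
    SQ = tab$SQ,
    NQ = tab$NQ,
    copy_number = tab$COPY_NUMBER,
    stringsAsFactors = FALSE
  )
}
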