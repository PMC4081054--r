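# Synthetic exome cohorts with the statistical structure the caller
# assumes: overdispersed NB counts, per-target rates spanning orders of
# magnitude, batch-shared multiplicative biases, per-sample library sizes,
# and spiked CNVs scaling the mean by copy/2.

#' Simulate an exome read-count cohort
#'
#' Targets receive GC fractions drawn from a Beta distribution centred on
#' 0.45 and lognormal baseline rates with median `depth`. Each batch gets
#' per-target multiplicative bias factors (lognormal, sd `batch_sd` on the
#' log scale) shared by its samples — emulating the highly correlated
#' within-batch structure of real cohorts — and each sample a lognormal
#' library-size factor. Counts are drawn NB with size `size` (variance
#' `mu + mu^2/size`). With `gc_variance = TRUE` dispersion is inflated
#' (size divided by 4) at GC < 0.3 or > 0.6 so the variance-trend fit has
#' GC signal to recover; the default leaves dispersion flat in GC.
#'
#' @param n_samples Number of samples.
#' @param n_targets Number of targets, spread over `n_chrom` chromosomes.
#' @param n_batches Number of batches (default 1).
#' @param depth Median per-target diploid read count (default 100).
#' @param size NB size (dispersion) parameter; default 200, i.e. variance
#'   about 1.5x Poisson at depth 100, typical of a well-matched
#'   same-platform batch.
#' @param batch_sd Log-scale sd of per-(target, batch) bias factors
#'   (default 0.3, giving clearly distinct batch clusters whose
#'   within-batch correlation approaches the ceiling set by the NB
#'   dispersion, as in real multi-run cohorts).
#' @param libsize_sd Log-scale sd of per-sample library-size factors
#'   (default 0.1).
#' @param rate_sd Log-scale sd of per-target baseline rates (default 1:
#'   target means span roughly two orders of magnitude, as real capture
#'   designs do; this spread is what makes samples highly correlated
#'   across targets).
#' @param n_chrom Number of chromosomes (default 2).
#' @param gc_variance Couple dispersion to GC extremes (default `FALSE`).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return List with `targets` (target table with `gc`), `counts`
#'   (integer matrix) and `truth` (batch labels, library sizes, per-target
#'   rates and dispersions, bias matrix, an initially empty `events`
#'   table, and all parameters including the seed).
#' @export
simulate_cohort <- function(n_samples, n_targets, n_batches = 1,
                            depth = 100, size = 200, batch_sd = 0.3,
                            libsize_sd = 0.1, rate_sd = 1, n_chrom = 2,
                            gc_variance = FALSE, seed = 1) {
  set.seed(seed)
  sim_cohort_impl(n_samples, n_targets, n_batches, depth, size, batch_sd,
                  libsize_sd, rate_sd, n_chrom, gc_variance, seed)
}

#' @keywords internal
sim_cohort_impl <- function(n_samples, n_targets, n_batches, depth, size,
                            batch_sd, libsize_sd, rate_sd, n_chrom,
                            gc_variance, seed, sample_ids = NULL) {
  stopifnot(n_samples >= 2, n_targets >= 10, n_batches >= 1, depth > 0,
            size > 0, batch_sd >= 0, libsize_sd >= 0)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
  }
  # targets: contiguous blocks per chromosome, exon-like lengths and gaps
  stopifnot(n_chrom <= 9)  # lexicographic chromosome order
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chrom)), n_targets))
  len <- sample(120:200, n_targets, replace = TRUE)
  gap <- round(stats::rlnorm(n_targets, log(3000), 0.8))
  start <- integer(n_targets)
  pos <- 0L
  for (i in seq_len(n_targets)) {
    if (i > 1L && chrom[i] != chrom[i - 1L]) pos <- 0L
    pos <- pos + gap[i]
    start[i] <- pos
    pos <- pos + len[i]
  }
  targets <- data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(start + len),
                        gc = stats::rbeta(n_targets, 9, 11),
                        stringsAsFactors = FALSE)
  rate <- depth * stats::rlnorm(n_targets, 0, rate_sd)
  target_size <- rep(size, n_targets)
  if (gc_variance) {
    extreme <- targets$gc < 0.3 | targets$gc > 0.6
    target_size[extreme] <- size / 4
  }
  batch <- rep_len(seq_len(n_batches), n_samples)
  bias <- matrix(stats::rlnorm(n_targets * n_batches, 0, batch_sd),
                 n_targets, n_batches)
  libsize <- stats::rlnorm(n_samples, 0, libsize_sd)
  mu <- rate * bias[, batch, drop = FALSE] *
    rep(libsize, each = n_targets)
  counts <- matrix(stats::rnbinom(n_targets * n_samples, mu = mu,
                                  size = target_size),
                   n_targets, n_samples,
                   dimnames = list(target_ids(targets), sample_ids))
  storage.mode(counts) <- "integer"
  truth <- list(
    params = list(n_samples = n_samples, n_targets = n_targets,
                  n_batches = n_batches, depth = depth, size = size,
                  batch_sd = batch_sd, libsize_sd = libsize_sd,
                  rate_sd = rate_sd, n_chrom = n_chrom,
                  gc_variance = gc_variance, seed = seed),
    batch = stats::setNames(batch, sample_ids),
    libsize = stats::setNames(libsize, sample_ids),
    rate = rate, bias = bias, target_size = target_size,
    events = empty_events()
  )
  list(targets = targets, counts = counts, truth = truth)
}

#' @keywords internal
empty_events <- function() {
  data.frame(sample = character(), chrom = character(),
             first_target = integer(), last_target = integer(),
             copy = integer(), stringsAsFactors = FALSE)
}

#' Spike CNVs into a simulated cohort
#'
#' Re-draws the counts of the spiked (sample, target) cells with the
#' diploid mean scaled by `copy/2`; copy 0 instead draws from a flat
#' Poisson background with mean `lambda0` per target. The truth table is
#' extended. Uses the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param sim A cohort from [simulate_cohort()].
#' @param events `data.frame` with columns `sample`, `first_target`,
#'   `last_target` (row indices into `sim$targets`, one chromosome each)
#'   and `copy` (one of 0, 1, 3, 4, 5, 6).
#' @param lambda0 Poisson mean of the zero-copy state (default 0.2).
#' @return The cohort with modified `counts` and updated `truth$events`.
#' @export
spike_cnvs <- function(sim, events, lambda0 = 0.2) {
  if (nrow(events) == 0L) return(sim)
  stopifnot(all(c("sample", "first_target", "last_target", "copy")
                %in% names(events)))
  targets <- sim$targets
  truth <- sim$truth
  counts <- sim$counts
  if (!all(events$copy %in% c(0L, 1L, 3L, 4L, 5L, 6L))) {
    stop("spiked copy numbers must be in {0, 1, 3, 4, 5, 6}")
  }
  if (any(events$first_target < 1L | events$last_target > nrow(targets) |
          events$first_target > events$last_target)) {
    stop("spiked event outside the simulated target set")
  }
  all_ev <- rbind(truth$events[, c("sample", "first_target", "last_target")],
                  events[, c("sample", "first_target", "last_target")])
  for (s in unique(all_ev$sample)) {
    ev <- all_ev[all_ev$sample == s, , drop = FALSE]
    if (nrow(ev) > 1L) {
      ev <- ev[order(ev$first_target), , drop = FALSE]
      if (any(ev$first_target[-1L] <= ev$last_target[-nrow(ev)])) {
        stop("overlapping spiked events in sample ", s)
      }
    }
  }
  for (r in seq_len(nrow(events))) {
    s <- events$sample[r]
    if (!s %in% colnames(counts)) stop("unknown sample: ", s)
    idx <- events$first_target[r]:events$last_target[r]
    if (length(unique(targets$chrom[idx])) != 1L) {
      stop("spiked event spans more than one chromosome")
    }
    cc <- events$copy[r]
    if (cc == 0L) {
      counts[idx, s] <- stats::rpois(length(idx), lambda0)
    } else {
      mu <- truth$rate[idx] * truth$bias[idx, truth$batch[[s]]] *
        truth$libsize[[s]] * cc / 2
      counts[idx, s] <- stats::rnbinom(length(idx), mu = mu,
                                       size = truth$target_size[idx])
    }
  }
  new_ev <- data.frame(sample = events$sample,
                       chrom = targets$chrom[events$first_target],
                       first_target = as.integer(events$first_target),
                       last_target = as.integer(events$last_target),
                       copy = as.integer(events$copy),
                       stringsAsFactors = FALSE)
  extra <- setdiff(names(events), names(new_ev))
  for (nm in extra) new_ev[[nm]] <- events[[nm]]
  if (nrow(truth$events) > 0L) {
    for (nm in setdiff(names(new_ev), names(truth$events))) {
      truth$events[[nm]] <- rep(NA, nrow(truth$events))
    }
    for (nm in setdiff(names(truth$events), names(new_ev))) {
      new_ev[[nm]] <- rep(NA, nrow(new_ev))
    }
    truth$events <- rbind(truth$events, new_ev[names(truth$events)])
  } else {
    truth$events <- new_ev
  }
  storage.mode(counts) <- "integer"
  sim$counts <- counts
  sim$truth <- truth
  sim
}

#' Simulate parent-proband trios with Mendelian CNV transmission
#'
#' Builds a cohort of `3 * n_trios` samples (father, mother, proband per
#' family), spikes `parent_cnvs` heterozygous CNVs (deletion copy 1 or
#' duplication copy 3, equally likely) of `cnv_targets[1]` to
#' `cnv_targets[2]` targets into each parent, transmits each parental
#' event to the proband independently with probability
#' `transmission_prob`, and adds Poisson(`de_novo_rate`) de novo events
#' per proband. Events within a family never overlap and are separated by
#' at least two targets.
#'
#' @param n_trios Number of trios.
#' @param n_targets,n_batches,depth,size,batch_sd,libsize_sd,n_chrom
#'   Cohort parameters, as in [simulate_cohort()]; the trio default
#'   `size = 70` reflects a noisier multi-batch cohort.
#' @param parent_cnvs CNVs spiked per parent (default 16). Together with
#'   the default target count this keeps CNV-carrying targets rare
#'   (about 0.5% of reference cells, so the spiked events barely perturb
#'   reference variance estimation) while giving each parent-proband
#'   pair a handful of high-quality calls, comparable to the per-pair
#'   call counts real trio cohorts yield at stringent quality
#'   thresholds; a stable median transmission ratio needs several
#'   eligible events per pair.
#' @param cnv_targets Length-2 range of event sizes in targets
#'   (default `c(3, 8)`).
#' @param transmission_prob Probability a parental event is transmitted
#'   (default 0.5, Mendelian).
#' @param de_novo_rate Expected de novo events per proband (default 0).
#' @param seed Integer seed.
#' @return List with `targets`, `counts`, `truth` and `pedigree`
#'   (`data.frame` proband/father/mother). `truth$events` carries `trio`,
#'   `origin` (father/mother/de_novo) and, for parental events,
#'   `transmitted`.
#' @export
simulate_trios <- function(n_trios, n_targets = 18000, n_batches = 3,
                           depth = 100, size = 70, batch_sd = 0.3,
                           libsize_sd = 0.1, rate_sd = 1, n_chrom = 6,
                           parent_cnvs = 16, cnv_targets = c(3, 8),
                           transmission_prob = 0.5, de_novo_rate = 0,
                           seed = 1) {
  stopifnot(n_trios >= 1, transmission_prob >= 0, transmission_prob <= 1,
            de_novo_rate >= 0, parent_cnvs >= 0,
            cnv_targets[1] >= 1, cnv_targets[2] >= cnv_targets[1])
  set.seed(seed)
  fam <- sprintf("fam%03d", seq_len(n_trios))
  ids <- as.vector(vapply(fam, function(f)
    paste0(f, c("_fa", "_mo", "_pb")), character(3)))
  sim <- sim_cohort_impl(3L * n_trios, n_targets, n_batches, depth, size,
                         batch_sd, libsize_sd, rate_sd, n_chrom,
                         gc_variance = FALSE, seed = seed,
                         sample_ids = ids)
  targets <- sim$targets
  events <- list()
  for (t in seq_len(n_trios)) {
    fa <- paste0(fam[t], "_fa"); mo <- paste0(fam[t], "_mo")
    pb <- paste0(fam[t], "_pb")
    placed <- matrix(integer(0), ncol = 2L)  # regions used in this family
    place_event <- function() {
      L <- sample(cnv_targets[1]:cnv_targets[2], 1L)
      for (attempt in 1:1000) {
        s <- sample.int(nrow(targets) - L + 1L, 1L)
        e <- s + L - 1L
        if (targets$chrom[s] != targets$chrom[e]) next
        if (nrow(placed) > 0L &&
            any(s <= placed[, 2L] + 2L & e >= placed[, 1L] - 2L)) next
        placed <<- rbind(placed, c(s, e))
        return(c(s, e))
      }
      stop("could not place a non-overlapping event; increase n_targets")
    }
    for (role in c("fa", "mo")) {
      parent <- if (role == "fa") fa else mo
      origin <- if (role == "fa") "father" else "mother"
      for (k in seq_len(parent_cnvs)) {
        reg <- place_event()
        cc <- sample(c(1L, 3L), 1L)
        transmitted <- stats::runif(1) < transmission_prob
        events[[length(events) + 1L]] <- data.frame(
          sample = parent, first_target = reg[1L], last_target = reg[2L],
          copy = cc, trio = fam[t], origin = origin,
          transmitted = transmitted, stringsAsFactors = FALSE)
        if (transmitted) {
          events[[length(events) + 1L]] <- data.frame(
            sample = pb, first_target = reg[1L], last_target = reg[2L],
            copy = cc, trio = fam[t], origin = origin,
            transmitted = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    n_dn <- stats::rpois(1L, de_novo_rate)
    for (k in seq_len(n_dn)) {
      reg <- place_event()
      events[[length(events) + 1L]] <- data.frame(
        sample = pb, first_target = reg[1L], last_target = reg[2L],
        copy = sample(c(1L, 3L), 1L), trio = fam[t], origin = "de_novo",
        transmitted = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(events) > 0L) {
    ev <- do.call(rbind, c(events, list(make.row.names = FALSE)))
    sim <- spike_cnvs(sim, ev)
  }
  sim$pedigree <- data.frame(proband = paste0(fam, "_pb"),
                             father = paste0(fam, "_fa"),
                             mother = paste0(fam, "_mo"),
                             stringsAsFactors = FALSE)
  sim
}

#' Write / read a simulation truth table
#'
#' @param truth The `truth` element of a simulated cohort.
#' @param path TSV path.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
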