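#' Read a pedigree table of parent-proband trios
#'
#' Expects a 3-column tab-delimited file: proband, father, mother (a
#' header row with those names is optional).
#'
#' @param path Pedigree file path.
#' @return `data.frame` with columns `proband`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  first <- tolower(strsplit(readLines(path, n = 1L), "\t")[[1L]])
  has_header <- all(c("proband", "father", "mother") %in% first)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < 3L) stop("pedigree needs 3 columns")
    names(tab)[1:3] <- c("proband", "father", "mother")
  }
  tab[, c("proband", "father", "mother")]
}

#' Per-sample reference exclusions for a trio cohort
#'
#' Builds the `exclude_references` map for [nbcnv()] from a pedigree:
#' each trio member's reference panel drops the other two members.
#' First-degree relatives share rare CNVs about half the time, so left
#' in the panel they inflate the reference variance precisely at the
#' regions under test, depressing SQ both in the carrier parent and in
#' the child being genotyped.
#'
#' @param pedigree `data.frame` with columns `proband`, `father`,
#'   `mother` (see [read_pedigree()]).
#' @return Named list of character vectors.
#' @export
pedigree_exclusions <- function(pedigree) {
  out <- list()
  for (i in seq_len(nrow(pedigree))) {
    trio <- c(pedigree$proband[i], pedigree$father[i], pedigree$mother[i])
    for (m in trio) {
      out[[m]] <- unique(c(out[[m]], setdiff(trio, m)))
    }
  }
  out
}

#' @keywords internal
complete_trios <- function(fit, pedigree) {
  ok <- pedigree$proband %in% fit$samples &
    pedigree$father %in% fit$samples &
    pedigree$mother %in% fit$samples
  if (any(!ok)) {
    message("skipping ", sum(!ok), " incomplete trio(s)")
  }
  pedigree[ok, , drop = FALSE]
}

#' Classify transmission of a parental CNV from child scores
#'
#' A parental CNV counts as transmitted if the child's SQ over the same
#' region and type exceeds the child's NQ, not transmitted if SQ < NQ,
#' and uncertain (excluded from ratios) on exact equality.
#'
#' @param child_sq,child_nq Child SQ and NQ scores (vectorized).
#' @return Character vector: `"transmitted"`, `"not_transmitted"` or
#'   `"uncertain"`.
#' @export
classify_transmission <- function(child_sq, child_nq) {
  ifelse(child_sq > child_nq, "transmitted",
         ifelse(child_sq < child_nq, "not_transmitted", "uncertain"))
}

#' Score transmission of parental calls in probands
#'
#' For every complete trio and every call made in a parent with
#' `SQ >= sq_threshold`, computes the proband's SQ/NQ over the parent's
#' called region (type-matched) and classifies transmission.
#'
#' @param fit An [nbcnv()] fit containing all trio members.
#' @param pedigree Pedigree `data.frame` (see [read_pedigree()]).
#' @param sq_threshold Minimum parental call SQ to evaluate (default 60).
#' @return `data.frame`, one row per evaluated parental call: `proband`,
#'   `parent`, `role` (father/mother), region columns, `type`,
#'   `parent_SQ`, `child_SQ`, `child_NQ`, `classification`.
#' @export
trio_transmission <- function(fit, pedigree, sq_threshold = 60) {
  stopifnot(inherits(fit, "nbcnv"))
  ped <- complete_trios(fit, pedigree)
  cl <- fit$calls
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    for (role in c("father", "mother")) {
      parent <- ped[[role]][i]
      child <- ped$proband[i]
      pc <- cl[cl$sample == parent & cl$SQ >= sq_threshold, , drop = FALSE]
      for (r in seq_len(nrow(pc))) {
        cs <- score_region(fit, child,
                           c(pc$first_target[r], pc$last_target[r]),
                           pc$type[r])
        rows[[length(rows) + 1L]] <- data.frame(
          proband = child, parent = parent, role = role,
          chrom = pc$chrom[r], start = pc$start[r], end = pc$end[r],
          first_target = pc$first_target[r],
          last_target = pc$last_target[r],
          n_targets = pc$n_targets[r], type = pc$type[r],
          parent_SQ = pc$SQ[r], child_SQ = cs$SQ, child_NQ = cs$NQ,
          classification = classify_transmission(cs$SQ, cs$NQ),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(proband = character(), parent = character(),
                      role = character(), chrom = character(),
                      start = integer(), end = integer(),
                      first_target = integer(), last_target = integer(),
                      n_targets = integer(), type = character(),
                      parent_SQ = numeric(), child_SQ = numeric(),
                      child_NQ = numeric(), classification = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-pair transmission ratios and their median
#'
#' For each parent-proband pair the transmission ratio is
#' `transmitted / (transmitted + not_transmitted)`; uncertain calls are
#' excluded, as are pairs with no eligible calls. Under Mendelian
#' inheritance of real calls the median ratio converges to 0.5 as the
#' quality threshold is raised.
#'
#' @param transmission Output of [trio_transmission()].
#' @return List with `per_pair` (`data.frame`: parent, proband,
#'   transmitted, not_transmitted, ratio), `median_ratio` and `undefined`
#'   (`TRUE` when no pair had an eligible call).
#' @export
transmission_ratio <- function(transmission) {
  tt <- transmission[transmission$classification != "uncertain", ,
                     drop = FALSE]
  if (nrow(tt) == 0L) {
    return(list(per_pair = data.frame(parent = character(),
                                      proband = character(),
                                      transmitted = integer(),
                                      not_transmitted = integer(),
                                      ratio = numeric()),
                median_ratio = NA_real_, undefined = TRUE))
  }
  key <- paste(tt$parent, tt$proband, sep = "\r")
  agg <- lapply(split(tt, key), function(d) {
    data.frame(parent = d$parent[1L], proband = d$proband[1L],
               transmitted = sum(d$classification == "transmitted"),
               not_transmitted = sum(d$classification == "not_transmitted"),
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  per_pair$ratio <- per_pair$transmitted /
    (per_pair$transmitted + per_pair$not_transmitted)
  list(per_pair = per_pair,
       median_ratio = stats::median(per_pair$ratio),
       undefined = FALSE)
}

#' De novo test for one proband call
#'
#' A proband call is de novo at a quality threshold if its SQ exceeds the
#' threshold and the (type-matched) NQ of *both* parents over the same
#' region also exceeds it.
#'
#' @param child_sq Proband call SQ.
#' @param father_nq,mother_nq Parental NQ scores over the call's region.
#' @param threshold Quality threshold.
#' @return Logical (vectorized).
#' @export
classify_de_novo <- function(child_sq, father_nq, mother_nq, threshold) {
  child_sq > threshold & father_nq > threshold & mother_nq > threshold
}

#' Score proband calls for de novo status
#'
#' @param fit An [nbcnv()] fit.
#' @param pedigree Pedigree `data.frame`.
#' @param threshold Quality threshold applied to the proband SQ and both
#'   parental NQs (default 90).
#' @return `data.frame`, one row per proband call: region columns,
#'   `child_SQ`, `father_NQ`, `mother_NQ`, `de_novo`.
#' @export
trio_de_novo <- function(fit, pedigree, threshold = 90) {
  stopifnot(inherits(fit, "nbcnv"))
  ped <- complete_trios(fit, pedigree)
  cl <- fit$calls
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    child <- ped$proband[i]
    pc <- cl[cl$sample == child, , drop = FALSE]
    for (r in seq_len(nrow(pc))) {
      region <- c(pc$first_target[r], pc$last_target[r])
      fa <- score_region(fit, ped$father[i], region, pc$type[r])
      mo <- score_region(fit, ped$mother[i], region, pc$type[r])
      rows[[length(rows) + 1L]] <- data.frame(
        proband = child, father = ped$father[i], mother = ped$mother[i],
        chrom = pc$chrom[r], start = pc$start[r], end = pc$end[r],
        n_targets = pc$n_targets[r], type = pc$type[r],
        child_SQ = pc$SQ[r], father_NQ = fa$NQ, mother_NQ = mo$NQ,
        de_novo = classify_de_novo(pc$SQ[r], fa$NQ, mo$NQ, threshold),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(proband = character(), father = character(),
                      mother = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_targets = integer(), type = character(),
                      child_SQ = numeric(), father_NQ = numeric(),
                      mother_NQ = numeric(), de_novo = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fraction of proband calls inherited, binned by call size
#'
#' A proband call counts as inherited if either parent's SQ over the
#' region exceeds that parent's NQ. The fraction inherited per size bin
#' is a proxy for call accuracy, since true de novo CNVs are rare.
#'
#' @param fit An [nbcnv()] fit.
#' @param pedigree Pedigree `data.frame`.
#' @param breaks Bin edges for `n_targets`, passed to [cut()] (right
#'   closed; default `c(0, 1, 2, 4, 8, 16, Inf)`).
#' @return `data.frame` with one row per occupied bin: `bin`, `n_calls`,
#'   `n_inherited`, `fraction_inherited`.
#' @export
size_binned_inheritance <- function(fit, pedigree,
                                    breaks = c(0, 1, 2, 4, 8, 16, Inf)) {
  stopifnot(inherits(fit, "nbcnv"))
  ped <- complete_trios(fit, pedigree)
  cl <- fit$calls
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    child <- ped$proband[i]
    pc <- cl[cl$sample == child, , drop = FALSE]
    for (r in seq_len(nrow(pc))) {
      region <- c(pc$first_target[r], pc$last_target[r])
      fa <- score_region(fit, ped$father[i], region, pc$type[r])
      mo <- score_region(fit, ped$mother[i], region, pc$type[r])
      rows[[length(rows) + 1L]] <- data.frame(
        n_targets = pc$n_targets[r],
        inherited = (fa$SQ > fa$NQ) || (mo$SQ > mo$NQ)
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(bin = character(), n_calls = integer(),
                      n_inherited = integer(),
                      fraction_inherited = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- do.call(rbind, rows)
  d$bin <- cut(d$n_targets, breaks = breaks)
  agg <- lapply(split(d, d$bin, drop = TRUE), function(x) {
    data.frame(bin = as.character(x$bin[1L]), n_calls = nrow(x),
               n_inherited = sum(x$inherited),
               fraction_inherited = mean(x$inherited),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(agg, list(make.row.names = FALSE)))
}
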