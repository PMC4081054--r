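#' Read exome capture targets from a BED file
#'
#' Parses a 3+ column BED file (0-based, half-open coordinates) into the
#' target table used throughout the package. Lines beginning with `#`,
#' `track` or `browser` are skipped. Targets are sorted by (chrom, start);
#' if the input was unsorted a notice is emitted. Overlapping targets are
#' retained as-is (no merging).
#'
#' @param path Path to a BED file with at least 3 tab-separated columns:
#'   chrom, start, end.
#' @return A `data.frame` with columns `chrom` (character), `start`, `end`
#'   (integer, 0-based half-open) and `gc` (numeric, `NA` until computed by
#'   [gc_content()] or supplied by the caller).
#' @seealso [gc_content()], [read_count_matrix()]
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("targets file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no targets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", lineno[bad[1L]],
         ": coordinates do not parse as integers")
  }
  if (any(end <= start)) {
    i <- which(end <= start)[1L]
    stop("zero- or negative-length target at BED line ", lineno[i], ": ",
         chrom[i], ":", start[i], "-", end[i])
  }
  targets <- data.frame(chrom = chrom, start = start, end = end,
                        gc = NA_real_, stringsAsFactors = FALSE)
  ord <- order(targets$chrom, targets$start, targets$end)
  if (!identical(ord, seq_len(nrow(targets)))) {
    message("targets were not sorted by (chrom, start); sorting")
    targets <- targets[ord, , drop = FALSE]
    rownames(targets) <- NULL
  }
  validate_targets(targets)
  targets
}

#' @keywords internal
validate_targets <- function(targets) {
  stopifnot(is.data.frame(targets),
            all(c("chrom", "start", "end") %in% names(targets)))
  if (any(targets$end <= targets$start)) {
    stop("targets contain zero- or negative-length intervals")
  }
  ord <- order(targets$chrom, targets$start, targets$end)
  if (!identical(ord, seq_len(nrow(targets)))) {
    stop("targets must be sorted by (chrom, start)")
  }
  if ("gc" %in% names(targets)) {
    gc <- targets$gc[!is.na(targets$gc)]
    if (length(gc) && (any(gc < 0) || any(gc > 1))) {
      stop("gc fractions must lie in [0, 1]")
    }
  }
  invisible(targets)
}

#' Target identifiers of the form "chrom:start-end"
#'
#' @param targets A target table, as from [read_targets()].
#' @return Character vector of identifiers (0-based half-open coordinates).
#' @export
target_ids <- function(targets) {
  paste0(targets$chrom, ":", targets$start, "-", targets$end)
}

#' Compute per-target GC fraction from a reference FASTA
#'
#' Fills the `gc` column of the target table with (#G + #C) / (#A + #C +
#' #G + #T) over each interval. Ambiguous IUPAC bases are excluded from
#' the denominator; a target consisting entirely of ambiguous bases gets
#' `gc = NaN` and is reported in a message. The computation is invariant
#' under the case of the FASTA sequence.
#'
#' @param targets Target table (see [read_targets()]).
#' @param fasta Path to an indexed reference FASTA (a `.fai` is created if
#'   missing and the file is writable).
#' @return The target table with `gc` filled.
#' @export
gc_content <- function(targets, fasta) {
  for (pkg in c("Rsamtools", "Biostrings", "GenomicRanges", "IRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for gc_content()")
    }
  }
  validate_targets(targets)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  info <- Rsamtools::seqinfo(fa)
  missing_chrom <- setdiff(unique(targets$chrom), GenomeInfoDb_seqnames(info))
  if (length(missing_chrom) > 0L) {
    stop("chromosome(s) absent from FASTA: ",
         paste(missing_chrom, collapse = ", "))
  }
  lens <- stats::setNames(GenomeInfoDb_seqlengths(info),
                          GenomeInfoDb_seqnames(info))
  over <- targets$end > lens[targets$chrom]
  if (any(over)) {
    i <- which(over)[1L]
    stop("target extends beyond contig end: ", target_ids(targets)[i])
  }
  gr <- GenomicRanges::GRanges(
    targets$chrom,
    IRanges::IRanges(start = targets$start + 1L, end = targets$end)
  )
  seqs <- Rsamtools::scanFa(fa, gr)
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- af[, "A"] + af[, "C"] + af[, "G"] + af[, "T"]
  gc <- ifelse(acgt > 0, (af[, "G"] + af[, "C"]) / acgt, NaN)
  if (any(!is.finite(gc))) {
    message(sum(!is.finite(gc)),
            " target(s) contain only ambiguous bases; gc set to NaN")
  }
  targets$gc <- gc
  targets
}

# seqinfo accessors live in GenomeInfoDb, which Rsamtools re-exports through
# its dependency chain; resolve them lazily so GenomeInfoDb stays undeclared.
GenomeInfoDb_seqnames <- function(info) {
  getExportedValue("GenomeInfoDb", "seqnames")(info)
}
GenomeInfoDb_seqlengths <- function(info) {
  getExportedValue("GenomeInfoDb", "seqlengths")(info)
}

#' Count reads overlapping each target in a BAM file
#'
#' A read is counted once for every target its aligned span overlaps by at
#' least one base, so a read spanning two adjacent targets increments both.
#' Unmapped reads and duplicates are excluded; reads below `min_mapq` are
#' excluded.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param targets Target table (see [read_targets()]).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return Integer vector of counts, one per target.
#' @export
count_reads_from_bam <- function(bam, targets, min_mapq = 20L) {
  for (pkg in c("Rsamtools", "GenomicRanges", "IRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for count_reads_from_bam()")
    }
  }
  validate_targets(targets)
  bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(bai))) {
    stop("BAM index (.bai) not found for ", bam,
         "; index the file (e.g. Rsamtools::indexBam) first")
  }
  bf <- Rsamtools::BamFile(bam)
  bam_chroms <- GenomeInfoDb_seqnames(Rsamtools::seqinfo(bf))
  missing_chrom <- setdiff(unique(targets$chrom), bam_chroms)
  if (length(missing_chrom) > 0L) {
    stop("chromosome(s) absent from BAM header: ",
         paste(missing_chrom, collapse = ", "),
         ". Check the chromosome-name dialect (e.g. 'chr1' vs '1') of the ",
         "targets file against the BAM.")
  }
  gr <- GenomicRanges::GRanges(
    targets$chrom,
    IRanges::IRanges(start = targets$start + 1L, end = targets$end)
  )
  param <- Rsamtools::ScanBamParam(
    which = gr,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE),
    mapqFilter = min_mapq
  )
  res <- Rsamtools::countBam(bf, param = param)
  if (nrow(res) != nrow(targets)) {
    stop("BAM counting returned ", nrow(res), " rows for ", nrow(targets),
         " targets")
  }
  as.integer(res$records)
}

#' Read / write a target-by-sample read-count matrix
#'
#' The on-disk format is a tab-delimited table whose first three columns
#' (`chrom`, `start`, `end`) identify the targets (0-based half-open) and
#' whose remaining columns, one per sample, hold non-negative integer read
#' counts. `write_count_matrix()` followed by `read_count_matrix()` is the
#' identity.
#'
#' @param path File path.
#' @return For `read_count_matrix()`, a list with elements `targets` (a
#'   target table, `gc` unset) and `counts` (integer matrix, one column per
#'   sample).
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tab)[1:3])) {
    stop("count matrix must start with columns chrom, start, end")
  }
  sample_ids <- names(tab)[-(1:3)]
  if (length(sample_ids) == 0L) stop("count matrix has no sample columns")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  counts <- as.matrix(tab[, sample_ids, drop = FALSE])
  if (!is.numeric(counts) || any(is.na(counts)) ||
      any(counts < 0) || any(counts != floor(counts))) {
    stop("count matrix cells must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  targets <- data.frame(chrom = as.character(tab$chrom),
                        start = as.integer(tab$start),
                        end = as.integer(tab$end),
                        gc = NA_real_, stringsAsFactors = FALSE)
  validate_targets(targets)
  rownames(counts) <- target_ids(targets)
  list(targets = targets, counts = counts)
}

#' @param counts Integer matrix of read counts (targets x samples) with
#'   column names giving sample ids.
#' @param targets Target table aligned row-for-row with `counts`.
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, targets, path) {
  validate_counts(counts, targets)
  out <- data.frame(chrom = targets$chrom, start = targets$start,
                    end = targets$end, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_counts <- function(counts, targets = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (targets x samples)")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique sample ids as column names")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!is.null(targets) && nrow(counts) != nrow(targets)) {
    stop("counts has ", nrow(counts), " rows but there are ",
         nrow(targets), " targets")
  }
  invisible(counts)
}
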