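test_that("read_targets parses, sorts and validates BED input", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t250", "chr2\t10\t20"), bed)
  tg <- read_targets(bed)
  expect_equal(nrow(tg), 3L)
  expect_equal(tg$end - tg$start, c(100L, 100L, 10L))
  # overlapping targets are both retained, ordered by start
  expect_equal(tg$start[1:2], c(100L, 150L))
  expect_true(all(is.na(tg$gc)))

  writeLines(c("chr2\t10\t20", "chr1\t100\t200"), bed)
  expect_message(tg2 <- read_targets(bed), "sorting")
  expect_equal(tg2$chrom, c("chr1", "chr2"))

  writeLines(c("chr1\t100\t200", "chr1\t200\t200"), bed)
  expect_error(read_targets(bed), "line 2")
  writeLines(c("chr1\t100\t200", "chr1\tx\t300"), bed)
  expect_error(read_targets(bed), "line 2")
  writeLines("chr1\t100", bed)
  expect_error(read_targets(bed), "3 columns")
})

test_that("gc_content computes base fractions, excluding ambiguity codes", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "GGGGACGTANGTNNNNacgtACGT"), fa)
  tg <- data.frame(chrom = "c1",
                   start = c(0L, 4L, 8L, 12L, 16L),
                   end = c(4L, 8L, 12L, 16L, 20L),
                   gc = NA_real_)
  expect_message(out <- gc_content(tg, fa), "ambiguous")
  expect_equal(out$gc[1], 1)
  expect_equal(out$gc[2], 0.5)
  expect_equal(out$gc[3], 1 / 3)   # N dropped from the denominator
  expect_true(is.nan(out$gc[4]))
  expect_equal(out$gc[5], out$gc[2])  # case invariance

  beyond <- data.frame(chrom = "c1", start = 20L, end = 30L, gc = NA_real_)
  expect_error(gc_content(beyond, fa), "beyond contig end")
  wrong <- data.frame(chrom = "chr9", start = 0L, end = 4L, gc = NA_real_)
  expect_error(gc_content(wrong, fa), "absent from FASTA")
})

make_test_bam <- function(reads = TRUE) {
  sam <- tempfile(fileext = ".sam")
  seq50 <- strrep("A", 50)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:c1\tLN:1000")
  body <- if (reads) {
    c(
      paste("r1", 0, "c1", 120, 60, "50M", "*", 0, 0, seq50, "*", sep = "\t"),
      paste("r4", 1024, "c1", 130, 60, "50M", "*", 0, 0, seq50, "*", sep = "\t"),
      paste("r5", 0, "c1", 140, 5, "50M", "*", 0, 0, seq50, "*", sep = "\t"),
      paste("r2", 0, "c1", 180, 60, "50M", "*", 0, 0, seq50, "*", sep = "\t"),
      paste("r3", 0, "c1", 500, 60, "50M", "*", 0, 0, seq50, "*", sep = "\t")
    )
  } else character(0)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

test_that("count_reads_from_bam counts overlaps with mapq/duplicate filters", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicRanges")
  tg <- data.frame(chrom = "c1", start = c(100L, 200L), end = c(200L, 300L),
                   gc = NA_real_)
  bam <- make_test_bam()

  # r1 inside target A; r2 spans the A/B boundary and increments both;
  # r3 outside; r4 duplicate-flagged; r5 mapq 5
  cnt <- count_reads_from_bam(bam, tg, min_mapq = 20L)
  oracle <- overlap_count_oracle(c(120L, 180L), c(169L, 229L), tg)
  expect_identical(cnt, oracle)
  expect_identical(cnt, c(2L, 1L))

  cnt0 <- count_reads_from_bam(bam, tg, min_mapq = 0L)
  oracle0 <- overlap_count_oracle(c(120L, 140L, 180L), c(169L, 189L, 229L), tg)
  expect_identical(cnt0, oracle0)

  empty <- make_test_bam(reads = FALSE)
  expect_identical(count_reads_from_bam(empty, tg), c(0L, 0L))

  # missing index
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(count_reads_from_bam(noidx, tg), "index")

  # chromosome-name dialect mismatch carries a remediation hint
  tg_chr <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                       gc = NA_real_)
  expect_error(count_reads_from_bam(bam, tg_chr), "dialect")
})

test_that("count matrix TSV round-trips bit-exactly and rejects bad cells", {
  sim <- tiny_cohort(n_samples = 30, n_targets = 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(sim$counts, sim$targets, path)
  back <- read_count_matrix(path)
  expect_identical(unname(back$counts), unname(sim$counts))
  expect_identical(colnames(back$counts), colnames(sim$counts))
  expect_identical(back$targets[c("chrom", "start", "end")],
                   sim$targets[c("chrom", "start", "end")])

  writeLines(c("chrom\tstart\tend\tsA\tsB",
               "chr1\t0\t100\t3.5\t2"), path)
  expect_error(read_count_matrix(path), "non-negative integers")
  writeLines(c("chrom\tstart\tend\tsA\tsA",
               "chr1\t0\t100\t3\t2"), path)
  expect_error(read_count_matrix(path), "duplicate sample")
})

test_that("calls tables round-trip through TSV and VCF output is well-formed", {
  calls <- data.frame(
    sample = c("S2", "S1"), type = c("DUP", "DEL"),
    chrom = c("chr2", "chr1"), start = c(5000L, 1000L),
    end = c(9000L, 2000L), first_target = c(10L, 1L),
    last_target = c(12L, 3L), n_targets = c(3L, 3L),
    SQ = c(75.25, 99), NQ = c(0.125, 0.001), copy_number = c(4L, 1L),
    stringsAsFactors = FALSE
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, tsv)
  back <- read_calls(tsv)
  expect_equal(back$sample, calls$sample)
  expect_equal(back$start, calls$start)
  expect_equal(back$end, calls$end)
  expect_equal(back$copy_number, calls$copy_number)
  expect_equal(back$SQ, round(calls$SQ, 3))

  # empty call set -> header-only file
  write_calls(calls[0, ], tsv)
  expect_equal(length(readLines(tsv)), 1L)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls(calls, vcf, format = "vcf")
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  header <- grep("^#CHROM", lines)
  expect_length(header, 1L)
  expect_equal(strsplit(lines[header], "\t")[[1]][10:11], c("S1", "S2"))
  recs <- read.delim(text = lines[(header + 1):length(lines)],
                     header = FALSE, stringsAsFactors = FALSE)
  expect_equal(recs$V1, c("chr1", "chr2"))      # sorted records
  expect_equal(recs$V5, c("<DEL>", "<DUP>"))
  expect_match(recs$V8[1], "END=2000;SVTYPE=DEL")
})
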