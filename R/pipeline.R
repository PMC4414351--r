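#' Estimate mean telomere length from reads
#'
#' Runs the full estimation workflow: build the telomeric index, align the
#' reads end-to-end, accumulate per-base coverage over the telomeric region,
#' obtain the genome base coverage (either supplied directly or from the
#' closed form `total_reads * rl / genome_length`), and convert the coverage
#' ratio into a mean telomere length.  Exactly one of `genome_length` and
#' `base_cov` must be given.
#'
#' Input is either an in-memory read set (`reads`) or one or two FASTQ files
#' (`fastq`; plain or gzip).  FASTQ input is processed in chunks, so the
#' whole file is never held in memory; paired-end mates are aligned
#' independently and both count towards the total read number.  If `rl` is
#' not given it is detected as the modal length of the first 10,000 reads;
#' reads of any other length are rejected with a counted warning (the
#' coverage formulas assume a single fixed read length).
#'
#' @param reads character vector of read sequences (or a data frame with a
#'   `seq` column, e.g. from [simulate_reads()]).
#' @param fastq path(s) to one (single-end) or two (paired-end) FASTQ files.
#' @param pattern telomeric repeat pattern.
#' @param rl read length; auto-detected when `NULL`.
#' @param min_seed minimum telomeric overlap (default `min(rl, 12)`).
#' @param n_chr haploid chromosome count.
#' @param genome_length total genome length in bp (for the closed-form base
#'   coverage).
#' @param base_cov externally computed genome base coverage (overrides the
#'   closed form).
#' @param max_mismatch_rate aligner mismatch budget, see
#'   [alignment_params()].
#' @param sam optional path: write a SAM file of the mapped reads.
#' @param chunk_size FASTQ chunk size in reads.
#' @return An `mtl_estimate` (see [estimate_mtl()]) with the pattern and
#'   `min_seed` fields filled in and the coverage profile attached as
#'   attribute `profile`.
#' @export
tel_estimate <- function(reads = NULL, fastq = NULL, pattern = "TTAGGG",
                         rl = NULL, min_seed = NULL, n_chr,
                         genome_length = NULL, base_cov = NULL,
                         max_mismatch_rate = 0.10, sam = NULL,
                         chunk_size = 50000L) {
  if (is.null(genome_length) == is.null(base_cov))
    stop("exactly one of `genome_length` and `base_cov` must be supplied",
         call. = FALSE)
  if (is.null(reads) == is.null(fastq))
    stop("exactly one of `reads` and `fastq` must be supplied", call. = FALSE)
  params <- alignment_params(max_mismatch_rate = max_mismatch_rate)

  if (!is.null(reads)) {
    if (is.data.frame(reads)) reads <- reads$seq
    reads <- as.character(reads)
    if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
    if (is.null(rl)) rl <- detect_read_length(reads)
    index <- build_index(pattern, rl, min_seed)
    aln <- align_reads(reads, index, params)
    profile <- compute_coverage(aln, index)
    stats <- alignment_stats(aln)
    if (!is.null(sam)) {
      ok <- nchar(reads) == rl
      write_sam(aln, index, sam, reads[ok])
    }
  } else {
    fastq <- as.character(fastq)
    if (!length(fastq) %in% 1:2)
      stop("`fastq` must name one or two files", call. = FALSE)
    missing <- fastq[!file.exists(fastq)]
    if (length(missing) > 0L)
      stop("FASTQ file not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (is.null(rl)) {
      first <- read_fastq(fastq[1L], n_max = 10000L)
      if (nrow(first) == 0L) stop("no reads in ", fastq[1L], call. = FALSE)
      rl <- detect_read_length(first$seq)
    }
    index <- build_index(pattern, rl, min_seed)
    tel_len <- nchar(index$telomeric_region)
    depth <- integer(tel_len)
    total <- 0L; mapped <- 0L; rejected <- 0L
    sam_con <- NULL
    if (!is.null(sam)) {
      sam_con <- file(sam, "wt")
      on.exit(close(sam_con), add = TRUE)
      writeLines(sam_header(index), sam_con)
    }
    for (f in fastq) {
      fastq_chunk_apply(f, chunk_size = chunk_size, fun = function(chunk) {
        total <<- total + nrow(chunk)
        aln <- suppressWarnings(
          align_reads(chunk$seq, index, params, ids = chunk$id))
        st <- alignment_stats(aln)
        mapped <<- mapped + st$mapped
        rejected <<- rejected + st$rejected
        prof <- compute_coverage(aln, index)
        depth <<- depth + prof$depth
        if (!is.null(sam_con)) {
          ok <- nchar(chunk$seq) == rl
          writeLines(sam_records(aln, chunk$seq[ok], chunk$qual[ok]), sam_con)
        }
        invisible(NULL)
      })
    }
    if (total == 0L) stop("no reads in the FASTQ input", call. = FALSE)
    if (rejected > 0L)
      warning(sprintf("%d read(s) rejected: length differs from rl = %d",
                      rejected, rl))
    profile <- structure(list(depth = depth,
                              tel_cov = sum(depth) / tel_len,
                              tel_len = tel_len),
                         class = "coverage_profile")
    stats <- list(total = total, mapped = mapped, rejected = rejected)
  }

  if (is.null(base_cov))
    base_cov <- estimate_base_cov(stats$total, rl, genome_length)
  est <- estimate_mtl(profile, base_cov, index$pl, rl, n_chr,
                      reads_total = stats$total,
                      reads_telomeric = stats$mapped)
  est$pattern <- index$pattern
  est$min_seed <- index$min_seed
  attr(est, "profile") <- profile
  est
}
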