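# Repeat-count comparator: a minimal re-creation of the count-based
# telomere length estimator family (reads are called telomeric when they
# contain at least k repeat occurrences; the calls are normalised by the
# GC-matched read fraction and scaled by a genome-length constant).  It
# exists so the alignment-based estimator can be compared against the
# count-based behaviour on identical reads.

#' Count non-overlapping repeat occurrences per read
#'
#' Exact, non-overlapping occurrences of `pattern` in forward orientation.
#' Use [telomeric_read_counts()] for the per-read maximum over both
#' orientations.
#'
#' @param reads character vector of read sequences.
#' @param pattern repeat pattern.
#' @return Integer vector of counts.
#' @export
#' @examples
#' count_repeats(strrep("TTAGGG", 6), "TTAGGG")  # 6
count_repeats <- function(reads, pattern) {
  pattern <- check_pattern(pattern)
  if (length(reads) == 0L) return(integer(0))
  m <- gregexpr(pattern, toupper(reads), fixed = TRUE)
  vapply(m, function(x) if (x[1L] == -1L) 0L else length(x), integer(1))
}

#' Per-read telomeric repeat count over both orientations
#'
#' @inheritParams count_repeats
#' @return Integer vector: `pmax` of the forward-pattern and
#'   reverse-complement-pattern counts.
#' @export
telomeric_read_counts <- function(reads, pattern) {
  pmax(count_repeats(reads, pattern),
       count_repeats(reads, revcomp(check_pattern(pattern))))
}

#' Parameters of the count-based estimator
#'
#' @param k minimum number of repeat occurrences for a read to be called
#'   telomeric (default 7).
#' @param gc_low,gc_high GC-fraction window bounds for the normalising read
#'   set (defaults 0.48 and 0.52).
#' @param gc_matched_genome_length genome-length constant: the length of
#'   genome whose GC composition matches the window (332,720,800 genome-wide
#'   for human; 21,722,000 for chromosome 1).
#' @param n_telomere_ends number of telomere ends the length is averaged
#'   over (2 per chromosome).
#' @return A list of class `count_estimator_params`.
#' @export
count_estimator_params <- function(k = 7L, gc_low = 0.48, gc_high = 0.52,
                                   gc_matched_genome_length,
                                   n_telomere_ends) {
  k <- check_count(k, "k")
  if (!(gc_low >= 0 && gc_low < gc_high && gc_high <= 1))
    stop("GC window bounds must satisfy 0 <= gc_low < gc_high <= 1",
         call. = FALSE)
  if (gc_matched_genome_length <= 0 || n_telomere_ends < 1)
    stop("`gc_matched_genome_length` and `n_telomere_ends` must be positive",
         call. = FALSE)
  structure(list(k = k, gc_low = gc_low, gc_high = gc_high,
                 gc_matched_genome_length = gc_matched_genome_length,
                 n_telomere_ends = n_telomere_ends),
            class = "count_estimator_params")
}

#' Count-based telomere length estimate
#'
#' Implements the repeat-count estimator `l = (t_k / N_gc) * C / E`, where
#' `t_k` is the number of reads containing at least `k` repeat occurrences
#' in either orientation, `N_gc` the number of reads whose GC fraction falls
#' in the window, `C` the GC-matched genome length and `E` the number of
#' telomere ends.  `t_k = 0` yields 0; `N_gc = 0` with telomeric reads
#' present is an error (the normalisation is undefined).
#'
#' @param reads character vector of read sequences.
#' @param params a [count_estimator_params()] object.
#' @param pattern repeat pattern.
#' @return A list of class `count_estimate` with `estimate` (bp), `t_k`,
#'   `n_gc`, `s` (the GC-matched fraction) and `total`.
#' @export
count_based_estimate <- function(reads, params, pattern = "TTAGGG") {
  stopifnot(inherits(params, "count_estimator_params"))
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- as.character(reads)
  total <- length(reads)
  counts <- telomeric_read_counts(reads, pattern)
  t_k <- sum(counts >= params$k)
  gc <- gc_fraction(reads)
  n_gc <- sum(gc >= params$gc_low & gc <= params$gc_high)
  est <- if (t_k == 0L) {
    0
  } else if (n_gc == 0L) {
    stop("undefined normalization: telomeric reads present but no reads in ",
         "the GC window", call. = FALSE)
  } else {
    (t_k / n_gc) * params$gc_matched_genome_length / params$n_telomere_ends
  }
  structure(list(estimate = est, t_k = t_k, n_gc = n_gc,
                 s = if (total > 0L) n_gc / total else NA_real_,
                 total = total, params = params),
            class = "count_estimate")
}

#' Classify reads by alignment-based vs count-based capture
#'
#' Runs both classifiers on the same reads and partitions them into
#' `both`, `aligned_only`, `counted_only` and `neither`.  The
#' `counted_only` class — reads that pass the repeat-count threshold but
#' fail end-to-end alignment — is where interstitial-repeat reads land:
#' their telomeric block is flanked on both sides by non-telomeric sequence,
#' so no placement can put the flanks on the one-sided N-tail.
#'
#' @param reads character vector of read sequences (all of the index read
#'   length).
#' @param index a [build_index()] object.
#' @param align_params an [alignment_params()] object.
#' @param k repeat-count threshold.
#' @param ids optional read identifiers.
#' @param fastq_out optional path: export the `counted_only` reads as FASTQ
#'   for inspection.
#' @return A list with `class` (factor per read), `counts` (table over the
#'   four classes) and `counted_only_ids`.
#' @export
classify_discordant <- function(reads, index,
                                align_params = alignment_params(),
                                k = 7L, ids = NULL, fastq_out = NULL) {
  stopifnot(inherits(index, "tel_index"))
  if (is.data.frame(reads)) {
    if (is.null(ids) && "id" %in% names(reads)) ids <- reads$id
    reads <- reads$seq
  }
  reads <- as.character(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  if (any(nchar(reads) != index$rl))
    stop("all reads must have the index read length for classification",
         call. = FALSE)
  aln <- align_reads(reads, index, align_params, ids = ids)
  aligned <- aln$mapped
  counted <- telomeric_read_counts(reads, index$pattern) >= k
  cls <- ifelse(aligned & counted, "both",
         ifelse(aligned, "aligned_only",
         ifelse(counted, "counted_only", "neither")))
  cls <- factor(cls, levels = c("both", "aligned_only", "counted_only",
                                "neither"))
  if (!is.null(fastq_out)) {
    sel <- cls == "counted_only"
    write_fastq(data.frame(id = ids[sel], seq = reads[sel],
                           stringsAsFactors = FALSE), fastq_out)
  }
  list(class = cls, counts = table(cls),
       counted_only_ids = ids[cls == "counted_only"])
}

#' Write a count-estimator report as TSV
#'
#' @param estimate a [count_based_estimate()] result.
#' @param path output path.
#' @param run_id run identifier.
#' @return `path`, invisibly.
#' @export
write_count_report <- function(estimate, path, run_id = "run1") {
  p <- estimate$params
  df <- data.frame(run_id = run_id, k = p$k, gc_low = p$gc_low,
                   gc_high = p$gc_high,
                   gc_matched_genome_length = p$gc_matched_genome_length,
                   n_telomere_ends = p$n_telomere_ends,
                   total_reads = estimate$total, t_k = estimate$t_k,
                   n_gc = estimate$n_gc, s = estimate$s,
                   length_bp = estimate$estimate, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
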