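#' Alignment parameters for the telomeric index aligner
#'
#' The aligner is an exhaustive end-to-end scanner: every candidate offset on
#' the index is evaluated on both strands, so the only tunables are the
#' mismatch budget and strand handling.  A placement is feasible when its
#' mismatch count over telomeric-region positions is at most
#' `floor(max_mismatch_rate * telomeric_overlap)`; N-tail positions match any
#' base at zero penalty.  The default budget of 10% of the telomeric overlap
#' approximates the minimum-score threshold of a standard end-to-end
#' short-read aligner (score floor about -0.6 - 0.6*rl with a maximum
#' per-mismatch penalty of 6, i.e. roughly rl/10 mismatches).
#'
#' @param max_mismatch_rate fraction of telomeric-overlap bases allowed to
#'   mismatch (default 0.10; must be in `[0, 0.5)`).
#' @param both_strands align the reverse complement of each read as well
#'   (default `TRUE`).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(max_mismatch_rate = 0.10, both_strands = TRUE) {
  if (!is.numeric(max_mismatch_rate) || length(max_mismatch_rate) != 1L ||
      is.na(max_mismatch_rate) || max_mismatch_rate < 0 ||
      max_mismatch_rate >= 0.5)
    stop("`max_mismatch_rate` must be a single number in [0, 0.5)",
         call. = FALSE)
  structure(list(max_mismatch_rate = max_mismatch_rate,
                 both_strands = isTRUE(both_strands)),
            class = "alignment_params")
}

#' Align reads end-to-end to a telomeric index
#'
#' For each read, evaluates every candidate offset in
#' `[0, length(full_sequence) - rl]` on the forward strand and (by default)
#' the reverse complement, counting mismatches only over telomeric-region
#' positions (the N-tail matches freely).  Among feasible placements the best
#' is chosen by (1) maximal telomeric overlap, (2) minimal mismatches,
#' (3) smallest offset, (4) forward strand.  Preferring maximal telomeric
#' overlap concentrates coverage mass on the telomeric region, so that only
#' the telomere-derived parts of junction reads are counted.
#'
#' Reads whose length differs from `index$rl` are rejected (counted, with a
#' warning, never an error) and do not appear in the returned table; they do
#' count towards the `total` in the attached statistics, which is the read
#' count used for base-coverage estimation.
#'
#' @param reads character vector of read sequences (alphabet `ACGTN`; an `N`
#'   mismatches every telomeric position and matches the N-tail freely).
#' @param index a [build_index()] object.
#' @param params an [alignment_params()] object.
#' @param ids optional read identifiers (default `read_1`, `read_2`, ...).
#' @return A `data.frame` of class `tel_alignments` with columns `read_id`,
#'   `mapped`, `offset` (0-based start on the full index sequence), `strand`
#'   (`"+"`/`"-"`), `mismatches` and `telomeric_overlap`, one row per
#'   length-consistent read.  Attribute `stats` holds
#'   `list(total, mapped, rejected)`.
#' @export
#' @examples
#' idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
#' align_reads("GGGTTAGGGTTAGGGTTAGG", idx)
align_reads <- function(reads, index, params = alignment_params(),
                        ids = NULL) {
  stopifnot(inherits(index, "tel_index"))
  if (is.data.frame(reads)) {
    if (is.null(ids) && "id" %in% names(reads)) ids <- reads$id
    reads <- reads$seq
  }
  reads <- toupper(as.character(reads))
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  if (length(ids) != length(reads))
    stop("`ids` must have the same length as `reads`", call. = FALSE)

  ok <- nchar(reads) == index$rl
  n_rejected <- sum(!ok)
  if (n_rejected > 0L)
    warning(sprintf("%d read(s) rejected: length differs from rl = %d",
                    n_rejected, index$rl))

  res <- .align_reads_cpp(reads[ok], index$full_sequence,
                          nchar(index$telomeric_region), index$rl,
                          params$max_mismatch_rate, params$both_strands)
  out <- data.frame(read_id = ids[ok], res, stringsAsFactors = FALSE)
  attr(out, "stats") <- list(total = length(reads),
                             mapped = sum(out$mapped),
                             rejected = n_rejected)
  attr(out, "params") <- params
  class(out) <- c("tel_alignments", "data.frame")
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one read; returns the
#' single alignment record as a list.
#'
#' @inheritParams align_reads
#' @param read one read sequence.
#' @return A list with elements `read_id`, `mapped`, `offset`, `strand`,
#'   `mismatches`, `telomeric_overlap`.
#' @export
align_read <- function(read, index, params = alignment_params()) {
  aln <- suppressWarnings(align_reads(read, index, params))
  if (nrow(aln) == 0L)
    stop("read length differs from the index read length", call. = FALSE)
  cols <- c("read_id", "mapped", "offset", "strand", "mismatches",
            "telomeric_overlap")
  stats::setNames(lapply(cols, function(cl) aln[[cl]][1L]), cols)
}

#' Alignment summary statistics
#'
#' @param alignments a [align_reads()] result.
#' @return `list(total, mapped, rejected)`.
#' @export
alignment_stats <- function(alignments) {
  attr(alignments, "stats")
}

# SAM record lines for a set of alignments (internal).  `reads` and `quals`
# are parallel to the alignment rows (length-consistent reads only).
sam_records <- function(alignments, reads, quals = NULL,
                        seq_name = "tel_index", include_unmapped = FALSE) {
  n <- nrow(alignments)
  if (n == 0L) return(character(0))
  reads <- toupper(as.character(reads))
  if (is.null(quals)) quals <- rep("*", n)
  keep <- alignments$mapped | include_unmapped
  a <- alignments[keep, , drop = FALSE]
  sq <- reads[keep]
  ql <- quals[keep]
  rev <- a$mapped & a$strand == "-"
  # SAM stores the read in reference orientation
  sq[rev] <- revcomp(sq[rev])
  ql[rev] <- vapply(strsplit(ql[rev], ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  flag <- ifelse(a$mapped, ifelse(a$strand == "-", 16L, 0L), 4L)
  pos <- ifelse(a$mapped, a$offset + 1L, 0L)  # SAM is 1-based
  cigar <- ifelse(a$mapped, paste0(nchar(sq), "M"), "*")
  rname <- ifelse(a$mapped, seq_name, "*")
  mapq <- ifelse(a$mapped, 255L, 0L)
  tags <- ifelse(a$mapped, paste0("\tNM:i:", a$mismatches), "")
  paste0(a$read_id, "\t", flag, "\t", rname, "\t", pos, "\t", mapq, "\t",
         cigar, "\t*\t0\t0\t", sq, "\t", ql, tags)
}

sam_header <- function(index, seq_name = "tel_index") {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", seq_name, nchar(index$full_sequence)),
    sprintf("@PG\tID:telometry\tPN:telometry\tVN:%s",
            as.character(utils::packageVersion("telometry"))))
}

#' Write alignments as SAM
#'
#' Emits a SAM 1.x file of the alignments against the telomeric index:
#' `POS` is the 1-based placement offset, flag bit 16 marks
#' reverse-complement placements, and the `NM` tag carries the mismatch
#' count.  Unmapped reads are optionally emitted with flag 4.
#'
#' @param alignments a [align_reads()] result.
#' @param index the [build_index()] object the reads were aligned to.
#' @param path output path.
#' @param reads read sequences parallel to the alignment rows.
#' @param quals optional per-base quality strings parallel to `reads`.
#' @param seq_name reference sequence name (default `"tel_index"`).
#' @param include_unmapped also emit unmapped reads with flag 4.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, index, path, reads, quals = NULL,
                      seq_name = "tel_index", include_unmapped = FALSE) {
  stopifnot(inherits(index, "tel_index"))
  if (length(reads) != nrow(alignments))
    stop("`reads` must be parallel to the alignment rows", call. = FALSE)
  lines <- c(sam_header(index, seq_name),
             sam_records(alignments, reads, quals, seq_name,
                         include_unmapped))
  writeLines(lines, path)
  invisible(path)
}

#' Export unmapped reads as FASTQ
#'
#' Writes the reads that did not align to the telomeric index to a FASTQ
#' file, e.g. for downstream whole-genome alignment by external tools.
#'
#' @inheritParams write_sam
#' @return `path`, invisibly.
#' @export
write_unmapped_fastq <- function(alignments, path, reads, quals = NULL) {
  if (length(reads) != nrow(alignments))
    stop("`reads` must be parallel to the alignment rows", call. = FALSE)
  un <- !alignments$mapped
  df <- data.frame(id = alignments$read_id[un], seq = reads[un],
                   stringsAsFactors = FALSE)
  if (!is.null(quals)) df$qual <- quals[un]
  write_fastq(df, path)
}
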