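#' Per-base coverage over the telomeric region of the index
#'
#' For each mapped alignment, increments depth at the telomeric-region
#' positions `[offset, offset + telomeric_overlap)`; N-tail positions are
#' never counted.  The scalar summary `tel_cov` is the mean depth over the
#' `rl + pl - 1` telomeric positions.  The function verifies the
#' conservation identity `sum(depth) == sum(telomeric_overlap)` on every
#' call.
#'
#' @param alignments a [align_reads()] result produced against `index`.
#' @param index the [build_index()] object the reads were aligned to.
#' @return An object of class `coverage_profile`: a list with `depth`
#'   (integer vector of length `rl + pl - 1`), `tel_cov` and `tel_len`.
#' @export
compute_coverage <- function(alignments, index) {
  stopifnot(inherits(index, "tel_index"))
  tel_len <- nchar(index$telomeric_region)
  full_len <- nchar(index$full_sequence)
  m <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(m) > 0L) {
    if (any(m$offset < 0L | m$offset > full_len - index$rl))
      stop("corrupt input: alignment offset outside the index", call. = FALSE)
    if (any(m$telomeric_overlap != pmin(index$rl, tel_len - m$offset)))
      stop("corrupt input: telomeric overlap inconsistent with offset",
           call. = FALSE)
  }
  # difference-array accumulation of the per-base depth
  delta <- integer(tel_len + 1L)
  if (nrow(m) > 0L) {
    starts <- tabulate(m$offset + 1L, nbins = tel_len + 1L)
    ends <- tabulate(m$offset + m$telomeric_overlap + 1L,
                     nbins = tel_len + 1L)
    delta <- starts - ends
  }
  depth <- cumsum(delta)[seq_len(tel_len)]
  stopifnot(sum(depth) == sum(m$telomeric_overlap))  # conservation
  structure(list(depth = as.integer(depth),
                 tel_cov = sum(depth) / tel_len,
                 tel_len = tel_len),
            class = "coverage_profile")
}

#' Closed-form genome base coverage
#'
#' Estimates the genome-wide mean coverage as
#' `total_reads * rl / genome_length`.  `total_reads` counts every sequenced
#' read (both mates of a pair, duplicates included); `genome_length` is the
#' total haploid genome length including telomeres.
#'
#' @param total_reads total number of sequenced reads.
#' @param rl read length in nt.
#' @param genome_length total genome length in bp.
#' @return The base coverage (a single number).
#' @export
#' @examples
#' estimate_base_cov(1000, 100, 1e5)  # 1.0
estimate_base_cov <- function(total_reads, rl, genome_length) {
  if (!is.numeric(genome_length) || length(genome_length) != 1L ||
      is.na(genome_length) || genome_length <= 0)
    stop("invalid parameter: `genome_length` must be a positive number",
         call. = FALSE)
  if (!is.numeric(total_reads) || length(total_reads) != 1L ||
      is.na(total_reads) || total_reads < 0)
    stop("invalid parameter: `total_reads` must be a non-negative count",
         call. = FALSE)
  total_reads * rl / genome_length
}

#' Mean telomere length from coverage
#'
#' Computes the relative telomeric coverage `rel_cov = tel_cov / base_cov`
#' and the mean telomere length
#' `MTL = rel_cov * (rl + pl - 1) / (2 * n_chr)`, where the factor 2
#' accounts for the two ends of each chromosome and `n_chr` is the number of
#' chromosomes in the haploid genome.  A zero telomeric coverage yields
#' `mtl = 0`; a non-positive `base_cov` is an error (no sequencing depth to
#' normalise against is not the same as no telomeric reads).
#'
#' @param profile a [compute_coverage()] object, or a single number taken as
#'   `tel_cov` directly.
#' @param base_cov genome-wide mean coverage (> 0).
#' @param pl repeat pattern length in nt.
#' @param rl read length in nt.
#' @param n_chr haploid chromosome count.
#' @param reads_total,reads_telomeric optional read counts carried into the
#'   returned record.
#' @return An object of class `mtl_estimate`: a list with `mtl`, `rel_cov`,
#'   `tel_cov`, `base_cov`, `rl`, `pl`, `n_chr`, `reads_total`,
#'   `reads_telomeric`.
#' @export
#' @examples
#' estimate_mtl(2.0, base_cov = 1.0, pl = 6, rl = 100, n_chr = 1)$mtl  # 105
estimate_mtl <- function(profile, base_cov, pl, rl, n_chr,
                         reads_total = NA_integer_,
                         reads_telomeric = NA_integer_) {
  tel_cov <- if (inherits(profile, "coverage_profile")) profile$tel_cov
             else as.numeric(profile)
  if (!is.numeric(base_cov) || length(base_cov) != 1L || is.na(base_cov) ||
      base_cov <= 0)
    stop("invalid parameter: `base_cov` must be a positive number",
         call. = FALSE)
  n_chr <- check_count(n_chr, "n_chr")
  stopifnot(tel_cov >= 0)
  rel_cov <- tel_cov / base_cov
  mtl <- rel_cov * (rl + pl - 1) / (2 * n_chr)
  structure(list(mtl = mtl, rel_cov = rel_cov, tel_cov = tel_cov,
                 base_cov = base_cov, rl = as.integer(rl),
                 pl = as.integer(pl), n_chr = n_chr,
                 reads_total = reads_total,
                 reads_telomeric = reads_telomeric,
                 pattern = NA_character_, min_seed = NA_integer_),
            class = "mtl_estimate")
}

#' @export
print.mtl_estimate <- function(x, ...) {
  cat("Mean telomere length estimate\n")
  cat(sprintf("  MTL:       %.1f bp\n", x$mtl))
  cat(sprintf("  tel.cov:   %.4g\n", x$tel_cov))
  cat(sprintf("  base.cov:  %.4g\n", x$base_cov))
  cat(sprintf("  rel.cov:   %.4g\n", x$rel_cov))
  cat(sprintf("  reads:     %s total, %s telomeric\n",
              format(x$reads_total), format(x$reads_telomeric)))
  invisible(x)
}

#' Write an estimate report as TSV
#'
#' One row with the run identifier, all effective parameters and every
#' intermediate quantity of the estimate.
#'
#' @param estimate an `mtl_estimate` (from [estimate_mtl()] or
#'   [tel_estimate()]).
#' @param path output path.
#' @param run_id run identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_estimate_report <- function(estimate, path, run_id = "run1") {
  df <- data.frame(run_id = run_id,
                   pattern = estimate$pattern,
                   rl = estimate$rl,
                   pl = estimate$pl,
                   min_seed = estimate$min_seed,
                   n_chr = estimate$n_chr,
                   reads_total = estimate$reads_total,
                   reads_telomeric = estimate$reads_telomeric,
                   tel_cov = estimate$tel_cov,
                   base_cov = estimate$base_cov,
                   rel_cov = estimate$rel_cov,
                   mtl_bp = estimate$mtl,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump the per-base depth profile as TSV
#'
#' @param profile a [compute_coverage()] object.
#' @param path output path.  Columns: `position` (1-based index position)
#'   and `depth`.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$tel_len),
                   depth = profile$depth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
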