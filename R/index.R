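#' Build a telomeric index
#'
#' Constructs the composite reference sequence used for telomeric read
#' alignment.  The index consists of a telomeric region — the repeat pattern
#' tiled from phase 0 and truncated to `rl + pl - 1` bases, so that a read of
#' length `rl` starting at any of the `pl` cyclic phases of the repeat fits
#' entirely inside it — followed by a 3' tail of `rl - min_seed` ambiguous
#' (`N`) bases to which any sequence matches at zero penalty.  The tail is
#' one-sided (3' only): reads spanning the telomere/subtelomere junction are
#' captured when their telomeric part is at the 5' end, while reads from
#' interstitial repeat arrays, whose telomeric part is flanked on both sides,
#' cannot be placed.
#'
#' By construction, every end-to-end placement of a length-`rl` read inside
#' the index overlaps the telomeric region by at least `min_seed` bases: the
#' minimum number of telomeric bases a read must contribute is enforced
#' structurally, with no post-filtering.
#'
#' @param pattern telomeric repeat pattern (uppercase DNA string, default
#'   `"TTAGGG"`, the vertebrate repeat).
#' @param rl read length in nt; all reads aligned to the index must have this
#'   exact length.
#' @param min_seed minimum number of telomeric bases a mapped read must
#'   overlap the telomeric region with.  Default `min(rl, 12)`: two full
#'   human repeat units, an overlap unlikely to occur by chance, clamped to
#'   the read length for very short reads.
#' @return An object of class `tel_index`: a list with elements `pattern`,
#'   `pl`, `rl`, `min_seed`, `telomeric_region`, `n_tail_length` and
#'   `full_sequence`.
#' @export
#' @examples
#' idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
#' idx$telomeric_region  # "TTAGGGTTAGGGTTAGGGTTAGGGT"
#' nchar(idx$full_sequence)  # 35
build_index <- function(pattern = "TTAGGG", rl, min_seed = NULL) {
  pattern <- check_pattern(pattern)
  pl <- nchar(pattern)
  rl <- check_count(rl, "rl")
  if (is.null(min_seed)) min_seed <- min(rl, 12L)
  min_seed <- check_count(min_seed, "min_seed")
  if (min_seed > rl)
    stop("invalid parameter: `min_seed` must not exceed the read length `rl`",
         call. = FALSE)
  if (rl < pl)
    warning("read length `rl` is shorter than the repeat pattern; ",
            "a single read cannot contain one full repeat unit")
  if (min_seed < pl)
    warning("`min_seed` is shorter than the repeat pattern; reads may map ",
            "with less than one full repeat unit of telomeric overlap")

  tel_len <- rl + pl - 1L
  telomeric_region <- tile_pattern(pattern, tel_len)
  n_tail_length <- rl - min_seed
  full_sequence <- paste0(telomeric_region, strrep("N", n_tail_length))

  structure(
    list(pattern = pattern, pl = pl, rl = rl, min_seed = min_seed,
         telomeric_region = telomeric_region,
         n_tail_length = n_tail_length,
         full_sequence = full_sequence),
    class = "tel_index"
  )
}

#' Cyclic rotations of a repeat pattern
#'
#' Returns all `pl` left rotations of the pattern (rotation `r` is the
#' pattern shifted left by `r` bases).  For a non-periodic pattern such as
#' `TTAGGG` all rotations are distinct, and each one is the prefix phase of
#' some pure-repeat read.  Periodic patterns (e.g. `"ATAT"`) are accepted
#' with a warning: alignment offsets become non-unique modulo the period,
#' but coverage-based length estimation is unaffected.
#'
#' @param pattern repeat pattern string.
#' @return Character vector of `nchar(pattern)` rotations, with attribute
#'   `periodic` set to `TRUE` if some rotations coincide.
#' @export
#' @examples
#' cyclic_rotations("TTAGGG")
cyclic_rotations <- function(pattern) {
  pattern <- check_pattern(pattern)
  pl <- nchar(pattern)
  rots <- vapply(seq_len(pl) - 1L, function(r) {
    paste0(substr(pattern, r + 1L, pl), substr(pattern, 1L, r))
  }, character(1))
  periodic <- anyDuplicated(rots) > 0L
  if (periodic)
    warning("pattern is periodic: its cyclic rotations are not all distinct")
  attr(rots, "periodic") <- periodic
  rots
}

#' Export a telomeric index as FASTA
#'
#' Writes the full index sequence (telomeric region plus N-tail) as a
#' single-record FASTA file, so that third-party aligners can be run against
#' the same index for cross-validation.
#'
#' @param index a [build_index()] object.
#' @param path output file path.
#' @param name FASTA record name (default `"tel_index"`).
#' @return `path`, invisibly.
#' @export
write_index_fasta <- function(index, path, name = "tel_index") {
  stopifnot(inherits(index, "tel_index"))
  x <- Biostrings::DNAStringSet(stats::setNames(index$full_sequence, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.tel_index <- function(x, ...) {
  cat("Telomeric index\n")
  cat(sprintf("  pattern:          %s (pl = %d)\n", x$pattern, x$pl))
  cat(sprintf("  read length:      %d nt\n", x$rl))
  cat(sprintf("  min seed:         %d nt\n", x$min_seed))
  cat(sprintf("  telomeric region: %d nt\n", nchar(x$telomeric_region)))
  cat(sprintf("  N-tail:           %d nt\n", x$n_tail_length))
  cat(sprintf("  total length:     %d nt\n", nchar(x$full_sequence)))
  invisible(x)
}
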