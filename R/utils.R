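# shared internal helpers

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (alphabet `ACGTN`).
#' @return character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("TTAGGG")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# tile `pattern` from phase 0 and truncate to `len` bases
tile_pattern <- function(pattern, len) {
  if (len <= 0L) return("")
  substr(strrep(pattern, ceiling(len / nchar(pattern))), 1L, len)
}

# validate a telomeric repeat pattern; returns the uppercased pattern
check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("invalid telomeric pattern: must be a single DNA string", call. = FALSE)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 1L || !grepl("^[ACGT]+$", pattern))
    stop("invalid telomeric pattern: must be non-empty and contain only A, C, G, T",
         call. = FALSE)
  pattern
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

# modal read length over (the head of) a read set
detect_read_length <- function(seqs, n_max = 10000L) {
  lens <- nchar(head(seqs, n_max))
  if (length(lens) == 0L) stop("no reads to detect read length from", call. = FALSE)
  tab <- table(lens)
  as.integer(names(tab)[which.max(tab)])
}

# fraction of G/C bases per read
gc_fraction <- function(seqs) {
  n <- nchar(seqs)
  gc <- nchar(gsub("[^GCgc]", "", seqs))
  gc / n
}
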