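# Synthetic-genome and Illumina-like read simulation.  The generator
# emulates the validation protocol the estimator is benchmarked with: a
# repeat-free random backbone standing in for a non-telomeric chromosome
# fragment, telomeres of known length attached to both ends, and uniformly
# placed substitution-error reads.

#' Generate a repeat-free random backbone sequence
#'
#' Draws a random DNA sequence at the requested GC content and locally
#' re-draws any window containing a cyclic rotation of the telomeric
#' pattern or of its reverse complement, so the backbone contains neither
#' pure nor interstitial telomeric repeats (mirroring the repeat-free
#' chromosome fragment used for validation).
#'
#' @param length backbone length in bp.
#' @param gc GC fraction (default 0.5).
#' @param pattern telomeric pattern to exclude.
#' @param seed optional RNG seed (omit to use the current RNG state).
#' @param max_iter redraw iterations before giving up.
#' @return A single DNA string.
#' @export
make_backbone <- function(length, gc = 0.5, pattern = "TTAGGG",
                          seed = NULL, max_iter = 100L) {
  if (!is.null(seed)) set.seed(seed)
  length <- check_count(length, "length")
  pattern <- check_pattern(pattern)
  forbidden <- unique(c(rotations_of(pattern), rotations_of(revcomp(pattern))))
  if (min(nchar(forbidden)) < 2L)
    stop("constraint error: cannot build a repeat-free backbone for a ",
         "single-base pattern", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(bases, length, replace = TRUE, prob = probs)
  for (iter in seq_len(max_iter)) {
    s <- paste(x, collapse = "")
    hits <- lapply(forbidden, function(m) {
      g <- gregexpr(m, s, fixed = TRUE)[[1L]]
      if (g[1L] == -1L) integer(0)
      else unlist(lapply(g, function(p) p:(p + nchar(m) - 1L)))
    })
    pos <- unique(unlist(hits))
    if (length(pos) == 0L) return(s)
    x[pos] <- sample(bases, length(pos), replace = TRUE, prob = probs)
  }
  stop("constraint error: could not generate a repeat-free backbone (",
       "GC content incompatible with the excluded motifs?)", call. = FALSE)
}

# rotations without the periodicity warning (internal)
rotations_of <- function(pattern) {
  pl <- nchar(pattern)
  vapply(seq_len(pl) - 1L, function(r)
    paste0(substr(pattern, r + 1L, pl), substr(pattern, 1L, r)), character(1))
}

#' Attach telomeres of known length to a backbone
#'
#' Draws the two telomere lengths independently from a normal distribution
#' truncated below at zero (the defaults, mean 10 kb and SD 7 kb, are the
#' study conditions of the validation protocol; the SD-to-mean ratio puts
#' about 8% of the untruncated mass below zero, so truncation is required)
#' and rounds each to the nearest half-pattern, allowing partial terminal
#' repeats.  The left telomere carries the forward pattern (tiled from the
#' chromosome terminus inward) and the right telomere the
#' reverse-complement pattern, so that on each end the repeats read
#' 5'-to-3' from the terminus toward the centromere.  With this layout a
#' read crossing either telomere/subtelomere junction presents its
#' telomeric block as a 5' prefix in one of its two orientations — the
#' configuration the one-sided N-tail of the telomeric index is designed to
#' capture — and double-stranded sequencing still yields reads of both the
#' G-rich and C-rich phase.
#'
#' @param backbone backbone DNA string (see [make_backbone()]).
#' @param pattern telomeric repeat pattern.
#' @param length_mean,length_sd mean and SD (bp) of the telomere-length
#'   distribution; `length_sd = 0` gives exact lengths.
#' @param seed optional RNG seed.
#' @return An object of class `synthetic_genome`: a list with `sequence`,
#'   `backbone_length`, `left_telomere_length`, `right_telomere_length`,
#'   `pattern`, `n_chr` (always 1) and `true_mtl` (the mean of the two
#'   telomere lengths, the ground truth for evaluation).
#' @export
attach_telomeres <- function(backbone, pattern = "TTAGGG",
                             length_mean = 10000, length_sd = 7000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pattern <- check_pattern(pattern)
  pl <- nchar(pattern)
  if (length_mean < 0 || length_sd < 0)
    stop("`length_mean` and `length_sd` must be non-negative", call. = FALSE)

  draw_length <- function() {
    if (length_sd == 0) return(length_mean)
    repeat {
      x <- rnorm(1L, length_mean, length_sd)
      if (x >= 0) return(x)
    }
  }
  half <- pl / 2
  round_half_pattern <- function(x) as.integer(round(round(x / half) * half))
  left_len <- round_half_pattern(draw_length())
  right_len <- round_half_pattern(draw_length())

  left <- tile_pattern(pattern, left_len)
  right <- tile_pattern(revcomp(pattern), right_len)
  structure(
    list(sequence = paste0(left, backbone, right),
         backbone_length = nchar(backbone),
         left_telomere_length = left_len,
         right_telomere_length = right_len,
         pattern = pattern, n_chr = 1L,
         true_mtl = (left_len + right_len) / 2),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome\n")
  cat(sprintf("  total length:   %d bp\n", nchar(x$sequence)))
  cat(sprintf("  backbone:       %d bp\n", x$backbone_length))
  cat(sprintf("  telomeres:      %d / %d bp (true MTL %.1f bp)\n",
              x$left_telomere_length, x$right_telomere_length, x$true_mtl))
  invisible(x)
}

# validate a paired-end configuration against the excluded combinations of
# the validation grid
check_sim_config <- function(rl, layout, insert_mean) {
  if (layout == "paired") {
    if (insert_mean == 200 && rl %in% c(100L, 150L))
      stop("configuration error: insert size 200 is not used with 100 nt ",
           "or 150 nt reads", call. = FALSE)
    if (insert_mean == 300 && rl == 150L)
      stop("configuration error: insert size 300 is not used with 150 nt ",
           "reads", call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate Illumina-like reads from a genome
#'
#' Read start positions are uniform over the genome and strands uniform;
#' substitution errors occur independently per base at `error_rate`
#' (uniform over the three alternative bases; no indels, no positional
#' ramp).  Paired-end layout draws the insert (outer fragment length) from
#' a normal distribution truncated to `[rl, genome length]` and emits the
#' two mates in FR orientation, mate 2 reverse-complemented.  The number of
#' reads is `round(coverage * genome_length / rl)` (pairs counting as two
#' reads), so emitted read-bases match the requested fold coverage to
#' within one read.  Optionally, a fraction of exact duplicate copies of
#' already-emitted reads is appended.  Fully deterministic given `seed`.
#'
#' @param genome a [attach_telomeres()] object or a DNA string.
#' @param rl read length in nt.
#' @param coverage requested fold coverage.
#' @param layout `"single"` or `"paired"`.
#' @param insert_mean,insert_sd insert-size distribution (paired only).
#'   The excluded grid combinations (insert 200 with 100/150 nt reads,
#'   insert 300 with 150 nt reads) raise a configuration error.
#' @param error_rate per-base substitution probability (default 0.002,
#'   Illumina-like; use 0 for error-free reads).
#' @param duplicate_fraction fraction of exact duplicate reads appended
#'   (default 0).
#' @param seed optional RNG seed.
#' @return A data frame of class `sim_reads` with columns `id`, `seq`,
#'   `mate` (1/2, `NA` for single-end), `start` (1-based start of the
#'   originating fragment end on the genome) and `strand`.  Attribute
#'   `manifest` records the ground truth (telomere lengths, genome length)
#'   and every configuration parameter.
#' @export
simulate_reads <- function(genome, rl, coverage,
                           layout = c("single", "paired"),
                           insert_mean = 300, insert_sd = 60,
                           error_rate = 0.002, duplicate_fraction = 0,
                           seed = NULL) {
  layout <- match.arg(layout)
  sequence <- if (inherits(genome, "synthetic_genome")) genome$sequence
              else as.character(genome)
  G <- nchar(sequence)
  rl <- check_count(rl, "rl")
  if (rl > G) stop("read length exceeds the genome length", call. = FALSE)
  if (coverage <= 0) stop("`coverage` must be positive", call. = FALSE)
  check_sim_config(rl, layout, insert_mean)
  if (!is.null(seed)) set.seed(seed)

  if (layout == "single") {
    n <- max(1L, as.integer(round(coverage * G / rl)))
    starts <- sample.int(G - rl + 1L, n, replace = TRUE)
    seqs <- substring(sequence, starts, starts + rl - 1L)
    minus <- sample(c(FALSE, TRUE), n, replace = TRUE)
    seqs[minus] <- revcomp(seqs[minus])
    df <- data.frame(id = sprintf("r%07d", seq_len(n)), seq = seqs,
                     mate = NA_integer_, start = starts,
                     strand = ifelse(minus, "-", "+"),
                     stringsAsFactors = FALSE)
  } else {
    n_pairs <- max(1L, as.integer(round(coverage * G / (2 * rl))))
    ins <- as.integer(round(rnorm(n_pairs, insert_mean, insert_sd)))
    bad <- ins < rl | ins > G
    while (any(bad)) {  # rejected draws are re-sampled
      ins[bad] <- as.integer(round(rnorm(sum(bad), insert_mean, insert_sd)))
      bad <- ins < rl | ins > G
    }
    starts <- 1L + as.integer(floor(runif(n_pairs) * (G - ins + 1L)))
    m1 <- substring(sequence, starts, starts + rl - 1L)
    m2 <- revcomp(substring(sequence, starts + ins - rl, starts + ins - 1L))
    minus <- sample(c(FALSE, TRUE), n_pairs, replace = TRUE)
    # a minus-strand fragment swaps which physical end is read first
    tmp <- m1[minus]; m1[minus] <- m2[minus]; m2[minus] <- tmp
    ids <- sprintf("p%07d", seq_len(n_pairs))
    df <- data.frame(
      id = c(ids, ids),
      seq = c(m1, m2),
      mate = rep(1:2, each = n_pairs),
      start = c(starts, starts + ins - rl),
      strand = rep(ifelse(minus, "-", "+"), 2L),
      stringsAsFactors = FALSE)
  }

  df$seq <- add_substitution_errors(df$seq, error_rate, rl)

  if (duplicate_fraction > 0) {
    n_dup <- as.integer(round(duplicate_fraction * nrow(df)))
    if (n_dup > 0L) {
      pick <- sample.int(nrow(df), n_dup, replace = TRUE)
      dup <- df[pick, , drop = FALSE]
      dup$id <- sprintf("%s_dup%d", dup$id, seq_len(n_dup))
      df <- rbind(df, dup)
    }
  }
  rownames(df) <- NULL

  manifest <- list(
    rl = rl, coverage = coverage, layout = layout,
    insert_mean = if (layout == "paired") insert_mean else NA,
    insert_sd = if (layout == "paired") insert_sd else NA,
    error_rate = error_rate, duplicate_fraction = duplicate_fraction,
    seed = if (is.null(seed)) NA else seed,
    n_reads = nrow(df), genome_length = G,
    pattern = if (inherits(genome, "synthetic_genome")) genome$pattern else NA,
    left_telomere_length =
      if (inherits(genome, "synthetic_genome")) genome$left_telomere_length else NA,
    right_telomere_length =
      if (inherits(genome, "synthetic_genome")) genome$right_telomere_length else NA,
    true_mtl =
      if (inherits(genome, "synthetic_genome")) genome$true_mtl else NA)
  attr(df, "manifest") <- manifest
  class(df) <- c("sim_reads", "data.frame")
  df
}

# uniform substitution errors: per-base Bernoulli(rate), realised as a
# binomial error count with uniformly sampled positions (equivalent, but
# avoids materialising one RNG draw per base)
add_substitution_errors <- function(seqs, rate, rl) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  n_bases <- length(seqs) * rl
  n_err <- rbinom(1L, n_bases, rate)
  if (n_err == 0L) return(seqs)
  pos <- sample.int(n_bases, n_err)
  r <- (pos - 1L) %/% rl + 1L
  p <- (pos - 1L) %% rl + 1L
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_err)) {
    orig <- substr(seqs[r[i]], p[i], p[i])
    alt <- bases[bases != orig]
    substr(seqs[r[i]], p[i], p[i]) <- alt[sample.int(length(alt), 1L)]
  }
  seqs
}

#' Export a synthetic genome as FASTA
#'
#' @param genome a [attach_telomeres()] object.
#' @param path output path.
#' @param name FASTA record name.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, name = "synthetic_chr") {
  stopifnot(inherits(genome, "synthetic_genome"))
  x <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a simulation ground-truth manifest as JSON
#'
#' @param reads a [simulate_reads()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(reads, path) {
  manifest <- attr(reads, "manifest")
  if (is.null(manifest)) stop("`reads` carries no manifest", call. = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
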