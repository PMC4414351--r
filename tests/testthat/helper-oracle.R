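# Independent brute-force alignment oracle and small sequence generators.
# The oracle enumerates every offset/strand placement with plain character
# vectors; it shares no code with the package's scanner.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_align <- function(seq, index, max_mismatch_rate = 0.1,
                         both_strands = TRUE) {
  full <- strsplit(index$full_sequence, "")[[1]]
  tel_len <- nchar(index$telomeric_region)
  rl <- index$rl
  best <- list(mapped = FALSE, offset = NA_integer_, strand = NA_character_,
               mismatches = NA_integer_, telomeric_overlap = NA_integer_)
  best_key <- c(-1L, 0L)
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    q <- strsplit(if (st == "+") seq else oracle_revcomp(seq), "")[[1]]
    for (o in 0:(length(full) - rl)) {
      ov <- min(rl, tel_len - o)
      if (ov <= 0) next
      mm <- sum(q[seq_len(ov)] != full[o + seq_len(ov)])
      if (mm > floor(max_mismatch_rate * ov + 1e-9)) next
      key <- c(ov, -mm)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best_key <- key
        best <- list(mapped = TRUE, offset = o, strand = st,
                     mismatches = mm, telomeric_overlap = ov)
      }
    }
  }
  best
}

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# pure-repeat read of length rl starting at cyclic phase `phase` (0-based)
pure_read <- function(pattern, rl, phase = 0L) {
  pl <- nchar(pattern)
  tiled <- strrep(pattern, ceiling((rl + phase) / pl) + 1L)
  substr(tiled, phase + 1L, phase + rl)
}

# mutate specific positions of a read to a different base
mutate_read <- function(seq, positions) {
  for (p in positions) {
    orig <- substr(seq, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), orig)[1L]
    substr(seq, p, p) <- alt
  }
  seq
}
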