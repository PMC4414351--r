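test_that("a pure-repeat read maps at its cyclic phase with no mismatches", {
  idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
  a <- align_read("GGGTTAGGGTTAGGGTTAGG", idx)
  expect_true(a$mapped)
  expect_identical(a$offset, 3L)
  expect_identical(a$strand, "+")
  expect_identical(a$mismatches, 0L)
  expect_identical(a$telomeric_overlap, 20L)
})

test_that("reverse-complement reads map on the minus strand", {
  idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
  a <- align_read("CCTAACCCTAACCCTAACCC", idx)  # rc of the phase-3 read
  expect_true(a$mapped)
  expect_identical(a$strand, "-")
  expect_identical(a$mismatches, 0L)
})

test_that("all cyclic phases of the pure repeat map cleanly at their offset", {
  for (pattern in c("TTAGGG", "ACGTC")) {
    pl <- nchar(pattern)
    idx <- build_index(pattern, rl = 30)
    for (phase in 0:(pl - 1L)) {
      a <- align_read(pure_read(pattern, 30L, phase), idx)
      expect_true(a$mapped)
      expect_identical(a$offset, phase)
      expect_identical(a$mismatches, 0L)
      expect_identical(a$telomeric_overlap, 30L)
    }
  }
})

test_that("sub-seed telomeric content does not map", {
  idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
  read <- paste0("TTAGGGTTA", strrep("C", 11))  # 9 telomeric + 11 junk bases
  a <- align_read(read, idx)
  o <- oracle_align(read, idx)
  expect_false(a$mapped)
  expect_false(o$mapped)
})

test_that("mismatches within the budget are tolerated", {
  idx <- build_index("TTAGGG", rl = 36, min_seed = 12)
  read <- mutate_read(pure_read("TTAGGG", 36L), c(5L, 20L))
  a <- align_read(read, idx)
  expect_true(a$mapped)
  expect_identical(a$mismatches, 2L)  # 2 <= floor(0.10 * 36) = 3
  # one more than the budget fails
  read4 <- mutate_read(pure_read("TTAGGG", 36L), c(5L, 14L, 20L, 29L))
  expect_false(align_read(read4, idx)$mapped)
})

test_that("junction reads map with the non-telomeric tail absorbed", {
  idx <- build_index("TTAGGG", rl = 36, min_seed = 12)
  tel_len <- nchar(idx$telomeric_region)
  max_off <- nchar(idx$full_sequence) - idx$rl
  set.seed(404)
  # telomeric prefix of exactly min_seed bases at the maximal offset, then
  # an arbitrary 3' tail sitting wholly on the N-tail
  prefix <- substr(idx$telomeric_region, max_off + 1L, tel_len)
  read <- paste0(prefix, random_dna(idx$rl - idx$min_seed))
  a <- align_read(read, idx)
  expect_true(a$mapped)
  expect_gte(a$telomeric_overlap, idx$min_seed)
})

test_that("scanner agrees with the brute-force oracle on random reads", {
  set.seed(101)
  grid <- expand.grid(pattern = c("AT", "ACG", "ACGT"), rl = c(6L, 9L, 12L),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    pattern <- grid$pattern[i]; rl <- grid$rl[i]
    idx <- suppressWarnings(build_index(pattern, rl, min_seed = min(rl, 5L)))
    reads <- c(
      vapply(0:(nchar(pattern) - 1L), function(p) pure_read(pattern, rl, p),
             character(1)),
      vapply(seq_len(40), function(j) random_dna(rl), character(1)),
      vapply(seq_len(40), function(j)
        mutate_read(pure_read(pattern, rl, j %% nchar(pattern)),
                    sample.int(rl, 1L)), character(1)))
    aln <- align_reads(reads, idx)
    for (j in seq_along(reads)) {
      o <- oracle_align(reads[j], idx)
      expect_identical(aln$mapped[j], o$mapped)
      if (o$mapped) {
        expect_identical(aln$offset[j], o$offset)
        expect_identical(aln$strand[j], o$strand)
        expect_identical(aln$mismatches[j], o$mismatches)
        expect_identical(aln$telomeric_overlap[j], o$telomeric_overlap)
      }
    }
  }
})

test_that("alignment is anti-symmetric under reverse complement", {
  idx <- build_index("TTAGGG", rl = 24)
  set.seed(7)
  reads <- c(vapply(1:20, function(i) pure_read("TTAGGG", 24L, i %% 6), character(1)),
             vapply(1:20, function(i) random_dna(24L), character(1)),
             vapply(1:20, function(i)
               paste0(substr(pure_read("TTAGGG", 24L), 1, 12),
                      random_dna(12L)), character(1)))
  fwd <- align_reads(reads, idx)
  rev <- align_reads(revcomp(reads), idx)
  expect_identical(fwd$mapped, rev$mapped)
  m <- fwd$mapped
  expect_identical(fwd$strand[m], c("-" = "+", "+" = "-")[rev$strand[m]],
                   ignore_attr = TRUE)
})

test_that("read sets are aligned with counted statistics", {
  idx <- build_index("TTAGGG", rl = 100)
  # empty stream
  a0 <- align_reads(character(0), idx)
  expect_identical(nrow(a0), 0L)
  expect_identical(alignment_stats(a0),
                   list(total = 0L, mapped = 0L, rejected = 0L))
  # pure repeats all map; random 100-mers essentially never do
  set.seed(5)
  pure <- vapply(1:100, function(i) pure_read("TTAGGG", 100L, i %% 6),
                 character(1))
  rnd <- vapply(1:100, function(i) random_dna(100L), character(1))
  a <- align_reads(c(pure, rnd), idx)
  st <- alignment_stats(a)
  expect_identical(st$total, 200L)
  expect_gte(st$mapped, 100L)
  expect_lte(st$mapped, 101L)
  # wrong-length reads are rejected with a warning, not an error
  expect_warning(a2 <- align_reads(c(pure[1], "TTAGGG"), idx), "rejected")
  st2 <- alignment_stats(a2)
  expect_identical(st2$rejected, 1L)
  expect_identical(st2$total, 2L)
  expect_identical(nrow(a2), 1L)
})

test_that("N bases mismatch the telomeric region but not the tail", {
  idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
  # N inside the telomeric overlap counts as a mismatch
  read <- pure_read("TTAGGG", 20L)
  substr(read, 3, 3) <- "N"
  a <- align_read(read, idx)
  expect_true(a$mapped)
  expect_identical(a$mismatches, 1L)
  # a junction read whose N-rich tail sits on the N-tail still maps
  prefix <- substr(idx$telomeric_region, 16, 25)  # maximal-offset seed
  a2 <- align_read(paste0(prefix, strrep("N", 10)), idx)
  expect_true(a2$mapped)
})

test_that("SAM output parses with standard tooling", {
  idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
  reads <- c("GGGTTAGGGTTAGGGTTAGG",       # + strand, offset 3
             "CCTAACCCTAACCCTAACCC",       # - strand
             paste0(strrep("C", 9), strrep("A", 11)))  # unmapped
  aln <- align_reads(reads, idx)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, idx, sam, reads, include_unmapped = TRUE)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  expect_identical(sort(as.character(rec$qname)),
                   sort(aln$read_id))
  m <- match(aln$read_id, rec$qname)
  expect_identical(as.integer(rec$pos[m][aln$mapped]),
                   aln$offset[aln$mapped] + 1L)
  expect_identical(as.character(rec$strand[m][aln$mapped]),
                   aln$strand[aln$mapped])
  # reverse-strand SEQ is stored in reference orientation
  expect_identical(as.character(rec$seq[m][2]), revcomp(reads[2]))
})

test_that("unmapped reads can be exported as FASTQ", {
  idx <- build_index("TTAGGG", rl = 20, min_seed = 10)
  reads <- c("GGGTTAGGGTTAGGGTTAGG", paste0(strrep("C", 9), strrep("A", 11)))
  aln <- align_reads(reads, idx)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_unmapped_fastq(aln, fq, reads)
  back <- read_fastq(fq)
  expect_identical(nrow(back), 1L)
  expect_identical(back$seq, reads[2])
})
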