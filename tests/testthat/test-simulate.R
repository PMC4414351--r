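test_that("backbones are repeat-free at the requested composition", {
  bb <- make_backbone(20000, gc = 0.5, seed = 51)
  expect_identical(nchar(bb), 20000L)
  motifs <- c(as.character(suppressWarnings(cyclic_rotations("TTAGGG"))),
              as.character(suppressWarnings(cyclic_rotations("CCCTAA"))))
  for (m in motifs) expect_false(grepl(m, bb, fixed = TRUE))
  gc <- nchar(gsub("[^GC]", "", bb)) / 20000
  expect_lt(abs(gc - 0.5), 0.02)
  # determinism
  expect_identical(bb, make_backbone(20000, gc = 0.5, seed = 51))
  # single-base patterns cannot be excluded from a four-letter alphabet
  expect_error(make_backbone(100, pattern = "A", seed = 1), "constraint")
})

test_that("exact telomeres tile the pattern from both termini", {
  bb <- make_backbone(1000, seed = 52)
  g <- attach_telomeres(bb, length_mean = 6000, length_sd = 0)
  expect_identical(g$left_telomere_length, 6000L)
  expect_identical(g$right_telomere_length, 6000L)
  expect_identical(g$true_mtl, 6000)
  expect_identical(nchar(g$sequence), 13000L)
  left <- substr(g$sequence, 1, 6000)
  right <- substr(g$sequence, 7001, 13000)
  expect_identical(count_repeats(left, "TTAGGG"), 1000L)   # 1000 full units
  expect_identical(count_repeats(right, "CCCTAA"), 1000L)
  # the right telomere read in reverse complement is a pure G-strand tiling
  expect_identical(count_repeats(revcomp(right), "TTAGGG"), 1000L)
})

test_that("telomere lengths follow the truncated normal", {
  set.seed(53)
  bb <- strrep("AC", 30)
  draws <- unlist(lapply(1:800, function(i) {
    g <- attach_telomeres(bb, length_mean = 10000, length_sd = 7000)
    c(g$left_telomere_length, g$right_telomere_length)
  }))
  expect_true(all(draws >= 0))
  # closed-form mean of Normal(10000, 7000) truncated below at 0
  a <- -10000 / 7000
  mu_trunc <- 10000 + 7000 * dnorm(a) / (1 - pnorm(a))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu_trunc), 4 * se)
  # the bulk of the distribution spans the expected range
  expect_gt(diff(range(draws)), 15000)
})

test_that("error-free reads are exact genome substrings at the requested depth", {
  bb <- make_backbone(9900, seed = 54)
  g <- attach_telomeres(bb, length_mean = 51, length_sd = 0)
  reads <- simulate_reads(g, rl = 100, coverage = 1, error_rate = 0, seed = 55)
  expect_identical(nrow(reads), 100L)  # round(1 * 10002 / 100)
  for (s in reads$seq[1:25]) {
    expect_true(grepl(s, g$sequence, fixed = TRUE) ||
                grepl(revcomp(s), g$sequence, fixed = TRUE))
  }
  # coverage accounting within one read
  expect_lte(abs(sum(nchar(reads$seq)) - 1 * nchar(g$sequence)), 100)
})

test_that("substitution errors occur at the configured rate", {
  genome <- strrep("A", 20000)
  reads <- simulate_reads(genome, rl = 20, coverage = 10, error_rate = 0.01,
                          seed = 56)
  n_bases <- sum(nchar(reads$seq))
  # each read is all-A (forward) or all-T (reverse complement)
  subs <- sum(vapply(reads$seq, function(s) {
    min(nchar(gsub("A", "", s)), nchar(gsub("T", "", s)))
  }, numeric(1)))
  ci <- qbinom(c(0.005, 0.995), n_bases, 0.01)
  expect_gte(subs, ci[1])
  expect_lte(subs, ci[2])
})

test_that("paired layout emits FR mates at the requested insert size", {
  bb <- make_backbone(50000, seed = 57)
  g <- attach_telomeres(bb, length_mean = 2000, length_sd = 0)
  reads <- simulate_reads(g, rl = 76, coverage = 1, layout = "paired",
                          insert_mean = 300, insert_sd = 30,
                          error_rate = 0, seed = 58)
  expect_identical(sort(unique(reads$mate)), c(1L, 2L))
  expect_lte(abs(nrow(reads) * 76 - nchar(g$sequence)), 2 * 76)
  # every mate is a genome substring in one orientation
  for (s in reads$seq[1:20])
    expect_true(grepl(s, g$sequence, fixed = TRUE) ||
                grepl(revcomp(s), g$sequence, fixed = TRUE))
  # mates of a pair come from opposite strands of one fragment
  p1 <- reads[reads$mate == 1L, ]; p2 <- reads[reads$mate == 2L, ]
  expect_identical(p1$id, p2$id)
  gap <- abs(p2$start - p1$start) + 76L
  expect_lt(abs(mean(gap) - 300), 10)
})

test_that("excluded grid combinations raise configuration errors", {
  g <- strrep("ACGT", 500)
  for (bad in list(c(100, 200), c(150, 200), c(150, 300))) {
    expect_error(simulate_reads(g, rl = bad[1], coverage = 0.5,
                                layout = "paired", insert_mean = bad[2]),
                 "configuration error")
  }
  # allowed combination passes validation
  expect_s3_class(simulate_reads(g, rl = 100, coverage = 0.5,
                                 layout = "paired", insert_mean = 300,
                                 insert_sd = 10, seed = 1),
                  "sim_reads")
})

test_that("duplicates copy already-emitted reads", {
  bb <- make_backbone(5000, seed = 59)
  g <- attach_telomeres(bb, length_mean = 500, length_sd = 0)
  reads <- simulate_reads(g, rl = 36, coverage = 2, duplicate_fraction = 0.05,
                          error_rate = 0.002, seed = 60)
  n_primary <- as.integer(round(2 * nchar(g$sequence) / 36))
  n_dup <- as.integer(round(0.05 * n_primary))
  expect_identical(nrow(reads), n_primary + n_dup)
  dups <- grepl("_dup", reads$id)
  expect_identical(sum(dups), n_dup)
  expect_true(all(reads$seq[dups] %in% reads$seq[!dups]))
})

test_that("simulation is byte-identical under a fixed seed", {
  bb <- make_backbone(5000, seed = 61)
  g <- attach_telomeres(bb, length_mean = 1000, length_sd = 200, seed = 62)
  r1 <- simulate_reads(g, rl = 36, coverage = 2, seed = 63)
  r2 <- simulate_reads(g, rl = 36, coverage = 2, seed = 63)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the manifest records ground truth and configuration", {
  bb <- make_backbone(5000, seed = 64)
  g <- attach_telomeres(bb, length_mean = 800, length_sd = 0)
  reads <- simulate_reads(g, rl = 51, coverage = 1, seed = 65)
  man <- attr(reads, "manifest")
  expect_identical(man$rl, 51L)
  expect_identical(man$true_mtl, g$true_mtl)
  expect_identical(man$left_telomere_length, g$left_telomere_length)
  expect_identical(man$genome_length, nchar(g$sequence))
  json <- withr::local_tempfile(fileext = ".json")
  write_manifest(reads, json)
  back <- jsonlite::read_json(json)
  expect_identical(back$rl, 51L)
  expect_equal(back$true_mtl, g$true_mtl)
})

test_that("genome FASTA export round-trips", {
  bb <- make_backbone(2000, seed = 66)
  g <- attach_telomeres(bb, length_mean = 300, length_sd = 0)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(g, path)
  x <- Biostrings::readDNAStringSet(path)
  expect_identical(as.character(x[[1]]), g$sequence)
})
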