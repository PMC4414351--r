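# FASTQ I/O.  Reading is chunked over a gzfile() connection (which also
# accepts plain text), so arbitrarily large files can be processed without
# holding them in memory, and malformed records are reported with their line
# number.

#' Apply a function to a FASTQ file in chunks
#'
#' Parses `path` (plain or gzip FASTQ) in blocks of `chunk_size` records and
#' calls `fun(chunk)` on each, where `chunk` is a data frame with columns
#' `id`, `seq`, `qual`.  Malformed records — a truncated 4-line block, a
#' header not starting with `@`, a separator not starting with `+`, or a
#' quality string whose length differs from the sequence — abort with an
#' error naming the offending line/record.
#'
#' @param path FASTQ file path.
#' @param fun function of one argument (the chunk data frame).
#' @param chunk_size number of records per chunk.
#' @return The total number of records processed, invisibly.
#' @export
fastq_chunk_apply <- function(path, fun, chunk_size = 50000L) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  line_no <- 0L
  n_records <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop(sprintf("malformed FASTQ in '%s': truncated record near line %d",
                   path, line_no + length(lines)), call. = FALSE)
    i <- seq(1L, length(lines), by = 4L)
    hdr <- lines[i]; seqs <- lines[i + 1L]
    sep <- lines[i + 2L]; quals <- lines[i + 3L]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad) > 0L)
      stop(sprintf("malformed FASTQ in '%s': line %d does not start with '@'",
                   path, line_no + (bad[1L] - 1L) * 4L + 1L), call. = FALSE)
    bad <- which(!startsWith(sep, "+"))
    if (length(bad) > 0L)
      stop(sprintf("malformed FASTQ in '%s': line %d does not start with '+'",
                   path, line_no + (bad[1L] - 1L) * 4L + 3L), call. = FALSE)
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad) > 0L) {
      id <- sub("^@", "", sub("\\s.*$", "", hdr[bad[1L]]))
      stop(sprintf(
        "malformed FASTQ in '%s': record '%s' (line %d) has %d sequence vs %d quality characters",
        path, id, line_no + (bad[1L] - 1L) * 4L + 1L,
        nchar(seqs[bad[1L]]), nchar(quals[bad[1L]])), call. = FALSE)
    }
    ids <- sub("\\s.*$", "", sub("^@", "", hdr))
    fun(data.frame(id = ids, seq = seqs, qual = quals,
                   stringsAsFactors = FALSE))
    n_records <- n_records + length(i)
    line_no <- line_no + length(lines)
  }
  invisible(n_records)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file path (plain or gzip).
#' @param n_max maximum number of records to read (default all).
#' @param chunk_size parsing chunk size in records.
#' @return A data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path, n_max = Inf, chunk_size = 50000L) {
  acc <- list()
  n <- 0L
  tryCatch(
    fastq_chunk_apply(path, chunk_size = chunk_size, fun = function(chunk) {
      acc[[length(acc) + 1L]] <<- chunk
      n <<- n + nrow(chunk)
      if (n >= n_max) stop(structure(class = c("fastq_done", "condition"),
                                     list(message = "", call = NULL)))
    }),
    fastq_done = function(e) NULL)
  if (length(acc) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, acc)
  if (is.finite(n_max) && nrow(out) > n_max) out <- out[seq_len(n_max), ]
  rownames(out) <- NULL
  out
}

#' Write reads as FASTQ
#'
#' @param reads a data frame with columns `id` and `seq` (and optionally
#'   `qual`), e.g. from [simulate_reads()], or a character vector of
#'   sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param qual_char quality character used when no qualities are present
#'   (default `"I"`, Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  if (is.character(reads))
    reads <- data.frame(id = sprintf("read_%d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  quals <- if ("qual" %in% names(reads)) reads$qual
           else strrep(qual_char, nchar(reads$seq))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", quals))
  writeLines(lines, con)
  invisible(path)
}
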