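# Accuracy metrics and the simulation sweep harness.

#' Relative error of an estimate
#'
#' `(EL - L) / L`, the signed relative error of the estimated over the
#' actual telomere length.  Undefined for `L <= 0`: such records yield `NA`
#' with a warning and are excluded (with a count) by [summarize_accuracy()].
#'
#' @param EL estimated length(s).
#' @param L actual length(s).
#' @return Numeric vector of signed relative errors.
#' @export
#' @examples
#' relative_error(10500, 10000)  # 0.05
relative_error <- function(EL, L) {
  bad <- !(L > 0) | is.na(L)
  if (any(bad))
    warning(sprintf("%d record(s) with non-positive actual length excluded",
                    sum(bad)))
  out <- (EL - L) / L
  out[bad] <- NA_real_
  out
}

#' Summarise estimation accuracy over a set of runs
#'
#' Aggregates per-run records into the standard accuracy measures: MRE (the
#' signed mean of relative errors), its standard error, RMSE over the raw
#' errors `EL - L`, and the coefficient of determination R-squared of the
#' ordinary least squares fit of `EL` on `L`.  An identity-line variant of
#' R-squared (`1 - sum((EL-L)^2) / sum((EL - mean(EL))^2)`) is also
#' reported for transparency; the OLS version is the headline statistic.
#'
#' @param records data frame with columns `L` (actual) and `EL`
#'   (estimated), one row per run.
#' @return An object of class `accuracy_report`: a list with `records`
#'   (the input plus a `rel_error` column), `n`, `n_excluded`, `mre`, `se`,
#'   `rmse`, `r_squared` and `r_squared_identity`.  `r_squared` is `NA`
#'   with fewer than two usable records.
#' @export
summarize_accuracy <- function(records) {
  stopifnot(is.data.frame(records), all(c("L", "EL") %in% names(records)))
  rel <- suppressWarnings(relative_error(records$EL, records$L))
  records$rel_error <- rel
  keep <- !is.na(rel)
  n <- sum(keep)
  L <- records$L[keep]; EL <- records$EL[keep]; rel <- rel[keep]
  mre <- if (n > 0L) mean(rel) else NA_real_
  se <- if (n > 1L) sd(rel) / sqrt(n) else NA_real_
  rmse <- if (n > 0L) sqrt(mean((EL - L)^2)) else NA_real_
  r2 <- if (n >= 2L && stats::var(L) > 0)
    summary(lm(EL ~ L))$r.squared else NA_real_
  r2_id <- if (n >= 2L && stats::var(EL) > 0)
    1 - sum((EL - L)^2) / sum((EL - mean(EL))^2) else NA_real_
  structure(list(records = records, n = n, n_excluded = sum(!keep),
                 mre = mre, se = se, rmse = rmse, r_squared = r2,
                 r_squared_identity = r2_id),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Accuracy report\n")
  cat(sprintf("  runs:  %d (%d excluded)\n", x$n, x$n_excluded))
  cat(sprintf("  MRE:   %+.3f%% (SE %.3f%%)\n", 100 * x$mre, 100 * x$se))
  cat(sprintf("  RMSE:  %.1f bp\n", x$rmse))
  cat(sprintf("  R2:    %.4f (OLS), %.4f (identity line)\n",
              x$r_squared, x$r_squared_identity))
  invisible(x)
}

#' Run a simulate-and-estimate sweep
#'
#' For every combination of read length and coverage (times `replicates`),
#' attaches fresh telomeres of random length to a shared backbone,
#' simulates reads, estimates the mean telomere length with
#' [tel_estimate()], and records the true and estimated lengths.
#' Deterministic given `seed`.
#'
#' @param read_lengths,coverages grid axes.
#' @param layout `"single"` or `"paired"`.
#' @param insert_mean,insert_sd insert-size distribution (paired only);
#'   the excluded grid combinations raise a configuration error up front.
#' @param replicates runs per grid cell.
#' @param backbone_length backbone length in bp (the validation design uses
#'   200 kb).
#' @param gc backbone GC fraction.
#' @param pattern telomeric repeat pattern.
#' @param telomere_mean,telomere_sd telomere-length distribution (bp).
#' @param error_rate per-base substitution probability.
#' @param duplicate_fraction duplicate-read fraction.
#' @param min_seed minimum telomeric overlap (default `min(rl, 12)`).
#' @param seed optional RNG seed.
#' @return An object of class `sweep_result`: a list with `runs` (one row
#'   per run: grid cell, replicate, `L`, `EL`, `rel_error`, read counts)
#'   and `summary` (an `accuracy_report` pooled over all runs).
#' @export
run_sweep <- function(read_lengths = c(36L, 76L, 100L),
                      coverages = c(1, 5, 30),
                      layout = c("single", "paired"),
                      insert_mean = 500, insert_sd = 200,
                      replicates = 3L, backbone_length = 200000L,
                      gc = 0.5, pattern = "TTAGGG",
                      telomere_mean = 10000, telomere_sd = 7000,
                      error_rate = 0.002, duplicate_fraction = 0,
                      min_seed = NULL, seed = NULL) {
  layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  for (rl in read_lengths) check_sim_config(rl, layout, insert_mean)

  backbone <- make_backbone(backbone_length, gc = gc, pattern = pattern)
  rows <- list()
  for (rl in read_lengths) {
    for (cov in coverages) {
      for (rep_i in seq_len(replicates)) {
        genome <- attach_telomeres(backbone, pattern = pattern,
                                   length_mean = telomere_mean,
                                   length_sd = telomere_sd)
        reads <- simulate_reads(genome, rl = rl, coverage = cov,
                                layout = layout,
                                insert_mean = insert_mean,
                                insert_sd = insert_sd,
                                error_rate = error_rate,
                                duplicate_fraction = duplicate_fraction)
        est <- tel_estimate(reads = reads$seq, pattern = pattern, rl = rl,
                            min_seed = min_seed, n_chr = genome$n_chr,
                            genome_length = nchar(genome$sequence))
        rows[[length(rows) + 1L]] <- data.frame(
          rl = rl, coverage = cov, replicate = rep_i, layout = layout,
          L = genome$true_mtl, EL = est$mtl,
          rel_error = (est$mtl - genome$true_mtl) / genome$true_mtl,
          reads_total = est$reads_total,
          reads_telomeric = est$reads_telomeric,
          stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, summary = summarize_accuracy(runs)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %d runs (%s-end)\n", nrow(x$runs),
              x$runs$layout[1L]))
  print(x$summary)
  invisible(x)
}

#' Write sweep results as TSV
#'
#' Writes the per-run table to `runs_path` and, when given, the pooled
#' summary to `summary_path`.
#'
#' @param sweep a [run_sweep()] result.
#' @param runs_path per-run TSV path.
#' @param summary_path optional pooled-summary TSV path.
#' @return `runs_path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, runs_path, summary_path = NULL) {
  write.table(sweep$runs, runs_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- sweep$summary
    df <- data.frame(n = s$n, mre = s$mre, se = s$se, rmse = s$rmse,
                     r_squared = s$r_squared,
                     r_squared_identity = s$r_squared_identity)
    write.table(df, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(runs_path)
}
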