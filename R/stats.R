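#' Pearson correlation between bulk RIN and averaged sRIN
#'
#' Correlates paired per-sample bulk RIN values with sample-level averaged
#' sRIN (mean of technical-replicate medians), via `stats::cor.test`. With
#' `n` paired samples the test statistic is
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, with a
#' two-sided p-value.
#'
#' @param bulk_rin Numeric vector of bulk RIN values, or a list of
#'   `sample_summary` objects carrying `bulk_rin` (then `averaged_srin` may
#'   be omitted).
#' @param averaged_srin Numeric vector of paired averaged sRIN values.
#' @return A `correlation_result` with `r`, `n`, `df`, `t_stat`, `p_value`.
#' @export
correlate_rin_srin <- function(bulk_rin, averaged_srin = NULL) {
  if (is.list(bulk_rin) && all(vapply(bulk_rin, inherits, logical(1),
                                      "sample_summary"))) {
    summaries <- bulk_rin
    bulk_rin <- vapply(summaries, function(s) {
      if (is.null(s$bulk_rin)) {
        stop("sample_summary without a paired bulk RIN value", call. = FALSE)
      }
      s$bulk_rin
    }, numeric(1))
    averaged_srin <- vapply(summaries, `[[`, numeric(1), "averaged_srin")
  }
  x <- as.numeric(bulk_rin)
  y <- as.numeric(averaged_srin)
  if (length(x) != length(y)) stop("inputs must be paired", call. = FALSE)
  if (length(x) < 3L) {
    stop("at least 3 paired samples are required", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("all values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one coordinate; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 df = unname(ct$parameter),
                 t_stat = unname(ct$statistic),
                 p_value = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result: r = %.4f (n = %d, df = %d), t = %.3f, p = %.4g>\n",
    x$r, x$n, x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' Per-probe hybridization efficiency table
#'
#' Averages raw fluorescence (FU) within each capture area, yielding one
#' efficiency estimate per probe per area (e.g. six areas give six estimates
#' per probe).
#'
#' @param fu_measurements Nested named list: per probe, a named list of
#'   per-capture-area FU vectors or matrices.
#' @return An `efficiency_table`: data frame with columns `probe`, `area`,
#'   `mean_fu`.
#' @export
hybridization_efficiency <- function(fu_measurements) {
  stopifnot(is.list(fu_measurements), length(fu_measurements) >= 1L)
  rows <- lapply(names(fu_measurements), function(probe) {
    areas <- fu_measurements[[probe]]
    stopifnot(is.list(areas), length(areas) >= 1L)
    means <- vapply(names(areas), function(a) {
      v <- as.numeric(areas[[a]])
      if (length(v) == 0L || any(!is.finite(v))) {
        stop(sprintf("empty or non-finite FU measurements for probe %s, area %s",
                     probe, a), call. = FALSE)
      }
      mean(v)
    }, numeric(1))
    data.frame(probe = probe, area = names(areas), mean_fu = unname(means),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Positive-pixel fraction per probe
#'
#' For each probe, counts valid non-misaligned pixels whose normalized
#' signal exceeds background plus threshold (`R_i > 0`) and divides by the
#' corresponding probe-1 count, so the fractions trace signal drop-off along
#' the c18RNA (fraction 1 is 1 by construction).
#'
#' @param map An `srin_map` from [compute_srin()].
#' @return Named numeric vector `c(P1 = 1, P2 = ..., P3 = ..., P4 = ...)`
#'   with the per-probe positive counts in attribute `"counts"`.
#' @export
positive_pixel_fractions <- function(map) {
  stopifnot(inherits(map, "srin_map"))
  use <- map$valid_mask & !map$misaligned_mask
  counts <- vapply(map$ratios, function(r) {
    sum(r[use] > 0, na.rm = TRUE)
  }, numeric(1))
  if (counts[1] == 0) {
    stop("no positive probe-1 pixels; fractions undefined", call. = FALSE)
  }
  fractions <- counts / counts[1]
  names(fractions) <- paste0("P", 1:4)
  attr(fractions, "counts") <- stats::setNames(counts, paste0("P", 1:4))
  fractions
}

#' Exon/intergenic read ratio
#'
#' Quality summary of a sequencing library: reads annotated to exons
#' divided by reads discarded as unannotatable (used as an intergenic
#' estimate). Counting itself is upstream; this consumes the two totals.
#'
#' @param annotated_reads Number of successfully annotated (exonic) reads.
#' @param discarded_reads Number of discarded (intergenic) reads; must be
#'   positive.
#' @return The ratio `annotated_reads / discarded_reads`.
#' @export
exon_intergenic_ratio <- function(annotated_reads, discarded_reads) {
  stopifnot(is.numeric(annotated_reads), is.numeric(discarded_reads),
            length(annotated_reads) == 1L, length(discarded_reads) == 1L)
  if (annotated_reads < 0 || discarded_reads < 0) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (discarded_reads == 0) {
    stop("discarded (intergenic) read count must be positive",
         call. = FALSE)
  }
  annotated_reads / discarded_reads
}
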