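#' Signal-to-noise threshold from the background scan
#'
#' The threshold is the `q`-th quantile of the P0 (pre-probe background
#' autofluorescence) intensity distribution, computed with the
#' linear-interpolation quantile definition (R type 7) so results are
#' bit-reproducible. The default `q = 0.75` suits most samples; for cells
#' expected to hold little total RNA, `q = 0.30` keeps weak but genuine
#' signal above the threshold.
#'
#' @param p0 The P0 [probe_image()] (or a numeric matrix).
#' @param q Quantile in `[0, 1]`.
#' @return A `threshold_spec` with fields `q` and `T` (FU).
#' @export
compute_threshold <- function(p0, q = 0.75) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop("`q` must be a single value in [0, 1]", call. = FALSE)
  }
  px <- if (inherits(p0, "probe_image")) p0$pixels else as.matrix(p0)
  if (length(px) == 0L) stop("P0 is empty", call. = FALSE)
  thr <- unname(stats::quantile(as.numeric(px), probs = q, type = 7))
  structure(list(q = q, T = thr), class = "threshold_spec")
}

#' Pixel-wise normalization field
#'
#' The normalization dataset `N = P1 - P0 - T`: probe 1 signal with the
#' background scan and the signal-to-noise threshold subtracted. Pixels with
#' `N <= 0` carry no detectable footprint signal and are marked invalid;
#' they stay masked throughout scoring rather than being set to zero, so
#' background never dilutes sample summaries.
#'
#' @param p1,p0 The P1 and P0 [probe_image()]s (or numeric matrices).
#' @param threshold A `threshold_spec` from [compute_threshold()], or a
#'   scalar threshold in FU.
#' @return A `normalization_field` with fields `N` (FU) and `valid_mask`
#'   (`N > 0`).
#' @export
compute_normalization <- function(p1, p0, threshold) {
  thr <- if (inherits(threshold, "threshold_spec")) threshold$T else threshold
  m1 <- if (inherits(p1, "probe_image")) p1$pixels else as.matrix(p1)
  m0 <- if (inherits(p0, "probe_image")) p0$pixels else as.matrix(p0)
  if (!identical(dim(m1), dim(m0))) {
    stop("P1 and P0 shapes differ", call. = FALSE)
  }
  n <- m1 - m0 - thr
  structure(list(N = n, valid_mask = n > 0, threshold = thr),
            class = "normalization_field")
}

#' Normalize one probe scan against the normalization field
#'
#' On valid pixels the normalized ratio is
#' `R_i = (P_i - P0 - T) / N`, putting probe `i`'s signal on a 0-1 detection
#' scale anchored by probe 1 (`R_1` is identically 1 by construction).
#' Invalid pixels are `NA`.
#'
#' @param pi_img Probe scan `P1`..`P4` ([probe_image()] or matrix).
#' @param p0 The P0 scan.
#' @param field A `normalization_field` from [compute_normalization()].
#' @return Numeric matrix of ratios, `NA` where the field is invalid.
#' @export
normalize_probe <- function(pi_img, p0, field) {
  stopifnot(inherits(field, "normalization_field"))
  mi <- if (inherits(pi_img, "probe_image")) pi_img$pixels else as.matrix(pi_img)
  m0 <- if (inherits(p0, "probe_image")) p0$pixels else as.matrix(p0)
  if (!identical(dim(mi), dim(field$N)) || !identical(dim(m0), dim(field$N))) {
    stop("probe image shape differs from the normalization field",
         call. = FALSE)
  }
  r <- (mi - m0 - field$threshold) / field$N
  r[!field$valid_mask] <- NA_real_
  r
}

#' Compute the per-pixel sRIN map
#'
#' Scores RNA completeness pixel by pixel from a registered five-round
#' stack. Each probe contributes up to 2.5 points: its normalized ratio is
#' floored at 0 (signal below background carries no evidence) and capped at
#' 1 before summation, so the clipped score spans 2.5 (only probe 1
#' detected) to 10 (all four probes fully detected). The unclipped raw sum
#' is kept as a registration diagnostic: under correct alignment no pixel
#' can exceed 10, so `raw > 10` flags inter-round misalignment. Flagged
#' pixels are excluded from sample summaries and positive-pixel counts.
#'
#' @param stack A registered [probe_stack()].
#' @param q Background quantile for [compute_threshold()] (default 0.75).
#' @return An `srin_map` with fields `srin` (clipped 0-10 score, `NA` where
#'   masked), `raw` (unclipped score), `valid_mask`, `misaligned_mask`
#'   (`raw > 10`), `ratios` (list `R1`..`R4`), `threshold` and `q`.
#' @export
compute_srin <- function(stack, q = 0.75) {
  stopifnot(inherits(stack, "probe_stack"))
  p0 <- stack_pixels(stack, "P0")
  thr <- compute_threshold(p0, q)
  field <- compute_normalization(stack_pixels(stack, "P1"), p0, thr)
  if (!any(field$valid_mask)) {
    warning("no pixel exceeds background + threshold; map is fully masked",
            call. = FALSE)
  }
  ratios <- lapply(1:4, function(i) {
    normalize_probe(stack_pixels(stack, paste0("P", i)), p0, field)
  })
  names(ratios) <- paste0("R", 1:4)
  raw <- srin_val <- matrix(0, stack$shape[1], stack$shape[2])
  for (r in ratios) {
    pos <- pmax(r, 0)
    raw <- raw + pos
    srin_val <- srin_val + pmin(pos, 1)
  }
  raw <- 2.5 * raw
  srin_val <- 2.5 * srin_val
  raw[!field$valid_mask] <- NA_real_
  srin_val[!field$valid_mask] <- NA_real_
  misaligned <- field$valid_mask & !is.na(raw) & raw > 10
  structure(list(srin = srin_val, raw = raw,
                 valid_mask = field$valid_mask,
                 misaligned_mask = misaligned,
                 ratios = ratios, threshold = thr$T, q = thr$q),
            class = "srin_map")
}

#' @export
print.srin_map <- function(x, ...) {
  nv <- sum(x$valid_mask)
  cat(sprintf(
    "<srin_map: %d x %d px, %d valid (%.1f%%), %d misaligned, q=%g, T=%g>\n",
    nrow(x$srin), ncol(x$srin), nv, 100 * nv / length(x$srin),
    sum(x$misaligned_mask), x$q, x$threshold))
  invisible(x)
}

#' Spatial misalignment diagnostic
#'
#' Pixels whose unclipped score exceeds 10 indicate inter-round registration
#' error. Under a mere handful of randomly scattered artifacts their spatial
#' distribution over a `G x G` partition should be even (proportional to
#' where valid pixels lie); systematic misregistration concentrates them. A
#' chi-square goodness-of-fit test compares flagged counts per cell with
#' expectation proportional to the per-cell valid-pixel totals. Cells
#' without valid pixels are excluded; cells with expected count below 5 are
#' merged with their next neighbor (row-major order) before the test.
#'
#' @param map An `srin_map` from [compute_srin()].
#' @param grid_size Number of partition cells per image side (default 8).
#' @return A `misalignment_report` with `flagged_fraction` (flagged / valid
#'   pixels), `grid_counts` (`G x G` flagged counts), `valid_counts`,
#'   `uniformity_stat`, `df` and `p_value`.
#' @export
detect_misalignment <- function(map, grid_size = 8L) {
  stopifnot(inherits(map, "srin_map"), grid_size >= 1L)
  nv_total <- sum(map$valid_mask)
  if (nv_total == 0L) {
    stop("map has no valid pixels; cannot assess misalignment",
         call. = FALSE)
  }
  g <- as.integer(grid_size)
  h <- nrow(map$srin)
  w <- ncol(map$srin)
  row_bin <- pmin(((seq_len(h) - 1L) * g) %/% h, g - 1L) + 1L
  col_bin <- pmin(((seq_len(w) - 1L) * g) %/% w, g - 1L) + 1L
  cell <- matrix(row_bin, h, w) + g * (matrix(col_bin, h, w, byrow = TRUE) - 1L)
  tab <- function(mask) {
    counts <- tabulate(cell[mask], nbins = g * g)
    matrix(counts, g, g)
  }
  valid_counts <- tab(map$valid_mask)
  grid_counts <- tab(map$misaligned_mask)
  n_flagged <- sum(grid_counts)
  keep <- as.vector(valid_counts) > 0L
  obs <- as.vector(grid_counts)[keep]
  expd <- n_flagged * as.vector(valid_counts)[keep] / nv_total
  if (n_flagged == 0L) {
    stat <- 0
    df <- max(length(obs) - 1L, 0L)
    p <- 1
  } else {
    merged <- merge_low_expected(obs, expd, min_expected = 5)
    if (length(merged$obs) <= 1L) {
      stat <- 0
      df <- 0L
      p <- 1
    } else {
      stat <- sum((merged$obs - merged$expected)^2 / merged$expected)
      df <- length(merged$obs) - 1L
      p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    }
  }
  structure(list(flagged_fraction = n_flagged / nv_total,
                 grid_counts = grid_counts,
                 valid_counts = valid_counts,
                 grid_size = g,
                 uniformity_stat = stat, df = df, p_value = p),
            class = "misalignment_report")
}

# Standard chi-square validity rule: pool adjacent classes until every
# expected count reaches min_expected (or one class remains).
merge_low_expected <- function(obs, expected, min_expected = 5) {
  while (length(obs) > 1L && any(expected < min_expected)) {
    i <- which(expected < min_expected)[1]
    j <- if (i < length(obs)) i + 1L else i - 1L
    obs[j] <- obs[j] + obs[i]
    expected[j] <- expected[j] + expected[i]
    obs <- obs[-i]
    expected <- expected[-i]
  }
  list(obs = obs, expected = expected)
}

#' @export
print.misalignment_report <- function(x, ...) {
  cat(sprintf(
    "<misalignment_report: %.3f%% of valid pixels flagged; chi-square %.2f on %d df, p = %.3g>\n",
    100 * x$flagged_fraction, x$uniformity_stat, x$df, x$p_value))
  invisible(x)
}

#' Summarize technical replicates into one sample-level sRIN value
#'
#' For each replicate map the median clipped score over valid,
#' non-misaligned pixels is taken; the sample value is the mean of those
#' replicate medians.
#'
#' @param maps A list of `srin_map` objects (technical replicates), or one
#'   map.
#' @param sample_id Optional sample identifier.
#' @param bulk_rin Optional paired bulk RIN value for later correlation.
#' @return A `sample_summary` with `replicate_medians`, `averaged_srin`,
#'   `sample_id` and `bulk_rin`.
#' @export
summarize_sample <- function(maps, sample_id = NULL, bulk_rin = NULL) {
  if (inherits(maps, "srin_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  medians <- vapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    stopifnot(inherits(m, "srin_map"))
    use <- m$valid_mask & !m$misaligned_mask
    if (!any(m$valid_mask)) {
      stop(sprintf("replicate %d has no valid pixels", i), call. = FALSE)
    }
    if (!any(use)) {
      stop(sprintf("replicate %d has no usable (non-misaligned) pixels", i),
           call. = FALSE)
    }
    stats::median(m$srin[use])
  }, numeric(1))
  structure(list(sample_id = sample_id,
                 replicate_medians = medians,
                 averaged_srin = mean(medians),
                 bulk_rin = bulk_rin),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary%s: averaged sRIN %.3f over %d replicate(s)%s>\n",
              if (is.null(x$sample_id)) "" else paste0(" ", x$sample_id),
              x$averaged_srin, length(x$replicate_medians),
              if (is.null(x$bulk_rin)) "" else
                sprintf(", bulk RIN %.2f", x$bulk_rin)))
  invisible(x)
}
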