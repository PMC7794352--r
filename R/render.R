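#' Render an sRIN map as a heat-map image
#'
#' Writes an RGB PNG of the clipped score with a fixed 0-10 color scale, so
#' heat maps from different samples are directly comparable (no per-image
#' autoscaling). Masked pixels are drawn in the background color. A vertical
#' color-bar legend spanning the full 0-10 scale (bottom to top) is embedded
#' at the right edge.
#'
#' @param map An `srin_map` from [compute_srin()].
#' @param path Output PNG path.
#' @param colormap Palette name accepted by [grDevices::hcl.colors()]
#'   (default `"Viridis"`).
#' @param background Background color for masked pixels.
#' @param legend Embed the color-bar legend strip (default `TRUE`).
#' @return Invisibly, a list with `path` and the RGB `array` written.
#' @export
render_heatmap <- function(map, path, colormap = "Viridis",
                           background = "#1a1a1a", legend = TRUE) {
  stopifnot(inherits(map, "srin_map"))
  if (length(map$srin) == 0L) stop("empty map", call. = FALSE)
  pal <- grDevices::hcl.colors(256, colormap)
  pal_rgb <- grDevices::col2rgb(pal) / 255
  bg_rgb <- grDevices::col2rgb(background)[, 1] / 255
  h <- nrow(map$srin)
  w <- ncol(map$srin)
  score <- pmin(pmax(map$srin, 0), 10)
  idx <- 1L + as.integer(round(score / 10 * 255))
  rgb_arr <- array(0, dim = c(h, w, 3))
  masked <- is.na(map$srin)
  for (ch in 1:3) {
    plane <- matrix(bg_rgb[ch], h, w)
    plane[!masked] <- pal_rgb[ch, idx[!masked]]
    rgb_arr[, , ch] <- plane
  }
  if (legend) {
    bar_w <- max(6L, w %/% 16L)
    gap_w <- 2L
    bar_idx <- 1L + as.integer(round(
      (rev(seq_len(h)) - 1) / max(h - 1, 1) * 255))  # 10 on top, 0 at bottom
    strip <- array(0, dim = c(h, gap_w + bar_w, 3))
    for (ch in 1:3) {
      strip[, seq_len(gap_w), ch] <- bg_rgb[ch]
      strip[, gap_w + seq_len(bar_w), ch] <- pal_rgb[ch, bar_idx]
    }
    full <- array(0, dim = c(h, w + gap_w + bar_w, 3))
    full[, seq_len(w), ] <- rgb_arr
    full[, w + seq_len(gap_w + bar_w), ] <- strip
    rgb_arr <- full
  }
  png::writePNG(rgb_arr, path)
  invisible(list(path = path, array = rgb_arr))
}

#' Render the spatial misalignment diagnostic plot
#'
#' Draws flagged pixels (unclipped score above 10) in red over a gray
#' tissue outline (the valid-pixel mask), with the diagnostic grid, the
#' flagged count per grid cell, and a caption giving the flagged fraction
#' and the chi-square uniformity p-value. An even spread of flags indicates
#' benign scattered artifacts; clustering (small p) indicates systematic
#' inter-round misregistration worth re-aligning.
#'
#' @param report A `misalignment_report` from [detect_misalignment()].
#' @param map The `srin_map` the report was computed from.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
render_misalignment <- function(report, map, path) {
  stopifnot(inherits(report, "misalignment_report"),
            inherits(map, "srin_map"))
  h <- nrow(map$srin)
  w <- ncol(map$srin)
  rgb_arr <- array(0.08, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- rgb_arr[, , ch]
    plane[map$valid_mask] <- 0.45
    rgb_arr[, , ch] <- plane
  }
  flag <- map$misaligned_mask
  rgb_arr[, , 1][flag] <- 1
  rgb_arr[, , 2][flag] <- 0.1
  rgb_arr[, , 3][flag] <- 0.1
  g <- report$grid_size
  grDevices::png(path, width = max(480, w * 4), height = max(520, h * 4 + 40))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3.5, 1, 2.5, 1))
  graphics::plot(NA, xlim = c(0, w), ylim = c(0, h), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Misalignment diagnostic (unclipped score > 10)")
  graphics::rasterImage(rgb_arr, 0, 0, w, h, interpolate = FALSE)
  graphics::abline(v = seq(0, w, length.out = g + 1),
                   h = seq(0, h, length.out = g + 1),
                   col = "#ffffff55")
  centers_x <- (seq_len(g) - 0.5) * w / g
  centers_y <- h - (seq_len(g) - 0.5) * h / g
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      n <- report$grid_counts[i, j]
      if (n > 0) {
        graphics::text(centers_x[j], centers_y[i], n,
                       col = "white", cex = 0.8)
      }
    }
  }
  graphics::mtext(sprintf(
    "flagged %.3f%% of valid pixels; uniformity chi-square %.2f (df %d), p = %.3g",
    100 * report$flagged_fraction, report$uniformity_stat,
    report$df, report$p_value), side = 1, line = 1.5, cex = 0.9)
  invisible(path)
}

#' Write a misalignment report as a CSV table
#'
#' One row per grid cell (row-major), with flagged and valid pixel counts,
#' plus summary columns repeated on each row for self-containment.
#'
#' @param report A `misalignment_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_misalignment_csv <- function(report, path) {
  stopifnot(inherits(report, "misalignment_report"))
  g <- report$grid_size
  df <- data.frame(
    cell_row = rep(seq_len(g), g),
    cell_col = rep(seq_len(g), each = g),
    flagged = as.vector(report$grid_counts),
    valid = as.vector(report$valid_counts),
    flagged_fraction = report$flagged_fraction,
    uniformity_stat = report$uniformity_stat,
    df = report$df,
    p_value = report$p_value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
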