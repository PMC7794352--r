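# Translate a matrix by (dx, dy) and keep the crop rectangle.
# Convention (documented in alignment_spec): the offset moves image content
# dx columns right and dy rows down; crop is 0-based half-open.
shift_crop <- function(mat, offset, crop) {
  dx <- offset[["dx"]]
  dy <- offset[["dy"]]
  rows0 <- crop[1]:(crop[2] - 1L) - dy   # 0-based source rows
  cols0 <- crop[3]:(crop[4] - 1L) - dx
  if (rows0[1] < 0L || rows0[length(rows0)] >= nrow(mat) ||
      cols0[1] < 0L || cols0[length(cols0)] >= ncol(mat)) {
    stop("crop rectangle falls outside a shifted image ",
         sprintf("(offset dx=%d dy=%d, image %dx%d)", dx, dy,
                 nrow(mat), ncol(mat)),
         call. = FALSE)
  }
  mat[rows0 + 1L, cols0 + 1L, drop = FALSE]
}

#' Apply per-round translations and a common crop to a probe stack
#'
#' Each round is translated by its offset (content moves `dx` columns right
#' and `dy` rows down) and the shared crop rectangle is retained, so all
#' output rounds land on a common pixel grid of shape
#' `c(row1 - row0, col1 - col0)`.
#'
#' @param stack A [probe_stack()].
#' @param spec An [alignment_spec()] whose crop lies inside every shifted
#'   image.
#' @return A registered [probe_stack()] of the crop shape.
#' @export
apply_alignment <- function(stack, spec) {
  stopifnot(inherits(stack, "probe_stack"), inherits(spec, "alignment_spec"))
  images <- lapply(srin_rounds(), function(r) {
    im <- stack$images[[r]]
    probe_image(shift_crop(im$pixels, spec$offsets[[r]], spec$crop),
                r, gain = im$gain)
  })
  names(images) <- srin_rounds()
  probe_stack(images)
}

#' Estimate inter-round translation offsets by cross-correlation
#'
#' Estimates, for every round, the integer translation that registers it to
#' the reference round, by locating the peak of the FFT cross-correlation of
#' mean-subtracted images. The returned offsets are corrective: feeding them
#' to [apply_alignment()] registers the stack. The reference round's offset
#' is `(0, 0)`.
#'
#' @param stack A [probe_stack()] (all rounds share one shape).
#' @param reference_round Round label used as the registration target.
#' @return An [alignment_spec()] with the estimated offsets and the largest
#'   common crop.
#' @export
estimate_offsets <- function(stack, reference_round = "P0") {
  stopifnot(inherits(stack, "probe_stack"))
  reference_round <- match.arg(reference_round, srin_rounds())
  ref <- stack_pixels(stack, reference_round)
  offsets <- lapply(srin_rounds(), function(r) {
    if (r == reference_round) return(c(dx = 0L, dy = 0L))
    d <- xcorr_peak(ref, stack_pixels(stack, r))
    c(dx = -d[["dx"]], dy = -d[["dy"]])  # corrective = minus displacement
  })
  names(offsets) <- srin_rounds()
  alignment_spec(offsets, shape = stack$shape)
}

# Displacement (dx, dy) of img relative to ref: the circular cross-correlation
# sum_a ref(a) * img(a + u) peaks at u = displacement.
xcorr_peak <- function(ref, img) {
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    stop("cannot estimate offsets from a constant image ",
         "(cross-correlation undefined)", call. = FALSE)
  }
  a <- ref - mean(ref)
  b <- img - mean(img)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L  # 0-based (row, col)
  n <- dim(cc)
  wrap <- function(u, len) if (u > len %/% 2L) u - len else u
  c(dy = wrap(peak[1], n[1]), dx = wrap(peak[2], n[2]))
}

# Read one single-channel image file; TIFF values come back as raw integer
# counts, PNG as 8-bit counts.
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path) * 255
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L) {
      stop("multi-channel image not supported: ", path,
           " has ", dim(px)[3], " channels", call. = FALSE)
    }
    px <- px[, , 1]
  }
  px
}

#' Read a five-round probe image stack from files
#'
#' Reads the P0-P4 scans of one capture area and, if an alignment is given,
#' applies the per-round translations and common crop so the result is
#' registered. Without an alignment the files must already share one shape.
#'
#' @param paths Named character vector or list with one single-channel image
#'   path per round `P0`..`P4` (TIFF or PNG).
#' @param alignment Optional [alignment_spec()]; identity if `NULL`.
#' @return A registered [probe_stack()].
#' @export
read_stack <- function(paths, alignment = NULL) {
  rounds <- srin_rounds()
  missing_rounds <- setdiff(rounds, names(paths))
  if (length(missing_rounds) > 0L) {
    stop("no file given for round(s): ",
         paste(missing_rounds, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(rounds, function(r) {
    if (!file.exists(paths[[r]])) {
      stop(sprintf("file for round %s not found: %s", r, paths[[r]]),
           call. = FALSE)
    }
    read_image(paths[[r]])
  })
  names(mats) <- rounds
  if (is.null(alignment)) {
    shapes <- vapply(mats, dim, integer(2))
    if (any(shapes != shapes[, 1])) {
      stop("image shapes differ across rounds and no alignment was given",
           call. = FALSE)
    }
    return(probe_stack(mats))
  }
  stopifnot(inherits(alignment, "alignment_spec"))
  aligned <- lapply(rounds, function(r) {
    shift_crop(mats[[r]], alignment$offsets[[r]], alignment$crop)
  })
  names(aligned) <- rounds
  probe_stack(aligned)
}

#' Write an intensity or score grid to a grayscale image file
#'
#' TIFF output is 16-bit grayscale; PNG output is 8-bit. Values are
#' multiplied by `scale` and must then lie within the bit depth's range
#' (sRIN maps use the fixed factor 1000, so scores 0-10 span 0-10000 counts).
#' Masked (`NA`) pixels are written as 0 and the mask is stored alongside in
#' `<path>_mask.<ext>` (255 = masked).
#'
#' @param pixels Numeric matrix; `NA` marks masked pixels.
#' @param path Output file path.
#' @param format `"tiff"` or `"png"`.
#' @param scale Fixed multiplicative factor applied before quantization.
#' @return Invisibly, a list with `path` and `mask_path` (`NULL` when no
#'   pixel is masked).
#' @export
write_image <- function(pixels, path, format = c("tiff", "png"), scale = 1) {
  format <- match.arg(format)
  pixels <- as.matrix(pixels)
  if (any(is.infinite(pixels))) {
    stop("pixels must be finite or NA (masked)", call. = FALSE)
  }
  mask <- is.na(pixels)
  vals <- pixels * scale
  vals[mask] <- 0
  maxval <- if (format == "tiff") 65535 else 255
  if (any(vals < 0 | vals > maxval)) {
    stop(sprintf("scaled values outside [0, %d]; adjust `scale`", maxval),
         call. = FALSE)
  }
  vals <- round(vals)
  write_gray <- function(m, p) {
    if (format == "tiff") {
      tiff::writeTIFF(m / 65535, p, bits.per.sample = 16L)
    } else {
      png::writePNG(m / 255, p)
    }
  }
  write_gray(vals, path)
  mask_path <- NULL
  if (any(mask)) {
    ext <- tools::file_ext(path)
    mask_path <- sub(sprintf("\\.%s$", ext), sprintf("_mask.%s", ext), path)
    write_gray(ifelse(mask, maxval, 0), mask_path)
  }
  invisible(list(path = path, mask_path = mask_path))
}
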