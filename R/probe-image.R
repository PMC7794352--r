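#' @keywords internal
"_PACKAGE"

# Hybridization rounds: P0 is the pre-probe background autofluorescence scan,
# P1-P4 are scans after hybridizing probes at increasing distance from the
# capture site along the c18RNA.
srin_rounds <- function() c("P0", "P1", "P2", "P3", "P4")

#' Single-round probe image
#'
#' A single-channel fluorescence scan of one capture area for one
#' hybridization round. Intensities are in fluorescence units (FU) and must
#' be non-negative. Scanner gain is carried as metadata only: the assay
#' assumes all rounds were scanned at the same gain, so no gain correction is
#' ever applied.
#'
#' @param pixels Numeric matrix of non-negative intensities (FU). Rows are
#'   image rows (y), columns are image columns (x).
#' @param round_label One of `"P0"`, `"P1"`, `"P2"`, `"P3"`, `"P4"`.
#' @param gain Optional scalar scanner gain (metadata only).
#' @return An object of class `probe_image` with fields `pixels`,
#'   `round_label` and `gain`.
#' @export
probe_image <- function(pixels, round_label, gain = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("probe image intensities must be non-negative and finite",
         call. = FALSE)
  }
  round_label <- match.arg(round_label, srin_rounds())
  if (!is.null(gain)) {
    stopifnot(is.numeric(gain), length(gain) == 1L, gain > 0)
  }
  structure(list(pixels = pixels, round_label = round_label, gain = gain),
            class = "probe_image")
}

#' @export
print.probe_image <- function(x, ...) {
  cat(sprintf("<probe_image %s: %d x %d px, FU range [%g, %g]%s>\n",
              x$round_label, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels),
              if (is.null(x$gain)) "" else sprintf(", gain %g", x$gain)))
  invisible(x)
}

as_probe_image <- function(x, round_label) {
  if (inherits(x, "probe_image")) {
    if (x$round_label != round_label) {
      stop(sprintf("image labelled %s supplied for round %s",
                   x$round_label, round_label), call. = FALSE)
    }
    x
  } else {
    probe_image(x, round_label)
  }
}

#' Registered stack of the five probe rounds
#'
#' Bundles the background scan and the four probe scans of one capture area
#' after registration: all five images must share the same shape and be on a
#' common pixel grid. Mismatched gains across rounds trigger a warning (the
#' assay expects a single gain), never a rescale.
#'
#' @param images A named list with elements `P0`..`P4`, each a numeric matrix
#'   or [probe_image()].
#' @return An object of class `probe_stack` with fields `images` (named list
#'   of `probe_image`) and `shape` (`c(height, width)`).
#' @export
probe_stack <- function(images) {
  rounds <- srin_rounds()
  missing_rounds <- setdiff(rounds, names(images))
  if (length(missing_rounds) > 0L) {
    stop("missing probe round(s): ", paste(missing_rounds, collapse = ", "),
         call. = FALSE)
  }
  images <- lapply(rounds, function(r) as_probe_image(images[[r]], r))
  names(images) <- rounds
  shapes <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("all rounds must share the same image shape; got ",
         paste(sprintf("%s=%dx%d", rounds, shapes[1, ], shapes[2, ]),
               collapse = ", "),
         call. = FALSE)
  }
  gains <- unlist(lapply(images, `[[`, "gain"))
  if (length(unique(gains)) > 1L) {
    warning("probe rounds were scanned at different gains; ",
            "sRIN assumes a common gain and applies no correction",
            call. = FALSE)
  }
  structure(list(images = images, shape = unname(shapes[, 1])),
            class = "probe_stack")
}

#' @export
print.probe_stack <- function(x, ...) {
  cat(sprintf("<probe_stack: %d x %d px, rounds %s>\n",
              x$shape[1], x$shape[2],
              paste(names(x$images), collapse = " ")))
  invisible(x)
}

stack_pixels <- function(stack, round) stack$images[[round]]$pixels

#' Per-round alignment specification
#'
#' Integer pixel translations per hybridization round plus the rectangle
#' retained after alignment. Coordinates are 0-based `(row, col)`; the crop
#' is half-open: `[row0, row1) x [col0, col1)`. An offset `c(dx, dy)` moves
#' image content `dx` columns right and `dy` rows down. Only whole-pixel
#' translations are supported.
#'
#' @param offsets Named list with one `c(dx, dy)` integer pair per round
#'   `P0`..`P4`.
#' @param crop Optional integer vector `c(row0, row1, col0, col1)` (0-based,
#'   half-open). When omitted it is computed from `shape` as the largest
#'   rectangle covered by every shifted image.
#' @param shape Image shape `c(height, width)`; required when `crop` is
#'   omitted.
#' @return An `alignment_spec` object with fields `offsets` and `crop`.
#' @export
alignment_spec <- function(offsets, crop = NULL, shape = NULL) {
  rounds <- srin_rounds()
  missing_rounds <- setdiff(rounds, names(offsets))
  if (length(missing_rounds) > 0L) {
    stop("alignment offsets missing for round(s): ",
         paste(missing_rounds, collapse = ", "), call. = FALSE)
  }
  offsets <- lapply(rounds, function(r) {
    o <- offsets[[r]]
    if (length(o) != 2L || any(o != round(o))) {
      stop("each offset must be an integer (dx, dy) pair", call. = FALSE)
    }
    o <- as.integer(o)
    names(o) <- c("dx", "dy")
    o
  })
  names(offsets) <- rounds
  if (is.null(crop)) {
    if (is.null(shape)) {
      stop("either `crop` or `shape` must be supplied", call. = FALSE)
    }
    dys <- vapply(offsets, `[[`, integer(1), "dy")
    dxs <- vapply(offsets, `[[`, integer(1), "dx")
    crop <- c(max(dys, 0L), shape[1] + min(dys, 0L),
              max(dxs, 0L), shape[2] + min(dxs, 0L))
    if (crop[2] <= crop[1] || crop[4] <= crop[3]) {
      stop("offsets leave no common image region", call. = FALSE)
    }
  }
  crop <- as.integer(crop)
  if (length(crop) != 4L || crop[1] < 0L || crop[3] < 0L ||
      crop[2] <= crop[1] || crop[4] <= crop[3]) {
    stop("`crop` must be c(row0, row1, col0, col1), 0-based half-open, ",
         "with row1 > row0 and col1 > col0", call. = FALSE)
  }
  names(crop) <- c("row0", "row1", "col0", "col1")
  structure(list(offsets = offsets, crop = crop), class = "alignment_spec")
}

#' Identity alignment for a given shape
#'
#' @param shape `c(height, width)`.
#' @return An [alignment_spec()] with zero offsets and a full-frame crop.
#' @export
identity_alignment <- function(shape) {
  zeros <- stats::setNames(
    rep(list(c(dx = 0L, dy = 0L)), 5L), srin_rounds())
  alignment_spec(zeros, shape = shape)
}

#' @export
print.alignment_spec <- function(x, ...) {
  offs <- vapply(x$offsets, function(o) sprintf("(%d,%d)", o[1], o[2]),
                 character(1))
  cat(sprintf("<alignment_spec: offsets %s; crop rows [%d,%d) cols [%d,%d)>\n",
              paste(sprintf("%s=%s", names(offs), offs), collapse = " "),
              x$crop[1], x$crop[2], x$crop[3], x$crop[4]))
  invisible(x)
}
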