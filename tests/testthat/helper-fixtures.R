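# Shared fixtures and independent oracles. The oracles deliberately use
# naive per-pixel loops so they share no code path with the vectorized
# implementation they check.

# Random five-round stack with a mix of valid, invalid and over-range
# pixels.
random_stack <- function(shape = c(32L, 32L), seed = 1) {
  set.seed(seed)
  n <- prod(shape)
  p0 <- matrix(runif(n, 0, 50), shape[1], shape[2])
  mk <- function(lo, hi) {
    pmax(p0 + matrix(runif(n, lo, hi), shape[1], shape[2]), 0)
  }
  probe_stack(list(P0 = p0, P1 = mk(-20, 200), P2 = mk(-40, 260),
                   P3 = mk(-40, 260), P4 = mk(-40, 260)))
}

# Per-pixel brute-force sRIN scoring (double loop, scalar arithmetic).
srin_oracle <- function(stack, q = 0.75) {
  px <- lapply(stack$images, `[[`, "pixels")
  thr <- unname(stats::quantile(as.numeric(px$P0), q, type = 7))
  h <- nrow(px$P0)
  w <- ncol(px$P0)
  srin <- raw <- matrix(NA_real_, h, w)
  valid <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      nn <- px$P1[i, j] - px$P0[i, j] - thr
      if (nn > 0) {
        valid[i, j] <- TRUE
        s <- r <- 0
        for (k in 1:4) {
          rk <- (px[[paste0("P", k)]][i, j] - px$P0[i, j] - thr) / nn
          r <- r + max(rk, 0)
          s <- s + min(max(rk, 0), 1)
        }
        raw[i, j] <- 2.5 * r
        srin[i, j] <- 2.5 * s
      }
    }
  }
  list(srin = srin, raw = raw, valid = valid, threshold = thr)
}

# Translate matrix content by (dx, dy), filling vacated pixels; the same
# convention alignment_spec documents (content moves dx right, dy down).
shift_fill <- function(mat, dx, dy, fill = 0) {
  h <- nrow(mat)
  w <- ncol(mat)
  out <- matrix(fill, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      sr <- r - dy
      sc <- c - dx
      if (sr >= 1 && sr <= h && sc >= 1 && sc <= w) {
        out[r, c] <- mat[sr, sc]
      }
    }
  }
  out
}

# Naive alignment oracle: per-round double-loop shift, then crop.
apply_alignment_oracle <- function(stack, spec) {
  lapply(stack$images, function(im) {
    r <- im$round_label
    o <- spec$offsets[[r]]
    shifted <- shift_fill(im$pixels, o[["dx"]], o[["dy"]], fill = NA)
    shifted[(spec$crop[1] + 1):spec$crop[2],
            (spec$crop[3] + 1):spec$crop[4], drop = FALSE]
  })
}

# Minimal hand-built srin_map for tests that probe downstream consumers.
fake_srin_map <- function(srin, raw = srin, valid = !is.na(srin),
                          misaligned = valid & !is.na(raw) & raw > 10,
                          ratios = NULL) {
  structure(list(srin = srin, raw = raw, valid_mask = valid,
                 misaligned_mask = misaligned, ratios = ratios,
                 threshold = 0, q = 0.75),
            class = "srin_map")
}

# Single-pixel-style uniform stack where every probe level is set directly.
flat_stack <- function(p0, p1, p2, p3, p4, shape = c(4L, 4L)) {
  mk <- function(v) matrix(v, shape[1], shape[2])
  probe_stack(list(P0 = mk(p0), P1 = mk(p1), P2 = mk(p2), P3 = mk(p3),
                   P4 = mk(p4)))
}

zero_offsets <- function() {
  stats::setNames(rep(list(c(dx = 0L, dy = 0L)), 5L),
                  c("P0", "P1", "P2", "P3", "P4"))
}
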