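# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so simulation calls never disturb user RNG flow.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seeds so nested simulations stay reproducible from one
# user-facing seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Probe positions along the c18RNA
#'
#' Distances, in nucleotides from the capture site, of the four
#' hybridization probe sites along the c18RNA (the strand synthesized from
#' captured 18S rRNA). A footprint reports at probe `i` only if it extends
#' at least `d_i` nucleotides, so the probe ladder reads out the fragment
#' length distribution. Defaults spread the four sites evenly over an
#' 18S-length molecule; real assay coordinates are configurable.
#'
#' @param distances Increasing positive numeric vector of four distances
#'   (nt).
#' @param full_length Length of the complete c18RNA (nt); default 1870, the
#'   approximate 18S rRNA length.
#' @return A `probe_layout` with fields `distances` and `full_length`.
#' @export
probe_layout <- function(distances = c(100, 600, 1100, 1600),
                         full_length = 1870) {
  stopifnot(is.numeric(distances), length(distances) == 4L)
  if (any(distances <= 0) || any(diff(distances) <= 0) ||
      distances[4] > full_length) {
    stop("probe distances must satisfy 0 < d1 < d2 < d3 < d4 <= full_length",
         call. = FALSE)
  }
  structure(list(distances = as.numeric(distances),
                 full_length = as.numeric(full_length)),
            class = "probe_layout")
}

#' Fluorescence noise and signal model for rendering
#'
#' Image formation parameters, all in fluorescence units (FU): constant
#' slide background `background`, tissue autofluorescence `autofluorescence`
#' per unit cell density, additive Gaussian sensor noise with standard
#' deviation `sd` (floored at zero, then quantized to 16-bit counts), and
#' full-detection probe signal `amplitude` per unit density. Defaults give a
#' signal-to-noise ratio of 20 at full signal (`sd` = 5% of `amplitude`)
#' over a substantial autofluorescent background — the regime the background
#' subtraction and quantile threshold are designed for.
#'
#' @param background Slide background level b0 (FU).
#' @param autofluorescence Tissue autofluorescence coefficient b1 (FU per
#'   unit density).
#' @param sd Additive noise standard deviation (FU).
#' @param amplitude Probe signal at full detection, A (FU per unit density).
#' @return A `noise_model` object.
#' @export
noise_model <- function(background = 2000, autofluorescence = 3000,
                        sd = 1000, amplitude = 20000) {
  vals <- c(background = background, autofluorescence = autofluorescence,
            sd = sd, amplitude = amplitude)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all noise model parameters must be finite and non-negative",
         call. = FALSE)
  }
  if (amplitude == 0 && sd == 0) {
    warning("amplitude and noise are both zero; rendered stacks will be ",
            "fully masked downstream", call. = FALSE)
  }
  structure(as.list(vals), class = "noise_model")
}

# Separable Gaussian smoothing with edge renormalization.
gauss_blur <- function(m, sigma) {
  smooth_1d <- function(n) {
    k <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
    k / rowSums(k)
  }
  smooth_1d(nrow(m)) %*% m %*% t(smooth_1d(ncol(m)))
}

#' Synthetic tissue phantom
#'
#' Ground-truth tissue model for the simulator: a cell density field `D` in
#' `[0, 1]` built from Gaussian-profile cells on an empty background, a mean
#' c18RNA fragment length field `mu` (nt) describing local RNA degradation,
#' and a necrotic mask marking pixels with no intact RNA. Three degradation
#' profiles are available: `"uniform"` (one `mu` everywhere), `"gradient"`
#' (`mu` ramps across columns over `mu_range`), and `"patchy"` (smooth
#' spatial variation of `mu` around its geometric mean plus necrotic islands
#' covering `necrotic_fraction` of the tissue pixels).
#'
#' @param shape `c(height, width)` in pixels.
#' @param n_cells Number of cells; `NULL` scales with area (about 60 for
#'   128 x 128). `0` gives an empty phantom.
#' @param profile Degradation profile, see above.
#' @param mu Mean fragment length (nt) for the `"uniform"` profile and the
#'   center of the `"patchy"` profile.
#' @param mu_range `c(low, high)` fragment-length range (nt) for the
#'   `"gradient"` profile.
#' @param necrotic_fraction Fraction of tissue pixels inside necrotic
#'   islands (`"patchy"` only).
#' @param cell_radius Gaussian radius of one cell (px).
#' @param seed Random seed (required; phantoms are reproducible).
#' @return A `tissue_phantom` with fields `density`, `mu`, `necrotic_mask`,
#'   `cell_mask` (density >= 0.1 and not necrotic) and `seed`.
#' @export
make_phantom <- function(shape, n_cells = NULL,
                         profile = c("uniform", "gradient", "patchy"),
                         mu = 3000, mu_range = c(800, 6000),
                         necrotic_fraction = 0.2, cell_radius = 4, seed) {
  profile <- match.arg(profile)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L)) {
    stop("`shape` must be positive c(height, width)", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  h <- shape[1]
  w <- shape[2]
  if (is.null(n_cells)) n_cells <- max(1L, round(h * w / 275))
  with_seed(seed, {
    density <- matrix(0, h, w)
    if (n_cells > 0L) {
      cy <- stats::runif(n_cells, 1, h)
      cx <- stats::runif(n_cells, 1, w)
      rows <- seq_len(h)
      cols <- seq_len(w)
      for (k in seq_len(n_cells)) {
        density <- density +
          exp(-(rows - cy[k])^2 / (2 * cell_radius^2)) %o%
          exp(-(cols - cx[k])^2 / (2 * cell_radius^2))
      }
      density <- pmin(1.5 * density, 1)    # saturated cell interiors
      density[density < 0.02] <- 0         # exact-zero background
    }
    tissue <- density > 0
    necrotic <- matrix(FALSE, h, w)
    mu_field <- switch(profile,
      uniform = {
        stopifnot(mu > 0)
        matrix(mu, h, w)
      },
      gradient = {
        if (any(mu_range <= 0) || diff(mu_range) <= 0) {
          stop("`mu_range` must be increasing and positive", call. = FALSE)
        }
        matrix(seq(mu_range[1], mu_range[2], length.out = w),
               h, w, byrow = TRUE)
      },
      patchy = {
        stopifnot(mu > 0, necrotic_fraction >= 0, necrotic_fraction < 1)
        texture <- gauss_blur(matrix(stats::rnorm(h * w), h, w),
                              sigma = max(h, w) / 16)
        texture <- texture / max(stats::sd(texture), 1e-12)
        fld <- mu * exp(0.5 * texture)
        if (necrotic_fraction > 0 && any(tissue)) {
          isl <- gauss_blur(matrix(stats::rnorm(h * w), h, w),
                            sigma = max(h, w) / 20)
          cut <- stats::quantile(isl[tissue], 1 - necrotic_fraction,
                                 type = 7)
          necrotic <- tissue & (isl > cut)
        }
        fld
      })
    structure(list(density = density, mu = mu_field,
                   necrotic_mask = necrotic,
                   cell_mask = density >= 0.1 & !necrotic,
                   seed = seed),
              class = "tissue_phantom")
  })
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf(
    "<tissue_phantom: %d x %d px, %.1f%% tissue, %.1f%% necrotic, mu [%g, %g] nt>\n",
    nrow(x$density), ncol(x$density),
    100 * mean(x$density > 0), 100 * mean(x$necrotic_mask),
    min(x$mu), max(x$mu)))
  invisible(x)
}

#' Shorten fragments to emulate cross-linking fixation
#'
#' Formalin cross-linking shortens the effective c18RNA fragments; this
#' scales the phantom's mean fragment length everywhere by `kappa` and
#' leaves everything else untouched. Successive applications compose
#' multiplicatively.
#'
#' @param phantom A [make_phantom()] result.
#' @param kappa Scaling factor in `(0, 1]`.
#' @return The modified `tissue_phantom`.
#' @export
apply_crosslinking <- function(phantom, kappa) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0 || kappa > 1) {
    stop("`kappa` must lie in (0, 1]", call. = FALSE)
  }
  phantom$mu <- phantom$mu * kappa
  phantom
}

# Probability that a footprint at a pixel reaches probe i: fragment length
# is exponential with the local mean, so p_i = exp(-d_i / mu); necrotic
# pixels carry no intact RNA at all.
detect_probabilities <- function(phantom, layout) {
  lapply(layout$distances, function(d) {
    p <- exp(-d / phantom$mu)
    p[phantom$necrotic_mask] <- 0
    p
  })
}

#' Render a synthetic five-round probe stack
#'
#' Simulates image formation for one capture area. The background round is
#' `P0 = b0 + b1 * D + noise`; each probe round adds the footprint signal
#' `A * D * p_i` on top of the same deterministic background, where
#' `p_i = exp(-d_i / mu)` is the probability a fragment reaches probe `i`.
#' Images are floored at zero and quantized to 16-bit counts. Optional
#' per-round integer translations emulate registration error; vacated
#' borders are filled with fresh background. Ground truth is returned
#' unshifted.
#'
#' The returned truth carries two score fields: `true_srin = 2.5 * sum(p_i)`,
#' the biophysical integrity on the 0-10 scale (it can fall below 2.5 when
#' even probe 1 is often missed), and `assay_srin = 2.5 * (1 + sum_{i>=2}
#' p_i / p_1)`, the score an ideal noise-free assay recovers — the assay
#' anchors probe 1 at full scale, so it measures detection relative to
#' probe 1.
#'
#' @param phantom A [make_phantom()] result.
#' @param layout A [probe_layout()].
#' @param noise A [noise_model()].
#' @param offsets Optional named list of integer `c(dx, dy)` per round
#'   `P0`..`P4`; `NULL` means no shift.
#' @param seed Random seed for the sensor noise.
#' @return A list with `stack` (a [probe_stack()]) and `truth` (a
#'   `ground_truth` with `detect`, `true_srin`, `assay_srin`, `cell_mask`).
#' @export
render_stack <- function(phantom, layout = probe_layout(),
                         noise = noise_model(), offsets = NULL, seed) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(layout, "probe_layout"),
            inherits(noise, "noise_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  h <- nrow(phantom$density)
  w <- ncol(phantom$density)
  rounds <- srin_rounds()
  if (is.null(offsets)) {
    offsets <- stats::setNames(rep(list(c(dx = 0L, dy = 0L)), 5L), rounds)
  }
  p <- detect_probabilities(phantom, layout)
  base <- noise$background + noise$autofluorescence * phantom$density
  signals <- c(list(P0 = base),
               stats::setNames(lapply(p, function(pi_) {
                 base + noise$amplitude * phantom$density * pi_
               }), paste0("P", 1:4)))
  quantize <- function(m) pmin(pmax(round(m), 0), 65535)
  images <- with_seed(seed, {
    lapply(rounds, function(r) {
      m <- signals[[r]]
      if (noise$sd > 0) m <- m + matrix(stats::rnorm(h * w, sd = noise$sd), h, w)
      m <- quantize(m)
      o <- as.integer(offsets[[r]])   # (dx, dy), named or positional
      dx <- o[[1]]
      dy <- o[[2]]
      if (dx != 0L || dy != 0L) {
        fill <- quantize(noise$background +
                           matrix(stats::rnorm(h * w, sd = noise$sd), h, w))
        shifted <- fill
        src_r <- seq_len(h) - dy
        src_c <- seq_len(w) - dx
        ok_r <- src_r >= 1L & src_r <= h
        ok_c <- src_c >= 1L & src_c <= w
        shifted[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
        m <- shifted
      }
      m
    })
  })
  names(images) <- rounds
  p1 <- p[[1]]
  ratio_sum <- matrix(0, h, w)
  for (i in 2:4) {
    ri <- ifelse(p1 > 0, pmin(p[[i]] / pmax(p1, 1e-300), 1), 0)
    ratio_sum <- ratio_sum + ri
  }
  truth <- structure(list(
    detect = stats::setNames(p, paste0("p", 1:4)),
    true_srin = ifelse(phantom$cell_mask,
                       2.5 * Reduce(`+`, p), NA_real_),
    assay_srin = ifelse(phantom$cell_mask & p1 > 0,
                        2.5 * (1 + ratio_sum), NA_real_),
    cell_mask = phantom$cell_mask),
    class = "ground_truth")
  list(stack = probe_stack(images), truth = truth)
}

#' Bulk RNA-integrity proxy for a fragment-length distribution
#'
#' Companion score to the pixel-wise map for dissolved samples: with
#' fragment length exponential with mean `mu`, the chance a fragment spans
#' probe `i` is `exp(-d_i / mu)`, and the proxy is 2.5 times the sum of the
#' four spanning probabilities, on the same 0-10 scale as the spatial score.
#' Mixtures of pools with different `mu` combine by volume weight. This is a
#' deliberately simple proxy sharing the spatial score's functional form; it
#' is not the electrophoresis-based RIN algorithm.
#'
#' @param mu Mean fragment length (nt); scalar or vector of mixture
#'   components. `Inf` means fully intact.
#' @param layout A [probe_layout()].
#' @param weights Positive mixture weights (recycled to `length(mu)`,
#'   normalized to sum 1).
#' @return A score in `[0, 10]`.
#' @export
bulk_rin_proxy <- function(mu, layout = probe_layout(), weights = NULL) {
  stopifnot(inherits(layout, "probe_layout"), is.numeric(mu),
            length(mu) >= 1L)
  if (any(is.na(mu)) || any(mu <= 0)) {
    stop("`mu` must be positive (Inf allowed for intact RNA)", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(mu))
  if (length(weights) != length(mu) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("`weights` must be positive and match `mu` in length",
         call. = FALSE)
  }
  weights <- weights / sum(weights)
  p <- vapply(layout$distances, function(d) {
    sum(weights * exp(-d / mu))
  }, numeric(1))
  2.5 * sum(p)
}

#' Simulated degradation ladder
#'
#' Builds a series of samples with strictly decreasing mean fragment length
#' (log-spaced over `mu_range`), each with `n_replicates` technical
#' replicate phantoms, together with the bulk integrity proxy per sample.
#' The default range spans bulk proxies from about 9 (nearly intact) down to
#' about 3 (heavily degraded) under the default probe layout.
#'
#' @param n_samples Number of ladder steps (>= 2).
#' @param mu_range `c(low, high)` mean fragment lengths (nt).
#' @param layout A [probe_layout()].
#' @param shape Phantom shape in pixels.
#' @param n_replicates Technical replicates per sample.
#' @param n_cells Cells per phantom (`NULL`: area-scaled default).
#' @param seed Random seed.
#' @return A `degradation_ladder`: list with `samples` (each holding
#'   `sample_id`, `mu`, `bulk_proxy`, `phantoms`) and the `layout`.
#' @export
degradation_ladder <- function(n_samples = 5, mu_range = c(450, 8000),
                               layout = probe_layout(),
                               shape = c(128L, 128L), n_replicates = 3,
                               n_cells = NULL, seed) {
  stopifnot(n_samples >= 2L, n_replicates >= 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (any(!is.finite(mu_range)) || any(mu_range <= 0) ||
      diff(mu_range) <= 0) {
    stop("`mu_range` must be finite, positive and strictly increasing",
         call. = FALSE)
  }
  mus <- exp(seq(log(mu_range[2]), log(mu_range[1]),
                 length.out = n_samples))
  seeds <- matrix(derive_seeds(seed, n_samples * n_replicates),
                  n_samples, n_replicates)
  samples <- lapply(seq_len(n_samples), function(s) {
    phantoms <- lapply(seq_len(n_replicates), function(r) {
      make_phantom(shape, n_cells = n_cells, profile = "uniform",
                   mu = mus[s], seed = seeds[s, r])
    })
    list(sample_id = sprintf("S%02d", s), mu = mus[s],
         bulk_proxy = bulk_rin_proxy(mus[s], layout),
         phantoms = phantoms)
  })
  structure(list(samples = samples, layout = layout, seed = seed),
            class = "degradation_ladder")
}

#' Render and score a degradation ladder end-to-end
#'
#' Renders every replicate phantom of a [degradation_ladder()], scores it
#' with [compute_srin()], and summarizes technical replicates into one
#' averaged sRIN per sample (mean of replicate medians over valid,
#' non-misaligned pixels).
#'
#' @param ladder A [degradation_ladder()].
#' @param noise A [noise_model()].
#' @param q Background quantile for scoring.
#' @param seed Random seed for the sensor noise.
#' @return A data frame with one row per sample: `sample_id`, `mu`,
#'   `bulk_proxy`, `averaged_srin`.
#' @export
score_ladder <- function(ladder, noise = noise_model(), q = 0.75, seed) {
  stopifnot(inherits(ladder, "degradation_ladder"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_rep <- length(ladder$samples[[1]]$phantoms)
  seeds <- matrix(derive_seeds(seed, length(ladder$samples) * n_rep),
                  length(ladder$samples), n_rep)
  rows <- lapply(seq_along(ladder$samples), function(s) {
    smp <- ladder$samples[[s]]
    maps <- lapply(seq_along(smp$phantoms), function(r) {
      sim <- render_stack(smp$phantoms[[r]], ladder$layout, noise,
                          seed = seeds[s, r])
      compute_srin(sim$stack, q = q)
    })
    summ <- summarize_sample(maps, sample_id = smp$sample_id,
                             bulk_rin = smp$bulk_proxy)
    data.frame(sample_id = smp$sample_id, mu = smp$mu,
               bulk_proxy = smp$bulk_proxy,
               averaged_srin = summ$averaged_srin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
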