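test_that("phantoms are reproducible and respect their parameters", {
  a <- make_phantom(c(64L, 64L), seed = 1)
  b <- make_phantom(c(64L, 64L), seed = 1)
  expect_identical(a, b)
  c <- make_phantom(c(64L, 64L), seed = 2)
  expect_false(identical(a$density, c$density))
  empty <- make_phantom(c(32L, 32L), n_cells = 0, seed = 1)
  expect_true(all(empty$density == 0))
  expect_error(make_phantom(c(0L, 32L), seed = 1), "positive")
  expect_true(all(a$density >= 0 & a$density <= 1))
  expect_true(all(a$mu > 0))
})

test_that("patchy necrotic islands cover the requested tissue fraction", {
  for (seed in c(5, 6, 7)) {
    ph <- make_phantom(c(128L, 128L), profile = "patchy",
                       necrotic_fraction = 0.2, seed = seed)
    frac <- sum(ph$necrotic_mask) / sum(ph$density > 0)
    expect_gt(frac, 0.18)
    expect_lt(frac, 0.22)
    expect_false(any(ph$cell_mask & ph$necrotic_mask))
  }
})

test_that("detection probabilities decay along the probe ladder", {
  for (profile in c("uniform", "gradient", "patchy")) {
    ph <- make_phantom(c(48L, 48L), profile = profile, seed = 9)
    sim <- render_stack(ph, noise = noise_model(sd = 0), seed = 10)
    p <- sim$truth$detect
    expect_true(all(p$p1 >= p$p2 & p$p2 >= p$p3 & p$p3 >= p$p4))
    expect_true(all(p$p1 <= 1 & p$p4 >= 0))
    expect_true(all(p$p1[ph$necrotic_mask] == 0))
  }
})

test_that("intact RNA scores 10 and fully degraded RNA scores 2.5", {
  nf <- noise_model(background = 0, autofluorescence = 3000, sd = 0)
  intact <- make_phantom(c(48L, 48L), mu = 1e12, seed = 11)
  m_hi <- compute_srin(render_stack(intact, noise = nf, seed = 12)$stack,
                       q = 0)
  expect_true(all(m_hi$srin[intact$cell_mask] == 10))
  # mean fragment length far below d2: probes 2-4 vanish, floor remains
  # (up to isolated one-count quantization flips at rounding boundaries)
  gone <- make_phantom(c(48L, 48L), mu = 40, seed = 11)
  m_lo <- compute_srin(render_stack(gone, noise = nf, seed = 12)$stack,
                       q = 0)
  expect_gte(mean(m_lo$srin[m_lo$valid_mask] == 2.5), 0.99)
  expect_equal(stats::median(m_lo$srin[m_lo$valid_mask]), 2.5)
})

test_that("noise-free rendering is inverted by the scorer", {
  ph <- make_phantom(c(64L, 64L), mu = 2500, seed = 13)
  nf <- noise_model(background = 0, autofluorescence = 3000, sd = 0)
  sim <- render_stack(ph, noise = nf, seed = 14)
  m <- compute_srin(sim$stack, q = 0)
  cm <- sim$truth$cell_mask
  # per-pixel tolerance: four probes' worth of one-count quantization error
  n_field <- stack_pixels(sim$stack, "P1") - stack_pixels(sim$stack, "P0")
  tol <- 10 / pmax(n_field, 1)
  ok <- abs(m$srin - sim$truth$assay_srin) <= tol
  expect_gte(mean(ok[cm], na.rm = TRUE), 0.99)
})

test_that("rendering is seed-reproducible", {
  ph <- make_phantom(c(32L, 32L), seed = 15)
  s1 <- render_stack(ph, seed = 16)
  s2 <- render_stack(ph, seed = 16)
  for (r in names(s1$stack$images)) {
    expect_identical(s1$stack$images[[r]]$pixels,
                     s2$stack$images[[r]]$pixels)
  }
  s3 <- render_stack(ph, seed = 17)
  expect_false(identical(s1$stack$images$P1$pixels,
                         s3$stack$images$P1$pixels))
})

test_that("cross-linking shortens fragments and lowers recovered scores", {
  ph <- make_phantom(c(64L, 64L), mu = 3000, seed = 18)
  expect_identical(apply_crosslinking(ph, 1), ph)
  twice <- apply_crosslinking(apply_crosslinking(ph, 0.5), 0.5)
  once <- apply_crosslinking(ph, 0.25)
  expect_equal(twice$mu, once$mu)
  expect_error(apply_crosslinking(ph, 0), "kappa")
  expect_error(apply_crosslinking(ph, -1), "kappa")
  expect_error(apply_crosslinking(ph, 1.5), "kappa")
  score_of <- function(p) {
    m <- compute_srin(render_stack(p, seed = 19)$stack)
    mean(m$srin[m$valid_mask & !m$misaligned_mask])
  }
  expect_lt(score_of(apply_crosslinking(ph, 0.1)), score_of(ph))
})

test_that("bulk proxy matches a Monte-Carlo fragment simulation", {
  layout <- probe_layout()
  expect_equal(bulk_rin_proxy(Inf, layout), 10)
  # 1:1 mixture of intact and fully degraded pools sits mid-scale
  expect_equal(bulk_rin_proxy(c(Inf, 1e-6), layout, weights = c(1, 1)), 5,
               tolerance = 1e-6)
  # independent oracle: draw exponential fragment lengths and count spans
  set.seed(20)
  for (mu in c(600, 2000, 8000)) {
    lens <- stats::rexp(2e5, rate = 1 / mu)
    mc <- 2.5 * sum(vapply(layout$distances,
                           function(d) mean(lens >= d), numeric(1)))
    expect_equal(bulk_rin_proxy(mu, layout), mc, tolerance = 0.02)
  }
  expect_error(bulk_rin_proxy(-5, layout), "positive")
  expect_error(bulk_rin_proxy(c(100, 200), layout, weights = c(1, -1)),
               "weights")
})

test_that("probe layout validates its geometry", {
  expect_error(probe_layout(c(100, 90, 1100, 1600)), "d1 < d2")
  expect_error(probe_layout(c(-5, 600, 1100, 1600)), "d1")
  expect_error(probe_layout(c(100, 600, 1100, 2000), full_length = 1870),
               "full_length")
  lay <- probe_layout()
  expect_equal(lay$distances, c(100, 600, 1100, 1600))
  expect_equal(lay$full_length, 1870)
})

test_that("the degradation ladder is ordered, reproducible and recoverable", {
  lad <- degradation_ladder(shape = c(64L, 64L), seed = 21)
  proxies <- vapply(lad$samples, `[[`, numeric(1), "bulk_proxy")
  mus <- vapply(lad$samples, `[[`, numeric(1), "mu")
  expect_true(all(diff(mus) < 0))
  expect_true(all(diff(proxies) < 0))
  expect_gt(proxies[1], 8.5)               # nearly intact at the top
  expect_lt(proxies[length(proxies)], 3.5) # heavily degraded at the bottom
  lad2 <- degradation_ladder(shape = c(64L, 64L), seed = 21)
  expect_identical(lad, lad2)
  expect_error(degradation_ladder(mu_range = c(2000, 2000), seed = 1),
               "increasing")
  expect_error(degradation_ladder(n_samples = 1, seed = 1), "n_samples")
  # end-to-end: recovered mean sRIN decreases along the ladder
  scored <- score_ladder(lad, seed = 22)
  expect_true(all(diff(scored$averaged_srin) < 0))
})
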