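test_that("read_stack round-trips five equally shaped TIFFs", {
  dir <- withr::local_tempdir()
  set.seed(42)
  mats <- lapply(1:5, function(i) {
    matrix(sample.int(65535, 64 * 64, replace = TRUE) - 1L, 64, 64)
  })
  names(mats) <- c("P0", "P1", "P2", "P3", "P4")
  paths <- vapply(names(mats), function(r) {
    p <- file.path(dir, paste0(r, ".tif"))
    write_image(mats[[r]], p, "tiff")
    p
  }, character(1))
  stack <- read_stack(paths)
  expect_equal(stack$shape, c(64L, 64L))
  for (r in names(mats)) {
    expect_equal(stack$images[[r]]$pixels, mats[[r]],
                 ignore_attr = TRUE)
  }
})

test_that("read_stack errors name the offending round", {
  dir <- withr::local_tempdir()
  paths <- vapply(c("P0", "P1", "P2", "P3", "P4"), function(r) {
    p <- file.path(dir, paste0(r, ".tif"))
    write_image(matrix(1, 8, 8), p, "tiff")
    p
  }, character(1))
  expect_error(read_stack(paths[c("P0", "P1", "P3", "P4")]), "P2")
  bad <- paths
  bad[["P3"]] <- file.path(dir, "nope.tif")
  expect_error(read_stack(bad), "P3")
  # differing shapes without an alignment spec
  write_image(matrix(1, 8, 10), paths[["P4"]], "tiff")
  expect_error(read_stack(paths), "shape")
})

test_that("read_stack rejects multi-channel images", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rgb.png")
  png::writePNG(array(0.5, dim = c(8, 8, 3)), p)
  expect_error(read_image(p), "multi-channel")
})

test_that("a matching alignment spec restores a shifted round", {
  dir <- withr::local_tempdir()
  set.seed(7)
  base <- matrix(sample.int(4096, 32 * 32, replace = TRUE), 32, 32)
  mats <- list(P0 = base, P1 = base + 5, P2 = shift_fill(base + 9, 3, 0),
               P3 = base + 2, P4 = base + 1)
  paths <- vapply(names(mats), function(r) {
    p <- file.path(dir, paste0(r, ".tif"))
    write_image(mats[[r]], p, "tiff")
    p
  }, character(1))
  offs <- zero_offsets()
  offs$P2 <- c(dx = -3L, dy = 0L)  # corrective translation
  spec <- alignment_spec(offs, shape = c(32L, 32L))
  stack <- read_stack(paths, spec)
  # on the retained region P2 equals the unshifted original
  orig_crop <- (base + 9)[(spec$crop[1] + 1):spec$crop[2],
                          (spec$crop[3] + 1):spec$crop[4]]
  expect_equal(stack$images$P2$pixels, orig_crop, ignore_attr = TRUE)
})

test_that("apply_alignment matches geometry and the loop oracle", {
  set.seed(11)
  stack <- random_stack(c(24L, 24L), seed = 11)
  # identity
  ident <- identity_alignment(stack$shape)
  same <- apply_alignment(stack, ident)
  expect_equal(same$images$P3$pixels, stack$images$P3$pixels)
  # uniform (1, 0) offset loses one column
  offs <- lapply(zero_offsets(), function(o) c(dx = 1L, dy = 0L))
  shifted <- apply_alignment(stack, alignment_spec(offs, shape = stack$shape))
  expect_equal(shifted$shape, c(24L, 23L))
  # random small offsets equal the naive double-loop oracle
  for (case_seed in 1:3) {
    set.seed(case_seed)
    offs <- lapply(zero_offsets(), function(o) {
      c(dx = sample(-3:3, 1), dy = sample(-3:3, 1))
    })
    spec <- alignment_spec(offs, shape = stack$shape)
    got <- apply_alignment(stack, spec)
    want <- apply_alignment_oracle(stack, spec)
    for (r in names(want)) {
      expect_equal(got$images[[r]]$pixels, want[[r]], ignore_attr = TRUE)
    }
  }
})

test_that("apply_alignment rejects a crop outside a shifted image", {
  stack <- random_stack(c(16L, 16L), seed = 2)
  offs <- zero_offsets()
  offs$P2 <- c(dx = 4L, dy = 0L)
  expect_error(
    apply_alignment(stack, alignment_spec(offs, crop = c(0L, 16L, 0L, 16L))),
    "crop")
})

test_that("aligning and then un-aligning reproduces the original crop", {
  stack <- random_stack(c(20L, 20L), seed = 5)
  set.seed(5)
  offs <- lapply(zero_offsets(), function(o) {
    c(dx = sample(-2:2, 1), dy = sample(-2:2, 1))
  })
  spec <- alignment_spec(offs, shape = stack$shape)
  fwd <- apply_alignment(stack, spec)
  neg <- lapply(offs, function(o) -o)
  spec_back <- alignment_spec(neg, shape = fwd$shape)
  back <- apply_alignment(fwd, spec_back)
  # the result is a pure crop of the original, identical for every round
  r0 <- spec$crop[1] + spec_back$crop[1]
  c0 <- spec$crop[3] + spec_back$crop[3]
  for (r in names(stack$images)) {
    expect_equal(
      back$images[[r]]$pixels,
      stack$images[[r]]$pixels[r0 + seq_len(back$shape[1]),
                               c0 + seq_len(back$shape[2])],
      ignore_attr = TRUE)
  }
})

test_that("estimate_offsets recovers injected integer shifts", {
  set.seed(31)
  base <- matrix(runif(64 * 64, 0, 100), 64, 64)
  base <- base + 200 * exp(-((row(base) - 30)^2 + (col(base) - 25)^2) / 150)
  # identical rounds give zero offsets everywhere
  ident <- probe_stack(list(P0 = base, P1 = base, P2 = base, P3 = base,
                            P4 = base))
  est0 <- estimate_offsets(ident, "P0")
  for (o in est0$offsets) expect_equal(unname(o), c(0L, 0L))
  # shifts up to 25% of the image size are recovered exactly
  for (d in list(c(5L, -2L), c(-10L, 7L), c(16L, 16L), c(0L, -16L))) {
    shifted <- probe_stack(list(
      P0 = base, P1 = base,
      P2 = shift_fill(base, d[1], d[2], fill = mean(base)),
      P3 = base, P4 = base))
    est <- estimate_offsets(shifted, "P0")
    expect_equal(unname(est$offsets$P2), -d)  # corrective = minus shift
    # and applying the corrective offsets restores pixel equality
    aligned <- apply_alignment(shifted, est)
    ref <- apply_alignment(ident, est)
    expect_equal(aligned$images$P2$pixels, ref$images$P0$pixels,
                 ignore_attr = TRUE)
  }
})

test_that("estimate_offsets refuses constant images", {
  flat <- flat_stack(10, 10, 10, 10, 10, shape = c(16L, 16L))
  expect_error(estimate_offsets(flat), "constant")
})

test_that("write_image round-trips, masks, and range-checks", {
  dir <- withr::local_tempdir()
  set.seed(3)
  m <- matrix(sample.int(65536, 256, replace = TRUE) - 1L, 16, 16)
  p <- file.path(dir, "grid.tif")
  write_image(m, p, "tiff")
  expect_equal(read_image(p), m, ignore_attr = TRUE)
  # masked pixels become zero with a mask file alongside
  m2 <- m
  m2[3, 5] <- NA
  res <- write_image(m2, file.path(dir, "masked.tif"), "tiff")
  expect_true(file.exists(res$mask_path))
  back <- read_image(res$path)
  expect_equal(back[3, 5], 0)
  mask <- read_image(res$mask_path)
  expect_identical(mask > 0, is.na(m2), ignore_attr = TRUE)
  # out-of-range values without rescaling are refused
  expect_error(write_image(matrix(70000, 2, 2), file.path(dir, "o.tif")),
               "outside")
  expect_error(write_image(matrix(-1, 2, 2), file.path(dir, "n.tif")),
               "outside")
})

test_that("mismatched per-round gains warn but never rescale", {
  imgs <- list(P0 = probe_image(matrix(1, 4, 4), "P0", gain = 1),
               P1 = probe_image(matrix(9, 4, 4), "P1", gain = 2),
               P2 = matrix(5, 4, 4), P3 = matrix(5, 4, 4),
               P4 = matrix(5, 4, 4))
  expect_warning(st <- probe_stack(imgs), "gain")
  expect_equal(st$images$P1$pixels[1, 1], 9)
})
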