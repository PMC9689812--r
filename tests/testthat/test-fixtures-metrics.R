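test_that("lesion fixture realises the requested contrast gap", {
  sp <- lesion_spec(rows = 64, cols = 64, noise_sd = 0,
                    gradient_amplitude = 0, texture_amplitude = 0,
                    contrast_gap = 0.3)
  fx <- make_lesion_image(sp)
  xi <- rgb_to_hsi(fx$image)$intensity
  gap <- mean(xi[!fx$mask]) - mean(xi[fx$mask])
  expect_equal(gap, 0.3, tolerance = 0.01 / 0.3)  # +-0.01 absolute
  expect_true(any(fx$mask) && !all(fx$mask))
})

test_that("fixtures are bit-identical under the same spec and seed", {
  sp <- lesion_spec(rows = 32, cols = 32, seed = 99)
  f1 <- make_lesion_image(sp)
  f2 <- make_lesion_image(sp)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$mask, f2$mask)
})

test_that("zero contrast gap produces a near-constant degenerate image", {
  sp <- lesion_spec(rows = 32, cols = 32, contrast_gap = 0, noise_sd = 0,
                    gradient_amplitude = 0, texture_amplitude = 0)
  fx <- make_lesion_image(sp)
  xi <- rgb_to_hsi(fx$image)$intensity
  expect_lt(diff(range(xi)), 1e-9)
  expect_equal(objective_score(xi)$score, 0)
})

test_that("lesion outside the frame is rejected", {
  expect_error(lesion_spec(rows = 32, cols = 32, axes = c(20, 18)),
               "inside the frame")
})

test_that("contrast degradation scales intensity spread and keeps colour", {
  fx <- make_lesion_image(lesion_spec(rows = 48, cols = 48, seed = 5))
  expect_equal(degrade_contrast(fx$image, 1), fx$image, tolerance = 1e-9)
  d <- degrade_contrast(fx$image, 0.5)
  xi0 <- rgb_to_hsi(fx$image)$intensity
  xi1 <- rgb_to_hsi(d)$intensity
  expect_equal(sd(xi1), 0.5 * sd(xi0), tolerance = 1e-6)
  # hue of strongly chromatic pixels survives the roundtrip
  h0 <- rgb_to_hsi(fx$image)$hue
  h1 <- rgb_to_hsi(d)$hue
  expect_lt(max(abs(h1 - h0)), 1e-6)
})

test_that("degraded images carry less entropy than the originals", {
  lower <- 0L
  for (seed in 1:20) {
    fx <- make_lesion_image(lesion_spec(rows = 32, cols = 32, seed = seed))
    xi0 <- rgb_to_hsi(fx$image)$intensity
    xi1 <- rgb_to_hsi(degrade_contrast(fx$image, 0.4))$intensity
    if (shannon_entropy(xi1) < shannon_entropy(xi0)) lower <- lower + 1L
  }
  expect_gte(lower, 19L)  # >= 95% of seeds
})

test_that("overlap metrics match direct evaluation of the count formulas", {
  a <- random_mask(8, 8); set.seed(2)
  expect_equal(overlap_score(a, a)$jaccard, 1)
  expect_equal(overlap_score(a, a)$dice, 1)

  # TP = 50, FP = 25, FN = 25 -> J = 0.5, P = R = 2/3, D = 2/3
  pred <- matrix(FALSE, 10, 10); truth <- matrix(FALSE, 10, 10)
  pred[1:75] <- TRUE            # 50 TP + 25 FP
  truth[c(1:50, 76:100)] <- TRUE
  ov <- overlap_score(pred, truth)
  expect_equal(c(ov$tp, ov$fp, ov$fn), c(50, 25, 25))
  expect_equal(ov$jaccard, 0.5)
  expect_equal(ov$precision, 2 / 3)
  expect_equal(ov$recall, 2 / 3)
  expect_equal(ov$dice, 2 * (2/3) * (2/3) / (2/3 + 2/3))

  # disjoint non-empty masks
  d1 <- matrix(FALSE, 4, 4); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 4, 4); d2[4, 4] <- TRUE
  expect_equal(overlap_score(d1, d2)$jaccard, 0)
  expect_equal(overlap_score(d1, d2)$dice, 0)

  # empty-mask conventions
  e <- matrix(FALSE, 4, 4)
  expect_equal(overlap_score(e, e)$dice, 1)
  expect_equal(overlap_score(e, d2)$dice, 0)
  expect_error(overlap_score(d1, matrix(FALSE, 3, 3)), "mismatch")
})

test_that("dice = 2J/(1+J) identity holds on random mask pairs", {
  set.seed(31)
  for (rep in 1:100) {
    ov <- overlap_score(random_mask(6, 6, runif(1)), random_mask(6, 6, runif(1)))
    expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard), tolerance = 1e-12)
    expect_gte(ov$dice, ov$jaccard)
  }
})

test_that("Otsu threshold splits bimodal images exactly and matches brute force", {
  bi <- matrix(c(rep(0.2, 60), rep(0.8, 40)), 10, 10)
  m <- otsu_mask(bi)
  expect_identical(m, bi < 0.5)

  # brute-force oracle: scan every cut, compute between-class variance
  # directly from the pixel values
  set.seed(19)
  for (rep in 1:5) {
    xi <- matrix(sample(c(runif(60, 0, 0.4), runif(40, 0.5, 1))), 10, 10)
    x <- as.vector(xi)
    idx <- pmin(floor(x * 256), 255)
    best <- -Inf; bestk <- NA
    for (k in 1:255) {
      lo <- idx <= (k - 1)
      w0 <- mean(lo)
      if (w0 == 0 || w0 == 1) next
      cb <- (0.5 + idx) / 256
      v <- w0 * (1 - w0) * (mean(cb[lo]) - mean(cb[!lo]))^2
      if (v > best) { best <- v; bestk <- k }
    }
    expect_equal(otsu_threshold(xi), bestk / 256)
  }

  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "constant")
  expect_warning(m0 <- otsu_mask(matrix(0.5, 4, 4)), "constant")
  expect_false(any(m0))
})

test_that("Otsu partitions agree with an independent library implementation", {
  # thresholds may sit anywhere on the flat between-class-variance plateau
  # between the modes (tie-break differs), so compare the induced partitions
  set.seed(23)
  for (rep in 1:5) {
    xi <- matrix(c(runif(200, 0, 0.45), runif(200, 0.55, 1)), 20, 20)
    ours <- xi < otsu_threshold(xi)
    ref <- xi < EBImage::otsu(xi, range = c(0, 1), levels = 256)
    expect_identical(ours, ref)
  }
})

test_that("high-contrast fixture is segmented almost perfectly by the Otsu baseline", {
  fx <- make_lesion_image(lesion_spec(rows = 64, cols = 64, contrast_gap = 0.4,
                                      noise_sd = 0.01, gradient_amplitude = 0,
                                      seed = 3))
  xi <- rgb_to_hsi(fx$image)$intensity
  expect_gte(overlap_score(otsu_mask(xi), fx$mask)$dice, 0.9)
})
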