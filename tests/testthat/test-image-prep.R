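test_that("z-score normalization matches the closed form and inverts", {
  z <- zscore_normalize(c(2, 4, 6))
  expect_equal(z$normalized, c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-9)
  expect_equal(z$normalized, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(z$params$mean, 4)
  expect_equal(z$params$std, sqrt(8 / 3))

  # population moments: mean 0, sd 1 within 1e-9; idempotent on fixed point
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 5))
    z <- zscore_normalize(v)
    expect_lt(abs(mean(z$normalized)), 1e-9)
    expect_lt(abs(sqrt(mean(z$normalized^2)) - 1), 1e-9)
    expect_equal(zscore_denormalize(z$normalized, z$params), v, tolerance = 1e-9)
    z2 <- zscore_normalize(z$normalized)
    expect_equal(z2$normalized, z$normalized, tolerance = 1e-9)
  }
  expect_error(zscore_normalize(c(5, 5, 5)), "variance")
  expect_error(zscore_normalize(3), "length")
})

test_that("preprocessing is identity with no options and denoises salt noise", {
  ph <- small_phantom(2, noise = 0)
  expect_identical(preprocess_image(ph$image, "none", "none"), ph$image)

  const <- matrix(0.4, 20, 20)
  expect_equal(preprocess_image(const, "none", "stretch"), const)

  # salt noise: median filter must strictly reduce MAE to the clean image
  noisy <- ph$image
  set.seed(9)
  hit <- sample(length(noisy), 80)
  noisy[hit] <- 1
  den <- preprocess_image(noisy, "median", "none")
  expect_lt(mean(abs(den - ph$image)), mean(abs(noisy - ph$image)))

  g <- preprocess_image(noisy, "gaussian", "clahe")
  expect_true(all(g >= 0 & g <= 1))
  expect_identical(dim(g), dim(noisy))
})

test_that("otsu equals the exhaustive between-class-variance sweep", {
  # two-level disc image: otsu mask recovers the disc exactly
  img <- matrix(0.2, 40, 40)
  rows <- matrix(1:40, 40, 40); cols <- t(rows)
  disc <- (rows - 20)^2 + (cols - 20)^2 <= 100
  img[disc] <- 0.9
  expect_identical(segment(img, "otsu"), disc)

  set.seed(4)
  for (i in 1:10) {
    im <- matrix(runif(400)^runif(1, 0.5, 2), 20, 20)
    expect_equal(otsu_threshold(im), otsu_oracle(im), tolerance = 1e-12)
  }
})

test_that("fixed and region-growing segmentation behave per contract", {
  img <- matrix(runif(400, 0, 0.99), 20, 20)
  expect_false(any(segment(img, "fixed", t = 1.0)))

  # crisp two-blob image: growing from one seed recovers exactly that
  # blob's connected component of the truth mask
  two <- matrix(0.2, 40, 40)
  rows <- matrix(1:40, 40, 40); cols <- t(rows)
  blob1 <- (rows - 12)^2 + (cols - 12)^2 <= 36
  blob2 <- (rows - 30)^2 + (cols - 28)^2 <= 25
  two[blob1] <- 0.85; two[blob2] <- 0.7
  grown <- segment(two, "region_grow", seeds = cbind(12, 12), tol = 0.2)
  expect_identical(unname(grown), unname(blob1))
  expect_identical(cc_count_oracle(blob1 | blob2), 2L)
  expect_error(segment(two, "region_grow", seeds = cbind(999, 1)), "bounds")
  expect_error(segment(two, "region_grow"), "seed")
})

test_that("feature extraction matches direct oracles", {
  # degenerate: constant image, full mask
  const <- matrix(0.5, 16, 16)
  fv <- extract_features(const, matrix(TRUE, 16, 16), hist_bins = 8)
  expect_identical(sum(fv$intensity$hist > 0), 1L)
  expect_equal(fv$texture$entropy, 0)
  expect_equal(fv$texture$energy, 1)

  # disc area within 5% of pi r^2
  img <- matrix(0, 64, 64)
  rows <- matrix(1:64, 64, 64); cols <- t(rows)
  disc <- (rows - 32)^2 + (cols - 32)^2 <= 12^2
  fv <- extract_features(img + disc * 0.8, disc)
  expect_lt(abs(fv$shape$area - pi * 144) / (pi * 144), 0.05)
  expect_lt(fv$shape$eccentricity, 0.1)

  # checkerboard has maximal co-occurrence contrast among the three
  # patterns, each checked against a direct GLCM computation
  checker <- (outer(1:8, 1:8, "+") %% 2) * 0.99
  grad <- matrix(seq(0, 0.99, length.out = 8), 8, 8)
  full <- matrix(TRUE, 8, 8)
  bins <- 8
  con <- vapply(list(checker, matrix(0.3, 8, 8), grad), function(im) {
    got <- extract_features(im, full, bins)$texture
    want <- glcm_oracle(im, bins)
    expect_equal(got$contrast, want$contrast, tolerance = 1e-12)
    expect_equal(got$homogeneity, want$homogeneity, tolerance = 1e-12)
    expect_equal(got$energy, want$energy, tolerance = 1e-12)
    expect_equal(got$entropy, want$entropy, tolerance = 1e-12)
    got$contrast
  }, 0)
  expect_true(con[1] > con[2] && con[1] > con[3])
  expect_error(extract_features(const, matrix(FALSE, 16, 16)), "empty")
})

test_that("features_to_distribution lands on the simplex", {
  expect_equal(features_to_distribution(c(2, 2, 2, 2)), rep(0.25, 4))
  expect_equal(features_to_distribution(c(0, 1, 3)), c(0, 0.25, 0.75),
               tolerance = 1e-9)
  set.seed(8)
  for (i in 1:50) {
    d <- features_to_distribution(rnorm(sample(3:60, 1), sd = 10))
    expect_gte(min(d), 0)
    expect_lt(abs(sum(d) - 1), 1e-9)
  }
  expect_error(features_to_distribution(c(1, NA, 2)), "finite")
})

test_that("PGM round trip is lossless at 8-bit", {
  img <- round(small_phantom(3)$image * 255) / 255
  p2 <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, p2)
  expect_equal(read_pgm(p2), img, tolerance = 1e-12)
  p5 <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, p5, ascii = FALSE)
  expect_equal(read_pgm(p5), img, tolerance = 1e-12)
})
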