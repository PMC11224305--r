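make_cube <- function(arr, grid, phase) hyperspectral_cube(arr, grid, phase)

test_that("dark correction subtracts the dark cube and clips at zero", {
  g <- wavelength_grid(n_bands = 5)
  sig <- array(runif(4 * 4 * 5, 1, 10), c(4, 4, 5))
  dark <- array(2, c(4, 4, 5))
  blue0 <- make_cube(sig, g, "blue")
  darkc <- make_cube(dark, g, "dark")

  ident <- dark_correct(blue0, make_cube(array(0, c(4, 4, 5)), g, "dark"))
  expect_equal(ident$data, sig)

  zero <- dark_correct(make_cube(dark, g, "blue"), darkc)
  expect_equal(max(abs(zero$data)), 0)

  known <- dark_correct(make_cube(dark + sig, g, "blue"), darkc)
  expect_equal(known$data, sig)

  expect_error(dark_correct(blue0, blue0), class = "hsifluor_validation_error")
})

test_that("dual-band normalization follows the geometric-mean formula", {
  g <- wavelength_grid()
  y <- spectrum(runif(310, 1, 5), g)

  unit <- dual_band_normalize(y, spectrum(rep(1, 310), g))
  expect_equal(as.numeric(unit), as.numeric(y))

  w <- rep(1, 310)
  w[as.numeric(g) >= 460 & as.numeric(g) <= 480] <- 4  # R_a = 4, R_b = 1
  half <- dual_band_normalize(y, spectrum(w, g))
  expect_equal(as.numeric(half), as.numeric(y) / 2)
  expect_equal(attr(half, "norm_factor"), 2)

  # uniform illumination scaling alpha applied to both the fluorescence and
  # the white reference cancels: alpha / sqrt(alpha * alpha) = 1
  alpha <- 3.7
  base <- dual_band_normalize(y, spectrum(w, g))
  scaled <- dual_band_normalize(spectrum(alpha * as.numeric(y), g),
                                spectrum(alpha * w, g))
  expect_equal(as.numeric(scaled), as.numeric(base), tolerance = 1e-12)

  expect_error(dual_band_normalize(y, spectrum(rep(0, 310), g)),
               class = "hsifluor_degenerate_reference_error")
})

# builds a blue cube whose 634 nm band contains the given intensity image
cube_from_image <- function(img, n_bands = 9) {
  g <- wavelength_grid(620, 650, n_bands)
  arr <- array(rep(img, n_bands), c(dim(img), n_bands))
  make_cube(arr, g, "blue")
}

test_that("a bright disk on dark background is segmented cleanly", {
  img <- matrix(0, 100, 100)
  disk <- disk_mask(100, c(50, 50), 30)
  img[disk] <- 10
  m <- segment_tumor(cube_from_image(img))
  jaccard <- sum(m$mask & disk) / sum(m$mask | disk)
  expect_gte(jaccard, 0.99)
  expect_match(m$method, "otsu")
})

test_that("an all-zero cube yields an empty mask with a warning", {
  expect_warning(m <- segment_tumor(cube_from_image(matrix(0, 20, 20))),
                 "empty mask")
  expect_false(any(m$mask))
})

test_that("artifact exclusion keeps only the largest bright component", {
  img <- matrix(0, 120, 120)
  big <- disk_mask(120, c(45, 45), 25)
  splash <- disk_mask(120, c(95, 95), 10)
  img[big] <- 8
  img[splash] <- 12
  kept <- segment_tumor(cube_from_image(img), exclude_artifacts = TRUE)
  expect_gte(sum(kept$mask & big) / sum(big), 0.95)
  expect_equal(sum(kept$mask & splash), 0)
  both <- segment_tumor(cube_from_image(img), exclude_artifacts = FALSE)
  expect_gt(sum(both$mask & splash), 0)
})

test_that("block extraction arithmetic and disjointness", {
  g <- wavelength_grid(n_bands = 4)
  arr <- array(7, c(60, 60, 4))
  cube <- make_cube(arr, g, "blue")

  mask <- matrix(FALSE, 60, 60)
  mask[11:50, 11:50] <- TRUE  # 40 x 40 square
  bs <- extract_block_spectra(cube, mask, block_size = 10)
  expect_equal(nrow(bs$spectra), 16)
  for (i in seq_len(16)) expect_equal(unname(bs$spectra[i, ]), rep(7, 4))

  # pairwise disjoint: no pixel contributes twice
  covered <- matrix(0, 60, 60)
  for (i in seq_len(nrow(bs$block_origin))) {
    r <- bs$block_origin$row0[i] + 1
    c <- bs$block_origin$col0[i] + 1
    covered[r:(r + 9), c:(c + 9)] <- covered[r:(r + 9), c:(c + 9)] + 1
  }
  expect_lte(max(covered), 1)

  small <- matrix(FALSE, 60, 60)
  small[1:9, 1:9] <- TRUE
  expect_equal(nrow(extract_block_spectra(cube, small, 10)$spectra), 0)
})

test_that("noiseless pipeline composition recovers phantom block abundances", {
  pr <- margin_preset(1)[[1]]
  ph <- biopsy_phantom(pr, diameter_px = 70, field_size = 140, seed = 21)
  B <- synthetic_basis()
  trip <- simulate_biopsy_cube(ph, B, noiseless(), seed = 22)
  bs <- preprocess_triplet(trip)
  key <- function(d) paste(d$row0, d$col0)
  m <- match(key(bs$block_origin), key(ph$blocks))
  expect_false(anyNA(m))
  expect_equal(nrow(bs$spectra), nrow(ph$blocks))
  ab <- unmix_matrix(bs$spectra * bs$norm_factor, B)
  expect_lt(max(abs(ab - ph$abundances[m, ])), 1e-6)
})

test_that("segmentation recall stays high at moderate contrast and noise", {
  pr <- margin_preset(1)[[1]]
  ph <- biopsy_phantom(pr, diameter_px = 80, field_size = 160, seed = 31)
  B <- synthetic_basis(wavelength_grid(n_bands = 30))
  trip <- simulate_biopsy_cube(ph, B, acquisition_noise_model(2, 1, 100),
                               seed = 32)
  blue <- dark_correct(trip$blue, trip$dark)
  m <- segment_tumor(blue)
  truth <- phantom_mask(ph)
  recall <- sum(m$mask & truth) / sum(truth)
  expect_gte(recall, 0.95)
})
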