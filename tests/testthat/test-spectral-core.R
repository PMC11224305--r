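test_that("default wavelength grid has 310 bands spanning 420-729 nm", {
  g <- wavelength_grid()
  expect_length(g, 310)
  expect_equal(as.numeric(g[1]), 420)
  expect_equal(as.numeric(g[length(g)]), 729)
  expect_true(all(diff(as.numeric(g)) > 0))
  expect_error(wavelength_grid(values = c(500, 450)), class = "hsifluor_grid_error")
})

test_that("synthetic basis peaks sit at the PpIX photo-state wavelengths", {
  B <- synthetic_basis()
  expect_identical(colnames(B$matrix),
                   c("PpIX634", "PpIX620", "NADH", "lipofuscin", "flavins"))
  lam <- as.numeric(B$grid)
  expect_equal(lam[which.max(B$matrix[, "PpIX634"])], 634)
  expect_equal(lam[which.max(B$matrix[, "PpIX620"])], 620)
  expect_true(all(B$matrix >= 0))
})

test_that("basis normalization contracts hold for any peak parameters", {
  pp <- default_peak_params()
  pp$fwhm_nm <- c(12, 30, 60, 90, 45)
  Bp <- synthetic_basis(peak_params = pp, normalization = "peak")
  expect_equal(unname(apply(Bp$matrix, 2, max)), rep(1, 5))
  Ba <- synthetic_basis(peak_params = pp, normalization = "area")
  dl <- mean(diff(as.numeric(Ba$grid)))
  expect_equal(unname(colSums(Ba$matrix) * dl), rep(1, 5), tolerance = 1e-12)
})

test_that("a delta-like peak approaches a one-hot column", {
  pp <- default_peak_params()
  pp$fwhm_nm[1] <- 0.05
  pp$skew[1] <- 0
  B <- synthetic_basis(peak_params = pp)
  col <- B$matrix[, 1]
  expect_equal(max(col), 1)
  expect_lt(sum(col) - 1, 1e-6)  # all mass in one band
})

test_that("peak centers outside the grid are rejected", {
  pp <- default_peak_params()
  pp$center_nm[3] <- 300
  expect_error(synthetic_basis(peak_params = pp),
               class = "hsifluor_parameter_error")
})

test_that("basis CSV writes and reads back identically", {
  B <- synthetic_basis()
  path <- withr::local_tempfile(fileext = ".csv")
  write_basis_csv(B, path)
  B2 <- read_basis_csv(path)
  expect_lt(max(abs(B$matrix - B2$matrix)), 1e-12)
  expect_equal(as.numeric(B$grid), as.numeric(B2$grid))
})

test_that("malformed basis CSV is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(wavelength_nm = 1:5, PpIX634 = 1, PpIX620 = 1, NADH = 1)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_basis_csv(path), class = "hsifluor_format_error")
  df2 <- data.frame(wavelength_nm = c(1, 3, 2, 4, 5), PpIX634 = 1,
                    PpIX620 = 1, NADH = 1, lipofuscin = 1, flavins = 1)
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_basis_csv(path), class = "hsifluor_format_error")
})

test_that("resampling onto the identical grid is the identity", {
  g <- wavelength_grid()
  s <- spectrum(runif(310), g)
  expect_equal(as.numeric(resample_to_grid(s, g)), as.numeric(s))
})

test_that("resampling a linear ramp gives exact linear interpolation", {
  src <- wavelength_grid(values = seq(420, 720, by = 5))
  ramp <- spectrum(2 * as.numeric(src) - 100, src)
  tgt <- wavelength_grid(values = seq(420, 720, by = 1))
  out <- resample_to_grid(ramp, tgt)
  expect_equal(as.numeric(out), 2 * as.numeric(tgt) - 100, tolerance = 1e-12)
  expect_error(resample_to_grid(ramp, wavelength_grid(400, 730, 50)),
               class = "hsifluor_grid_error")
})

test_that("noiseless mixtures are recovered exactly by NNLS", {
  B <- synthetic_basis()
  truth <- c(1, 2, 0, 0, 3)
  y <- reconstruct_spectrum(truth, B)
  c_hat <- unmix_nnls(y, B)
  expect_lt(max(abs(c_hat - truth)), 1e-8)
  expect_lt(attr(c_hat, "residual_norm"), 1e-8)

  z <- unmix_nnls(spectrum(rep(0, 310)), B)
  expect_equal(as.numeric(z), rep(0, 5))
  expect_equal(attr(z, "residual_norm"), 0)
})

test_that("NNLS recovers random non-negative mixtures from a full-rank basis", {
  B <- synthetic_basis()
  set.seed(101)
  for (i in 1:20) {
    truth <- rexp(5)
    y <- reconstruct_spectrum(truth, B)
    expect_lt(max(abs(unmix_nnls(y, B) - truth)), 1e-8)
  }
})

test_that("NNLS is scaling-equivariant", {
  B <- synthetic_basis()
  set.seed(7)
  y <- spectrum(abs(drop(B$matrix %*% rexp(5)) + rnorm(310, sd = 5)), B$grid)
  base <- unmix_nnls(y, B)
  for (alpha in c(0, 0.5, 3, 100)) {
    scaled <- unmix_nnls(spectrum(alpha * as.numeric(y), B$grid), B)
    expect_equal(as.numeric(scaled), alpha * as.numeric(base),
                 tolerance = 1e-8)
  }
})

test_that("NNLS objective matches the exhaustive support-enumeration oracle", {
  set.seed(2024)
  for (i in 1:100) {
    A <- matrix(abs(rnorm(50)), 10, 5)
    b <- drop(A %*% abs(rnorm(5))) + rnorm(10, sd = 0.3)
    fit <- nnls_solve(A, b)
    expect_lt(abs(0.5 * fit$residual_norm^2 -
                  brute_force_nnls_objective(A, b)), 1e-10)
  }
})

test_that("NNLS agrees with an established solver on random instances", {
  skip_if_not_installed("pracma")
  set.seed(5)
  for (i in 1:20) {
    A <- matrix(abs(rnorm(60)), 12, 5)
    b <- abs(rnorm(12))
    ours <- nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(ours$x, ref$x, tolerance = 1e-8)
  }
})

test_that("adding a sixth basis column never increases the residual", {
  set.seed(12)
  for (i in 1:25) {
    A <- matrix(abs(rnorm(60)), 12, 5)
    b <- abs(rnorm(12))
    r5 <- nnls_solve(A, b)$residual_norm
    r6 <- nnls_solve(cbind(A, abs(rnorm(12))), b)$residual_norm
    expect_lte(r6, r5 + 1e-12)
  }
})

test_that("reconstruction is the linear mixture of basis columns", {
  B <- synthetic_basis()
  onehot <- reconstruct_spectrum(c(1, 0, 0, 0, 0), B)
  expect_equal(as.numeric(onehot), unname(B$matrix[, 1]))
  expect_equal(as.numeric(reconstruct_spectrum(rep(0, 5), B)), rep(0, 310))
  set.seed(3)
  truth <- rexp(5)
  y <- reconstruct_spectrum(truth, B)
  y2 <- reconstruct_spectrum(unmix_nnls(y, B), B)
  expect_lt(max(abs(as.numeric(y) - as.numeric(y2))), 1e-8)
})

test_that("grid mismatch between spectrum and basis is an error", {
  B <- synthetic_basis()
  s <- spectrum(runif(50), wavelengths <- wavelength_grid(420, 729, 50))
  expect_error(unmix_nnls(s, B), class = "hsifluor_shape_error")
})
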