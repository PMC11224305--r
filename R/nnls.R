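#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min_x 0.5 * ||A x - b||^2` subject to `x >= 0`. This is the
#' workhorse behind spectral unmixing: at termination the Karush-Kuhn-Tucker
#' conditions hold, i.e. for every active (positive) coefficient the gradient
#' component `(A'(Ax - b))_i` is zero within `tol`, and for every zero
#' coefficient it is `>= -tol`.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol KKT tolerance; default `1e-10 * max(|A'b|)` (scale-free).
#' @param max_iter Safety cap on active-set iterations.
#' @return List with `x` (solution, length n), `residual_norm` = `||Ax - b||`,
#'   and `iterations`.
#' @export
nnls_solve <- function(A, b, tol = NULL, max_iter = 30 * ncol(A)) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) {
    stop_hsi("nrow(A) must equal length(b)", "hsifluor_shape_error")
  }
  n <- ncol(A)
  Atb <- drop(crossprod(A, b))
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1e-300)

  x <- numeric(n)
  passive <- rep(FALSE, n)     # P: coefficients allowed to be positive
  w <- Atb                     # negative gradient -A'(Ax - b) at x = 0
  iter <- 0L

  repeat {
    # outer loop: grow the passive set while an inactive coefficient has a
    # strictly positive gradient descent direction
    candidates <- which(!passive & w > tol)
    if (!length(candidates)) break
    j <- candidates[which.max(w[candidates])]
    passive[j] <- TRUE

    repeat {
      iter <- iter + 1L
      if (iter > max_iter) break
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0   # rank-deficient subproblem: drop dependent cols
      if (all(z[P] > 0)) {
        x <- z
        break
      }
      # inner loop: step toward z until the first passive coefficient hits 0
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol * max(abs(x), 1)] <- FALSE
      x[!passive] <- 0
    }
    if (iter > max_iter) break
    w <- Atb - drop(crossprod(A, A %*% x))
  }

  r <- b - drop(A %*% x)
  list(x = x, residual_norm = sqrt(sum(r^2)), iterations = iter)
}

#' Unmix a measured spectrum into fluorophore abundances
#'
#' Finds the non-negative abundance vector c minimizing
#' `0.5 * ||y - B c||^2`, where the columns of B are the five endmember
#' emission spectra. Abundances carry the intensity units of the spectrum per
#' unit (normalized) basis column.
#'
#' @param y A [spectrum()] on the same grid as the basis.
#' @param basis A `fluorophore_basis`.
#' @param tol Optional KKT tolerance passed to [nnls_solve()].
#' @return An `abundance_vector`: named numeric 5-vector with attribute
#'   `residual_norm` (`||y - Bc||`).
#' @examples
#' B <- synthetic_basis()
#' truth <- c(PpIX634 = 1, PpIX620 = 2, NADH = 0, lipofuscin = 0, flavins = 3)
#' y <- reconstruct_spectrum(truth, B)
#' round(unmix_nnls(y, B), 8)
#' @export
unmix_nnls <- function(y, basis, tol = NULL) {
  g <- attr(y, "grid")
  if (is.null(g)) y <- spectrum(y, basis$grid) else if (!grids_equal(g, basis$grid)) {
    stop_hsi("spectrum and basis are on different wavelength grids",
             "hsifluor_shape_error")
  }
  fit <- nnls_solve(basis$matrix, as.numeric(y), tol = tol)
  structure(stats::setNames(fit$x, basis$names),
            residual_norm = fit$residual_norm,
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  print(round(unclass(x), 6))
  cat(sprintf("residual_norm: %.6g\n", attr(x, "residual_norm")))
  invisible(x)
}

#' Reconstruct a spectrum from fluorophore abundances
#'
#' Returns the linear mixture `B c`.
#' @param c Numeric 5-vector of abundances (an `abundance_vector` or plain
#'   numeric in canonical fluorophore order).
#' @param basis A `fluorophore_basis`.
#' @return A [spectrum()] on the basis grid.
#' @export
reconstruct_spectrum <- function(c, basis) {
  spectrum(drop(basis$matrix %*% as.numeric(c)), basis$grid)
}

#' Unmix a matrix of spectra
#'
#' Row-wise [unmix_nnls()] for a spectra matrix (one spectrum per row).
#' @param Y m x bands matrix.
#' @param basis A `fluorophore_basis`.
#' @return m x 5 abundance matrix with a `residual_norm` attribute (length m).
#' @export
unmix_matrix <- function(Y, basis) {
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(basis$matrix)) {
    stop_hsi("spectra matrix width does not match basis grid",
             "hsifluor_shape_error")
  }
  out <- matrix(0, nrow(Y), ncol(basis$matrix),
                dimnames = list(NULL, basis$names))
  res <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    fit <- nnls_solve(basis$matrix, Y[i, ])
    out[i, ] <- fit$x
    res[i] <- fit$residual_norm
  }
  attr(out, "residual_norm") <- res
  out
}
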