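#' PCA with variance-explained reporting
#'
#' Mean-centers the data, eigendecomposes its covariance matrix, keeps the
#' `n` components with the largest eigenvalues, and reports the variance
#' explained: the sum of the selected eigenvalues over the total variance
#' (the trace of the covariance matrix).
#'
#' @param data m x d numeric matrix or data.frame (rows = samples).
#' @param n Number of components to keep (1 <= n <= d).
#' @return A `pca_result`: list with `components` (d x n loadings),
#'   `eigenvalues` (all d, non-increasing), `variance_explained` (in
#'   `[0, 1]`), `mean` (the subtracted column means), `scores` (m x n
#'   projections).
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' pca_variance_explained(X, 2)$variance_explained
#' @export
pca_variance_explained <- function(data, n) {
  X <- as.matrix(data)
  if (nrow(X) < 2) stop_hsi("need at least 2 rows", "hsifluor_parameter_error")
  if (n < 1 || n > ncol(X)) {
    stop_hsi("n must be between 1 and ncol(data)", "hsifluor_parameter_error")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- stats::cov(Xc)
  total <- sum(diag(C))
  if (total <= 0) {
    stop_hsi("data has zero total variance", "hsifluor_zero_variance_error")
  }
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  structure(list(components = eg$vectors[, seq_len(n), drop = FALSE],
                 eigenvalues = ev,
                 variance_explained = sum(ev[seq_len(n)]) / sum(ev),
                 mean = mu,
                 scores = Xc %*% eg$vectors[, seq_len(n), drop = FALSE]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, variance explained %.1f%%\n",
              ncol(x$components), 100 * x$variance_explained))
  invisible(x)
}

#' t-SNE embedding for visualization
#'
#' Deterministic (seeded) t-distributed stochastic neighbor embedding in 2 or
#' 3 dimensions. Used for plotting only; embeddings are never fed to the
#' classifiers.
#'
#' @param data m x d matrix.
#' @param dims 2 or 3.
#' @param perplexity t-SNE perplexity; requires `m > 3 * perplexity`.
#' @param seed Integer seed.
#' @return m x dims embedding matrix.
#' @export
tsne_embed <- function(data, dims = 2, perplexity = 30, seed = 1) {
  X <- as.matrix(data)
  if (!dims %in% c(2, 3)) {
    stop_hsi("dims must be 2 or 3", "hsifluor_parameter_error")
  }
  if (nrow(X) <= 3 * perplexity) {
    stop_hsi("too few samples for this perplexity (need m > 3*perplexity)",
             "hsifluor_parameter_error")
  }
  with_seed(seed, {
    fit <- Rtsne::Rtsne(X, dims = dims, perplexity = perplexity,
                        check_duplicates = FALSE, pca = TRUE, verbose = FALSE)
    fit$Y
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sample KS statistic `D` and its p-value. The default
#' asymptotic p-value uses the Kolmogorov distribution evaluated at
#' `D * (sqrt(ne) + 0.12 + 0.11/sqrt(ne))` with effective sample size
#' `ne = n1*n2/(n1+n2)`, the classical small-sample-corrected approximation
#' used by common implementations; `method = "permutation"` enumerates (or
#' samples) label reassignments for an exact small-n reference.
#'
#' @param x,y Numeric samples (unequal sizes allowed).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm Permutation count; complete enumeration is used when
#'   `choose(n1+n2, n1) <= n_perm`.
#' @param seed Seed for sampled permutations.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 1e5, seed = 1) {
  method <- match.arg(method)
  d <- ks_statistic(x, y)
  if (method == "asymptotic") {
    n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y))
    ne <- n1 * n2 / (n1 + n2)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
    p <- ks_q(lambda)
  } else {
    n1 <- length(x)
    pooled <- c(x, y)
    n <- length(pooled)
    if (choose(n, n1) <= n_perm) {
      combs <- utils::combn(n, n1)
      ds <- apply(combs, 2, function(idx) {
        ks_statistic(pooled[idx], pooled[-idx])
      })
    } else {
      ds <- with_seed(seed, replicate(n_perm, {
        idx <- sample.int(n, n1)
        ks_statistic(pooled[idx], pooled[-idx])
      }))
    }
    p <- mean(ds >= d - 1e-12)
  }
  list(statistic = d, p_value = min(max(p, 0), 1))
}

ks_statistic <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(all_v)
  Fy <- stats::ecdf(y)(all_v)
  max(abs(Fx - Fy))
}

# Kolmogorov distribution tail Q(lambda) = 2 * sum (-1)^{j-1} exp(-2 j^2 l^2)
ks_q <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Pairwise KS significance battery over fluorophore abundances
#'
#' For every unordered pair of classes and every fluorophore, tests the null
#' hypothesis that the two classes' abundances come from the same
#' distribution. Pairs/fluorophores with `p >= alpha` are collected as
#' exceptions. All supplied samples are pooled per class; no multiple-testing
#' correction is applied by default (raw pairwise p-values at `alpha`), an
#' adjustment method can be requested.
#'
#' @param abundances m x 5 matrix (columns = fluorophores).
#' @param labels Length-m class labels.
#' @param alpha Significance level (default 0.01).
#' @param method p-value method for [ks_two_sample()].
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method,
#'   applied across all pair-by-fluorophore tests.
#' @return A `ks_report`: list with `table` (long data.frame:
#'   `fluorophore,class_a,class_b,D,p_value,significant`), `p_values` (list
#'   of symmetric per-fluorophore matrices with unit diagonal),
#'   `exceptions` (rows with `p >= alpha`), `alpha`, `classes`.
#' @export
ks_battery <- function(abundances, labels, alpha = 0.01,
                       method = c("asymptotic", "permutation"),
                       p_adjust = "none") {
  method <- match.arg(method)
  A <- as.matrix(abundances)
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding classes with fewer than 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !labels %in% small
    A <- A[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop_hsi("need at least two classes with >= 2 samples each",
             "hsifluor_parameter_error")
  }
  fl <- colnames(A)
  if (is.null(fl)) fl <- paste0("f", seq_len(ncol(A)))
  pairs <- utils::combn(classes, 2)
  rows <- list()
  pv <- lapply(fl, function(f) {
    m <- matrix(1, length(classes), length(classes),
                dimnames = list(classes, classes))
    m
  })
  names(pv) <- fl
  r <- 0L
  for (j in seq_along(fl)) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      res <- ks_two_sample(A[labels == a, j], A[labels == b, j],
                           method = method)
      pv[[j]][a, b] <- pv[[j]][b, a] <- res$p_value
      r <- r + 1L
      rows[[r]] <- data.frame(fluorophore = fl[j], class_a = a, class_b = b,
                              D = res$statistic, p_value = res$p_value,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (p_adjust != "none") {
    tab$p_value <- stats::p.adjust(tab$p_value, method = p_adjust)
    for (j in seq_along(fl)) {
      idx <- tab$fluorophore == fl[j]
      pv[[j]][cbind(tab$class_a[idx], tab$class_b[idx])] <- tab$p_value[idx]
      pv[[j]][cbind(tab$class_b[idx], tab$class_a[idx])] <- tab$p_value[idx]
    }
  }
  tab$significant <- tab$p_value < alpha
  structure(list(table = tab, p_values = pv,
                 exceptions = tab[!tab$significant, , drop = FALSE],
                 alpha = alpha, classes = classes),
            class = "ks_report")
}

#' @export
print.ks_report <- function(x, ...) {
  cat(sprintf("<ks_report> %d classes, %d tests at alpha=%g: %d exception(s)\n",
              length(x$classes), nrow(x$table), x$alpha, nrow(x$exceptions)))
  if (nrow(x$exceptions)) print(x$exceptions)
  else cat("  all class pairs significantly different in all fluorophores\n")
  invisible(x)
}

#' Export a KS report to the long CSV format
#'
#' Columns: `task,fluorophore,class_a,class_b,D,p_value,significant`.
#' @param report A `ks_report`.
#' @param path Output CSV.
#' @param task Task name written to every row.
#' @export
write_ks_csv <- function(report, path, task = "") {
  df <- cbind(task = task, report$table)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
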