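# Independent oracles used across the suite. These never call the code paths
# they are checking.

# Exhaustive-support NNLS oracle: solve unconstrained least squares on every
# subset of columns, keep non-negative solutions, return the smallest
# objective 0.5*||Ax - b||^2.
brute_force_nnls_objective <- function(A, b) {
  n <- ncol(A)
  best <- 0.5 * sum(b^2)  # empty support
  for (s in seq_len(2^n - 1)) {
    S <- which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)
    cf <- qr.coef(qr(A[, S, drop = FALSE]), b)
    cf[is.na(cf)] <- 0
    x <- numeric(n)
    x[S] <- cf
    if (all(x >= 0)) {
      obj <- 0.5 * sum((A %*% x - b)^2)
      if (obj < best) best <- obj
    }
  }
  best
}

# Pairwise rank-comparison AUC: concordant pairs + half ties.
rank_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Mean silhouette coefficient for a 2-group labeling of an embedding.
silhouette_mean <- function(emb, labels) {
  d <- as.matrix(dist(emb))
  s <- vapply(seq_len(nrow(emb)), function(i) {
    same <- labels == labels[i]
    a <- mean(d[i, same & seq_len(nrow(emb)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Small, fast margin dataset used by several classification tests.
small_margin_dataset <- function(delta = 1, n_biopsies = 4, seed = 42) {
  simulate_dataset("margin", margin_preset(delta),
                   n_biopsies_per_class = n_biopsies, seed = seed,
                   field_size = 600, diameter_range = c(190, 280))
}

# A hand-built dataset-like object with explicit per-class block counts,
# for testing the balancing/exclusion rules without simulation.
roster_dataset <- function(counts, seed = 1) {
  set.seed(seed)
  blocks <- do.call(rbind, lapply(names(counts), function(cl) {
    n <- counts[[cl]]
    data.frame(biopsy_id = paste0(cl, "_b", rep(1:2, length.out = n)),
               label = cl,
               row0 = 10 * (seq_len(n) %% 25),
               col0 = 10 * (seq_len(n) %/% 25),
               stringsAsFactors = FALSE)
  }))
  list(blocks = blocks,
       abundances = matrix(abs(rnorm(nrow(blocks) * 5)), ncol = 5,
                           dimnames = list(NULL, c("PpIX634", "PpIX620",
                                                   "NADH", "lipofuscin",
                                                   "flavins"))))
}
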