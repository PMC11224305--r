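#' Model grids for the classification protocol
#'
#' A model specification is `list(algorithm = <name>, params = <list>)`.
#' `model_grid_table1()` enumerates the full published search grid:
#' random forests (number of trees 50-150, minimum node size, feature
#' subsampling sqrt/log2/all), KNN (k in 3-9, uniform/distance weights,
#' Minkowski p 1-2), SVM (RBF/linear/polynomial/sigmoid kernels), multilayer
#' perceptrons (1-3 hidden ReLU layers of 25-150 neurons, Adam or L-BFGS),
#' and AdaBoost (50 stumps, SAMME.R). The random-forest engine splits on Gini
#' impurity; alternative split criteria are not enumerated.
#' `model_grid_default()` is a small per-family grid for demos and quick
#' runs.
#'
#' @return List of model specifications.
#' @export
model_grid_table1 <- function() {
  grid <- list()
  for (nt in c(50, 75, 100, 125, 150)) {
    for (mf in c("sqrt", "log2", "all")) {
      for (ns in c(2, 3, 4)) {
        grid[[length(grid) + 1]] <- model_spec("random_forest",
          ntree = nt, max_features = mf, nodesize = ns)
      }
    }
  }
  for (k in c(3, 5, 7, 9)) {
    for (w in c("uniform", "distance")) {
      for (p in c(1, 2)) {
        grid[[length(grid) + 1]] <- model_spec("knn", k = k, weights = w,
                                               p = p)
      }
    }
  }
  for (kn in c("radial", "linear", "polynomial", "sigmoid")) {
    grid[[length(grid) + 1]] <- model_spec("svm", kernel = kn)
  }
  for (hl in 1:3) {
    for (nn in c(25, 50, 100, 150)) {
      for (sv in c("adam", "lbfgs")) {
        grid[[length(grid) + 1]] <- model_spec("mlp", hidden_layers = hl,
                                               neurons = nn, solver = sv)
      }
    }
  }
  grid[[length(grid) + 1]] <- model_spec("adaboost", n_estimators = 50,
                                         learning_rate = 1)
  grid
}

#' @rdname model_grid_table1
#' @export
model_grid_default <- function() {
  list(model_spec("random_forest", ntree = 100, max_features = "sqrt",
                  nodesize = 2),
       model_spec("knn", k = 5, weights = "distance", p = 2),
       model_spec("svm", kernel = "radial"),
       model_spec("mlp", hidden_layers = 1, neurons = 50, solver = "adam"),
       model_spec("adaboost", n_estimators = 50, learning_rate = 1))
}

#' @rdname model_grid_table1
#' @param algorithm One of `"random_forest"`, `"knn"`, `"svm"`, `"mlp"`,
#'   `"adaboost"`.
#' @param ... Hyperparameters for that algorithm.
#' @export
model_spec <- function(algorithm, ...) {
  algorithm <- match.arg(algorithm,
                         c("random_forest", "knn", "svm", "mlp", "adaboost"))
  structure(list(algorithm = algorithm, params = list(...)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  sprintf("%s(%s)", x$algorithm, ps)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Fit a classification model
#'
#' Dispatches a [model_spec()] to its engine. All engines consume a numeric
#' feature matrix and a factor of labels and expose class-probability
#' predictions through [predict_model()].
#'
#' @param spec A [model_spec()].
#' @param x m x p feature matrix.
#' @param y Length-m labels (coerced to factor).
#' @param seed Optional seed (tree and initialization randomness).
#' @return A fitted `hsif_model`.
#' @export
fit_model <- function(spec, x, y, seed = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  fit <- with_seed(seed, switch(spec$algorithm,
    random_forest = fit_rf(spec$params, x, y),
    knn = fit_knn(spec$params, x, y),
    svm = fit_svm(spec$params, x, y),
    mlp = fit_mlp(spec$params, x, y),
    adaboost = fit_adaboost(spec$params, x, y)))
  structure(list(spec = spec, fit = fit, levels = levels(y)),
            class = "hsif_model")
}

#' @rdname fit_model
#' @param model A fitted `hsif_model`.
#' @param newdata Feature matrix to predict.
#' @return `predict_model`: list with `class` (factor) and `prob`
#'   (m x K matrix of class scores summing to 1 per row).
#' @export
predict_model <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  prob <- switch(model$spec$algorithm,
    random_forest = predict(model$fit, newdata, type = "prob"),
    knn = predict_knn(model$fit, newdata),
    svm = attr(predict(model$fit, newdata, probability = TRUE),
               "probabilities"),
    mlp = predict_mlp(model$fit, newdata),
    adaboost = predict_adaboost(model$fit, newdata))
  prob <- prob[, model$levels, drop = FALSE]
  cls <- factor(model$levels[max.col(prob, ties.method = "first")],
                levels = model$levels)
  list(class = cls, prob = prob)
}

# ---- random forest (randomForest; Gini splitting) --------------------------

fit_rf <- function(p, x, y) {
  mtry <- switch(p$max_features %||% "sqrt",
                 sqrt = max(1, floor(sqrt(ncol(x)))),
                 log2 = max(1, floor(log2(ncol(x)))),
                 all = ncol(x))
  randomForest::randomForest(x = x, y = y, ntree = p$ntree %||% 100,
                             mtry = mtry, nodesize = p$nodesize %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- k-nearest neighbors (Minkowski p, uniform/distance weights) -----------

fit_knn <- function(p, x, y) {
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2, stats::sd), 1e-12)
  list(x = scale(x, ctr, scl), y = y, k = p$k %||% 5,
       weights = p$weights %||% "uniform", p = p$p %||% 2,
       center = ctr, scale = scl, levels = levels(y))
}

predict_knn <- function(fit, newdata) {
  Z <- scale(newdata, fit$center, fit$scale)
  K <- length(fit$levels)
  prob <- matrix(0, nrow(Z), K, dimnames = list(NULL, fit$levels))
  for (i in seq_len(nrow(Z))) {
    d <- (rowSums(abs(sweep(fit$x, 2, Z[i, ]))^fit$p))^(1 / fit$p)
    nn <- order(d)[seq_len(fit$k)]
    w <- if (fit$weights == "distance") 1 / pmax(d[nn], 1e-12) else rep(1, fit$k)
    for (j in seq_along(nn)) {
      cl <- as.integer(fit$y[nn[j]])
      prob[i, cl] <- prob[i, cl] + w[j]
    }
  }
  prob / rowSums(prob)
}

# ---- SVM (e1071, Platt-scaled probabilities) -------------------------------

fit_svm <- function(p, x, y) {
  e1071::svm(x = x, y = y, kernel = p$kernel %||% "radial",
             probability = TRUE)
}

# ---- multilayer perceptron (ReLU hidden layers, softmax output) ------------
# In-package implementation: hidden layers of equal width, ReLU activations,
# cross-entropy loss, trained with Adam (minibatch) or full-batch L-BFGS.
# Features are standardized internally.

fit_mlp <- function(p, x, y) {
  hl <- p$hidden_layers %||% 1
  nn <- p$neurons %||% 50
  solver <- p$solver %||% "adam"
  epochs <- p$epochs %||% 60
  lr <- p$learning_rate %||% 1e-3
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2, stats::sd), 1e-12)
  X <- scale(x, ctr, scl)
  K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  sizes <- c(ncol(X), rep(nn, hl), K)
  L <- length(sizes) - 1
  init_layer <- function(l) {
    # He initialization for ReLU layers
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = numeric(sizes[l + 1]))
  }
  params <- lapply(seq_len(L), init_layer)

  forward <- function(params, X) {
    acts <- list(X)
    for (l in seq_len(L)) {
      Z <- sweep(acts[[l]] %*% params[[l]]$W, 2, -params[[l]]$b)
      acts[[l + 1]] <- if (l < L) pmax(Z, 0) else softmax(Z)
    }
    acts
  }
  loss_grad <- function(params, X, Y) {
    acts <- forward(params, X)
    m <- nrow(X)
    P <- acts[[L + 1]]
    loss <- -sum(Y * log(pmax(P, 1e-12))) / m
    grads <- vector("list", L)
    delta <- (P - Y) / m
    for (l in rev(seq_len(L))) {
      grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                         b = colSums(delta))
      if (l > 1) {
        delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
      }
    }
    list(loss = loss, grads = grads)
  }

  if (solver == "adam") {
    m1 <- lapply(params, lapply, function(v) v * 0)
    m2 <- m1
    t <- 0
    batch <- min(64, nrow(X))
    for (ep in seq_len(epochs)) {
      idx <- sample.int(nrow(X))
      for (s in seq(1, nrow(X), by = batch)) {
        b <- idx[s:min(s + batch - 1, nrow(X))]
        lg <- loss_grad(params, X[b, , drop = FALSE], Y[b, , drop = FALSE])
        t <- t + 1
        for (l in seq_len(L)) {
          for (nm in c("W", "b")) {
            g <- lg$grads[[l]][[nm]]
            m1[[l]][[nm]] <- 0.9 * m1[[l]][[nm]] + 0.1 * g
            m2[[l]][[nm]] <- 0.999 * m2[[l]][[nm]] + 0.001 * g^2
            mhat <- m1[[l]][[nm]] / (1 - 0.9^t)
            vhat <- m2[[l]][[nm]] / (1 - 0.999^t)
            params[[l]][[nm]] <- params[[l]][[nm]] -
              lr * mhat / (sqrt(vhat) + 1e-8)
          }
        }
      }
    }
  } else {  # lbfgs: full-batch on the flattened parameter vector
    shapes <- lapply(params, function(pl) list(W = dim(pl$W),
                                               b = length(pl$b)))
    flatten <- function(params) {
      unlist(lapply(params, function(pl) c(pl$W, pl$b)))
    }
    unflatten <- function(v) {
      out <- vector("list", L); pos <- 1
      for (l in seq_len(L)) {
        nw <- prod(shapes[[l]]$W)
        W <- matrix(v[pos:(pos + nw - 1)], shapes[[l]]$W[1], shapes[[l]]$W[2])
        pos <- pos + nw
        b <- v[pos:(pos + shapes[[l]]$b - 1)]
        pos <- pos + shapes[[l]]$b
        out[[l]] <- list(W = W, b = b)
      }
      out
    }
    opt <- stats::optim(flatten(params),
      fn = function(v) loss_grad(unflatten(v), X, Y)$loss,
      gr = function(v) flatten(loss_grad(unflatten(v), X, Y)$grads),
      method = "L-BFGS-B", control = list(maxit = 200))
    params <- unflatten(opt$par)
  }

  list(params = params, L = L, center = ctr, scale = scl,
       levels = levels(y),
       forward = NULL)
}

softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

predict_mlp <- function(fit, newdata) {
  A <- scale(newdata, fit$center, fit$scale)
  for (l in seq_len(fit$L)) {
    Z <- sweep(A %*% fit$params[[l]]$W, 2, -fit$params[[l]]$b)
    A <- if (l < fit$L) pmax(Z, 0) else softmax(Z)
  }
  colnames(A) <- fit$levels
  A
}

# ---- AdaBoost (SAMME.R over depth-1 rpart stumps) --------------------------

fit_adaboost <- function(p, x, y) {
  n_est <- p$n_estimators %||% 50
  lr <- p$learning_rate %||% 1
  K <- nlevels(y)
  n <- nrow(x)
  vars <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(y = y, x)
  names(df) <- c("y", vars)
  w <- rep(1 / n, n)
  stumps <- list()
  ycode <- matrix(-1 / (K - 1), n, K)
  ycode[cbind(seq_len(n), as.integer(y))] <- 1
  for (t in seq_len(n_est)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = 0, xval = 0,
                                                       minsplit = 2))
    P <- pmin(pmax(predict(fit, df, type = "prob"), 1e-6), 1 - 1e-6)
    P <- P / rowSums(P)
    lp <- log(P)
    stumps[[t]] <- fit
    # SAMME.R weight update
    w <- w * exp(-lr * (K - 1) / K * rowSums(ycode * lp))
    w <- w / sum(w)
    if (any(!is.finite(w))) break
  }
  list(stumps = stumps, lr = lr, levels = levels(y), K = K, vars = vars)
}

predict_adaboost <- function(fit, newdata) {
  nd <- as.data.frame(newdata)
  colnames(nd) <- fit$vars
  K <- fit$K
  H <- matrix(0, nrow(nd), K, dimnames = list(NULL, fit$levels))
  for (st in fit$stumps) {
    P <- pmin(pmax(predict(st, nd, type = "prob"), 1e-6), 1 - 1e-6)
    lp <- log(P / rowSums(P))
    H <- H + fit$lr * (K - 1) * (lp - rowMeans(lp))
  }
  softmax(H / (K - 1))
}
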