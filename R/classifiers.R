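# Small self-contained learners backing the evaluation harness. The
# environment ships no classifier packages beyond glmnet, so the classical
# models are implemented here directly with the harness's default
# hyperparameters. All fit functions take (X, y) with y in {0,1} and return
# an object with a predict method returning 0/1 labels.

# ---- CART ------------------------------------------------------------------
# Weighted binary regression/classification tree. For binary y the weighted
# SSE criterion is proportional to the weighted Gini impurity, so one
# criterion serves classification, weighted boosting and regression trees.

cart_best_split <- function(X, y, w, feat_idx) {
  best <- NULL
  tot_w <- sum(w); tot_wy <- sum(w * y); tot_wy2 <- sum(w * y^2)
  base_sse <- tot_wy2 - tot_wy^2 / tot_w
  for (j in feat_idx) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    n <- length(xs)
    if (xs[1] == xs[n]) next
    ws <- w[ord]; ys <- y[ord]
    cw <- cumsum(ws); cwy <- cumsum(ws * ys); cwy2 <- cumsum(ws * ys^2)
    pos <- which(xs[-n] < xs[-1])  # split between pos and pos+1
    if (length(pos) == 0) next
    sse_l <- cwy2[pos] - cwy[pos]^2 / cw[pos]
    rw <- tot_w - cw[pos]; rwy <- tot_wy - cwy[pos]
    sse_r <- (tot_wy2 - cwy2[pos]) - rwy^2 / rw
    sse <- sse_l + sse_r
    i <- which.min(sse)
    if (is.null(best) || sse[i] < best$sse) {
      best <- list(sse = sse[i], j = j,
                   thr = (xs[pos[i]] + xs[pos[i] + 1]) / 2)
    }
  }
  if (!is.null(best) && best$sse >= base_sse - 1e-12) best <- NULL
  best
}

cart_grow <- function(X, y, w, depth, max_depth, min_split, mtry, rng) {
  value <- sum(w * y) / sum(w)
  # purity stop must compare responses, not assume y in [0,1]: the same
  # tree serves classification and boosted regression on residuals
  if (depth >= max_depth || length(y) < min_split ||
      max(y) - min(y) <= 1e-12) {
    return(list(leaf = TRUE, value = value))
  }
  feat_idx <- seq_len(ncol(X))
  if (!is.null(mtry) && mtry < ncol(X)) feat_idx <- rng$sample(feat_idx, mtry)
  sp <- cart_best_split(X, y, w, feat_idx)
  if (is.null(sp)) return(list(leaf = TRUE, value = value))
  go_l <- X[, sp$j] <= sp$thr
  list(leaf = FALSE, j = sp$j, thr = sp$thr,
       left = cart_grow(X[go_l, , drop = FALSE], y[go_l], w[go_l],
                        depth + 1, max_depth, min_split, mtry, rng),
       right = cart_grow(X[!go_l, , drop = FALSE], y[!go_l], w[!go_l],
                         depth + 1, max_depth, min_split, mtry, rng))
}

cart_fit <- function(X, y, w = NULL, max_depth = 3, min_split = 2,
                     mtry = NULL, rng = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  structure(list(root = cart_grow(X, y, w, 0, max_depth, min_split,
                                  mtry, rng)),
            class = "woafs_cart")
}

cart_node_predict <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$value; return(out) }
  go_l <- X[idx, node$j] <= node$thr
  out <- cart_node_predict(node$left, X, idx[go_l], out)
  cart_node_predict(node$right, X, idx[!go_l], out)
}

# returns P(y = 1) per row
cart_predict_prob <- function(model, X) {
  cart_node_predict(model$root, X, seq_len(nrow(X)), numeric(nrow(X)))
}

# ---- learners --------------------------------------------------------------

fit_decision_tree <- function(X, y, hyper, seed) {
  cart_fit(X, y, max_depth = hyper$max_depth)
}
predict_decision_tree <- function(model, X) as.integer(cart_predict_prob(model, X) > 0.5)

fit_random_forest <- function(X, y, hyper, seed) {
  rng <- local_rng(seed)
  n <- nrow(X)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(hyper$n_estimators), function(b) {
    rows <- rng$sample(seq_len(n), n, replace = TRUE)
    cart_fit(X[rows, , drop = FALSE], y[rows], max_depth = hyper$max_depth,
             mtry = mtry, rng = rng)
  })
  structure(list(trees = trees), class = "woafs_rf")
}
predict_random_forest <- function(model, X) {
  votes <- rowMeans(vapply(model$trees,
                           function(tr) as.numeric(cart_predict_prob(tr, X) > 0.5),
                           numeric(nrow(X))))
  as.integer(votes > 0.5)
}

# AdaBoost (SAMME, discrete) with depth-1 stumps.
fit_adaboost <- function(X, y, hyper, seed) {
  n <- length(y)
  w <- rep(1 / n, n)
  s <- 2 * y - 1
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(hyper$n_estimators)) {
    st <- cart_fit(X, y, w = w, max_depth = hyper$max_depth)
    pred <- as.integer(cart_predict_prob(st, X) > 0.5)
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- hyper$learning_rate * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  structure(list(stumps = stumps, alphas = alphas), class = "woafs_ada")
}
predict_adaboost <- function(model, X) {
  score <- numeric(nrow(X))
  for (m in seq_along(model$stumps)) {
    pm <- 2 * as.integer(cart_predict_prob(model$stumps[[m]], X) > 0.5) - 1
    score <- score + model$alphas[m] * pm
  }
  as.integer(score > 0)
}

# Gradient-boosted trees, logistic loss, depth-limited regression trees.
fit_gradient_boosting <- function(X, y, hyper, seed) {
  n <- length(y)
  f <- rep(0, n)
  trees <- vector("list", hyper$n_estimators)
  for (m in seq_len(hyper$n_estimators)) {
    resid <- y - 1 / (1 + exp(-f))  # negative gradient of log-loss
    tr <- cart_fit(X, resid, max_depth = hyper$max_depth)
    trees[[m]] <- tr
    f <- f + hyper$learning_rate * cart_predict_prob(tr, X)
  }
  structure(list(trees = trees, lr = hyper$learning_rate), class = "woafs_gbt")
}
predict_gradient_boosting <- function(model, X) {
  f <- numeric(nrow(X))
  for (tr in model$trees) f <- f + model$lr * cart_predict_prob(tr, X)
  as.integer(f > 0)
}

fit_knn <- function(X, y, hyper, seed) {
  structure(list(X = X, y = y, k = hyper$n_neighbors), class = "woafs_knn")
}
predict_knn <- function(model, X) {
  tr <- model$X
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- colSums((t(tr) - X[i, ])^2)
    nb <- order(d2)[seq_len(min(model$k, nrow(tr)))]
    as.integer(mean(model$y[nb]) > 0.5)
  }, integer(1))
}

fit_naive_bayes <- function(X, y, hyper, seed) {
  eps <- hyper$var_smoothing * max(apply(X, 2, stats::var))
  if (!is.finite(eps) || eps <= 0) eps <- hyper$var_smoothing
  stats_by_class <- lapply(c(0L, 1L), function(cls) {
    Xc <- X[y == cls, , drop = FALSE]
    list(prior = mean(y == cls), mu = colMeans(Xc),
         v = apply(Xc, 2, function(col) mean((col - mean(col))^2)) + eps)
  })
  structure(list(s = stats_by_class), class = "woafs_gnb")
}
predict_naive_bayes <- function(model, X) {
  ll <- vapply(model$s, function(st) {
    log(st$prior) + rowSums(-0.5 * log(2 * pi * rep(st$v, each = nrow(X))) -
      0.5 * sweep(X, 2, st$mu)^2 / rep(st$v, each = nrow(X)))
  }, numeric(nrow(X)))
  as.integer(ll[, 2] > ll[, 1])
}

# Linear SVM via squared-hinge loss (smooth, BFGS-friendly) with L2 penalty
# and balanced class weights.
fit_svm_linear <- function(X, y, hyper, seed) {
  s <- 2 * y - 1
  n <- length(y)
  cls_w <- n / (2 * pmax(table(factor(y, levels = c(0, 1))), 1))
  ci <- as.numeric(cls_w[as.character(y)]) * hyper$C
  obj <- function(par) {
    w <- par[-1]; b <- par[1]
    m <- 1 - s * (X %*% w + b)
    0.5 * sum(w^2) + sum(ci * pmax(m, 0)^2)
  }
  grad <- function(par) {
    w <- par[-1]; b <- par[1]
    m <- as.numeric(1 - s * (X %*% w + b))
    act <- pmax(m, 0)
    g_m <- -2 * ci * act * s
    c(sum(g_m), w + as.numeric(t(X) %*% g_m))
  }
  fit <- stats::optim(rep(0, ncol(X) + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  structure(list(w = fit$par[-1], b = fit$par[1]), class = "woafs_svm")
}
predict_svm_linear <- function(model, X) {
  as.integer(as.numeric(X %*% model$w + model$b) > 0)
}

# One-hidden-layer MLP (relu, Adam, binary cross-entropy).
fit_mlp <- function(X, y, hyper, seed) {
  rng <- local_rng(seed)
  d <- ncol(X); h <- hyper$hidden_layer_sizes
  W1 <- matrix(rng$rnorm(d * h, sd = sqrt(2 / d)), d, h)
  b1 <- numeric(h); W2 <- matrix(rng$rnorm(h, sd = sqrt(2 / h)), h, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  lr <- hyper$learning_rate_init; n <- nrow(X); bs <- min(32L, n)
  step <- 0
  for (epoch in seq_len(hyper$max_iter)) {
    idx <- rng$sample(seq_len(n))
    for (start in seq(1, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1, n)]
      Xb <- X[rows, , drop = FALSE]; yb <- y[rows]
      Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
      A1 <- pmax(Z1, 0)
      z2 <- as.numeric(A1 %*% params$W2) + params$b2
      p <- 1 / (1 + exp(-z2))
      dz2 <- (p - yb) / length(yb)
      g <- list(W1 = NULL, b1 = NULL,
                W2 = t(A1) %*% dz2, b2 = sum(dz2))
      dA1 <- outer(dz2, as.numeric(params$W2))
      dZ1 <- dA1 * (Z1 > 0)
      g$W1 <- t(Xb) %*% dZ1
      g$b1 <- colSums(dZ1)
      step <- step + 1
      for (nm in names(params)) {
        mom[[nm]] <- 0.9 * mom[[nm]] + 0.1 * g[[nm]]
        vel[[nm]] <- 0.999 * vel[[nm]] + 0.001 * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - 0.9^step)
        vhat <- vel[[nm]] / (1 - 0.999^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  }
  structure(params, class = "woafs_mlp")
}
predict_mlp <- function(model, X) {
  A1 <- pmax(sweep(X %*% model$W1, 2, model$b1, "+"), 0)
  z2 <- as.numeric(A1 %*% model$W2) + model$b2
  as.integer(z2 > 0)
}

fit_l1_logistic_clf <- function(X, y, hyper, seed) {
  structure(list(fit = fit_l1_logistic(X, y, hyper$C)), class = "woafs_l1lr")
}
predict_l1_logistic_clf <- function(model, X) predict_l1_logistic(model$fit, X)
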