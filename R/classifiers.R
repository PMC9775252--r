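# Minimal deterministic implementations of the four classifiers used for
# network-feature classification: RBF-kernel SVM (SMO), CART decision tree,
# k-nearest neighbours and a bagged random forest. Written in-package
# because no classifier library is part of the supported dependency set;
# each is validated in the test suite against separable / chance-level
# constructions. All are deterministic given the RNG state at call time.

# --- support vector machine -------------------------------------------------

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
  exp(-gamma * pmax(d2, 0))
}

# C-SVC trained with simplified SMO (pairwise coordinate ascent on the
# dual with random second index). Adequate and exact enough for the
# desk-scale problems this package targets (tens of samples).
svm_train <- function(X, y, C = 1, gamma = NULL, tol = 1e-4,
                      max_passes = 20, max_iter = 20000) {
  X <- as.matrix(X)
  yy <- ifelse(y == levels(factor(y))[1], -1, 1)  # second level = +1
  n <- nrow(X)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  f <- function(i) sum(alpha * yy * K[, i]) + b
  passes <- 0
  iter <- 0
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    for (i in seq_len(n)) {
      iter <- iter + 1
      Ei <- f(i) - yy[i]
      if ((yy[i] * Ei < -tol && alpha[i] < C) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample(seq_len(n)[-i], 1)
        Ej <- f(j) - yy[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yy[i] != yy[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yy[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-6) next
        ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
          yy[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
          yy[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  list(X = X, yy = yy, alpha = alpha, b = b, gamma = gamma,
       levels = levels(factor(y)))
}

svm_predict <- function(model, Xnew) {
  K <- rbf_kernel(as.matrix(Xnew), model$X, model$gamma)
  score <- as.vector(K %*% (model$alpha * model$yy)) + model$b
  factor(ifelse(score >= 0, model$levels[2], model$levels[1]),
         levels = model$levels)
}

# --- k-nearest neighbours ---------------------------------------------------

knn_predict <- function(Xtrain, ytrain, Xnew, k = 3) {
  Xtrain <- as.matrix(Xtrain); Xnew <- as.matrix(Xnew)
  y <- factor(ytrain)
  k <- min(k, nrow(Xtrain))
  pred <- character(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    d <- sqrt(rowSums(sweep(Xtrain, 2, Xnew[i, ])^2))
    ord <- order(d)          # stable: ties broken by training order
    nb <- y[ord[seq_len(k)]]
    tab <- table(nb)
    winners <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(winners) == 1) winners
               else as.character(nb[1])  # tie: the single nearest neighbour
  }
  factor(pred, levels = levels(y))
}

# --- CART decision tree -----------------------------------------------------

gini <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

# Recursive binary splits on Gini impurity; grown to purity (min_leaf 1,
# no depth limit, no pruning). `mtry` features are drawn per split from the
# current RNG stream when building forest trees.
tree_build <- function(X, y, min_leaf = 1, mtry = NULL, depth = 0) {
  y <- factor(y)
  if (length(unique(y)) == 1 || nrow(X) < 2 * min_leaf || depth > 30) {
    tab <- table(y)
    return(list(leaf = TRUE,
                label = names(tab)[which.max(tab)], levels = levels(y)))
  }
  feats <- seq_len(ncol(X))
  if (!is.null(mtry) && mtry < length(feats))
    feats <- sort(sample(feats, mtry))
  best <- list(gain = -Inf)
  g0 <- gini(y)
  for (j in feats) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    cuts <- (v[-1] + v[-length(v)]) / 2
    for (cut in cuts) {
      left <- X[, j] <= cut
      nl <- sum(left); nr <- sum(!left)
      if (nl < min_leaf || nr < min_leaf) next
      gain <- g0 - (nl * gini(y[left]) + nr * gini(y[!left])) / length(y)
      if (gain > best$gain + 1e-12) best <- list(gain = gain, j = j, cut = cut)
    }
  }
  if (!is.finite(best$gain) || best$gain <= 1e-12) {
    tab <- table(y)
    return(list(leaf = TRUE,
                label = names(tab)[which.max(tab)], levels = levels(y)))
  }
  left <- X[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut, levels = levels(y),
       left = tree_build(X[left, , drop = FALSE], y[left], min_leaf, mtry,
                         depth + 1),
       right = tree_build(X[!left, , drop = FALSE], y[!left], min_leaf, mtry,
                          depth + 1))
}

tree_predict_one <- function(node, x) {
  while (!node$leaf) node <- if (x[node$j] <= node$cut) node$left else node$right
  node$label
}

tree_predict <- function(tree, Xnew) {
  Xnew <- as.matrix(Xnew)
  factor(apply(Xnew, 1, function(x) tree_predict_one(tree, x)),
         levels = tree$levels)
}

# --- random forest ----------------------------------------------------------

forest_train <- function(X, y, n_trees = 100, mtry = NULL, min_leaf = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  lapply(seq_len(n_trees), function(t) {
    idx <- sample(nrow(X), nrow(X), replace = TRUE)
    tree_build(X[idx, , drop = FALSE], y[idx], min_leaf = min_leaf,
               mtry = mtry)
  })
}

forest_predict <- function(forest, Xnew) {
  votes <- sapply(forest, function(tr) as.character(tree_predict(tr, Xnew)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  lv <- forest[[1]]$levels
  factor(apply(votes, 1, function(v) {
    tab <- table(factor(v, levels = lv))
    lv[which.max(tab)]   # tie: first level, deterministic
  }), levels = lv)
}
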