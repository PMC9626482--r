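# Baseline regressors run through the same harness as the PGNN.
# No tree/kernel libraries are assumed: CART-style trees, bagging, boosting,
# AdaBoost.R2 and RBF kernel ridge (the `svr` stand-in) are implemented here.

# ---- regression tree (variance-reduction CART) ----

fit_tree <- function(X, y, w = NULL, max_depth = 6L, min_node = 5L,
                     mtry = ncol(X)) {
  if (is.null(w)) w <- rep(1, length(y))
  build <- function(idx, depth) {
    yi <- y[idx]; wi <- w[idx]
    pred <- sum(wi * yi) / sum(wi)
    if (depth >= max_depth || length(idx) < 2 * min_node ||
        stats::var(yi) < 1e-12) {
      return(list(leaf = TRUE, pred = pred))
    }
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- NULL; best_sse <- Inf
    for (j in feats) {
      xj <- X[idx, j]
      ord <- order(xj)
      xs <- xj[ord]; ys <- yi[ord]; ws <- wi[ord]
      csy <- cumsum(ws * ys); csw <- cumsum(ws); csy2 <- cumsum(ws * ys^2)
      n <- length(xs)
      valid <- which(xs[-n] < xs[-1])          # split between distinct values
      valid <- valid[valid >= min_node & (n - valid) >= min_node]
      if (!length(valid)) next
      sse_l <- csy2[valid] - csy[valid]^2 / csw[valid]
      sse_r <- (csy2[n] - csy2[valid]) -
        (csy[n] - csy[valid])^2 / (csw[n] - csw[valid])
      sse <- sse_l + sse_r
      b <- which.min(sse)
      if (sse[b] < best_sse - 1e-12) {
        best_sse <- sse[b]
        best <- list(j = j, cut = (xs[valid[b]] + xs[valid[b] + 1]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, pred = pred))
    left <- idx[X[idx, best$j] <= best$cut]
    right <- idx[X[idx, best$j] > best$cut]
    list(leaf = FALSE, j = best$j, cut = best$cut, pred = pred,
         left = build(left, depth + 1), right = build(right, depth + 1))
  }
  build(seq_along(y), 0L)
}

predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$pred; return() }
    go_l <- X[idx, node$j] <= node$cut
    rec(node$left, idx[go_l]); rec(node$right, idx[!go_l])
  }
  rec(node, seq_len(nrow(X)))
  out
}

# ---- baseline fitting dispatch ----

fit_baseline <- function(records, config) {
  X <- feature_matrix(records)
  y <- records$damage_pct
  alg <- config$algorithm
  state <- with_seed(config$seed, switch(alg,
    linear = {
      df <- as.data.frame(X)
      list(fit = stats::lm(y ~ ., data = cbind(df, y = y)))
    },
    decision_tree = {
      list(tree = fit_tree(X, y, max_depth = config$max_depth %||% 8L,
                           min_node = config$min_node %||% 5L))
    },
    random_forest = {
      n_trees <- config$n_trees %||% 100L
      mtry <- config$mtry %||% 2L
      trees <- lapply(seq_len(n_trees), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        fit_tree(X[idx, , drop = FALSE], y[idx],
                 max_depth = config$max_depth %||% 10L,
                 min_node = config$min_node %||% 3L, mtry = mtry)
      })
      list(trees = trees)
    },
    gradient_boosting = {
      n_trees <- config$n_trees %||% 100L
      shrink <- config$shrinkage %||% 0.1
      f0 <- mean(y); r <- y - f0
      trees <- vector("list", n_trees)
      for (m in seq_len(n_trees)) {
        tr <- fit_tree(X, r, max_depth = config$max_depth %||% 3L,
                       min_node = config$min_node %||% 5L)
        r <- r - shrink * predict_tree(tr, X)
        trees[[m]] <- tr
      }
      list(f0 = f0, trees = trees, shrinkage = shrink)
    },
    adaboost = {
      # AdaBoost.R2 with linear loss, weighted-resampling weak learners
      n_trees <- config$n_trees %||% 50L
      w <- rep(1 / nrow(X), nrow(X))
      trees <- list(); betas <- numeric(0)
      for (m in seq_len(n_trees)) {
        idx <- sample.int(nrow(X), replace = TRUE, prob = w)
        tr <- fit_tree(X[idx, , drop = FALSE], y[idx],
                       max_depth = config$max_depth %||% 4L,
                       min_node = config$min_node %||% 5L)
        err <- abs(y - predict_tree(tr, X))
        D <- max(err); if (D <= 0) { trees <- c(trees, list(tr)); betas <- c(betas, 1e-10); break }
        L <- err / D
        ebar <- sum(w * L)
        if (ebar >= 0.5) break
        beta <- ebar / (1 - ebar)
        w <- w * beta^(1 - L); w <- w / sum(w)
        trees <- c(trees, list(tr)); betas <- c(betas, beta)
        if (ebar < 1e-8) break
      }
      if (!length(trees)) {
        trees <- list(fit_tree(X, y, max_depth = 4L)); betas <- 0.5
      }
      list(trees = trees, betas = betas)
    },
    svr = {
      # RBF kernel ridge regression (kernel-regression stand-in for SVR)
      gam <- config$kernel_gamma %||% 0.5
      lam <- config$ridge %||% 1e-2
      mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd); sd_[sd_ == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
      K <- rbf_kernel(Xs, Xs, gam)
      y_mu <- mean(y)
      alpha <- solve(K + lam * diag(nrow(K)), y - y_mu)
      list(Xs = Xs, mu = mu, sd = sd_, gamma = gam, alpha = alpha, y_mu = y_mu)
    },
    stop_bad(sprintf("unknown algorithm '%s'", alg), "configuration_error")))
  structure(list(algorithm = alg, state = state, config = config),
            class = c("baseline_predictor", "damage_predictor"))
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' @export
predict_damage.baseline_predictor <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  s <- object$state
  raw <- switch(object$algorithm,
    linear = as.numeric(stats::predict(s$fit, newdata = as.data.frame(X))),
    decision_tree = predict_tree(s$tree, X),
    random_forest = rowMeans(vapply(s$trees, function(tr) predict_tree(tr, X),
                                    numeric(nrow(X)))),
    gradient_boosting = {
      p <- rep(s$f0, nrow(X))
      for (tr in s$trees) p <- p + s$shrinkage * predict_tree(tr, X)
      p
    },
    adaboost = {
      # weighted median of weak predictions, weights log(1/beta)
      P <- vapply(s$trees, function(tr) predict_tree(tr, X), numeric(nrow(X)))
      if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
      wts <- log(1 / pmax(s$betas, 1e-12))
      apply(P, 1, function(p) {
        o <- order(p); cw <- cumsum(wts[o])
        p[o][which(cw >= 0.5 * sum(wts))[1]]
      })
    },
    svr = {
      Xs <- sweep(sweep(X, 2, s$mu), 2, s$sd, "/")
      as.numeric(rbf_kernel(Xs, s$Xs, s$gamma) %*% s$alpha) + s$y_mu
    })
  clip01(raw)
}
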