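#' Model configuration
#'
#' Hyperparameters for [train_damage_model()]. The network follows the
#' three-hidden-layer, 50-neuron architecture selected by grid-search CV;
#' `phys_weight` weighs the monotonicity (physical-loss) penalty against the
#' empirical mean-squared error. The collocation grid — unlabeled points on
#' which monotonicity in time is enforced — is `colloc_anchors` random
#' (voltage, frequency, flow) anchors from the training domain, each crossed
#' with `colloc_times` time points spanning the training time range.
#'
#' @param algorithm one of "pgnn", "linear", "decision_tree", "random_forest",
#'   "gradient_boosting", "adaboost", "svr".
#' @param hidden_layers,neurons_per_layer network architecture (pgnn).
#' @param phys_weight lambda >= 0, weight of the physical loss (pgnn).
#' @param epochs,learning_rate Adam optimisation budget (pgnn).
#' @param patience early-stopping patience on validation loss when a
#'   validation set is supplied; `Inf` disables.
#' @param colloc_anchors,colloc_times collocation grid size (pgnn).
#' @param hinge_margin training-time slack added inside the monotonicity
#'   hinge, in standardised-target units, so satisfied constraints keep a
#'   buffer; the reported PHYLOSS and [physical_loss()] are the pure hinge.
#' @param seed integer seed for initialisation and collocation sampling.
#' @param grid named list of hyperparameter vectors for [grid_search_cv()];
#'   entries override fields of this config.
#' @param ... algorithm-specific settings (e.g. `max_depth`, `n_trees`,
#'   `shrinkage`, `mtry`, `kernel_gamma`, `ridge`).
#' @return an object of class `model_config`.
#' @export
model_config <- function(algorithm = "pgnn", hidden_layers = 3L,
                         neurons_per_layer = 50L, phys_weight = 1.0,
                         epochs = 2000L, learning_rate = 1e-3,
                         patience = 100L, colloc_anchors = 60L,
                         colloc_times = 40L, hinge_margin = 5e-3,
                         seed = 1L, grid = list(), ...) {
  algorithm <- match.arg(algorithm, c("pgnn", "linear", "decision_tree",
                                      "random_forest", "gradient_boosting",
                                      "adaboost", "svr"))
  if (hidden_layers < 1 || neurons_per_layer < 1) {
    stop_bad("network needs >= 1 hidden layer and >= 1 neuron", "invalid_parameter")
  }
  check_finite_nonneg(phys_weight, "phys_weight")
  check_finite_positive(learning_rate, "learning_rate")
  structure(c(list(algorithm = algorithm,
                   hidden_layers = as.integer(hidden_layers),
                   neurons_per_layer = as.integer(neurons_per_layer),
                   phys_weight = phys_weight, epochs = as.integer(epochs),
                   learning_rate = learning_rate, patience = patience,
                   colloc_anchors = as.integer(colloc_anchors),
                   colloc_times = as.integer(colloc_times),
                   hinge_margin = hinge_margin,
                   seed = as.integer(seed), grid = grid),
              list(...)),
            class = "model_config")
}

# ---- multilayer perceptron internals (tanh hidden units, linear output) ----

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(1 / fan_in)),
                      fan_in, sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < n_l) tanh(z) else z
  }
  acts
}

# backprop given dL/doutput (column vector g); returns gradients per layer
mlp_backward <- function(layers, acts, g) {
  n_l <- length(layers)
  grads <- vector("list", n_l)
  delta <- g
  for (l in rev(seq_len(n_l))) {
    a_prev <- acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
    }
  }
  grads
}

#' Train the physics-guided neural network
#'
#' Fits a tanh multilayer perceptron by full-batch Adam on the loss
#' \deqn{L = \mathrm{MSE}(train) + \lambda\,\mathrm{PHYLOSS}(collocation),}
#' where PHYLOSS is the mean hinge penalty on consecutive-time prediction
#' decreases over the collocation grid (see [physical_loss()]). Features are
#' z-scored by training statistics; the target is standardised internally for
#' optimisation and mapped back to percent at prediction, so the user-facing
#' scale stays percent damage. Predictions are clipped to [0, 100] at the
#' predictor boundary only.
#'
#' @param records training DoE records (data.frame, DoE schema).
#' @param config a [model_config()] with `algorithm = "pgnn"`.
#' @param validation optional held-out records for early stopping.
#' @return a `pgnn_predictor` (also `damage_predictor`) carrying the fitted
#'   weights, standardisation constants, collocation grid, seed, and a
#'   per-epoch `history` data.frame with both loss components.
#' @export
train_pgnn <- function(records, config = model_config("pgnn"),
                       validation = NULL) {
  stopifnot(nrow(records) >= 1)
  X <- feature_matrix(records)
  y <- records$damage_pct
  mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  y_mu <- mean(y); y_sd <- stats::sd(y); if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mu) / y_sd

  # collocation grid: anchors from observed (V, f, Q) combos, dense time axis
  colloc <- with_seed(config$seed + 1L, {
    combos <- unique(records[c("voltage_kV", "frequency_kHz", "flow_slm")])
    idx <- sample.int(nrow(combos), min(config$colloc_anchors, nrow(combos)))
    anchors <- combos[idx, , drop = FALSE]
    times <- seq(min(X[, 4]), max(X[, 4]), length.out = config$colloc_times)
    list(anchors = anchors, times = times)
  })
  n_anchor <- nrow(colloc$anchors); n_time <- length(colloc$times)
  Xc <- cbind(voltage_kV = rep(colloc$anchors$voltage_kV, each = n_time),
              frequency_kHz = rep(colloc$anchors$frequency_kHz, each = n_time),
              flow_slm = rep(colloc$anchors$flow_slm, each = n_time),
              time_s = rep(colloc$times, n_anchor))
  Xcs <- sweep(sweep(Xc, 2, mu), 2, sd_, "/")

  sizes <- c(ncol(X), rep(config$neurons_per_layer, config$hidden_layers), 1L)
  layers <- mlp_init(sizes, config$seed)
  lambda <- config$phys_weight
  margin <- config$hinge_margin %||% 2e-3   # standardised-target units
  n <- nrow(Xs)
  n_pairs <- n_anchor * (n_time - 1)
  lo <- rep(seq_len(n_time - 1), n_anchor) + rep((seq_len(n_anchor) - 1) * n_time, each = n_time - 1)

  adam_m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  Z <- rbind(Xs, Xcs)

  has_val <- !is.null(validation) && nrow(validation) > 0
  if (has_val) {
    Xv <- sweep(sweep(feature_matrix(validation), 2, mu), 2, sd_, "/")
    yv <- (validation$damage_pct - y_mu) / y_sd
    best_val <- Inf; best_layers <- layers; wait <- 0
  }

  hist_mse <- hist_phy <- numeric(config$epochs)
  n_epochs_run <- config$epochs
  for (epoch in seq_len(config$epochs)) {
    acts <- mlp_forward(layers, Z)
    out <- acts[[length(acts)]][, 1]
    yhat <- out[seq_len(n)]
    yc <- out[-seq_len(n)]
    res <- yhat - ys
    mse <- mean(res^2)
    diffs <- yc[lo] - yc[lo + 1]          # positive = violation of monotonicity
    # the reported PHYLOSS is the pure hinge; the training subgradient uses a
    # small margin so satisfied constraints keep a buffer (a margin-free hinge
    # stops pushing the moment a pair is merely non-decreasing, leaving
    # machine-small wiggles in flat regions)
    viol <- diffs > -margin
    phy <- if (n_pairs > 0) sum(pmax(diffs, 0)) / n_pairs else 0
    loss <- mse + lambda * phy
    if (!is.finite(loss)) {
      stop_bad(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
               "divergence_error")
    }
    hist_mse[epoch] <- mse; hist_phy[epoch] <- phy

    g <- numeric(length(out))
    g[seq_len(n)] <- 2 * res / n
    if (lambda > 0 && any(viol)) {
      i_hi <- lo[viol]
      gc_ <- numeric(length(yc))
      add <- lambda / n_pairs
      for (i in i_hi) { gc_[i] <- gc_[i] + add; gc_[i + 1] <- gc_[i + 1] - add }
      g[-seq_len(n)] <- gc_
    }
    grads <- mlp_backward(layers, acts, matrix(g, ncol = 1))
    t_corr1 <- 1 - b1^epoch; t_corr2 <- 1 - b2^epoch
    for (l in seq_along(layers)) {
      for (p in c("W", "b")) {
        adam_m[[l]][[p]] <- b1 * adam_m[[l]][[p]] + (1 - b1) * grads[[l]][[p]]
        adam_v[[l]][[p]] <- b2 * adam_v[[l]][[p]] + (1 - b2) * grads[[l]][[p]]^2
        step <- config$learning_rate * (adam_m[[l]][[p]] / t_corr1) /
          (sqrt(adam_v[[l]][[p]] / t_corr2) + eps)
        layers[[l]][[p]] <- layers[[l]][[p]] - step
      }
    }
    if (has_val && is.finite(config$patience)) {
      vout <- mlp_forward(layers, Xv)
      vmse <- mean((vout[[length(vout)]][, 1] - yv)^2)
      if (vmse < best_val - 1e-12) { best_val <- vmse; best_layers <- layers; wait <- 0 }
      else { wait <- wait + 1; if (wait >= config$patience) { n_epochs_run <- epoch; break } }
    }
  }
  if (has_val && is.finite(config$patience)) layers <- best_layers

  structure(list(layers = layers, x_mu = mu, x_sd = sd_, y_mu = y_mu,
                 y_sd = y_sd, config = config, colloc = colloc,
                 seed = config$seed,
                 history = data.frame(epoch = seq_len(n_epochs_run),
                                      mse = hist_mse[seq_len(n_epochs_run)],
                                      phyloss = hist_phy[seq_len(n_epochs_run)])),
            class = c("pgnn_predictor", "damage_predictor"))
}

#' @export
predict_damage.pgnn_predictor <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$x_mu), 2, object$x_sd, "/")
  acts <- mlp_forward(object$layers, Xs)
  clip01(acts[[length(acts)]][, 1] * object$y_sd + object$y_mu)
}

#' Persist and restore a fitted PGNN
#'
#' The on-disk format is a self-describing JSON file holding the weights,
#' standardisation constants, architecture and seed.
#'
#' @param object a `pgnn_predictor`.
#' @param path file path (.json).
#' @return `save_predictor` returns `path` invisibly; `load_predictor` the
#'   restored predictor.
#' @export
save_predictor <- function(object, path) {
  stopifnot(inherits(object, "pgnn_predictor"))
  payload <- list(
    format = "plasmadose-pgnn-1",
    x_mu = object$x_mu, x_sd = object$x_sd,
    y_mu = object$y_mu, y_sd = object$y_sd, seed = object$seed,
    layers = lapply(object$layers, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(p$format, "plasmadose-pgnn-1"))
  layers <- lapply(seq_len(nrow(p$layers)), function(i) {
    list(W = matrix(unlist(p$layers$W[i]), p$layers$dim[[i]][1],
                    p$layers$dim[[i]][2]),
         b = unlist(p$layers$b[i]))
  })
  structure(list(layers = layers, x_mu = p$x_mu, x_sd = p$x_sd,
                 y_mu = p$y_mu, y_sd = p$y_sd, seed = p$seed,
                 history = NULL, config = NULL),
            class = c("pgnn_predictor", "damage_predictor"))
}
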