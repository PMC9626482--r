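#' Train/test split of DoE records
#'
#' Seeded shuffle followed by a disjoint partition; train size is
#' `round(n * train_fraction)` (the study used a 75:25 ratio).
#'
#' @param records DoE data.frame.
#' @param train_fraction fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @export
split_data <- function(records, train_fraction = 0.75, seed = 1L) {
  n <- nrow(records)
  if (n < 4) stop_bad("need at least 4 records to split", "insufficient_data")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_bad("'train_fraction' must be in (0, 1)", "invalid_parameter")
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(n * train_fraction)
  list(train = records[idx[seq_len(n_train)], , drop = FALSE],
       test = records[idx[-seq_len(n_train)], , drop = FALSE])
}

#' Minority-region specification for SMOTE-style oversampling
#'
#' The minority region is defined by damage-value rarity: damage is binned and
#' a record is minority when its bin count falls below `threshold` times the
#' modal bin count. In the study's data these rare values sat mostly at short
#' irradiation times.
#'
#' @param bin_width damage histogram bin width, percent (> 0).
#' @param threshold fraction of the modal bin count in (0, 1].
#' @param short_time_cutoff bookkeeping cutoff (s) marking the short-time
#'   stratum.
#' @param k nearest-neighbour count for interpolation (>= 1).
#' @param minority_factor target multiplication factor for minority records.
#' @param majority_factor multiplication factor for majority records; `NULL`
#'   (default) counterbalances by bringing the majority count up to the
#'   augmented minority count when the latter is larger.
#' @return object of class `minority_region_spec`.
#' @export
minority_region_spec <- function(bin_width = 5, threshold = 0.3,
                                 short_time_cutoff = 10, k = 5L,
                                 minority_factor = 3, majority_factor = NULL) {
  if (bin_width <= 0) stop_bad("'bin_width' must be > 0", "invalid_parameter")
  if (threshold <= 0 || threshold > 1) {
    stop_bad("'threshold' must be in (0, 1]", "invalid_parameter")
  }
  if (k < 1) stop_bad("'k' must be >= 1", "invalid_parameter")
  structure(list(bin_width = bin_width, threshold = threshold,
                 short_time_cutoff = short_time_cutoff, k = as.integer(k),
                 minority_factor = minority_factor,
                 majority_factor = majority_factor),
            class = "minority_region_spec")
}

#' Flag records in the minority (rare-damage) region
#'
#' @param records DoE data.frame with a `damage_pct` column.
#' @param spec a [minority_region_spec()].
#' @return logical mask, TRUE for minority records. Deterministic.
#' @export
identify_minority_region <- function(records, spec = minority_region_spec()) {
  if (!nrow(records)) stop_bad("empty record list", "invalid_parameter")
  bins <- floor(records$damage_pct / spec$bin_width)
  counts <- table(bins)
  modal <- max(counts)
  rare_bins <- names(counts)[counts < spec$threshold * modal]
  as.character(bins) %in% rare_bins
}

#' SMOTE-style oversampling for a continuous target
#'
#' SMOTER-style interpolation: each synthetic record is a convex combination
#' `x_new = x_i + u (x_j - x_i)`, u ~ Uniform(0, 1), of a region member and one
#' of its `k` nearest neighbours from the same region, with distances measured
#' in the standardised joint (features, damage) space. All columns — features
#' and the damage target — are interpolated with the same u. Minority records
#' are multiplied by `minority_factor`; the majority region is counterbalanced
#' by the same rule up to the augmented minority count (or its own explicit
#' factor). Original records are always retained; synthetic records carry
#' `synthetic = TRUE` provenance.
#'
#' @param records DoE data.frame.
#' @param minority_mask logical mask from [identify_minority_region()].
#' @param spec a [minority_region_spec()].
#' @param seed integer seed.
#' @return data.frame of original plus synthetic records with a logical
#'   `synthetic` column.
#' @export
smote_oversample <- function(records, minority_mask = NULL,
                             spec = minority_region_spec(), seed = 1L) {
  if (is.null(minority_mask)) minority_mask <- identify_minority_region(records, spec)
  stopifnot(length(minority_mask) == nrow(records))
  cols <- c("voltage_kV", "frequency_kHz", "flow_slm", "time_s", "damage_pct")
  M <- as.matrix(records[cols])
  mu <- colMeans(M); sd_ <- apply(M, 2, stats::sd); sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Ms <- sweep(sweep(M, 2, mu), 2, sd_, "/")

  synth_region <- function(idx, n_new) {
    if (n_new <= 0 || !length(idx)) return(NULL)
    if (length(idx) == 1) {
      warning("region has a single record; duplicating it", call. = FALSE)
      return(M[rep(idx, n_new), , drop = FALSE])
    }
    sub <- Ms[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(sub))^2
    diag(d2) <- Inf
    kk <- min(spec$k, length(idx) - 1)
    nn <- matrix(apply(d2, 1, function(r) order(r)[seq_len(kk)]),
                 ncol = kk, byrow = TRUE)
    base <- sample.int(length(idx), n_new, replace = TRUE)
    mate <- vapply(base, function(b) nn[b, sample.int(kk, 1)], 1L)
    u <- stats::runif(n_new)
    M[idx[base], , drop = FALSE] +
      u * (M[idx[mate], , drop = FALSE] - M[idx[base], , drop = FALSE])
  }

  with_seed(seed, {
    n_min <- sum(minority_mask); n_maj <- sum(!minority_mask)
    new_min <- round(n_min * (spec$minority_factor - 1))
    aug_min_total <- n_min + max(0, new_min)
    maj_target <- if (is.null(spec$majority_factor)) {
      max(n_maj, aug_min_total)
    } else round(n_maj * spec$majority_factor)
    new_maj <- maj_target - n_maj
    S_min <- synth_region(which(minority_mask), new_min)
    S_maj <- synth_region(which(!minority_mask), new_maj)
    synth <- rbind(S_min, S_maj)
    out <- records[cols]
    out$synthetic <- FALSE
    if (!is.null(synth) && nrow(synth)) {
      add <- as.data.frame(synth)
      names(add) <- cols
      add$synthetic <- TRUE
      out <- rbind(out, add)
    }
    rownames(out) <- NULL
    out
  })
}

#' Physical (monotonicity) loss of a prediction function
#'
#' Mean hinge penalty over consecutive-time prediction decreases on a
#' collocation set: for every anchor (V, f, Q) and its sorted time grid,
#' accumulates `max(0, f(t_i) - f(t_{i+1}))` and averages over all pairs.
#' Zero if and only if predictions are non-decreasing in time on the set.
#'
#' @param predictor a `damage_predictor` (or plain function(v, f, q, t)).
#' @param anchors data.frame with columns `voltage_kV`, `frequency_kHz`,
#'   `flow_slm`.
#' @param times sorted ascending numeric time grid (>= 2 points), shared by
#'   all anchors, or a list of one grid per anchor.
#' @return scalar >= 0.
#' @export
physical_loss <- function(predictor, anchors, times) {
  if (is.function(predictor)) predictor <- as_damage_predictor(predictor, clip = FALSE)
  grids <- if (is.list(times) && !is.data.frame(times)) times else
    rep(list(times), nrow(anchors))
  stopifnot(length(grids) == nrow(anchors))
  total <- 0; n_pairs <- 0
  for (a in seq_len(nrow(anchors))) {
    tg <- grids[[a]]
    if (is.unsorted(tg, strictly = FALSE)) {
      stop_bad("time grid must be sorted ascending", "invalid_parameter")
    }
    if (length(tg) < 2) next
    nd <- data.frame(voltage_kV = anchors$voltage_kV[a],
                     frequency_kHz = anchors$frequency_kHz[a],
                     flow_slm = anchors$flow_slm[a], time_s = tg)
    p <- predict_damage(predictor, nd)
    d <- p[-length(p)] - p[-1]
    total <- total + sum(pmax(0, d))
    n_pairs <- n_pairs + length(d)
  }
  if (n_pairs == 0) 0 else total / n_pairs
}

#' Fit a damage model (PGNN or a baseline) to DoE records
#'
#' @param records training DoE data.frame (a `synthetic` provenance column, if
#'   present, is ignored for fitting).
#' @param config a [model_config()].
#' @param validation optional validation records (PGNN early stopping).
#' @return a `damage_predictor`.
#' @export
train_damage_model <- function(records, config = model_config(),
                               validation = NULL) {
  if (!nrow(records)) stop_bad("no training records", "insufficient_data")
  if (config$algorithm == "pgnn") train_pgnn(records, config, validation)
  else fit_baseline(records, config)
}

#' Evaluate a predictor on unaugmented test records
#'
#' R^2 = 1 - SS_res / SS_tot, RMSE = sqrt(mean squared error), MAE = mean
#' absolute error, all on the percent-damage scale.
#'
#' @param predictor a `damage_predictor`.
#' @param test test data.frame; must not contain synthetic records.
#' @return object of class `fit_result`: list(r2, rmse, mae, n).
#' @export
evaluate_model <- function(predictor, test) {
  if (!nrow(test)) stop_bad("empty test set", "invalid_parameter")
  if (!is.null(test$synthetic) && any(test$synthetic)) {
    stop_bad("test set contains synthetic (oversampled) records",
             "invalid_parameter")
  }
  y <- test$damage_pct
  yhat <- predict_damage(predictor, test)
  res <- y - yhat
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in test targets; R^2 undefined", call. = FALSE)
    NaN
  } else 1 - sum(res^2) / ss_tot
  structure(list(r2 = r2, rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
                 n = length(y)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: R^2 = %.4f, RMSE = %.3f%%, MAE = %.3f%% (n = %d)\n",
              x$r2, x$rmse, x$mae, x$n))
  invisible(x)
}

#' Grid-search cross-validation with leakage-safe oversampling
#'
#' Fivefold (by default) grid-search CV in which [smote_oversample()] is
#' applied to each fold's training portion only, after the fold split;
#' validation portions never contain synthetic records. The best grid point
#' minimises mean validation RMSE; ties break on fewer grid parameters, then
#' lexicographic order.
#'
#' @param records training records.
#' @param config a [model_config()]; its `grid` field (named list of vectors)
#'   defines the search space. An empty grid evaluates the config as-is.
#' @param n_folds number of folds (>= 2); default 5.
#' @param spec a [minority_region_spec()].
#' @param seed integer seed (fold assignment and per-fold oversampling).
#' @return list with `best_config`, `best_score` (mean RMSE), and `results`, a
#'   data.frame of one row per grid point with per-fold RMSEs.
#' @export
grid_search_cv <- function(records, config = model_config(), n_folds = 5L,
                           spec = minority_region_spec(), seed = 1L) {
  n <- nrow(records)
  if (n_folds < 2) stop_bad("'n_folds' must be >= 2", "invalid_parameter")
  if (n < n_folds * 2) stop_bad("fold with < 2 records", "insufficient_data")
  grid <- config$grid
  points <- if (length(grid)) {
    expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else data.frame(row.names = 1)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))

  fold_scores <- matrix(NA_real_, nrow(points), n_folds)
  audit <- list()
  for (g in seq_len(nrow(points))) {
    cfg <- config
    for (nm in names(points)) cfg[[nm]] <- points[[nm]][g]
    for (f in seq_len(n_folds)) {
      tr <- records[fold_id != f, , drop = FALSE]
      va <- records[fold_id == f, , drop = FALSE]
      mask <- identify_minority_region(tr, spec)
      aug <- smote_oversample(tr, mask, spec, seed = seed + 1000L * g + f)
      fit <- train_damage_model(aug, cfg)
      yhat <- predict_damage(fit, va)
      fold_scores[g, f] <- sqrt(mean((va$damage_pct - yhat)^2))
      # provenance audit: validation folds must never contain synthetic records
      audit[[length(audit) + 1]] <- data.frame(
        grid_point = g, fold = f, n_val = nrow(va),
        n_synth_val = if (is.null(va$synthetic)) 0L else sum(va$synthetic),
        n_train_aug = nrow(aug), n_synth_train = sum(aug$synthetic))
    }
  }
  audit <- do.call(rbind, audit)
  mean_rmse <- rowMeans(fold_scores)
  # tie-breaks: lowest mean RMSE, then fewest parameters, then lexicographic
  ord <- order(mean_rmse, seq_len(nrow(points)))
  best <- ord[1]
  best_config <- config
  for (nm in names(points)) best_config[[nm]] <- points[[nm]][best]
  results <- cbind(points, mean_rmse = mean_rmse,
                   as.data.frame(fold_scores) |>
                     stats::setNames(paste0("fold", seq_len(n_folds))))
  list(best_config = best_config, best_score = mean_rmse[best],
       results = results, fold_id = fold_id, audit = audit)
}

#' Audit physical consistency of a fitted predictor
#'
#' Scans predictions over a (V, f, Q) parameter grid crossed with a sorted
#' time grid and enumerates every consecutive-time decrease.
#'
#' @param predictor a `damage_predictor`.
#' @param anchors data.frame of (voltage_kV, frequency_kHz, flow_slm) rows.
#' @param times sorted ascending time grid.
#' @return list with `n_violations`, `max_magnitude`, and `violations`, a
#'   data.frame of (anchor row, t_lo, t_hi, drop).
#' @export
check_physical_consistency <- function(predictor, anchors, times) {
  if (is.unsorted(times)) stop_bad("time grid must be sorted", "invalid_parameter")
  rows <- list()
  for (a in seq_len(nrow(anchors))) {
    nd <- data.frame(voltage_kV = anchors$voltage_kV[a],
                     frequency_kHz = anchors$frequency_kHz[a],
                     flow_slm = anchors$flow_slm[a], time_s = times)
    p <- predict_damage(predictor, nd)
    drop <- p[-length(p)] - p[-1]
    bad <- which(drop > 0)
    if (length(bad)) {
      rows[[length(rows) + 1]] <- data.frame(
        anchor = a, voltage_kV = anchors$voltage_kV[a],
        frequency_kHz = anchors$frequency_kHz[a],
        flow_slm = anchors$flow_slm[a],
        t_lo = times[bad], t_hi = times[bad + 1], drop = drop[bad])
    }
  }
  viol <- if (length(rows)) do.call(rbind, rows) else
    data.frame(anchor = integer(), voltage_kV = numeric(),
               frequency_kHz = numeric(), flow_slm = numeric(),
               t_lo = numeric(), t_hi = numeric(), drop = numeric())
  list(n_violations = nrow(viol),
       max_magnitude = if (nrow(viol)) max(viol$drop) else 0,
       violations = viol)
}
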