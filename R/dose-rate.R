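#' Extract LTP dose rates from a dose vs. DNA-damage database
#'
#' For each database point, finds the irradiation time `t_irr` at which the
#' fitted damage model, at the fixed process parameters, produces the point's
#' percent damage, and estimates \deqn{\text{dose rate} = \text{dose} / t_{irr}}
#' in Gy/s. Points whose damage is unreachable on the time domain are flagged
#' (never silently dropped) and excluded from clustering.
#'
#' @param predictor a `damage_predictor`.
#' @param voltage,frequency,flow fixed process parameters (kV, kHz, slm).
#' @param db data.frame in the dose-damage schema (`radiation_type`,
#'   `study_id`, `dose_Gy`, `damage_pct`).
#' @param t_min,t_max,tolerance,n_bracket,t_resolution inversion settings,
#'   see [itf_query()].
#' @return data.frame with the db columns plus `t_irr_s`, `dose_rate_Gy_per_s`,
#'   `reachable`, `status`.
#' @export
extract_dose_rates <- function(predictor, voltage = 8, frequency = 1, flow = 2,
                               db, t_min = 0.5, t_max = 120, tolerance = 0.1,
                               n_bracket = 256L, t_resolution = 1e-3) {
  if (missing(db) || !nrow(db)) stop_bad("empty dose-damage database", "invalid_parameter")
  q <- itf_query(voltage, frequency, flow, target_damage = 0,
                 t_min = t_min, t_max = t_max, tolerance = tolerance,
                 n_bracket = n_bracket, t_resolution = t_resolution)
  inv <- find_irradiation_times(predictor, q, db$damage_pct)
  out <- db
  out$voltage_kV <- voltage; out$frequency_kHz <- frequency; out$flow_slm <- flow
  out$t_irr_s <- inv$t_irr
  out$dose_rate_Gy_per_s <- out$dose_Gy / inv$t_irr
  out$reachable <- inv$status == "ok"
  out$status <- inv$status
  out
}

#' Seeded Lloyd K-means for one-dimensional values
#'
#' Lloyd iterations to convergence (unchanged assignment), best of `restarts`
#' seeded initialisations by within-cluster sum of squares. Initialisation is
#' k-means++-style (distance-weighted sampling). An emptied cluster is
#' re-seeded at the point farthest from its nearest centroid. Centroids are
#' returned sorted ascending with labels relabelled accordingly, so label 1 is
#' always the lowest dose-rate cluster.
#'
#' @param values numeric vector (length >= k).
#' @param k number of clusters (>= 1); the study used k = 4.
#' @param restarts number of seeded initialisations; default 10.
#' @param seed integer seed.
#' @return list with integer `labels` (1..k), ascending `centroids`, and
#'   `wcss`.
#' @export
kmeans_1d <- function(values, k = 4L, restarts = 10L, seed = 1L) {
  n <- length(values)
  if (k < 1 || k > n) stop_bad("need 1 <= k <= length(values)", "invalid_parameter")
  if (k == n) {
    o <- order(values)
    labels <- integer(n); labels[o] <- seq_len(n)
    return(list(labels = labels, centroids = values[o], wcss = 0))
  }
  lloyd_once <- function(centers) {
    repeat {
      d <- abs(outer(values, centers, "-"))
      lab <- max.col(-d, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(lab == j)) {             # empty cluster: re-seed at farthest point
          far <- which.max(apply(d, 1, min))
          centers[j] <- values[far]
          d <- abs(outer(values, centers, "-"))
          lab <- max.col(-d, ties.method = "first")
        }
      }
      new_centers <- vapply(seq_len(k), function(j) mean(values[lab == j]), 0)
      if (all(new_centers == centers)) break
      centers <- new_centers
    }
    wcss <- sum((values - centers[lab])^2)
    list(lab = lab, centers = centers, wcss = wcss)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- numeric(k)
      centers[1] <- sample(values, 1)
      if (k > 1) for (j in 2:k) {
        d2 <- apply(abs(outer(values, centers[seq_len(j - 1)], "-")), 1, min)^2
        centers[j] <- if (sum(d2) > 0) sample(values, 1, prob = d2) else sample(values, 1)
      }
      fit <- lloyd_once(unique_jitter(centers))
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  o <- order(best$centers)
  relabel <- integer(k); relabel[o] <- seq_len(k)
  list(labels = relabel[best$lab], centroids = best$centers[o],
       wcss = best$wcss)
}

# duplicate initial centers would immediately empty a cluster; nudge them
unique_jitter <- function(centers) {
  while (anyDuplicated(centers)) {
    d <- duplicated(centers)
    centers[d] <- centers[d] * (1 + 1e-9) + 1e-12
  }
  centers
}

#' Per-cluster outlier treatment and summary
#'
#' Within each cluster, removes members outside the Tukey fences
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR] (quartiles by linear interpolation,
#' `stats::quantile` type 7), then reports the centroid (mean) and sample
#' standard deviation (n - 1 denominator; 0 for a single member) of the
#' retained members. A cluster that would empty retains its original members
#' with a warning.
#'
#' @param values numeric vector of dose rates, Gy/s.
#' @param labels integer cluster labels (1..k).
#' @param k number of clusters.
#' @return data.frame with one row per cluster: `label`, `centroid_Gy_per_s`,
#'   `sd_Gy_per_s`, `n_before`, `n_after`, and list-columns `removed` and
#'   `retained` with the discarded and kept values.
#' @export
treat_outliers_and_summarize <- function(values, labels, k = max(labels)) {
  stopifnot(length(values) == length(labels), all(labels %in% seq_len(k)))
  rows <- lapply(seq_len(k), function(j) {
    v <- values[labels == j]
    if (!length(v)) return(NULL)
    qs <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- qs[2] - qs[1]
    keep <- v >= qs[1] - 1.5 * iqr & v <= qs[2] + 1.5 * iqr
    if (!any(keep)) {
      warning(sprintf("cluster %d emptied by outlier treatment; retaining all members", j),
              call. = FALSE)
      keep <- rep(TRUE, length(v))
    }
    r <- v[keep]
    data.frame(label = j, centroid_Gy_per_s = mean(r),
               sd_Gy_per_s = if (length(r) > 1) stats::sd(r) else 0,
               n_before = length(v), n_after = length(r),
               removed = I(list(v[!keep])), retained = I(list(r)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster reachable dose-rate estimates and summarise
#'
#' Convenience wrapper: runs [kmeans_1d()] on the reachable estimates of an
#' [extract_dose_rates()] table, attaches the cluster label (NA for
#' unreachable rows), and returns the per-cluster summary after Tukey outlier
#' treatment.
#'
#' @param estimates output of [extract_dose_rates()].
#' @param k number of clusters (default 4).
#' @param restarts,seed passed to [kmeans_1d()].
#' @return list with `estimates` (labelled) and `summary` (see
#'   [treat_outliers_and_summarize()]).
#' @export
cluster_dose_rates <- function(estimates, k = 4L, restarts = 10L, seed = 1L) {
  ok <- which(estimates$reachable)
  if (length(ok) < k) stop_bad("fewer reachable estimates than clusters",
                               "insufficient_data")
  km <- kmeans_1d(estimates$dose_rate_Gy_per_s[ok], k = k,
                  restarts = restarts, seed = seed)
  estimates$cluster <- NA_integer_
  estimates$cluster[ok] <- km$labels
  list(estimates = estimates,
       summary = treat_outliers_and_summarize(
         estimates$dose_rate_Gy_per_s[ok], km$labels, k))
}
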