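# Independent oracles, kept free of the code paths they check.

# exact 1-D k-means by dynamic programming over the sorted values
# (optimal clusters are contiguous in sorted order)
kmeans_1d_dp_oracle <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {           # WCSS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- seg_cost(1, j)
  if (k > 1) for (q in 2:k) for (j in q:n) {
    for (i in q:j) {
      cand <- D[q - 1, i - 1] + seg_cost(i, j)
      if (cand < D[q, j]) D[q, j] <- cand
    }
  }
  D[k, n]
}

# dense-scan inversion oracle: smallest grid time whose prediction reaches
# the target (NA when the curve never gets within tolerance)
itf_scan_oracle <- function(predictor, voltage, frequency, flow, target,
                            t_min = 0.5, t_max = 120, n = 1e5,
                            tolerance = 0.1) {
  tg <- seq(t_min, t_max, length.out = n)
  fg <- predict_damage(predictor, data.frame(
    voltage_kV = voltage, frequency_kHz = frequency, flow_slm = flow,
    time_s = tg))
  hit <- which(fg >= target)
  if (length(hit)) return(tg[hit[1]])
  near <- which(abs(fg - target) <= tolerance)
  if (length(near)) tg[near[1]] else NA_real_
}

# definitional regression metrics
metrics_oracle <- function(y, yhat) {
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       rmse = sqrt(sum((y - yhat)^2) / length(y)),
       mae = sum(abs(y - yhat)) / length(y))
}

# best one-to-one component/cluster agreement (exhaustive over permutations)
bijective_recovery <- function(component, cluster, k) {
  tab <- table(factor(component, seq_len(k)), factor(cluster, seq_len(k)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, sum(tab[cbind(seq_len(k), p)]))
  }
  best / sum(tab)
}
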