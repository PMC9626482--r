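test_that("split_data partitions 75:25, seeded", {
  doe <- fixture_doe()[1:100, ]
  sp <- split_data(doe, 0.75, seed = 2)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  joined <- rbind(sp$train, sp$test)
  expect_setequal(rownames(joined), rownames(doe))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  sp2 <- split_data(doe, 0.75, seed = 2)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_data(doe, 0.75, seed = 3)))
  expect_error(split_data(doe[1:3, ], 0.75), class = "insufficient_data")
  expect_error(split_data(doe, 1.2), class = "invalid_parameter")
})

test_that("identify_minority_region flags rare damage bins", {
  mk <- function(d) data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2,
                               time_s = seq_along(d), damage_pct = d)
  spec <- minority_region_spec(bin_width = 10, threshold = 0.5)
  # hand histogram: bin of the four 5s is modal (4); bin of 90 has count 1 < 2
  expect_identical(identify_minority_region(mk(c(5, 5, 5, 5, 90)), spec),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # all equal -> single (modal) bin, nothing flagged
  expect_identical(identify_minority_region(mk(rep(42, 6)), spec),
                   rep(FALSE, 6))
  # threshold 1 flags every non-modal bin
  spec1 <- minority_region_spec(bin_width = 10, threshold = 1)
  expect_identical(identify_minority_region(mk(c(5, 5, 15, 25)), spec1),
                   c(FALSE, FALSE, TRUE, TRUE))
  empty <- data.frame(voltage_kV = numeric(0), frequency_kHz = numeric(0),
                      flow_slm = numeric(0), time_s = numeric(0),
                      damage_pct = numeric(0))
  expect_error(identify_minority_region(empty), class = "invalid_parameter")
})

test_that("smote_oversample interpolates convexly with provenance", {
  rec <- data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2,
                    time_s = c(5, 10, rep(30, 8)),
                    damage_pct = c(4, 8, rnorm(8, 50, 1)))
  mask <- c(TRUE, TRUE, rep(FALSE, 8))
  spec <- minority_region_spec(k = 1, minority_factor = 4)
  aug <- smote_oversample(rec, mask, spec, seed = 1)
  expect_true(all(rec$damage_pct %in% aug$damage_pct[!aug$synthetic]))
  synth <- aug[aug$synthetic, ]
  expect_gt(nrow(synth), 0)
  # minority records at (t=5, d=4) and (t=10, d=8): every interpolant obeys
  # the collinearity identity d = 0.8 t exactly
  s_min <- synth[synth$time_s <= 10, ]
  expect_true(all(abs(s_min$damage_pct - 0.8 * s_min$time_s) < 1e-12))
  # convex hull: synthetic values stay inside the member range per region
  expect_true(all(s_min$time_s >= 5 & s_min$time_s <= 10))
})

test_that("smote degenerate cases behave", {
  rec <- data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2,
                    time_s = c(5, 5, 30, 30, 30, 30),
                    damage_pct = c(4, 4, 50, 50, 50, 50))
  mask <- c(TRUE, TRUE, rep(FALSE, 4))
  # identical minority records -> synthetics equal them exactly
  aug <- smote_oversample(rec, mask, minority_region_spec(k = 1, minority_factor = 3),
                          seed = 2)
  s <- aug[aug$synthetic & aug$time_s < 30, ]
  expect_true(all(s$time_s == 5 & s$damage_pct == 4))
  # factor 1 for both regions -> no-op
  none <- smote_oversample(rec, mask,
                           minority_region_spec(minority_factor = 1,
                                                majority_factor = 1),
                           seed = 3)
  expect_equal(sum(none$synthetic), 0)
  expect_equal(nrow(none), nrow(rec))
  # single-record region duplicates with a warning
  expect_warning(
    smote_oversample(rec[c(1, 3:6), ], c(TRUE, rep(FALSE, 4)),
                     minority_region_spec(minority_factor = 3), seed = 4),
    "single record")
})

test_that("smote is seeded and balances the majority region", {
  rec <- small_doe()
  mask <- identify_minority_region(rec, minority_region_spec())
  a <- smote_oversample(rec, mask, seed = 7)
  b <- smote_oversample(rec, mask, seed = 7)
  expect_identical(a, b)
  spec <- minority_region_spec(minority_factor = 10)
  aug <- smote_oversample(rec, mask, spec, seed = 7)
  # counterbalancing: majority grows to match the augmented minority count
  n_min <- sum(mask); n_maj <- sum(!mask)
  min_total <- n_min + round(n_min * 9)
  maj_total <- max(n_maj, min_total)
  expect_equal(nrow(aug), min_total + maj_total)
  expect_true(all(aug$damage_pct[!aug$synthetic] %in% rec$damage_pct))
})

test_that("physical_loss matches hand hinge values", {
  anchor <- data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2)
  # monotone function -> 0
  expect_identical(physical_loss(function(v, f, q, t) 2 * t, anchor, c(1, 2, 3)),
                   0)
  # f(t) = -t on {1,2,3}: hinge terms {1, 1}, mean 1.0 (unclipped predictor)
  expect_equal(physical_loss(function(v, f, q, t) -t, anchor, c(1, 2, 3)), 1.0)
  # single time point -> no pairs -> 0
  expect_identical(physical_loss(function(v, f, q, t) -t, anchor, 5), 0)
  expect_error(physical_loss(function(v, f, q, t) t, anchor, c(3, 2, 1)),
               class = "invalid_parameter")
})

test_that("PHYLOSS = 0 iff non-decreasing on the collocation set", {
  anchors <- data.frame(voltage_kV = c(8, 10), frequency_kHz = c(1, 2),
                        flow_slm = c(2, 2))
  tg <- seq(0, 50, length.out = 20)
  monotone <- list(function(v, f, q, t) t^2 / 50,
                   function(v, f, q, t) 50 * (1 - exp(-0.05 * t)),
                   function(v, f, q, t) rep(7, length(t)))
  for (fn in monotone) expect_equal(physical_loss(fn, anchors, tg), 0)
  wiggly <- list(function(v, f, q, t) sin(t), function(v, f, q, t) 50 - t / 2)
  for (fn in wiggly) expect_gt(physical_loss(fn, anchors, tg), 0)
})

test_that("evaluate_model reproduces definitional metrics", {
  # hand computation: y = {1,2,3}, yhat = {1,2,4}
  pred <- as_damage_predictor(function(v, f, q, t) c(1, 2, 4), clip = FALSE)
  test <- data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2,
                     time_s = 1:3, damage_pct = c(1, 2, 3))
  r <- evaluate_model(pred, test)
  expect_equal(r$mae, 1 / 3)
  expect_equal(r$rmse, 1 / sqrt(3))
  expect_equal(r$r2, 0.5)
  # perfect predictor
  perfect <- as_damage_predictor(function(v, f, q, t) c(1, 2, 3), clip = FALSE)
  rp <- evaluate_model(perfect, test)
  expect_equal(rp$r2, 1); expect_equal(rp$rmse, 0); expect_equal(rp$mae, 0)
  # predicting the test mean gives R^2 = 0
  mean_pred <- as_damage_predictor(function(v, f, q, t) rep(2, length(t)),
                                   clip = FALSE)
  expect_equal(evaluate_model(mean_pred, test)$r2, 0)
  # zero-variance targets
  const <- test; const$damage_pct <- 5
  expect_warning(rz <- evaluate_model(pred, const), "undefined")
  expect_true(is.nan(rz$r2))
  # augmented test sets are rejected
  bad <- test; bad$synthetic <- c(FALSE, TRUE, FALSE)
  expect_error(evaluate_model(pred, bad), class = "invalid_parameter")
})

test_that("metrics agree with an independent implementation on random vectors", {
  set.seed(123)
  for (trial in 1:100) {
    y <- rnorm(10, 50, 20); yhat <- y + rnorm(10, 0, 5)
    test <- data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2,
                       time_s = 1:10, damage_pct = y)
    pred <- as_damage_predictor(local({ v <- yhat; function(V, F_, Q, t) v }),
                                clip = FALSE)
    got <- evaluate_model(pred, test)
    want <- metrics_oracle(y, yhat)
    expect_lt(abs(got$r2 - want$r2), 1e-10)
    expect_lt(abs(got$rmse - want$rmse), 1e-10)
    expect_lt(abs(got$mae - want$mae), 1e-10)
  }
})

test_that("check_physical_consistency finds planted violations", {
  anchor <- data.frame(voltage_kV = 8, frequency_kHz = 1, flow_slm = 2)
  mono <- true_damage_predictor(kinetics_config(noise_sd = 0))
  expect_equal(check_physical_consistency(mono, anchor, seq(0, 100, 5))$n_violations, 0)
  # planted: f(t) = t for t <= 30 else 60 - t on grid {10,...,50}:
  # decreases at (30,40) and (40,50), each of magnitude 10
  planted <- as_damage_predictor(function(v, f, q, t) ifelse(t <= 30, t, 60 - t),
                                 clip = FALSE)
  rep_ <- check_physical_consistency(planted, anchor, c(10, 20, 30, 40, 50))
  expect_equal(rep_$n_violations, 2)
  expect_equal(rep_$max_magnitude, 10)
  expect_error(check_physical_consistency(mono, anchor, c(3, 1, 2)),
               class = "invalid_parameter")
})

test_that("grid_search_cv picks the best grid point, leakage-safe", {
  doe <- small_doe(seed = 5)
  cfg <- model_config("decision_tree", seed = 1,
                      grid = list(max_depth = c(1L, 6L)))
  res <- grid_search_cv(doe, cfg, n_folds = 5, seed = 9)
  # fold sizes partition the data
  expect_equal(sum(table(res$fold_id)), nrow(doe))
  expect_equal(length(table(res$fold_id)), 5)
  # independent re-loop oracle over the same folds and grid
  for (g in seq_len(nrow(res$results))) {
    rmse_f <- numeric(5)
    for (f in 1:5) {
      tr <- doe[res$fold_id != f, ]; va <- doe[res$fold_id == f, ]
      mask <- identify_minority_region(tr, minority_region_spec())
      aug <- smote_oversample(tr, mask, minority_region_spec(),
                              seed = 9 + 1000L * g + f)
      fit <- train_damage_model(aug, model_config("decision_tree", seed = 1,
                                                  max_depth = res$results$max_depth[g]))
      rmse_f[f] <- sqrt(mean((va$damage_pct - predict_damage(fit, va))^2))
    }
    expect_equal(mean(rmse_f), res$results$mean_rmse[g], tolerance = 1e-12)
  }
  expect_equal(res$best_score, min(res$results$mean_rmse))
  # a deep tree beats a stump on smooth kinetics
  expect_equal(res$best_config$max_depth, 6L)
  # no synthetic record ever reached a validation fold
  expect_true(all(res$audit$n_synth_val == 0))
  expect_gt(sum(res$audit$n_synth_train), 0)
  # single-point grid returns that config
  one <- grid_search_cv(doe, model_config("linear", grid = list()), n_folds = 5,
                        seed = 9)
  expect_equal(one$best_config$algorithm, "linear")
  expect_error(grid_search_cv(doe[1:6, ], cfg, n_folds = 5),
               class = "insufficient_data")
})

test_that("fold sizes are balanced for n divisible by folds", {
  doe <- fixture_doe()[1:100, ]
  res <- grid_search_cv(doe, model_config("linear"), n_folds = 5, seed = 1)
  expect_true(all(table(res$fold_id) == 20))
})

test_that("baseline algorithms fit and beat the mean on smooth data", {
  doe <- small_doe(seed = 8, noise_sd = 0.5)
  sp <- split_data(doe, 0.75, seed = 8)
  for (alg in c("linear", "decision_tree", "random_forest",
                "gradient_boosting", "adaboost", "svr")) {
    fit <- train_damage_model(sp$train, model_config(alg, seed = 2))
    ev <- evaluate_model(fit, sp$test)
    expect_gt(ev$r2, 0.5)
    p <- predict_damage(fit, sp$test)
    expect_true(all(is.finite(p) & p >= 0 & p <= 100))
  }
})
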