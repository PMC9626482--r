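test_that("relative deviation grids follow |est - ref| / ref", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)      # hand grid {1, 2; 3, 4}
  expect_equal(relative_deviation_grid(m, 2),
               matrix(c(0.5, 0.5, 0, 1), 2, 2))
  expect_equal(relative_deviation_grid(matrix(5), 5), matrix(0))
  expect_equal(relative_deviation_grid(matrix(10), 5), matrix(1))
  expect_error(relative_deviation_grid(m, 0), class = "invalid_parameter")
  # NA (undefined) cells propagate
  m[1, 1] <- NA
  expect_true(is.na(relative_deviation_grid(m, 2)[1, 1]))
  # invariance under joint rescaling
  set.seed(1)
  g <- matrix(rlnorm(6), 2, 3)
  for (c_ in c(0.1, 3, 100)) {
    expect_equal(relative_deviation_grid(g * c_, 2 * c_),
                 relative_deviation_grid(g, 2))
  }
})

test_that("parameter_sweep matches a direct single-cell computation", {
  gt <- true_damage_predictor(kinetics_config(noise_sd = 0))
  db <- generate_literature_db(separated_db_config(seed = 5))
  sw <- parameter_sweep(gt, db, voltages = 8, frequencies = 1, flow = 2,
                        k = 4, seed = 3)
  expect_equal(dim(sw$centroid), c(1, 1))
  est <- extract_dose_rates(gt, voltage = 8, frequency = 1, flow = 2, db = db)
  cl <- cluster_dose_rates(est, k = 4,
                           seed = stage_seed(3, "cell_1_1"))
  low <- cl$summary[cl$summary$label == 1, ]
  expect_equal(sw$centroid[1, 1], low$centroid_Gy_per_s)
  expect_equal(sw$min_rate[1, 1], min(unlist(low$retained)))
})

test_that("the default sweep grid has the study's 3 x 15 shape", {
  gt <- true_damage_predictor(kinetics_config(noise_sd = 0))
  db <- generate_literature_db(separated_db_config(seed = 2))[1:48, ]
  sw <- parameter_sweep(gt, db, k = 2, seed = 1)
  expect_equal(dim(sw$centroid), c(3, 15))
  expect_equal(sw$frequencies, seq(0.5, 4, by = 0.25))
  expect_equal(sw$voltages, c(7, 8, 9))
  expect_true(all(sw$centroid > 0, na.rm = TRUE))
})

test_that("lowest-cluster centroid grows with frequency for alpha_f > 0", {
  gt <- true_damage_predictor(kinetics_config(noise_sd = 0))
  db <- generate_literature_db(separated_db_config(seed = 4))
  sw <- parameter_sweep(gt, db, voltages = c(7, 8, 9),
                        frequencies = seq(1, 4, by = 0.5), flow = 2,
                        k = 4, seed = 2)
  cons <- 0; tot <- 0
  for (i in seq_along(sw$voltages)) {
    row <- sw$centroid[i, ]
    ok <- !is.na(row)
    d <- diff(row[ok])
    cons <- cons + sum(d >= -1e-9); tot <- tot + length(d)
  }
  expect_gte(cons / tot, 0.9)
})

test_that("comparison summaries aggregate deviations correctly", {
  mk_sweep <- function(centroid, min_rate = centroid) {
    structure(list(centroid = centroid, min_rate = min_rate,
                   voltages = seq_len(nrow(centroid)),
                   frequencies = seq_len(ncol(centroid)), flow = 2, k = 4),
              class = "sweep_grid")
  }
  refs <- data.frame(radiation_type = c("gamma", "proton"),
                     rate_Gy_per_s = c(2, 0.05), placeholder = TRUE)
  # deviations {0.1, 0.3, 0.2} vs reference 2 -> estimates {2.2, 2.6, 2.4}
  sw <- mk_sweep(matrix(c(2.2, 2.6, 2.4), 1, 3),
                 min_rate = matrix(c(0.2, 0.3, 0.25), 1, 3))
  cs <- comparison_summary(list(gamma = sw), refs)
  expect_equal(cs$min_rel_dev, 0.1)
  expect_equal(cs$avg_rel_dev, 0.2)
  expect_equal(cs$ratio_min_to_reference, 0.2 / 2)
  # single defined cell: min = avg; ratio 0.2 / 0.05 = 4
  one <- mk_sweep(matrix(c(0.2, NA), 1, 2), matrix(c(0.2, NA), 1, 2))
  cp <- comparison_summary(list(proton = one), refs)
  expect_equal(cp$min_rel_dev, cp$avg_rel_dev)
  expect_equal(cp$ratio_min_to_reference, 4)
  # all-undefined types are excluded with a warning
  bad <- mk_sweep(matrix(NA_real_, 1, 2))
  expect_warning(out <- comparison_summary(list(gamma = bad), refs),
                 "undefined")
  expect_null(out)
  # min deviation never exceeds the average
  set.seed(6)
  for (i in 1:10) {
    sw_i <- mk_sweep(matrix(rlnorm(6), 2, 3))
    cs_i <- comparison_summary(list(gamma = sw_i), refs)
    expect_lte(cs_i$min_rel_dev, cs_i$avg_rel_dev)
  }
})

test_that("reference rates load with placeholder flags", {
  refs <- read_reference_rates()
  expect_true(all(c("gamma", "xray", "proton", "ion") %in% refs$radiation_type))
  expect_true(all(refs$rate_Gy_per_s > 0))
  expect_true(all(refs$placeholder))
  m <- measured_ltp_rates()
  expect_equal(unname(m["fricke"]), 0.76)
  expect_equal(unname(m["alanine"]), 0.01)
})

test_that("summaries survive a CSV round trip of the estimates", {
  gt <- true_damage_predictor(kinetics_config(noise_sd = 0))
  db <- generate_literature_db(separated_db_config(seed = 6))
  est <- extract_dose_rates(gt, db = db)
  cl <- cluster_dose_rates(est, k = 4, seed = 9)
  reach <- cl$estimates[cl$estimates$reachable, ]
  path <- tempfile(fileext = ".csv")
  write_csv_cols <- c("radiation_type", "study_id", "dose_Gy", "damage_pct",
                      "t_irr_s", "dose_rate_Gy_per_s", "cluster")
  utils::write.csv(reach[write_csv_cols], path, row.names = FALSE)
  back <- utils::read.csv(path)
  s_mem <- treat_outliers_and_summarize(reach$dose_rate_Gy_per_s,
                                        reach$cluster, 4)
  s_csv <- treat_outliers_and_summarize(back$dose_rate_Gy_per_s,
                                        back$cluster, 4)
  expect_equal(s_csv$centroid_Gy_per_s, s_mem$centroid_Gy_per_s,
               tolerance = 1e-9)
  expect_equal(s_csv$n_after, s_mem$n_after)
})
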