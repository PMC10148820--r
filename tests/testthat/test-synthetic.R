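test_that("the packaged catalogue matches the corpus design", {
  cat_ <- design_catalogue()
  expect_equal(sum(cat_$use == "fit"), 533)
  ## pulse-train series at 2, 4, 8, 16 minutes
  pp <- unique(cat_$protocol_id[grepl("^pulse", cat_$protocol_id)])
  expect_setequal(pp, c("pulse_0.2_2min", "pulse_0.2_4min",
                        "pulse_0.2_8min", "pulse_0.2_16min"))
  ## no duplicate (dataset id, time) pairs
  expect_false(any(duplicated(cat_[, c("dataset_id", "time_s")])))
  ## every modality of the corpus is represented
  expect_setequal(unique(cat_$modality),
                  c("ms_fold_change_pp", "ms_fold_change_p",
                    "wb_percent_total_phospho", "wb_percent_pY",
                    "nuc_cyt_ratio", "cell_area"))
  ## mono-phospho MS rows are test-only until flipped for the
  ## best-fitting experiment
  mono <- cat_$modality == "ms_fold_change_p"
  expect_true(all(cat_$use[mono] == "test"))
  expect_true(all(cat_$include_best_fit[mono]))
  withmono <- catalogue_with_mono(cat_)
  expect_true(all(withmono$use[mono] == "fit"))
  expect_equal(sum(withmono$use == "fit"), 533 + sum(mono))
  ## the ramp series is held out for testing
  expect_true(all(cat_$use[cat_$protocol_id == "ramp_0.2_1200"] == "test"))
})

test_that("generation is exact without noise and reproducible with it", {
  net <- ref_net("mixed")
  cat_ <- ms_catalogue()
  d0 <- generate_dataset(net, cat_, noise = FALSE)
  mu <- hogmix:::predict_dataset(net, cat_)
  expect_equal(d0$value, mu)
  ## fold change at the basal reference is 1; percent ranges hold pre-noise
  expect_equal(d0$value[d0$time_s == 0 & d0$modality == "ms_fold_change_pp"], 1,
               tolerance = 1e-6)

  d1 <- generate_dataset(net, cat_, noise = TRUE, seed = 13)
  d2 <- generate_dataset(net, cat_, noise = TRUE, seed = 13)
  expect_identical(d1$value, d2$value)
  expect_false(identical(d1$value,
                         generate_dataset(net, cat_, noise = TRUE,
                                          seed = 14)$value))
})

test_that("generated noise has the catalogue's error scale", {
  net <- ref_net("mixed")
  row1 <- ms_catalogue()[3, , drop = FALSE]
  reps <- do.call(rbind, lapply(seq_len(1000), function(i) {
    r <- row1
    r$dataset_id <- sprintf("rep%04d", i)
    r
  }))
  d <- generate_dataset(net, reps, noise = TRUE, seed = 21)
  expect_equal(sd(d$value), row1$sigma, tolerance = 0.1 * row1$sigma)
})

test_that("percent observables stay in range across the generated corpus", {
  net <- ref_net("mixed")
  cat_ <- design_catalogue()
  cat_ <- cat_[cat_$error_class %in% c("wb", "wb_ptp"), ]
  d <- generate_dataset(net, cat_, noise = FALSE)
  expect_true(all(d$value >= 0 & d$value <= 100))
})

test_that("a well-posed single-parameter recovery is accurate", {
  net <- ref_net("mixed")
  cat_ <- ms_catalogue()
  ctrl <- hog_control(n_starts = 4, top_set = 2, iter_cap = 20,
                      max_rounds = 1, free = "kcat_ptp3")
  rec <- recovery_experiment(net, cat_, ctrl, seed = 31)
  expect_equal(rec$n_total, 1)
  expect_equal(rec$n_within_order + sum(rec$deviations$abs_dev > 1),
               rec$n_total)
  expect_equal(rec$median_dev, median(rec$deviations$abs_dev))
  expect_lt(rec$median_dev, 0.3)
})
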