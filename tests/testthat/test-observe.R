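test_that("observables have their defining values on a reference trajectory", {
  tr <- wt_step_traj("mixed")
  ## fold change is 1 at the basal reference
  for (mod in c("ms_fold_change_pp", "ms_fold_change_p")) {
    f <- evaluate_observable(tr, mod)
    expect_equal(f[1], 1, tolerance = 1e-6)
  }
  ## percent phosphorylation lies in [0, 100]
  for (mod in c("wb_percent_total_phospho", "wb_percent_pY")) {
    w <- evaluate_observable(tr, mod)
    expect_true(all(w >= 0 & w <= 100))
  }
  ## cell area is volume^(2/3)
  expect_equal(evaluate_observable(tr, "cell_area"), tr$volume^(2 / 3))
})

test_that("equal nuclear and cytosolic concentrations give ratio one", {
  tr <- wt_step_traj("mixed")
  spec <- observable_spec(tr$network, "nuc_cyt_ratio")
  tr2 <- tr
  ## construct amounts with equal concentrations: nuclear pool = 10% share
  tr2$amounts[, spec$numerator] <- 0
  tr2$amounts[, spec$denominator] <- 0
  tr2$amounts[, "Hog1n"] <- 0.1
  tr2$amounts[, "Hog1c"] <- 0.9
  expect_equal(unique(evaluate_observable(tr2, "nuc_cyt_ratio")), 1)
})

test_that("objective matches its closed form and a brute-force oracle", {
  ## all residuals zero, sigma = 1: objective is n log(2 pi)
  cat_ <- ms_catalogue()
  net <- ref_net("mixed")
  d0 <- generate_dataset(net, cat_, noise = FALSE)
  d0$sigma <- 1
  v0 <- objective(net, dataset = d0)
  expect_equal(as.numeric(v0), nrow(d0) * log(2 * pi), tolerance = 1e-4)

  ## brute-force per-point summation on a 10-point toy dataset
  d <- ms_dataset()[1:10, ]
  v <- objective(net, dataset = d)
  mu <- predict_dataset(net, d)
  brute <- sum((d$value - mu)^2 / d$sigma^2 + log(2 * pi * d$sigma^2))
  expect_equal(as.numeric(v), brute, tolerance = 1e-6)

  ## doubling one residual strictly increases the objective
  d2 <- d
  d2$value[3] <- mu[3] + 2 * (d$value[3] - mu[3])
  expect_gt(as.numeric(objective(net, dataset = d2)), as.numeric(v))
})

test_that("objective is invariant to row order and dataset splitting", {
  net <- ref_net("mixed")
  d <- ms_dataset()
  v <- as.numeric(objective(net, dataset = d))
  set.seed(1)
  v_shuf <- as.numeric(objective(net, dataset = d[sample(nrow(d)), ]))
  expect_equal(v_shuf, v, tolerance = 1e-9)
  d_split <- d
  half <- seq_len(nrow(d)) <= nrow(d) / 2
  d_split$dataset_id <- ifelse(half, paste0(d$dataset_id, "_a"),
                               paste0(d$dataset_id, "_b"))
  expect_equal(as.numeric(objective(net, dataset = d_split)), v,
               tolerance = 1e-9)
})

test_that("freeing an error-model sigma never worsens the optimum", {
  net <- ref_net("mixed")
  d <- ms_dataset()
  topo <- net$topology
  anchors <- stats::setNames(net$parameters$log10, net$parameters$name)
  ctrl_fix <- hog_control(n_starts = 2, top_set = 2, iter_cap = 1,
                          free = "kcat1")
  fixed_val <- as.numeric(objective(net, dataset = d))
  ## optimise only the sigma of the ms error class, from the truth
  ctrl_sig <- hog_control(n_starts = 2, top_set = 2, iter_cap = 30,
                          free = "kcat1", fit_sigma = "ms")
  fn <- hogmix:::make_objective(net, d, ctrl_sig)
  start <- c(anchors[["kcat1"]], log10(0.2))
  names(start) <- c("kcat1", "sigma_ms")
  res <- local_optimize(fn, start, hogmix:::fit_bounds(net, ctrl_sig),
                        ctrl_sig)
  expect_lte(res$value, fixed_val + 1e-8)
})

test_that("strain and protocol identifiers parse to the right objects", {
  s <- strain_from_id("ptp2d+ptp3d")
  expect_setequal(s$deletions, c("PTP2", "PTP3"))
  expect_equal(strain_from_id("s248e")$pbs2_s248, "S248E")
  expect_true(strain_from_id("hog1as")$hog1_inhibited)
  expect_equal(strain_from_id("Pbs2x10")$overexpression, c(Pbs2 = 10))
  expect_error(strain_from_id("nonsense"), "unknown strain token")

  p <- protocol_from_id("pulse_0.2_8min")
  expect_equal(p$kind, "pulse_train")
  expect_equal(p$pulse_period, 8)
  expect_equal(protocol_from_id("ramp_0.2_1200")$ramp_duration, 1200)
  expect_error(protocol_from_id("square_0.4"), "unknown protocol")
})
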