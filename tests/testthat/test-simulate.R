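test_that("protocol constructors validate their fields", {
  expect_error(hog_protocol("step", amplitude = 1.5), "1 M")
  expect_error(hog_protocol("ramp", 0.2), "ramp_duration")
  expect_error(hog_protocol("pulse_train", 0.2, pulse_period = 3), "2, 4, 8, 16")
  expect_silent(hog_protocol("pulse_train", 0.2, pulse_period = 8))
})

test_that("external osmolarity follows the protocol exactly", {
  base <- 0.25
  st <- hog_protocol("step", 0.4, onset = 60)
  expect_equal(osmolarity(st, c(0, 59.9, 60, 600), baseline = base),
               base + c(0, 0, 0.4, 0.4))
  rp <- hog_protocol("ramp", 0.2, ramp_duration = 1200)
  expect_equal(osmolarity(rp, c(0, 600, 1200, 1800), baseline = base),
               base + c(0, 0.1, 0.2, 0.2))
  ## pulse train has the exact requested period
  pt <- hog_protocol("pulse_train", 0.2, pulse_period = 4)
  tt <- seq(0, 1920, by = 15)
  o <- osmolarity(pt, tt, baseline = base)
  expect_equal(o, osmolarity(pt, tt + 240, baseline = base))
  expect_setequal(unique(o), base + c(0, 0.2))
})

test_that("equilibration reaches a fixed point independent of the start", {
  net <- ref_net("mixed")
  eq <- equilibrate(net)
  expect_true(eq$converged)
  expect_lt(eq$rhs_norm, 1e-9)

  ## a further long integration moves no species appreciably
  tr <- run_protocol(net, hog_protocol("none", horizon = 1e4),
                     tgrid = c(0, 1e4), eq = eq)
  drift <- abs(tr$amounts[2, ] - tr$amounts[1, ]) /
    (abs(tr$amounts[1, ]) + 1e-8)
  expect_lt(max(drift), 1e-6)

  ## a different admissible start reaches the same equilibrium
  y2 <- initial_state(net)
  y2["Hog1c"] <- 0.3; y2["Hog1n"] <- 0.7
  y2["Vol"] <- 0.95; y2["Glyc"] <- 0.2
  eq2 <- equilibrate(net, y0 = y2)
  expect_true(eq2$converged)
  expect_lt(max(abs(eq2$state - eq$state) / (abs(eq$state) + 1e-5)), 1e-4)
})

test_that("removing the tyrosine phosphatases raises equilibrium Hog1-PP", {
  eq_wt <- equilibrate(ref_net("mixed"))
  eq_ptp <- equilibrate(ref_net("mixed",
                                hog_strain(deletions = c("PTP2", "PTP3"))))
  pp <- function(eq) eq$state[["Hog1PPc"]] + eq$state[["Hog1PPn"]]
  expect_gt(pp(eq_ptp), 10 * pp(eq_wt))
})

test_that("a 0.4 M step shrinks the cell within a minute, then it recovers", {
  tr <- wt_step_traj("mixed")
  expect_true(tr$success)
  i60 <- which(tr$time == 60)
  expect_lt(tr$volume[i60], 0.95 * tr$volume[1])
  expect_gt(tr$volume[length(tr$volume)], 0.97 * tr$volume[1])
})

test_that("no stimulus keeps every species at its equilibrium value", {
  net <- ref_net("mixed")
  tr <- run_protocol(net, hog_protocol("none", horizon = 1800),
                     tgrid = seq(0, 1800, 300))
  rel <- abs(sweep(tr$amounts, 2, tr$amounts[1, ])) /
    (matrix(abs(tr$amounts[1, ]), nrow(tr$amounts), ncol(tr$amounts),
            byrow = TRUE) + 1e-8)
  expect_lt(max(rel), 1e-6)
})

test_that("conserved totals hold along trajectories, across step events", {
  net <- ref_net("mixed")
  tr <- run_protocol(net, hog_protocol("pulse_train", 0.2, pulse_period = 4,
                                       horizon = 1200),
                     tgrid = seq(0, 1200, 30))
  expect_true(tr$success)
  expect_true(!is.unsorted(tr$time, strictly = TRUE))
  for (prot in c("Hog1", "Pbs2", "Ssk2", "Ptp2")) {
    tot <- species_total(tr, tr$network$conserved[[prot]])
    expect_lt(diff(range(tot)) / tot[1], 1e-6)
  }
  expect_true(min(tr$amounts) >= 0)
})

test_that("mechanism limits of the mixed network match the pure variants", {
  proto <- hog_protocol("step", 0.4, horizon = 1200)
  tg <- seq(0, 1200, 10)
  nm <- build_network(hog_topology("mixed"))
  nd <- build_network(hog_topology("distributive"))
  np <- build_network(hog_topology("processive"))

  trm <- run_protocol(nm, proto, tg, log10_overrides = c(k_phospho = -30),
                      rtol = 1e-10, atol = 1e-12)
  trd <- run_protocol(nd, proto, tg, rtol = 1e-10, atol = 1e-12)
  sh <- intersect(colnames(trm$amounts), colnames(trd$amounts))
  expect_lt(max(abs(trm$amounts[, sh] - trd$amounts[, sh])), 1e-6)

  trq <- run_protocol(nm, proto, tg,
                      log10_overrides = c(k_off = -30, kon2 = -30),
                      rtol = 1e-10, atol = 1e-12)
  trp <- run_protocol(np, proto, tg, rtol = 1e-10, atol = 1e-12)
  sh <- intersect(colnames(trq$amounts), colnames(trp$amounts))
  expect_lt(max(abs(trq$amounts[, sh] - trp$amounts[, sh])), 1e-6)
})

test_that("reported observables are converged with respect to solver tolerance", {
  net <- ref_net("mixed")
  proto <- hog_protocol("step", 0.4, horizon = 1200)
  tg <- seq(0, 1200, 60)
  a <- run_protocol(net, proto, tg, rtol = 1e-8, atol = 1e-10)
  b <- run_protocol(net, proto, tg, rtol = 1e-9, atol = 1e-11)
  for (mod in c("wb_percent_total_phospho", "nuc_cyt_ratio", "cell_area")) {
    va <- evaluate_observable(a, mod)
    vb <- evaluate_observable(b, mod)
    expect_lt(max(abs(va - vb) / (abs(vb) + 1e-6)), 1e-3)
  }
})

test_that("trajectories export to a tidy long data frame", {
  tr <- wt_step_traj("mixed")
  df <- as.data.frame(tr)
  expect_setequal(colnames(df), c("time", "species", "compartment", "amount"))
  expect_equal(nrow(df), length(tr$time) * ncol(tr$amounts))
  expect_setequal(unique(df$compartment), c("membrane", "cytosol", "nucleus"))
})
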