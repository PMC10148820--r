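test_that("processivity score reduces, scales and orders as defined", {
  ## no feedback complex: plain k_phospho / k_off
  expect_equal(processivity_score(0.3, 0, 4, 60, 8), 4 / 8)
  ## equal rates: complex split is irrelevant
  expect_equal(processivity_score(0.2, 0.7, 4, 4, 8), 4 / 8)
  ## raising the feedback rate with nonzero feedback complex raises the score
  s1 <- processivity_score(0.2, 0.1, 4, 30, 8)
  s2 <- processivity_score(0.2, 0.1, 4, 60, 8)
  expect_gt(s2, s1)
  ## scale invariance in the complex amounts
  expect_equal(processivity_score(0.02, 0.01, 4, 30, 8), s1)
  ## undefined when both complexes vanish
  expect_true(is.na(processivity_score(0, 0, 4, 30, 8)))
  expect_error(processivity_score(-1, 0, 4, 30, 8), "nonnegative")
})

test_that("processivity rises after stimulus onset on the reference model", {
  tr <- wt_step_traj("mixed")
  sc <- processivity_timecourse(tr)
  pre <- sc[tr$time == 0]
  post_peak <- max(sc[tr$time > 0 & tr$time < 1200], na.rm = TRUE)
  expect_gt(post_peak, 3 * pre)
  ## constant complexes give a constant score
  tr2 <- tr
  tr2$amounts[, "Pbs2PPHog1P"] <- 0.1
  tr2$amounts[, "Pbs2PPHog1P_feedback"] <- 0.05
  expect_equal(length(unique(round(processivity_timecourse(tr2), 12))), 1)
  ## topology without the feedback complexes is refused with a clear error
  trd <- wt_step_traj("processive")
  expect_error(processivity_timecourse(trd), "mixed mechanism")
})

test_that("S248 alleles move the pre-stimulus processivity score", {
  sc_wt <- processivity_timecourse(wt_step_traj("mixed"))[1]
  tra <- run_protocol(ref_net("mixed", hog_strain(pbs2_s248 = "S248A")),
                      hog_protocol("step", 0.4, horizon = 60),
                      tgrid = c(0, 60))
  tre <- run_protocol(ref_net("mixed", hog_strain(pbs2_s248 = "S248E")),
                      hog_protocol("step", 0.4, horizon = 60),
                      tgrid = c(0, 60))
  expect_lt(processivity_timecourse(tra)[1], sc_wt)
  expect_gt(processivity_timecourse(tre)[1], sc_wt)
})

test_that("Hill fits recover known exponents and match a grid search", {
  d <- seq(0.01, 1, length.out = 30)
  hill <- function(d, n, ec50, b = 0.1, m = 1.1)
    b + (m - b) * d^n / (ec50^n + d^n)
  ## noiseless Michaelian and ultrasensitive curves
  for (n_true in c(1, 3)) {
    hf <- hill_fit(d, hill(d, n_true, 0.2))
    expect_equal(hf$n, n_true, tolerance = 1e-3)
    expect_equal(hf$ec50, 0.2, tolerance = 1e-3)
  }
  ## noisy curve: matches a dense grid-search oracle within the grid step
  set.seed(8)
  y <- hill(d, 2.5, 0.3) + rnorm(30, 0, 0.02)
  hf <- hill_fit(d, y)
  grid_n <- seq(0.5, 6, by = 0.05)
  grid_e <- seq(0.05, 0.8, by = 0.005)
  sse <- outer(grid_n, grid_e, Vectorize(function(n, e)
    sum((y - hill(d, n, e, hf$basal, hf$max))^2)))
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(hf$n, grid_n[best[1]], tolerance = 0.05)
  expect_equal(hf$ec50, grid_e[best[2]], tolerance = 0.005)
  ## degenerate input is refused
  expect_error(hill_fit(d[1:5], rep(1, 5)), "degenerate")
})

test_that("perturbation ensembles are seeded, bounded and degenerate-safe", {
  net <- ref_net("mixed")
  proto <- hog_protocol("step", 0.4, horizon = 600)
  e1 <- perturbation_ensemble(net, proto, n_runs = 4, seed = 3)
  e2 <- perturbation_ensemble(net, proto, n_runs = 4, seed = 3)
  expect_identical(e1$max_pp, e2$max_pp)
  prot <- c("Sln1", "Ssk1", "Ssk2", "Ste20", "Pbs2", "Ptp2", "Ptp3")
  expect_true(all(as.matrix(e1[, prot]) >= 0.5 &
                    as.matrix(e1[, prot]) <= 2))
  expect_true(all(e1$ok))

  ## collapsed interval: every run equals the unperturbed response
  e0 <- perturbation_ensemble(net, proto, n_runs = 3, seed = 1,
                              interval = c(1, 1))
  expect_lt(diff(range(e0$max_pp)), 1e-6)
  tr <- run_protocol(net, proto, tgrid = seq(0, 600, 10))
  expect_equal(e0$max_pp[1],
               max(100 * species_total(tr, c("Hog1PPc", "Hog1PPn"))),
               tolerance = 1e-6)
})

test_that("perturbation regression is exact on constructed responses", {
  set.seed(9)
  n <- 40
  prot <- c("Sln1", "Ssk1", "Ssk2", "Ste20", "Pbs2", "Ptp2", "Ptp3")
  M <- matrix(exp(runif(n * 7, log(0.5), log(2))), n, 7,
              dimnames = list(NULL, prot))
  df <- data.frame(M, max_pp = 10 + 3 * M[, "Pbs2"])
  cf <- coef(regress_perturbations(df))
  expect_equal(unname(cf["Pbs2"]), 3, tolerance = 1e-8)
  expect_equal(max(abs(cf[setdiff(prot, "Pbs2")])), 0, tolerance = 1e-8)

  ## constant response: all slopes zero
  df2 <- data.frame(M, max_pp = 7)
  expect_equal(max(abs(coef(regress_perturbations(df2))[-1])), 0,
               tolerance = 1e-10)

  ## matches the normal-equations solution on a noisy 20-run set
  df3 <- data.frame(M[1:20, ], max_pp = 5 + rnorm(20))
  cf3 <- coef(regress_perturbations(df3))
  X <- cbind(1, as.matrix(df3[, prot]))
  beta <- solve(t(X) %*% X, t(X) %*% df3$max_pp)
  expect_equal(unname(cf3), as.vector(beta), tolerance = 1e-8)

  ## collinear designs are refused, and undersized ones too
  df4 <- df3; df4$Ssk1 <- 2 * df4$Pbs2
  expect_error(regress_perturbations(df4), "collinear")
  expect_error(regress_perturbations(df3[1:10, ]), "twice as many")
})

test_that("bootstrap histogram proportions partition the sample", {
  set.seed(10)
  x <- rnorm(300)
  h <- histogram_with_bootstrap(x, breaks = seq(-4, 4, by = 1), seed = 2)
  expect_equal(sum(h$proportion) + attr(h, "out_of_range"), 1,
               tolerance = 1e-12)
  ## single all-covering bin: proportion one, no bootstrap variance
  h1 <- histogram_with_bootstrap(x, breaks = c(-10, 10), seed = 2)
  expect_equal(h1$proportion, 1)
  expect_equal(h1$sd, 0)
  expect_error(histogram_with_bootstrap(numeric(0), c(0, 1)), "empty")

  ## 200-resample SDs agree with a large-B reference within 30% relative
  href <- histogram_with_bootstrap(x, breaks = c(-4, -1, 0, 1, 4),
                                   n_boot = 10000, seed = 3)
  h200 <- histogram_with_bootstrap(x, breaks = c(-4, -1, 0, 1, 4),
                                   n_boot = 200, seed = 4)
  expect_true(all(abs(h200$sd - href$sd) / href$sd < 0.3))
})
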