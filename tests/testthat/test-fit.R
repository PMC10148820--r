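quad_bounds <- function(k) {
  b <- cbind(rep(-3, k), rep(3, k))
  rownames(b) <- paste0("p", seq_len(k))
  b
}

test_that("uniform start sampling respects bounds and the seed", {
  b <- quad_bounds(3)
  s1 <- sample_starts(b, 50, seed = 11)
  s2 <- sample_starts(b, 50, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1 >= -3 & s1 <= 3))
  expect_false(identical(s1, sample_starts(b, 50, seed = 12)))

  ## empirical CDF of one coordinate is uniform (Kolmogorov bound, alpha 1%)
  x <- sample_starts(matrix(c(-3, 3), 1, 2,
                            dimnames = list("p1", NULL)), 1e4, seed = 5)[, 1]
  u <- (x + 3) / 6
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 1.63 / sqrt(length(u)))   # K-S critical value at 1%
})

test_that("local optimisation solves bound-constrained quadratics", {
  b <- quad_bounds(2)
  fn <- function(x) sum((x - c(0.5, -1))^2) + 2
  r <- local_optimize(fn, c(p1 = -2, p2 = 2), b)
  expect_equal(unname(r$par), c(0.5, -1), tolerance = 1e-4)
  expect_equal(r$value, 2, tolerance = 1e-6)

  ## minimum outside bounds: solution on the boundary
  fn2 <- function(x) sum((x - c(5, 0))^2)
  r2 <- local_optimize(fn2, c(p1 = 0, p2 = 0), b)
  expect_equal(unname(r2$par[1]), 3, tolerance = 1e-6)

  ## starting at the optimum changes nothing
  r3 <- local_optimize(fn, c(p1 = 0.5, p2 = -1), b)
  expect_equal(unname(r3$par), c(0.5, -1), tolerance = 1e-6)
  expect_lte(r3$value, fn(c(0.5, -1)))

  ## universally failing objective returns the start, flagged
  r4 <- local_optimize(function(x) NaN, c(p1 = 0, p2 = 0), b)
  expect_equal(r4$status, "failed")
  expect_equal(unname(r4$par), c(0, 0))
})

test_that("refinement recovers a convex optimum and keeps a sane history", {
  b <- quad_bounds(3)
  target <- c(1.2, -0.7, 0.3)
  fn <- function(x) sum((x - target)^2)
  ctrl <- hog_control(n_starts = 200, top_set = 20, iter_cap = 100)
  res <- refine(fn, b, ctrl, seed = 2)
  expect_equal(unname(res$par), target, tolerance = 1e-3)
  ## best-per-round history is non-increasing up to the stopping round
  expect_true(all(diff(res$history) <= 1e-12))
  expect_gte(res$rounds, 2)
})

test_that("degenerate elite sets take the covariance regularisation path", {
  b <- quad_bounds(2)
  elite <- matrix(1, 10, 2, dimnames = list(NULL, rownames(b)))
  set.seed(1)
  s <- hogmix:::mvn_resample(elite, 20, b, cov_floor = 1e-4)
  expect_true(attr(s, "regularized"))
  expect_equal(dim(s), c(20, 2))
  expect_true(all(s >= -3 & s <= 3))

  ## a flat objective (all optima identical) still completes a refine run
  fn <- function(x) 1
  res <- refine(fn, b, hog_control(n_starts = 10, top_set = 5, iter_cap = 5),
                seed = 1)
  expect_equal(res$value, 1)
  expect_equal(res$rounds, 2)
})

test_that("AIC follows its definition and ranking flags large differences", {
  expect_equal(compute_aic(0, L_max = 1), 0)
  expect_equal(compute_aic(5, loglik = -10), 30)
  expect_error(compute_aic(2, L_max = 0), "non-finite")
  expect_error(compute_aic(2), "supply")

  fits <- list(list(label = "a", k = 3, value = 94, aic = 100),
               list(label = "b", k = 4, value = 104, aic = 112),
               list(label = "c", k = 2, value = 101, aic = 105))
  rk <- rank_models(fits)
  expect_equal(rk$label, c("a", "c", "b"))
  expect_equal(rk$dAIC, c(0, 5, 12))
  expect_equal(rk$highly_significant, c(FALSE, FALSE, TRUE))
})

test_that("an anchored reduced fit improves the objective on synthetic data", {
  net <- ref_net("mixed")
  d <- ms_dataset()
  anchors <- stats::setNames(net$parameters$log10, net$parameters$name)
  ctrl <- hog_control(n_starts = 4, top_set = 2, iter_cap = 15,
                      max_rounds = 1, free = "kcat1")
  fit <- hog_fit(d, net$topology, ctrl, seed = 9, anchors = anchors)
  expect_s3_class(fit, "hog_fit")
  expect_equal(fit$k, 1)
  expect_equal(fit$aic, 2 * fit$k + fit$value)
  ## the truth lies within reach: fitted objective must beat a bad start
  start_val <- hogmix:::make_objective(
    hogmix::set_network_params(build_network(net$topology), anchors),
    d, ctrl)(c(kcat1 = -2))
  expect_lt(fit$value, start_val)
  ## logLik/AIC accessors agree with the stored values
  expect_equal(as.numeric(stats::AIC(fit)), fit$aic)
  expect_equal(length(residuals(fit)), sum(d$use == "fit"))
  expect_equal(length(fitted(fit)), sum(d$use == "fit"))
  ## determinism: same control and seed reproduce the same fit
  fit2 <- hog_fit(d, net$topology, ctrl, seed = 9, anchors = anchors)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$value, fit2$value)
})
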