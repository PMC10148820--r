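#' Fitting settings for multistart likelihood optimisation
#'
#' Defaults follow the reference pipeline: 10,000 uniform starting vectors
#' per round, bound-constrained local descent capped at 400 iterations or
#' an objective change below 1e-6, multivariate-normal resampling from the
#' 100 best vectors of the previous round, repeated until the best
#' goodness of fit of the latest round is as good or worse than the round
#' before.  Reduced budgets for scaled-down experiments are set here.
#'
#' @param n_starts starting vectors per round.
#' @param iter_cap local-optimiser iteration cap.
#' @param tol objective-change stopping tolerance.
#' @param top_set size of the elite set driving the resampling.
#' @param max_rounds hard cap on refinement rounds (`Inf` = stop rule only).
#' @param free character vector of parameter names to fit (`NULL` = all
#'   non-fixed parameters of the network).
#' @param fit_sigma character vector of error classes whose sigma is fitted
#'   (log10-parameterised, floored at 1e-3) instead of fixed.
#' @param cov_floor diagonal floor added to a degenerate resampling
#'   covariance.
#' @param verbose log per-round multistart progress.
#' @return A list of class `"hog_control"`.
#' @export
hog_control <- function(n_starts = 10000, iter_cap = 400, tol = 1e-6,
                        top_set = 100, max_rounds = Inf, free = NULL,
                        fit_sigma = character(0), cov_floor = 1e-4,
                        verbose = FALSE) {
  stopifnot(n_starts >= top_set, top_set >= 2, iter_cap >= 1, tol > 0)
  structure(list(n_starts = n_starts, iter_cap = iter_cap, tol = tol,
                 top_set = top_set, max_rounds = max_rounds, free = free,
                 fit_sigma = fit_sigma, cov_floor = cov_floor,
                 verbose = isTRUE(verbose)),
            class = "hog_control")
}

#' Sample uniform starting vectors
#'
#' Each coordinate is drawn uniformly between its lower and upper log10
#' bound; reproducible under the seed.
#'
#' @param bounds two-column matrix (lower, upper), one row per parameter;
#'   rownames are parameter names.
#' @param n number of vectors.
#' @param seed RNG seed.
#' @return `n` x `k` matrix of log10 parameter vectors.
#' @export
sample_starts <- function(bounds, n, seed = 1L) {
  stopifnot(is.matrix(bounds), ncol(bounds) == 2, all(bounds[, 1] < bounds[, 2]))
  set.seed(seed)
  k <- nrow(bounds)
  m <- matrix(stats::runif(n * k), n, k)
  out <- sweep(sweep(m, 2, bounds[, 2] - bounds[, 1], "*"), 2,
               bounds[, 1], "+")
  colnames(out) <- rownames(bounds)
  out
}

#' Bound-constrained local optimisation in log10 space
#'
#' Deterministic descent (L-BFGS-B) from one starting vector, stopping at
#' the iteration cap or when the objective change falls below `tol`.  The
#' returned value never exceeds the starting value; an objective that fails
#' at every probe returns the start with status `"failed"`.
#'
#' @param fn objective function of a log10 parameter vector.
#' @param start named numeric start.
#' @param bounds two-column matrix of log10 bounds.
#' @param control a [hog_control()].
#' @return List with `par`, `value`, `status`, `iterations`.
#' @export
local_optimize <- function(fn, start, bounds, control = hog_control()) {
  f0 <- suppressWarnings(fn(start))
  if (!is.finite(f0))
    return(list(par = start, value = Inf, status = "failed", iterations = 0L))
  safe_fn <- function(x) {
    v <- suppressWarnings(fn(x))
    if (!is.finite(v)) 1e12 else v
  }
  res <- try(stats::optim(start, safe_fn, method = "L-BFGS-B",
                          lower = bounds[, 1], upper = bounds[, 2],
                          control = list(maxit = control$iter_cap,
                                         factr = control$tol /
                                           .Machine$double.eps)),
             silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$value) ||
      res$value > f0) {
    return(list(par = start, value = f0, status = "no_improvement",
                iterations = 0L))
  }
  list(par = stats::setNames(res$par, names(start)), value = res$value,
       status = if (res$convergence == 0) "converged" else "iteration_cap",
       iterations = res$counts[["function"]])
}

## multivariate normal sampling from the elite set, projected into bounds
mvn_resample <- function(elite, n, bounds, cov_floor) {
  mu <- colMeans(elite)
  S <- stats::cov(elite)
  ch <- try(chol(S), silent = TRUE)
  regularized <- FALSE
  while (inherits(ch, "try-error")) {
    S <- S + diag(cov_floor, ncol(S))
    regularized <- TRUE
    ch <- try(chol(S), silent = TRUE)
    cov_floor <- cov_floor * 10
  }
  z <- matrix(stats::rnorm(n * ncol(elite)), n, ncol(elite))
  out <- sweep(z %*% ch, 2, mu, "+")
  out <- pmin(pmax(out, matrix(bounds[, 1], n, ncol(out), byrow = TRUE)),
              matrix(bounds[, 2], n, ncol(out), byrow = TRUE))
  colnames(out) <- colnames(elite)
  attr(out, "regularized") <- regularized
  out
}

#' Multistart refinement with multivariate-normal resampling
#'
#' Rounds of (sample starts, locally optimise each, rank).  The first round
#' samples uniformly within bounds; later rounds sample from a multivariate
#' normal whose mean and covariance come from the previous round's top set
#' (projected back into bounds, with a diagonal floor if degenerate).  The
#' loop stops when the best objective of the latest round is as good or
#' worse than the round before (or at `max_rounds`).  Ties in the top-set
#' selection break by start index (stable sort) for reproducibility.
#'
#' @param fn objective function of a named log10 vector.
#' @param bounds two-column log10 bound matrix with rownames.
#' @param control a [hog_control()].
#' @param seed RNG seed.
#' @return List with the overall best `par` and `value`, per-round
#'   `history` of best objectives, number of `rounds`, and the final elite
#'   set.
#' @export
refine <- function(fn, bounds, control = hog_control(), seed = 1L) {
  history <- numeric(0)
  best_par <- NULL
  best_val <- Inf
  elite <- NULL
  round <- 0L
  repeat {
    round <- round + 1L
    starts <- if (round == 1L) {
      sample_starts(bounds, control$n_starts, seed = seed)
    } else {
      set.seed(seed + round)
      mvn_resample(elite, control$n_starts, bounds, control$cov_floor)
    }
    vals <- numeric(nrow(starts))
    pars <- vector("list", nrow(starts))
    for (i in seq_len(nrow(starts))) {
      st <- stats::setNames(starts[i, ], colnames(starts))
      r <- local_optimize(fn, st, bounds, control)
      vals[i] <- r$value
      pars[[i]] <- r$par
    }
    ord <- order(vals, seq_along(vals))   # stable tie-break by start index
    top <- ord[seq_len(min(control$top_set, length(ord)))]
    elite <- do.call(rbind, pars[top])
    round_best <- vals[ord[1]]
    if (round_best < best_val) {
      best_val <- round_best
      best_par <- pars[[ord[1]]]
    }
    prev <- if (length(history)) history[length(history)] else Inf
    history <- c(history, round_best)
    if (isTRUE(control$verbose))
      message(sprintf("round %d: best objective %.6g (%d starts)",
                      round, round_best, nrow(starts)))
    if (round >= 2L && round_best >= prev) break
    if (round >= control$max_rounds) break
  }
  list(par = best_par, value = best_val, history = history,
       rounds = round, elite = elite)
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 ln(L_max)` with `k` the number of fitted parameters.
#' Either the maximal likelihood `L_max` or its log may be supplied.
#'
#' @param k number of fitted parameters (>= 0).
#' @param L_max maximal likelihood.
#' @param loglik log of the maximal likelihood (alternative to `L_max`).
#' @return The AIC value.
#' @export
compute_aic <- function(k, L_max = NULL, loglik = NULL) {
  stopifnot(k >= 0)
  if (is.null(loglik)) {
    if (is.null(L_max)) stop("supply L_max or loglik")
    loglik <- log(L_max)
  }
  if (!is.finite(loglik)) stop("non-finite likelihood")
  2 * k - 2 * loglik
}

#' Rank fitted models by AIC
#'
#' Orders fits ascending by AIC and computes differences to the best model;
#' a difference greater than ten is flagged as highly significant.
#'
#' @param fits list of `"hog_fit"` objects (or any objects with `aic` and a
#'   `label`).
#' @return Data frame: `label`, `k`, `m2logL`, `AIC`, `dAIC`,
#'   `highly_significant`, ordered by AIC.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  df <- data.frame(
    label = vapply(fits, function(f)
      if (!is.null(f$label)) f$label else format(f$topology), character(1)),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    m2logL = vapply(fits, function(f) as.numeric(f$value), numeric(1)),
    AIC = vapply(fits, function(f) as.numeric(f$aic), numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$AIC), , drop = FALSE]
  df$dAIC <- df$AIC - df$AIC[1]
  df$highly_significant <- df$dAIC > 10
  rownames(df) <- NULL
  df
}

## objective closure over the free log10 parameters (and fitted sigmas)
make_objective <- function(network, dataset, control) {
  conditions <- compile_conditions(network, dataset)
  free <- free_params(network, control)
  sig_names <- if (length(control$fit_sigma))
    paste0("sigma_", control$fit_sigma) else character(0)
  function(theta) {
    stopifnot(length(theta) == length(free) + length(sig_names))
    ov <- theta[seq_along(free)]
    names(ov) <- free
    sig <- NULL
    if (length(sig_names)) {
      sig <- 10^theta[length(free) + seq_along(sig_names)]
      names(sig) <- control$fit_sigma
      sig <- pmax(sig, 1e-3)
    }
    as.numeric(objective(network, dataset = dataset, log10_overrides = ov,
                         sigma_overrides = sig, conditions = conditions))
  }
}

free_params <- function(network, control) {
  if (!is.null(control$free)) {
    bad <- setdiff(control$free, network$parameters$name)
    if (length(bad)) stop("unknown free parameter(s): ",
                          paste(bad, collapse = ", "))
    return(control$free)
  }
  network$parameters$name[!network$parameters$fixed]
}

fit_bounds <- function(network, control) {
  free <- free_params(network, control)
  i <- match(free, network$parameters$name)
  b <- cbind(network$parameters$lower[i], network$parameters$upper[i])
  rownames(b) <- free
  if (length(control$fit_sigma)) {
    sb <- matrix(rep(c(-3, 2), each = length(control$fit_sigma)), ncol = 2)
    rownames(sb) <- paste0("sigma_", control$fit_sigma)
    b <- rbind(b, sb)
  }
  b
}

#' Fit a HOG submodel topology to a multimodal dataset
#'
#' The central model-fitting interface: builds the reaction network for the
#' topology, forms the -2 log likelihood over all `use == "fit"` rows of
#' the dataset (simulating every strain x protocol condition), and
#' minimises it by multistart local optimisation with multivariate-normal
#' resampling ([refine()]).  Returns a classed fit with the usual
#' accessor methods (`print`, `summary`, `coef`, `logLik`, `AIC`,
#' `predict`, `residuals`, `fitted`, `simulate`, `plot`).
#'
#' @param dataset a dataset data frame (see [read_dataset()]).
#' @param topology a [hog_topology()].
#' @param control a [hog_control()]; for desk-scale experiments reduce
#'   `n_starts`/`top_set`/`iter_cap` and restrict `free`.
#' @param seed RNG seed governing start sampling and resampling.
#' @param start optional named log10 vector: skip the multistart and run a
#'   single local optimisation from here.
#' @param anchors optional named log10 vector pinning non-free parameters
#'   to known values (used by recovery and model-recovery experiments).
#' @return An object of class `"hog_fit"`.
#' @export
hog_fit <- function(dataset, topology = hog_topology("mixed"),
                    control = hog_control(), seed = 1L, start = NULL,
                    anchors = NULL) {
  network <- build_network(topology)
  if (!is.null(anchors))
    network <- set_network_params(
      network, anchors[names(anchors) %in% network$parameters$name])
  validate_dataset(dataset)
  fn <- make_objective(network, dataset, control)
  bounds <- fit_bounds(network, control)
  t0 <- Sys.time()
  if (is.null(start)) {
    res <- refine(fn, bounds, control, seed = seed)
  } else {
    r <- local_optimize(fn, start[rownames(bounds)], bounds, control)
    res <- list(par = r$par, value = r$value, history = r$value,
                rounds = 1L, elite = NULL)
  }
  k <- nrow(bounds)
  n_fit <- sum(dataset$use == "fit")
  fit <- structure(
    list(topology = topology, network = network,
         coefficients = res$par, value = res$value, k = k,
         aic = compute_aic(k, loglik = -res$value / 2),
         history = res$history, rounds = res$rounds,
         n_points = n_fit, dataset = dataset, control = control,
         seed = seed, elapsed = as.numeric(Sys.time() - t0, units = "secs"),
         label = format(topology)),
    class = "hog_fit")
  fit
}

#' Fit several topologies and rank them
#'
#' Fits each topology to the same dataset with the same settings and seed
#' and returns the fits with their AIC ranking.
#'
#' @param dataset dataset data frame.
#' @param topologies list of [hog_topology()] (e.g.
#'   [enumerate_topologies()]).
#' @param control a [hog_control()].
#' @param seed RNG seed (same for every topology).
#' @return A `"hog_fit_list"`: list of fits with a `ranking` attribute.
#' @export
hog_fit_models <- function(dataset, topologies, control = hog_control(),
                           seed = 1L) {
  fits <- lapply(topologies, function(tp)
    hog_fit(dataset, tp, control = control, seed = seed))
  structure(list(fits = fits, ranking = rank_models(fits)),
            class = "hog_fit_list")
}

#' @export
print.hog_fit_list <- function(x, ...) {
  cat("AIC ranking of", length(x$fits), "fitted topologies\n")
  print(x$ranking, digits = 5)
  invisible(x)
}
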