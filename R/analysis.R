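#' Processivity score of the Hog1-Pbs2 reaction
#'
#' Ratio of the immediate second-phosphorylation flux of Pbs2-bound
#' mono-phosphorylated Hog1 to its dissociation flux:
#' \deqn{\frac{[C]\,k_{phospho} + [C_{fb}]\,k_{phospho,feed}}
#'            {([C] + [C_{fb}])\,k_{off}}}
#' where \eqn{[C]} and \eqn{[C_{fb}]} are the nascent mono-phospho complexes
#' on basal and feedback-modified Pbs2 and \eqn{k_{off}} is the shared
#' dissociation rate.  A low score indicates distributive-like behaviour, a
#' high score processive-like behaviour.
#'
#' @param complex amount of `Pbs2PPHog1P` (mono-phospho Hog1 bound to
#'   activated Pbs2); vectorised.
#' @param complex_fb amount of `Pbs2PPHog1P_feedback`.
#' @param k_phospho,k_phospho_feed second-step rate constants (1/s).
#' @param k_off shared dissociation rate constant (1/s).
#' @return Numeric score (vectorised); `NA` where both complex amounts are
#'   zero (the score is undefined there).
#' @export
processivity_score <- function(complex, complex_fb, k_phospho,
                               k_phospho_feed, k_off) {
  stopifnot(k_phospho > 0, k_phospho_feed > 0, k_off > 0)
  if (any(complex < 0 | complex_fb < 0, na.rm = TRUE))
    stop("complex amounts must be nonnegative")
  den <- (complex + complex_fb) * k_off
  out <- (complex * k_phospho + complex_fb * k_phospho_feed) / den
  out[den == 0] <- NA_real_
  out
}

#' Processivity score along a trajectory
#'
#' Evaluates [processivity_score()] at every time point of a simulated
#' trajectory, using the trajectory's own rate constants.  Requires a
#' topology with an immediate second step, a dissociation route and
#' positive feedback on Pbs2 (i.e. the two nascent complex species).
#'
#' @param trajectory a successful `"hog_trajectory"`.
#' @return Numeric vector over the trajectory time grid (undefined points
#'   are `NA`).
#' @export
processivity_timecourse <- function(trajectory) {
  stopifnot(inherits(trajectory, "hog_trajectory"), trajectory$success)
  need <- c("Pbs2PPHog1P", "Pbs2PPHog1P_feedback")
  miss <- setdiff(need, colnames(trajectory$amounts))
  if (length(miss))
    stop("topology lacks species ", paste(miss, collapse = ", "),
         ": a mixed mechanism with positive feedback on Pbs2 is required")
  pv <- trajectory$params
  for (nm in c("k_phospho", "k_off"))
    if (!nm %in% names(pv))
      stop("topology lacks rate ", nm,
           ": a mixed mechanism is required for the processivity score")
  kpf <- if ("k_phospho_feed" %in% names(pv)) pv[["k_phospho_feed"]]
         else pv[["k_phospho"]]
  processivity_score(trajectory$amounts[, "Pbs2PPHog1P"],
                     trajectory$amounts[, "Pbs2PPHog1P_feedback"],
                     pv[["k_phospho"]], kpf, pv[["k_off"]])
}

#' Simulated dose-response of maximal Hog1-PP
#'
#' For each dose, equilibrates the network, applies a step of that
#' amplitude and records the maximal percentage of doubly phosphorylated
#' Hog1 over the horizon (or, for a basic cascade, maximal MAPK-PP percent).
#'
#' @param network a `"hog_network"`.
#' @param doses numeric vector of step amplitudes (M NaCl, or input units
#'   for a basic cascade).
#' @param horizon simulation horizon (s).
#' @param tgrid output grid (defaults to 10-s spacing).
#' @param summary `"max"` (maximal response over the horizon; the
#'   single-cell analogue of per-cell maximal activation) or `"final"`
#'   (value at the end of the horizon, a steady-state readout for systems
#'   without adaptation such as the basic cascade).
#' @return Data frame with `dose` and `response` (percent).
#' @export
dose_response <- function(network, doses, horizon = 1500, tgrid = NULL,
                          summary = c("max", "final")) {
  summary <- match.arg(summary)
  stopifnot(length(doses) >= 1)
  if (is.null(tgrid)) tgrid <- seq(0, horizon, by = 10)
  sp <- colnames_pp(network)
  tot <- total_for_pp(network)
  eq <- equilibrate(network)
  resp <- vapply(doses, function(d) {
    tr <- run_protocol(network, hog_protocol("step", amplitude = d,
                                             horizon = horizon),
                       tgrid = tgrid, eq = eq)
    if (!tr$success) return(NA_real_)
    v <- 100 * species_total(tr, sp) / tot
    if (summary == "max") max(v) else v[length(v)]
  }, numeric(1))
  data.frame(dose = doses, response = resp)
}

colnames_pp <- function(network) {
  sp <- network$species$name
  if ("Kpp" %in% sp) "Kpp" else intersect(c("Hog1PPc", "Hog1PPn"), sp)
}

total_for_pp <- function(network) {
  prot <- if ("Kpp" %in% network$species$name) "K" else "Hog1"
  sum(network$species$init[network$species$name %in%
                             network$conserved[[prot]]])
}

#' Fit a Hill function to a dose-response curve
#'
#' Least-squares fit of
#' `basal + (max - basal) * d^n / (EC50^n + d^n)` with deterministic
#' initialisation (`n0 = 2`, EC50 started at the half-maximal dose by
#' interpolation) and `n` bounded in (0.1, 20).
#'
#' @param doses numeric vector of doses (> 0 except an optional zero dose).
#' @param responses numeric responses.
#' @return A `"hog_hill"` object: list with `basal`, `max`, `ec50`, `n`,
#'   fitted values, residual sum of squares, a `monotone` diagnostic flag
#'   and the `nls` fit.
#' @export
hill_fit <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), length(doses) >= 5)
  ok <- is.finite(doses) & is.finite(responses)
  d <- doses[ok]; y <- responses[ok]
  o <- order(d); d <- d[o]; y <- y[o]
  basal0 <- min(y); max0 <- max(y)
  if (max0 <= basal0) stop("degenerate dose-response: no dynamic range")
  half <- basal0 + (max0 - basal0) / 2
  above <- which(y >= half)
  ec0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    stats::approx(y[(i - 1):i], d[(i - 1):i], xout = half)$y
  } else stats::median(d)
  if (!is.finite(ec0) || ec0 <= 0) ec0 <- stats::median(d[d > 0])
  df <- data.frame(d = d, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ basal + (ymax - basal) * d^n / (ec50^n + d^n),
    data = df,
    start = list(basal = basal0, ymax = max0, ec50 = ec0, n = 2),
    lower = c(-Inf, -Inf, 1e-8, 0.1),
    upper = c(Inf, Inf, Inf, 20),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  monotone <- all(diff(y) >= -0.05 * (max0 - basal0))
  structure(list(basal = unname(cf["basal"]), max = unname(cf["ymax"]),
                 ec50 = unname(cf["ec50"]), n = unname(cf["n"]),
                 fitted = stats::fitted(fit),
                 rss = sum(stats::residuals(fit)^2),
                 monotone = monotone, doses = d, responses = y, fit = fit),
            class = "hog_hill")
}

#' @export
print.hog_hill <- function(x, ...) {
  cat(sprintf("Hill fit: n = %.3f, EC50 = %.4g, basal = %.3g, max = %.3g%s\n",
              x$n, x$ec50, x$basal, x$max,
              if (!x$monotone) "  [warning: non-monotone data]" else ""))
  invisible(x)
}

#' Robustness ensemble under protein-abundance perturbations
#'
#' Draws `n_runs` perturbation schemes (independent log-uniform multipliers
#' in `interval` for each of Sln1, Ssk1, Ssk2, Ste20, Pbs2, Ptp2 and Ptp3),
#' re-equilibrates the perturbed network, applies the protocol and records
#' the maximal Hog1-PP percentage.
#'
#' @param network a `"hog_network"`.
#' @param protocol a [hog_protocol()] (e.g. a 0.4 M step).
#' @param n_runs number of simulations.
#' @param seed RNG seed (reproducible).
#' @param interval multiplier range, default `c(0.5, 2)`.
#' @param proteins perturbed proteins.
#' @return A `"hog_ensemble"`: data frame of multipliers with columns
#'   `run`, one per protein, `max_pp` (percent) and `ok`; failed runs are
#'   recorded, not dropped.
#' @export
perturbation_ensemble <- function(network, protocol, n_runs, seed = 1L,
                                  interval = c(0.5, 2),
                                  proteins = c("Sln1", "Ssk1", "Ssk2",
                                               "Ste20", "Pbs2", "Ptp2",
                                               "Ptp3")) {
  stopifnot(n_runs >= 1, length(interval) == 2, interval[1] <= interval[2],
            interval[1] > 0)
  set.seed(seed)
  mult <- matrix(exp(stats::runif(n_runs * length(proteins),
                                  log(interval[1]), log(interval[2]))),
                 nrow = n_runs,
                 dimnames = list(NULL, proteins))
  sp <- colnames_pp(network)
  res <- numeric(n_runs)
  ok <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    st <- hog_strain(overexpression = mult[i, ])
    net_i <- apply_strain(network, st)
    tot <- total_for_pp(net_i)
    tr <- run_protocol(net_i, protocol,
                       tgrid = seq(0, protocol$horizon, by = 10))
    if (tr$success) {
      res[i] <- max(100 * species_total(tr, sp) / tot)
      ok[i] <- TRUE
    } else {
      res[i] <- NA_real_
      ok[i] <- FALSE
    }
  }
  out <- data.frame(run = seq_len(n_runs), mult, max_pp = res, ok = ok)
  class(out) <- c("hog_ensemble", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "interval") <- interval
  out
}

#' Multiple linear regression of ensemble maxima on multipliers
#'
#' Ordinary least squares of the maximal Hog1-PP percentage on the protein
#' multipliers (plus intercept), to ask whether a linear relationship
#' between abundance changes and pathway output exists.
#'
#' @param ensemble a `"hog_ensemble"` (or data frame with multiplier
#'   columns and `max_pp`).
#' @param proteins multiplier column names; defaults to the seven perturbed
#'   proteins present in the ensemble.
#' @return The `lm` fit, with a `collinear` attribute from a QR rank check.
#' @export
regress_perturbations <- function(ensemble,
                                  proteins = intersect(
                                    c("Sln1", "Ssk1", "Ssk2", "Ste20",
                                      "Pbs2", "Ptp2", "Ptp3"),
                                    colnames(ensemble))) {
  df <- as.data.frame(ensemble)[, c(proteins, "max_pp")]
  df <- df[is.finite(df$max_pp), , drop = FALSE]
  if (nrow(df) < 2 * length(proteins))
    stop("need at least twice as many runs as proteins")
  X <- cbind(1, as.matrix(df[, proteins]))
  rk <- qr(X)$rank
  if (rk < ncol(X))
    stop("collinear design: rank ", rk, " < ", ncol(X))
  fit <- stats::lm(stats::reformulate(proteins, response = "max_pp"),
                   data = df)
  attr(fit, "collinear") <- FALSE
  fit
}

#' Histogram proportions with bootstrap standard deviations
#'
#' Proportion of the sample in each bin, with the standard deviation of the
#' proportions estimated from bootstrap resamples.
#'
#' @param sample numeric sample.
#' @param breaks increasing vector of bin edges.
#' @param n_boot number of bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @return Data frame with `lower`, `upper`, `proportion`, `sd`; the mass
#'   outside the bin range is reported in the `"out_of_range"` attribute.
#' @export
histogram_with_bootstrap <- function(sample, breaks, n_boot = 200,
                                     seed = 1L) {
  if (!length(sample)) stop("empty sample")
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  set.seed(seed)
  n <- length(sample)
  prop1 <- function(x) {
    cts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks))[seq_len(length(breaks) - 1)]
    cts / length(x)
  }
  p <- prop1(sample)
  bs <- replicate(n_boot, prop1(sample[sample.int(n, n, replace = TRUE)]))
  sds <- if (is.matrix(bs)) apply(bs, 1, stats::sd) else stats::sd(bs)
  out <- data.frame(lower = utils::head(breaks, -1),
                    upper = utils::tail(breaks, -1),
                    proportion = p, sd = sds)
  attr(out, "out_of_range") <- 1 - sum(p)
  out
}
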