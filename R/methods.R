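## S3 methods for "hog_fit"

#' @export
print.hog_fit <- function(x, ...) {
  cat("HOG model fit\n")
  cat("  topology:    ", format(x$topology), "\n")
  cat("  data points: ", x$n_points, " (fit)\n", sep = "")
  cat(sprintf("  -2 logL:      %.4f\n", x$value))
  cat(sprintf("  k:            %d fitted parameters\n", x$k))
  cat(sprintf("  AIC:          %.4f\n", x$aic))
  cat("  rounds:      ", x$rounds, " (best per round: ",
      paste(sprintf("%.3f", x$history), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.hog_fit <- function(object, ...) {
  r <- residuals(object, type = "pearson")
  structure(list(fit = object,
                 resid_summary = summary(r),
                 coef = coef(object)),
            class = "summary.hog_fit")
}

#' @export
print.summary.hog_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted log10 parameters:\n")
  print(round(x$coef, 4))
  cat("\nPearson residuals (fit rows):\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
coef.hog_fit <- function(object, ...) object$coefficients

#' @export
logLik.hog_fit <- function(object, ...) {
  structure(-object$value / 2, df = object$k, nobs = object$n_points,
            class = "logLik")
}

#' Predicted observable values for dataset rows
#'
#' Simulates every condition of `newdata` under the fitted parameters and
#' evaluates each row's observable at its time point.
#'
#' @param object a `"hog_fit"`.
#' @param newdata dataset data frame (defaults to the training dataset,
#'   including its `use == "test"` rows).
#' @param ... unused.
#' @return Numeric vector of predictions aligned with `newdata` rows.
#' @export
predict.hog_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$dataset
  predict_dataset(object$network, newdata,
                  log10_overrides = fitted_overrides(object))
}

fitted_overrides <- function(object) {
  cf <- coef(object)
  cf[!startsWith(names(cf), "sigma_")]
}

## simulate all conditions of a dataset and evaluate per-row observables
predict_dataset <- function(network, dataset, log10_overrides = NULL) {
  validate_dataset(dataset)
  base <- set_network_params(network, log10_overrides)
  conditions <- compile_conditions(network, dataset)
  out <- rep(NA_real_, nrow(dataset))
  eqs <- new.env(parent = emptyenv())
  for (cond in conditions) {
    sel <- dataset$dataset_id %in% cond$dataset_ids
    if (!any(sel)) next
    dd <- dataset[sel, , drop = FALSE]
    net_c <- apply_strain(base, cond$strain)
    eq <- get0(cond$strain_key, envir = eqs)
    if (is.null(eq)) {
      eq <- equilibrate(net_c)
      assign(cond$strain_key, eq, envir = eqs)
    }
    traj <- run_protocol(net_c, cond$protocol,
                         tgrid = sort(unique(c(0, dd$time_s,
                                               cond$protocol$horizon))),
                         eq = eq)
    if (!traj$success) next
    for (mod in unique(dd$modality)) {
      ii <- which(sel)[dd$modality == mod]
      out[ii] <- evaluate_observable(traj, mod,
                                     times = dataset$time_s[ii])
    }
  }
  out
}

#' @export
fitted.hog_fit <- function(object, ...) {
  d <- object$dataset
  predict(object)[d$use == "fit"]
}

#' Residuals of a HOG model fit
#'
#' @param object a `"hog_fit"`.
#' @param type `"pearson"` (scaled by each row's sigma) or `"response"`.
#' @param ... unused.
#' @return Numeric vector over the fit rows.
#' @export
residuals.hog_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  d <- object$dataset[object$dataset$use == "fit", , drop = FALSE]
  r <- d$value - fitted(object)
  if (type == "pearson") r <- r / d$sigma
  r
}

#' Simulate replicate datasets from a fitted model
#'
#' Parametric simulation: predictions under the fitted parameters plus
#' Gaussian noise at each row's error scale.
#'
#' @param object a `"hog_fit"`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A list of `nsim` dataset data frames.
#' @export
simulate.hog_fit <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- predict(object)
  set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    d <- object$dataset
    d$value <- mu + stats::rnorm(length(mu), 0, d$sigma)
    d
  })
}

#' Plot data and fitted curves per dataset
#'
#' One panel per dataset id: measured points with error bars and the
#' fitted model's prediction over a dense time grid.
#'
#' @param x a `"hog_fit"`.
#' @param datasets dataset ids to show (default: the first four).
#' @param ... passed to `plot`.
#' @export
plot.hog_fit <- function(x, datasets = NULL, ...) {
  d <- x$dataset
  ids <- unique(d$dataset_id)
  if (is.null(datasets)) datasets <- utils::head(ids, 4)
  old <- par(mfrow = c(ceiling(length(datasets) / 2),
                       min(2, length(datasets))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (id in datasets) {
    dd <- d[d$dataset_id == id, , drop = FALSE]
    tgrid <- seq(0, max(dd$time_s), length.out = 100)
    curve_d <- dd[rep(1, length(tgrid)), , drop = FALSE]
    curve_d$time_s <- tgrid
    yhat <- predict(x, curve_d)
    plot(dd$time_s / 60, dd$value, pch = 19,
         xlab = "time (min)", ylab = dd$modality[1], main = id,
         ylim = range(c(dd$value - dd$sigma, dd$value + dd$sigma, yhat),
                      na.rm = TRUE), ...)
    segments(dd$time_s / 60, dd$value - dd$sigma,
             dd$time_s / 60, dd$value + dd$sigma, col = "grey50")
    lines(tgrid / 60, yhat, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
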