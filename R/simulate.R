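#' Define an osmotic stimulus protocol
#'
#' External-osmolarity forcing applied on top of the medium baseline:
#' nothing, a step, a linear ramp, or a square pulse train alternating
#' high/low half-periods.
#'
#' @param kind one of `"none"`, `"step"`, `"ramp"`, `"pulse_train"`.
#' @param amplitude added NaCl molarity (M), `>= 0` and at most 1 M.
#' @param onset stimulus onset time (s).
#' @param ramp_duration ramp duration (s), required for `kind = "ramp"`.
#' @param pulse_period pulse period in minutes, one of 2, 4, 8, 16.
#' @param horizon simulated horizon (s).
#' @return An object of class `"hog_protocol"`.
#' @export
hog_protocol <- function(kind = c("none", "step", "ramp", "pulse_train"),
                         amplitude = 0.4, onset = 0, ramp_duration = NULL,
                         pulse_period = NULL, horizon = 2400) {
  kind <- match.arg(kind)
  if (kind == "none") amplitude <- 0
  stopifnot(amplitude >= 0, horizon > 0)
  if (amplitude > 1) stop("amplitude above the 1 M NaCl guard")
  if (kind == "ramp") {
    if (is.null(ramp_duration) || ramp_duration <= 0)
      stop("ramp_duration > 0 required for a ramp protocol")
  }
  if (kind == "pulse_train") {
    if (is.null(pulse_period) || !pulse_period %in% c(2, 4, 8, 16))
      stop("pulse_period must be one of 2, 4, 8, 16 minutes")
  }
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 ramp_duration = ramp_duration, pulse_period = pulse_period,
                 horizon = horizon),
            class = "hog_protocol")
}

#' @export
format.hog_protocol <- function(x, ...) {
  switch(x$kind,
         none = "no stimulus",
         step = sprintf("step %.3g M at t=%gs", x$amplitude, x$onset),
         ramp = sprintf("ramp to %.3g M over %gs", x$amplitude, x$ramp_duration),
         pulse_train = sprintf("pulse train %.3g M, period %g min",
                               x$amplitude, x$pulse_period))
}

#' @export
print.hog_protocol <- function(x, ...) {
  cat("Stimulus protocol:", format(x), "\n")
  invisible(x)
}

## times at which the forcing is discontinuous (solver restart points)
protocol_breaks <- function(protocol, horizon) {
  switch(protocol$kind,
         none = numeric(0),
         step = protocol$onset,
         ramp = c(protocol$onset, protocol$onset + protocol$ramp_duration),
         pulse_train = {
           half <- protocol$pulse_period * 60 / 2
           br <- seq(protocol$onset, horizon, by = half)
           br
         })
}

#' External osmolarity of a protocol over time
#'
#' @param protocol a [hog_protocol()].
#' @param times numeric vector of times (s).
#' @param baseline medium baseline osmolarity (M).
#' @return Numeric vector of external osmolarity values.
#' @export
osmolarity <- function(protocol, times, baseline = 0) {
  p <- numeric(24)
  p[8] <- match(protocol$kind, c("none", "step", "ramp", "pulse_train")) - 1
  p[9] <- protocol$amplitude
  p[10] <- protocol$onset
  p[11] <- if (is.null(protocol$ramp_duration)) 1 else protocol$ramp_duration
  p[12] <- if (is.null(protocol$pulse_period)) 1 else protocol$pulse_period * 60
  p[13] <- baseline
  .Call(hog_osm_C, as.numeric(times), p)
}

## ---------------------------------------------------------------------
## packing the network + parameters + protocol for the compiled core

PARMS_LEN <- 6000

pack_parms <- function(network, params = NULL, protocol = NULL) {
  if (is.null(params)) params <- param_values(network)
  sp <- network$species$name
  nspec <- length(sp)
  spi <- stats::setNames(seq_along(sp) - 1L, sp)

  ## per-reaction encoding
  reac <- matrix(0, 6, length(network$reactions))
  ## parameter value slots: base params in table order, derived appended
  base_names <- network$parameters$name
  all_names <- c(base_names, names(network$derived))
  pvals <- params[all_names]
  if (anyNA(pvals)) stop("missing parameter values for packing")
  pidx <- stats::setNames(seq_along(all_names) - 1L, all_names)

  sto_r <- integer(0); sto_s <- integer(0); sto_c <- numeric(0)
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    kind <- match(rx$kind, c("mass_action", "michaelis_menten", "signal")) - 1L
    ip1 <- pidx[[rx$params[[1]]]]
    ip2 <- if (length(rx$params) > 1) pidx[[rx$params[[2]]]] else -1L
    if (kind == 1L) { # MM: enzyme first slot, substrate second
      is1 <- spi[[rx$enzyme]]
      is2 <- spi[[names(rx$reactants)[1]]]
      is3 <- -1L
    } else {
      rs <- names(rx$reactants)
      is1 <- spi[[rs[1]]]
      is2 <- if (length(rs) > 1) spi[[rs[2]]] else -1L
      is3 <- -1L
    }
    reac[, j] <- c(kind, ip1, ip2, is1, is2, is3)
    ## net stoichiometry
    net_st <- stats::setNames(numeric(0), character(0))
    acc <- function(v, sgn) {
      for (nm in names(v)) {
        cur <- if (nm %in% names(net_st)) net_st[[nm]] else 0
        net_st[[nm]] <<- cur + sgn * v[[nm]]
      }
    }
    acc(rx$reactants, -1); acc(rx$products, +1)
    net_st <- net_st[net_st != 0]
    sto_r <- c(sto_r, rep.int(j - 1L, length(net_st)))
    sto_s <- c(sto_s, spi[names(net_st)])
    sto_c <- c(sto_c, unname(net_st))
  }

  hw <- spi[network$hog1pp_drive]
  hdr <- numeric(24)
  hdr[1] <- nspec
  hdr[2] <- length(network$reactions)
  hdr[3] <- length(sto_r)
  hdr[4] <- length(all_names)
  hdr[5] <- length(hw)
  hdr[6] <- as.numeric(network$volume)
  hdr[7] <- network$signal_mode
  if (!is.null(protocol)) {
    hdr[8] <- match(protocol$kind, c("none", "step", "ramp", "pulse_train")) - 1
    hdr[9] <- protocol$amplitude
    hdr[10] <- protocol$onset
    hdr[11] <- if (is.null(protocol$ramp_duration)) 1 else protocol$ramp_duration
    hdr[12] <- if (is.null(protocol$pulse_period)) 1
               else protocol$pulse_period * 60
  }
  hdr[13] <- if ("osm_baseline" %in% names(params)) params[["osm_baseline"]] else 0
  if (network$volume) {
    vp <- c("vol_kpv", "vol_Pt0", "vol_Vlp", "vol_osmi", "vol_vhog",
            "vol_vind", "vol_kglyout", "vol_v0gly")
    hdr[14:21] <- params[vp]
  }
  out <- c(hdr, as.numeric(hw), as.numeric(reac),
           as.numeric(rbind(sto_r, sto_s, sto_c)), as.numeric(pvals))
  if (length(out) > PARMS_LEN) stop("packed network exceeds the parms buffer")
  c(out, numeric(PARMS_LEN - length(out)))
}

## initial state vector (species inits + volume states)
initial_state <- function(network) {
  y <- stats::setNames(network$species$init, network$species$name)
  if (network$volume) y <- c(y, Vol = 1, Glyc = 0.05)
  y
}

rhs_eval <- function(packed, t, y) .Call(hog_rhs_C, as.numeric(t),
                                         as.numeric(y), packed)

## one smooth-piece integration
ode_piece <- function(y, times, packed, rtol, atol, maxsteps = 10000) {
  out <- suppressWarnings(
    deSolve::ode(y = y, times = times, func = "hog_derivs",
                 parms = packed, dllname = "hogmix",
                 initfunc = "hog_initmod", jacfunc = "hog_jac",
                 jactype = "fullusr", nout = 1, outnames = "signal",
                 rtol = rtol, atol = atol, maxsteps = maxsteps,
                 method = "lsoda"))
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop("integration failed (stiff or divergent parameter set)")
  out
}

#' Pre-equilibrate a network to its zero-stimulus steady state
#'
#' Long stiff integration under the unstimulated condition until the
#' right-hand-side norm falls below `tol` (relative to the state norm), with
#' a hard time cap.  Non-convergence returns a failure signal rather than an
#' error so that fitting loops can penalise pathological parameter draws.
#'
#' @param network a `"hog_network"`.
#' @param params optional named linear-scale parameter vector (defaults to
#'   the network's values); or a named list of log10 overrides via
#'   `log10_overrides`.
#' @param log10_overrides named numeric vector of log10 parameter overrides.
#' @param tol relative RHS-norm convergence criterion.
#' @param t_max cap on equilibration time (s).
#' @param y0 optional starting state (defaults to the network's initial
#'   amounts).
#' @return A list with `state` (named steady state), `converged` (logical),
#'   `rhs_norm`, and the packed parameter blob reused by [run_protocol()].
#' @export
equilibrate <- function(network, params = NULL, log10_overrides = NULL,
                        tol = 1e-9, t_max = 8e5, y0 = NULL) {
  if (is.null(params)) params <- param_values(network, log10_overrides)
  packed <- pack_parms(network, params, hog_protocol("none"))
  y <- if (is.null(y0)) initial_state(network) else y0
  t_chunk <- 5e4
  t_done <- 0
  converged <- FALSE
  rhs_norm <- Inf
  while (t_done < t_max) {
    sol <- try(ode_piece(y, c(0, t_chunk), packed, rtol = 1e-10, atol = 1e-12),
               silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol[nrow(sol), ])))
      return(list(state = y, converged = FALSE, rhs_norm = NA_real_,
                  packed = packed, params = params))
    y <- sol[nrow(sol), 1 + seq_along(y)]
    names(y) <- names(initial_state(network))
    f <- rhs_eval(packed, 0, y)
    rhs_norm <- sqrt(sum(f^2)) / (sqrt(sum(y^2)) + 1)
    t_done <- t_done + t_chunk
    if (rhs_norm < tol) { converged <- TRUE; break }
    t_chunk <- t_chunk * 4
  }
  list(state = y, converged = converged, rhs_norm = rhs_norm,
       packed = packed, params = params)
}

#' Simulate a network under a stimulus protocol
#'
#' Integrates the pre-equilibrated network with the external osmolarity
#' following the protocol exactly; step and pulse discontinuities are
#' handled as solver restarts.  Amounts are checked for conservation and
#' negativity (solver noise down to -1e-12 is clipped; worse is a failure).
#'
#' @param network a `"hog_network"`.
#' @param protocol a [hog_protocol()].
#' @param tgrid output time grid (s); defaults to 1-s spacing over the
#'   protocol horizon for analysis use.
#' @param params optional named linear-scale parameter vector.
#' @param log10_overrides named numeric vector of log10 parameter overrides.
#' @param eq optional result of [equilibrate()] to reuse.
#' @param rtol,atol solver tolerances.
#' @return A `"hog_trajectory"`: list with `time`, species matrix `amounts`,
#'   `volume` and `glycerol` series, external `osmolarity`, `signal`,
#'   `success` flag and solver diagnostics.
#' @export
run_protocol <- function(network, protocol, tgrid = NULL, params = NULL,
                         log10_overrides = NULL, eq = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  if (is.null(eq))
    eq <- equilibrate(network, params, log10_overrides)
  if (!eq$converged)
    return(failed_trajectory(network, protocol, "equilibration failed"))
  if (is.null(tgrid))
    tgrid <- seq(0, protocol$horizon, by = 1)
  tgrid <- sort(unique(as.numeric(tgrid)))
  stopifnot(all(tgrid >= 0))
  packed <- pack_parms(network, eq$params, protocol)

  breaks <- protocol_breaks(protocol, max(tgrid))
  breaks <- breaks[breaks > 0 & breaks < max(tgrid)]
  edges <- sort(unique(c(0, breaks, max(tgrid))))
  y <- eq$state
  nsp <- nrow(network$species)
  out_t <- numeric(0)
  out_y <- NULL
  out_sig <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    t0 <- edges[i]; t1 <- edges[i + 1]
    tt <- tgrid[tgrid >= t0 & tgrid <= t1]
    tt <- sort(unique(c(t0, tt, t1)))
    ## integrate on absolute time; each smooth piece restarts the solver
    sol <- try(ode_piece(y, tt, packed, rtol, atol), silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol)))
      return(failed_trajectory(network, protocol, "integration failure"))
    keep <- sol[, 1] %in% tgrid
    out_t <- c(out_t, sol[keep, 1])
    ys <- sol[keep, 1 + seq_along(y), drop = FALSE]
    out_y <- rbind(out_y, ys)
    out_sig <- c(out_sig, sol[keep, ncol(sol)])
    y <- sol[nrow(sol), 1 + seq_along(y)]
    names(y) <- names(eq$state)
  }
  dup <- duplicated(out_t)
  out_t <- out_t[!dup]; out_y <- out_y[!dup, , drop = FALSE]
  out_sig <- out_sig[!dup]

  amounts <- out_y[, seq_len(nsp), drop = FALSE]
  colnames(amounts) <- network$species$name
  if (min(amounts) < -1e-12)
    return(failed_trajectory(network, protocol, "negative amounts"))
  amounts[amounts < 0] <- 0

  traj <- structure(
    list(time = out_t,
         amounts = amounts,
         volume = if (network$volume) out_y[, nsp + 1] else rep(1, length(out_t)),
         glycerol = if (network$volume) out_y[, nsp + 2] else rep(0, length(out_t)),
         osmolarity = osmolarity(protocol, out_t,
                                 baseline = if ("osm_baseline" %in%
                                                  names(eq$params))
                                   eq$params[["osm_baseline"]] else 0),
         signal = out_sig,
         network = network,
         protocol = protocol,
         params = eq$params,
         basal = eq$state,
         success = TRUE,
         diagnostics = list(rhs_norm = eq$rhs_norm)),
    class = "hog_trajectory")
  traj
}

failed_trajectory <- function(network, protocol, why) {
  structure(list(time = numeric(0), amounts = NULL, volume = numeric(0),
                 glycerol = numeric(0), osmolarity = numeric(0),
                 signal = numeric(0), network = network, protocol = protocol,
                 params = NULL, basal = NULL, success = FALSE,
                 diagnostics = list(reason = why)),
            class = "hog_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hog_trajectory <- function(x, ...) {
  if (!x$success) {
    cat("Failed trajectory:", x$diagnostics$reason, "\n")
    return(invisible(x))
  }
  cat("Trajectory:", length(x$time), "time points over",
      max(x$time), "s;", ncol(x$amounts), "species;",
      format(x$protocol), "\n")
  invisible(x)
}

#' Sum of amounts over a set of species along a trajectory
#'
#' @param trajectory a successful `"hog_trajectory"`.
#' @param species character vector of species names.
#' @return Numeric vector over the trajectory's time grid.
#' @export
species_total <- function(trajectory, species) {
  stopifnot(trajectory$success)
  miss <- setdiff(species, colnames(trajectory$amounts))
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  rowSums(trajectory$amounts[, species, drop = FALSE])
}

#' Summarise a trajectory as a JSON-ready list
#'
#' Compact machine-readable summary: protocol, horizon, basal and peak
#' doubly phosphorylated Hog1 (where present), volume minimum, and solver
#' diagnostics.  Pass to [write_results()] for a manifest-stamped JSON
#' file.
#'
#' @param trajectory a successful `"hog_trajectory"`.
#' @return A named list.
#' @export
trajectory_summary <- function(trajectory) {
  stopifnot(inherits(trajectory, "hog_trajectory"), trajectory$success)
  out <- list(protocol = format(trajectory$protocol),
              horizon_s = max(trajectory$time),
              n_time_points = length(trajectory$time),
              volume_min = min(trajectory$volume),
              success = trajectory$success)
  pp <- intersect(c("Hog1PPc", "Hog1PPn"), colnames(trajectory$amounts))
  if (length(pp)) {
    v <- species_total(trajectory, pp)
    out$hog1pp_basal <- v[1]
    out$hog1pp_peak <- max(v)
    out$hog1pp_peak_time_s <- trajectory$time[which.max(v)]
  }
  out
}

#' Export a trajectory as a tidy data frame
#'
#' @param x a successful `"hog_trajectory"`.
#' @param ... unused.
#' @return A long data frame (time, species, compartment, amount).
#' @export
as.data.frame.hog_trajectory <- function(x, ...) {
  stopifnot(x$success)
  sp <- x$network$species
  data.frame(
    time = rep(x$time, times = nrow(sp)),
    species = rep(sp$name, each = length(x$time)),
    compartment = rep(sp$compartment, each = length(x$time)),
    amount = as.vector(x$amounts),
    stringsAsFactors = FALSE)
}
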