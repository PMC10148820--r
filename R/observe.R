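## Observables map simulated trajectories onto the measured quantities:
## mass-spec fold changes relative to the basal state, western-blot percent
## phosphorylation of total Hog1, nuclear-to-cytosolic Hog1 concentration
## ratio, and relative cell area.  The nuclear compartment is taken as 10%
## of cell volume for the concentration conversion.

NUCLEAR_FRACTION <- 0.1

#' Species sets behind each observable modality
#'
#' Returns the numerator (and denominator) species sets used by
#' [evaluate_observable()] for a given network, so the mapping is explicit
#' and testable.
#'
#' @param network a `"hog_network"`.
#' @param modality one of `"ms_fold_change_pp"`, `"ms_fold_change_p"`,
#'   `"wb_percent_total_phospho"`, `"wb_percent_pY"`, `"nuc_cyt_ratio"`,
#'   `"cell_area"`.
#' @return A list with `numerator` and (where applicable) `denominator`
#'   species, plus the reference kind.
#' @export
observable_spec <- function(network,
                            modality = c("ms_fold_change_pp", "ms_fold_change_p",
                                         "wb_percent_total_phospho",
                                         "wb_percent_pY", "nuc_cyt_ratio",
                                         "cell_area")) {
  modality <- match.arg(modality)
  sp <- network$species$name
  mono_free <- intersect(c("Hog1Pc", "Hog1Pn"), sp)
  ## complexes carrying mono-phosphorylated Hog1
  mono_cplx <- sp[grepl("^Pbs2PPHog1P", sp)]
  pp <- intersect(c("Hog1PPc", "Hog1PPn"), sp)
  hog_all <- network$conserved$Hog1
  nuc <- sp[grepl("n$", sp) & grepl("^Hog1", sp)]
  cyt <- setdiff(hog_all, nuc)
  out <- switch(modality,
    ms_fold_change_pp = list(numerator = pp, reference = "t0"),
    ms_fold_change_p = list(numerator = c(mono_free, mono_cplx),
                            reference = "t0"),
    wb_percent_total_phospho = list(numerator = c(mono_free, mono_cplx, pp),
                                    denominator = hog_all, reference = "total"),
    ## the pY antibody sees doubly phosphorylated Hog1 and the mono form
    ## phosphorylated at Y176 (the modelled mono species)
    wb_percent_pY = list(numerator = c(mono_free, mono_cplx, pp),
                         denominator = hog_all, reference = "total"),
    nuc_cyt_ratio = list(numerator = nuc, denominator = cyt,
                         reference = "concentration"),
    cell_area = list(reference = "volume"))
  out$modality <- modality
  out
}

#' Evaluate an observable along a trajectory
#'
#' `ms_fold_change_*` is amount(t)/amount(basal) of the mapped species set;
#' `wb_percent_*` is 100 x phosphorylated / total Hog1 over all compartments
#' and complexes; `nuc_cyt_ratio` is the nuclear over cytosolic Hog1
#' concentration (nucleus = 10% of cell volume); `cell_area` is
#' volume^(2/3) normalised to the pre-stress volume.
#'
#' @param trajectory a successful `"hog_trajectory"`.
#' @param modality observable modality (see [observable_spec()]).
#' @param times optional times at which to interpolate (defaults to the
#'   trajectory grid).
#' @return Numeric vector of observable values; attribute `"flagged"` is
#'   `TRUE` when a division-by-zero reference was encountered (the values
#'   are then `NA` and the objective applies a penalty).
#' @export
evaluate_observable <- function(trajectory, modality, times = NULL) {
  stopifnot(inherits(trajectory, "hog_trajectory"))
  if (!trajectory$success) stop("cannot evaluate observables on a failed trajectory")
  net <- trajectory$network
  spec <- observable_spec(net, modality)
  basal <- trajectory$basal

  val <- switch(spec$modality,
    ms_fold_change_pp = ,
    ms_fold_change_p = {
      num <- species_total(trajectory, spec$numerator)
      ref <- sum(basal[spec$numerator])
      if (ref <= 0) return(flagged_series(trajectory$time, times))
      num / ref
    },
    wb_percent_total_phospho = ,
    wb_percent_pY = {
      num <- species_total(trajectory, spec$numerator)
      den <- species_total(trajectory, spec$denominator)
      if (any(den <= 0)) return(flagged_series(trajectory$time, times))
      100 * num / den
    },
    nuc_cyt_ratio = {
      num <- species_total(trajectory, spec$numerator) / NUCLEAR_FRACTION
      den <- species_total(trajectory, spec$denominator) / (1 - NUCLEAR_FRACTION)
      if (any(den <= 0)) return(flagged_series(trajectory$time, times))
      num / den
    },
    cell_area = trajectory$volume^(2 / 3))

  if (!is.null(times)) {
    val <- stats::approx(trajectory$time, val, xout = times, rule = 2)$y
  }
  val
}

flagged_series <- function(tgrid, times) {
  n <- if (is.null(times)) length(tgrid) else length(times)
  structure(rep(NA_real_, n), flagged = TRUE)
}

## ---------------------------------------------------------------------
## the -2 log likelihood objective

#' Goodness-of-fit objective (-2 log likelihood)
#'
#' Gaussian additive error on each observable's own scale:
#' sum over points of (y - yhat)^2 / sigma^2 + log(2 pi sigma^2).  Datasets
#' are grouped into simulation conditions (strain x protocol); any
#' condition whose simulation fails contributes a large finite penalty so
#' multistart optimisation survives pathological parameter draws.
#'
#' @param network the base (wild-type) `"hog_network"`.
#' @param params named linear-scale parameter vector, or `NULL` for the
#'   network defaults.
#' @param dataset a dataset data frame (see [read_dataset()] for the
#'   column contract); only rows with `use == "fit"` enter unless
#'   `use_all = TRUE`.
#' @param log10_overrides named log10 parameter overrides (the fitting
#'   interface).
#' @param sigma_overrides optional named vector mapping `error_class` to a
#'   fitted sigma value replacing the per-row `sigma` of that class.
#' @param conditions optional precompiled condition list from
#'   [compile_conditions()] (avoids re-deriving strain networks).
#' @param use_all include `use == "test"` rows.
#' @param penalty objective contribution per data point of a failed
#'   condition.
#' @return The scalar objective; attributes `"n"` (points scored) and
#'   `"failed"` (number of failed conditions).
#' @export
objective <- function(network, params = NULL, dataset,
                      log10_overrides = NULL, sigma_overrides = NULL,
                      conditions = NULL, use_all = FALSE, penalty = 1e4) {
  if (nrow(dataset) == 0) stop("empty dataset")
  if (is.null(conditions)) conditions <- compile_conditions(network, dataset)
  rows <- if (use_all) dataset else dataset[dataset$use == "fit", , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows with use == \"fit\" in dataset")

  ## parameter overrides act on the base network, then strains on top, so
  ## allele transforms (e.g. S248E association boost) see the fitted values
  base <- set_network_params(network, log10_overrides)

  total <- 0
  n_pts <- 0L
  n_failed <- 0L
  eq_cache <- new.env(parent = emptyenv())
  net_cache <- new.env(parent = emptyenv())
  for (cond in conditions) {
    sel <- rows$dataset_id %in% cond$dataset_ids
    if (!any(sel)) next
    dd <- rows[sel, , drop = FALSE]
    key <- cond$strain_key
    net_c <- get0(key, envir = net_cache)
    if (is.null(net_c)) {
      net_c <- apply_strain(base, cond$strain)
      assign(key, net_c, envir = net_cache)
    }
    eq <- get0(key, envir = eq_cache)
    if (is.null(eq)) {
      eq <- equilibrate(net_c)
      assign(key, eq, envir = eq_cache)
    }
    traj <- if (eq$converged)
      run_protocol(net_c, cond$protocol,
                   tgrid = sort(unique(c(0, dd$time_s, cond$protocol$horizon))),
                   eq = eq)
    else failed_trajectory(net_c, cond$protocol, "equilibration failed")
    sig <- dd$sigma
    if (!is.null(sigma_overrides)) {
      hit <- dd$error_class %in% names(sigma_overrides)
      sig[hit] <- sigma_overrides[dd$error_class[hit]]
    }
    if (!traj$success) {
      total <- total + penalty * nrow(dd)
      n_failed <- n_failed + 1L
      n_pts <- n_pts + nrow(dd)
      next
    }
    for (mod in unique(dd$modality)) {
      di <- dd[dd$modality == mod, , drop = FALSE]
      yhat <- evaluate_observable(traj, mod, times = di$time_s)
      si <- sig[dd$modality == mod]
      if (isTRUE(attr(yhat, "flagged")) || any(!is.finite(yhat))) {
        total <- total + penalty * nrow(di)
      } else {
        total <- total + sum((di$value - yhat)^2 / si^2 + log(2 * pi * si^2))
      }
      n_pts <- n_pts + nrow(di)
    }
  }
  structure(total, n = n_pts, failed = n_failed)
}

#' Group a dataset into simulation conditions
#'
#' One condition per (strain, protocol) combination, carrying the
#' strain-applied network, the protocol object and the dataset ids mapped to
#' it.
#'
#' @param network the base `"hog_network"`.
#' @param dataset a dataset data frame.
#' @return A list of condition descriptors.
#' @export
compile_conditions <- function(network, dataset) {
  key <- paste(dataset$strain, dataset$protocol_id, sep = "|")
  out <- list()
  for (k in unique(key)) {
    rows <- dataset[key == k, , drop = FALSE]
    strain <- strain_from_id(rows$strain[1])
    proto <- protocol_from_id(rows$protocol_id[1],
                              horizon = max(rows$time_s, 60))
    out[[k]] <- list(
      strain = strain,
      protocol = proto,
      strain_key = rows$strain[1],
      dataset_ids = unique(rows$dataset_id))
  }
  out
}

#' Set network parameters from log10 overrides
#'
#' Returns a copy of the network with the named parameters' log10 values
#' replaced.  Unknown names are an error.
#'
#' @param network a `"hog_network"`.
#' @param log10_overrides named numeric vector (may be `NULL`).
#' @return The updated network.
#' @export
set_network_params <- function(network, log10_overrides = NULL) {
  if (is.null(log10_overrides) || !length(log10_overrides)) return(network)
  i <- match(names(log10_overrides), network$parameters$name)
  if (anyNA(i))
    stop("unknown parameter(s): ",
         paste(names(log10_overrides)[is.na(i)], collapse = ", "))
  network$parameters$log10[i] <- as.numeric(log10_overrides)
  network
}

#' Parse a strain identifier string
#'
#' The dataset dialect encodes strains as `"wt"` or `+`-separated tokens:
#' gene deletions in lower case with a `d` suffix (`pbs2d`, `ptp2d+ptp3d`),
#' `s248a`/`s248e` alleles, `ssk2fbdead`, `hog1as` (inhibited), and
#' `<Protein>x<factor>` overexpression.
#'
#' @param id strain identifier string.
#' @return A [hog_strain()].
#' @export
strain_from_id <- function(id) {
  if (id %in% c("wt", "", "WT")) return(hog_strain())
  toks <- strsplit(id, "+", fixed = TRUE)[[1]]
  del <- character(0); s248 <- "wt"; fbdead <- FALSE; inhib <- FALSE
  overe <- numeric(0)
  for (tk in toks) {
    if (grepl("^(pbs2|sln1|sho1|ssk2|ptp2|ptp3)d$", tk)) {
      del <- c(del, toupper(sub("d$", "", tk)))
    } else if (tk == "s248a") s248 <- "S248A"
    else if (tk == "s248e") s248 <- "S248E"
    else if (tk == "ssk2fbdead") fbdead <- TRUE
    else if (tk == "hog1as") inhib <- TRUE
    else if (grepl("^[A-Za-z0-9]+x[0-9.]+$", tk)) {
      pr <- sub("x[0-9.]+$", "", tk)
      overe[pr] <- as.numeric(sub("^[A-Za-z0-9]+x", "", tk))
    } else stop("unknown strain token: ", tk)
  }
  hog_strain(deletions = del, pbs2_s248 = s248, ssk2_feedback_dead = fbdead,
             hog1_inhibited = inhib, overexpression = overe)
}

#' Parse a protocol identifier string
#'
#' Identifiers: `"none"`, `"step_<M>"`, `"ramp_<M>_<s>"`,
#' `"pulse_<M>_<min>min"`.
#'
#' @param id protocol identifier string.
#' @param horizon horizon (s) when not implied by the data.
#' @return A [hog_protocol()].
#' @export
protocol_from_id <- function(id, horizon = 2400) {
  if (id == "none") return(hog_protocol("none", horizon = horizon))
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "step")
    hog_protocol("step", amplitude = as.numeric(parts[2]), horizon = horizon)
  else if (kind == "ramp")
    hog_protocol("ramp", amplitude = as.numeric(parts[2]),
                 ramp_duration = as.numeric(parts[3]), horizon = horizon)
  else if (kind == "pulse")
    hog_protocol("pulse_train", amplitude = as.numeric(parts[2]),
                 pulse_period = as.numeric(sub("min$", "", parts[3])),
                 horizon = horizon)
  else stop("unknown protocol id: ", id)
}

protocol_to_id <- function(protocol) {
  switch(protocol$kind,
         none = "none",
         step = sprintf("step_%g", protocol$amplitude),
         ramp = sprintf("ramp_%g_%g", protocol$amplitude, protocol$ramp_duration),
         pulse_train = sprintf("pulse_%g_%gmin", protocol$amplitude,
                               protocol$pulse_period))
}
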