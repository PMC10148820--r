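#' Reference calibration of the HOG model
#'
#' The package ships one hand-calibrated reference parameter set per
#' phosphorylation mechanism (all with two-component positive feedback on
#' Pbs2 and negative feedback on Ssk2).  The calibration was chosen once to
#' reproduce the qualitative behaviour of the system under study --
#' low basal Hog1-PP with fast near-complete activation at 0.4 M NaCl and
#' adaptation within ~15 minutes; volume drop and glycerol-driven recovery
#' (partial in pbs2-deleted cells); raised basal and prolonged
#' phosphorylation without Ptp2/Ptp3; the double-peaked mono-phosphorylated
#' Hog1 time course under a distributive mechanism; suppression of
#' activation under Pbs2 excess in the processive variant -- and then
#' frozen.  It serves as the default ground truth for the synthetic-data
#' generator and for analysis examples.
#'
#' @param mechanism `"mixed"`, `"distributive"` or `"processive"`.
#' @return Named numeric vector of log10 parameter overrides for
#'   [build_network()]'s parameter table.
#' @seealso [hog_reference_network()]
#' @export
hog_reference_params <- function(mechanism = c("mixed", "distributive",
                                               "processive")) {
  mechanism <- match.arg(mechanism)
  shared <- c(
    k_sln1_off = log10(0.3), k_sln1_on = log10(0.2),
    k_ssk1_act = log10(0.05), k_ssk1_deact_sln1 = log10(400),
    k_fb_on = log10(1.2), Km_fb = log10(0.3), k_fb_off = log10(0.1),
    kcat1 = log10(8), k_phospho = log10(4), k_off = log10(8),
    kcat2 = log10(8),
    k_nfb = log10(2),
    vol_vhog = log10(8e-4), vol_vind = log10(6e-4),
    vol_kglyout = log10(1e-4), vol_v0gly = log10(2e-6),
    vol_Vlp = log10(0.6),
    k_pbs2_ssk2 = log10(1.0), k_pbs2_ste11 = log10(0.7),
    kcat_ptp3 = log10(8), kcat_ptp2 = log10(8),
    kon_ste20 = log10(1), k_ste11_act = log10(1.5),
    k_ste11_deact = log10(1), k_sho1_deact = log10(1),
    ptc_c = log10(0.05), ptc_n = log10(0.05),
    k_imp = log10(0.033), k_exp = log10(0.3),
    k_imp_pp = log10(0.1), k_exp_pp = log10(0.3))
  if (mechanism == "processive") {
    ## the best-fitting processive variant relies on a faster immediate
    ## second step and a tighter catalytically dead Pbs2-Hog1 scaffold
    ## complex (which titrates Hog1 away when Pbs2 is in excess)
    shared[["k_phospho"]] <- log10(20)
    shared <- c(shared, kon_scaf = log10(1.5), koff_scaf = log10(0.3))
  }
  drop <- switch(mechanism,
                 distributive = "k_phospho",
                 processive = c("k_off", "kcat2"),
                 character(0))
  shared[setdiff(names(shared), drop)]
}

#' Build a reference-calibrated network
#'
#' Convenience wrapper: builds the topology for the requested mechanism
#' (positive feedback on Pbs2 with both components, negative feedback on),
#' applies the frozen reference calibration and optionally a strain.
#'
#' @param mechanism `"mixed"`, `"distributive"` or `"processive"`.
#' @param strain optional [hog_strain()].
#' @return A `"hog_network"`.
#' @export
hog_reference_network <- function(mechanism = c("mixed", "distributive",
                                                "processive"),
                                  strain = NULL) {
  mechanism <- match.arg(mechanism)
  net <- build_network(hog_topology(mechanism, "pbs2",
                                    c("catalytic", "affinity"),
                                    negative_feedback = TRUE))
  ov <- hog_reference_params(mechanism)
  ov <- ov[names(ov) %in% net$parameters$name]
  net <- set_network_params(net, ov)
  if (!is.null(strain)) net <- apply_strain(net, strain)
  net
}
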