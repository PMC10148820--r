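## Reaction-network construction.
##
## A "hog_network" is a plain-list container: a species table (name,
## compartment, initial amount), a reaction list (reactants/products with
## stoichiometry, rate-law kind, parameter names, optional enzyme), a
## parameter table (log10 value, log10 bounds, fixed flag, bound class), a
## list of derived parameters (products of named parameters, used for the
## feedback multipliers), and conserved-total membership per protein.
## Amounts are copy-number-like units normalised so wild-type totals are 1;
## observables are ratios/percentages and therefore scale-free.

new_network <- function(topology = NULL, volume = TRUE, signal_mode = 0L) {
  structure(
    list(species = data.frame(name = character(0), compartment = character(0),
                              init = numeric(0), stringsAsFactors = FALSE),
         reactions = list(),
         parameters = data.frame(name = character(0), log10 = numeric(0),
                                 lower = numeric(0), upper = numeric(0),
                                 fixed = logical(0), class = character(0),
                                 stringsAsFactors = FALSE),
         derived = list(),
         conserved = list(),
         hog1pp_drive = character(0),
         volume = volume,
         signal_mode = as.integer(signal_mode),
         topology = topology),
    class = "hog_network")
}

add_species <- function(net, name, compartment = "cytosol", init = 0) {
  net$species <- rbind(net$species,
                       data.frame(name = name, compartment = compartment,
                                  init = init, stringsAsFactors = FALSE))
  net
}

add_param <- function(net, name, value, class = "other", fixed = FALSE) {
  b <- param_bounds(class, if (is.null(net$topology)) "unconstrained"
                           else net$topology$bounds)
  net$parameters <- rbind(net$parameters,
                          data.frame(name = name, log10 = log10(value),
                                     lower = b[1], upper = b[2],
                                     fixed = fixed, class = class,
                                     stringsAsFactors = FALSE))
  net
}

## class-wise log10 bounds; the physiological table approximates rate ranges
## of generic yeast kinases/phosphatases and diffusion-limited association
param_bounds <- function(class, mode) {
  if (mode == "physiological") {
    switch(class,
           kinase      = c(-1, 2),
           assoc       = c(-3, 4),
           dissoc      = c(-3, 2),
           phosphatase = c(-1, 2),
           km          = c(-2, 1),
           mult        = c(0, 3),
           transport   = c(-4, 1),
           volume      = c(-8, 1),
           c(-3, 3))
  } else {
    if (class == "volume") c(-8, 1) else c(-3, 3)
  }
}

## reactants / products are named stoichiometry vectors (catalysts appear on
## both sides); `params` is k for mass action, c(kcat, Km) for MM, k for
## signal-driven steps; MM stores the enzyme separately
add_reaction <- function(net, reactants, products, kind = "mass_action",
                         params, enzyme = NULL, tag = NULL) {
  stopifnot(kind %in% c("mass_action", "michaelis_menten", "signal"))
  net$reactions[[length(net$reactions) + 1L]] <-
    list(reactants = reactants, products = products, kind = kind,
         params = params, enzyme = enzyme, tag = tag)
  net
}

r1 <- function(...) { # named stoichiometry shorthand: r1(A = 1, B = 1)
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

#' Stoichiometry matrix of a reaction network
#'
#' Net stoichiometry (products minus reactants), species in rows and
#' reactions in columns; catalysts cancel.
#'
#' @param network a `"hog_network"`.
#' @return numeric matrix with species names as rownames.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  S <- matrix(0, length(sp), length(network$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    for (nm in names(rx$reactants)) S[nm, j] <- S[nm, j] - rx$reactants[[nm]]
    for (nm in names(rx$products))  S[nm, j] <- S[nm, j] + rx$products[[nm]]
  }
  S
}

## resolve derived parameters to a full named linear-scale vector
param_values <- function(network, log10_overrides = NULL) {
  p <- network$parameters
  vals <- 10^p$log10
  names(vals) <- p$name
  if (!is.null(log10_overrides)) {
    bad <- setdiff(names(log10_overrides), p$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals[names(log10_overrides)] <- 10^unlist(log10_overrides)
  }
  for (nm in names(network$derived))
    vals[nm] <- prod(vals[network$derived[[nm]]])
  vals
}

## every parameter name a reaction refers to, base or derived
referenced_params <- function(network) {
  unique(unlist(lapply(network$reactions, function(r) r$params)))
}

#' Construct the overcomplete HOG reaction network for one topology
#'
#' Builds the reaction network carved out by a [hog_topology()]: the Sln1
#' (Sln1 relay -> Ssk1 -> Ssk2) and Sho1 (Sho1/Ste20 -> Ste11) branches
#' converging on Pbs2, the Hog1-Pbs2 binding/phosphorylation machinery
#' dictated by the mechanism, nuclear/cytosolic Hog1 shuttling, the Ptp2
#' (nuclear), Ptp3 (cytosolic) and Ptc (background) phosphatases, the
#' cell-volume module, and the feedback reactions selected by the topology.
#'
#' The distributive mechanism releases mono-phosphorylated Hog1 from the
#' nascent `Pbs2PPHog1P` complex (no immediate second step); rebinding forms
#' `Pbs2PPHog1P_re` from which the second phosphorylation proceeds.  The
#' processive mechanism has no dissociation of the nascent complex and (by
#' default) no rebinding of free mono-phosphorylated Hog1.  The mixed
#' mechanism contains both routes, with rates `k_phospho` (immediate second
#' step) and `k_off` (dissociation).
#'
#' @param topology a [hog_topology()].
#' @return A `"hog_network"`.
#' @export
build_network <- function(topology) {
  stopifnot(inherits(topology, "hog_topology"))
  if (topology$positive_feedback == "none" &&
      length(topology$feedback_components) > 0)
    stop("feedback components named without a positive-feedback target")
  mech <- topology$mechanism
  pf <- topology$positive_feedback
  comps <- topology$feedback_components
  has_cat <- "catalytic" %in% comps
  has_aff <- "affinity" %in% comps
  dist_like <- mech %in% c("distributive", "mixed")
  proc_like <- mech %in% c("processive", "mixed")
  rebind <- dist_like || (mech == "processive" && topology$processive_rebinding)

  net <- new_network(topology = topology, volume = TRUE, signal_mode = 0L)

  ## --- species ---------------------------------------------------------
  net <- add_species(net, "Sln1",  "membrane", 1)
  net <- add_species(net, "Sln1i", "membrane", 0)
  net <- add_species(net, "Ssk1",  "cytosol", 1)
  net <- add_species(net, "Ssk1a", "cytosol", 0)
  net <- add_species(net, "Ssk2",  "cytosol", 1)
  net <- add_species(net, "Ssk2a", "cytosol", 0)
  net <- add_species(net, "Sho1",  "membrane", 1)
  net <- add_species(net, "Sho1a", "membrane", 0)
  net <- add_species(net, "Ste20", "cytosol", 1)
  net <- add_species(net, "Sho1aSte20", "membrane", 0)
  net <- add_species(net, "Ste11", "cytosol", 1)
  net <- add_species(net, "Ste11a", "cytosol", 0)
  net <- add_species(net, "Pbs2",  "cytosol", 1)
  net <- add_species(net, "Pbs2PP", "cytosol", 0)
  net <- add_species(net, "Pbs2Hog1", "cytosol", 0)
  net <- add_species(net, "Pbs2PPHog1",  "cytosol", 0)
  net <- add_species(net, "Pbs2PPHog1P", "cytosol", 0)
  if (rebind) net <- add_species(net, "Pbs2PPHog1P_re", "cytosol", 0)
  pbs2_fb <- pf == "pbs2"
  if (pbs2_fb) {
    net <- add_species(net, "Pbs2PP_feedback", "cytosol", 0)
    net <- add_species(net, "Pbs2PPHog1_feedback",  "cytosol", 0)
    net <- add_species(net, "Pbs2PPHog1P_feedback", "cytosol", 0)
    if (rebind) net <- add_species(net, "Pbs2PPHog1P_re_feedback", "cytosol", 0)
  }
  if (pf == "sln1_and_ste20") net <- add_species(net, "Sln1_feedback", "membrane", 0)
  if (pf == "ssk1_and_ste20") net <- add_species(net, "Ssk1a_feedback", "cytosol", 0)
  if (pf %in% c("sln1_and_ste20", "ssk1_and_ste20")) {
    net <- add_species(net, "Ste20_feedback", "cytosol", 0)
    net <- add_species(net, "Sho1aSte20_feedback", "membrane", 0)
  }
  net <- add_species(net, "Hog1c",  "cytosol", 1)
  net <- add_species(net, "Hog1Pc", "cytosol", 0)
  net <- add_species(net, "Hog1PPc", "cytosol", 0)
  net <- add_species(net, "Hog1n",  "nucleus", 0)
  net <- add_species(net, "Hog1Pn", "nucleus", 0)
  net <- add_species(net, "Hog1PPn", "nucleus", 0)
  net <- add_species(net, "Ptp2", "nucleus", 0.3)
  net <- add_species(net, "Ptp3", "cytosol", 0.3)

  ## --- parameters (defaults form the reference calibration scaffold) ---
  net <- add_param(net, "k_sln1_off", 2,     "kinase")
  net <- add_param(net, "k_sln1_on",  0.05,  "other")
  net <- add_param(net, "k_ssk1_act", 0.1,   "kinase")
  net <- add_param(net, "k_ssk1_deact_sln1", 200, "kinase")
  net <- add_param(net, "k_ssk1_deact0", 0.05, "other")
  net <- add_param(net, "k_ssk2_act", 5,     "kinase")
  net <- add_param(net, "k_ssk2_deact", 0.2, "phosphatase")
  if (topology$negative_feedback)
    net <- add_param(net, "k_nfb", 10, "kinase")
  net <- add_param(net, "k_sho1_act", 0.5,   "kinase")
  net <- add_param(net, "k_sho1_deact", 0.5, "other")
  net <- add_param(net, "kon_ste20", 5,      "assoc")
  net <- add_param(net, "koff_ste20", 0.5,   "dissoc")
  net <- add_param(net, "k_ste11_act", 5,    "kinase")
  net <- add_param(net, "k_ste11_deact", 0.5, "phosphatase")
  net <- add_param(net, "k_pbs2_ssk2", 1.5,  "kinase")
  net <- add_param(net, "k_pbs2_ste11", 1.0, "kinase")
  net <- add_param(net, "Km_pbs2", 0.3, "km")
  net <- add_param(net, "k_pbs2_deact", 1,   "phosphatase")
  if (pf != "none") {
    net <- add_param(net, "k_fb_on", 20,   "kinase")
    net <- add_param(net, "Km_fb", 0.1,    "km")
    net <- add_param(net, "k_fb_off", 0.05, "other")
    if (has_cat) net <- add_param(net, "fb_cat", 15, "mult")
    if (has_aff) net <- add_param(net, "fb_aff", 15, "mult")
  }
  net <- add_param(net, "kon_scaf", 0.1, "assoc")
  net <- add_param(net, "koff_scaf", 1,   "dissoc")
  net <- add_param(net, "kon1", 10,  "assoc")
  net <- add_param(net, "koff0", 1,  "dissoc")
  net <- add_param(net, "kcat1", 2,  "kinase")
  if (proc_like) net <- add_param(net, "k_phospho", 2, "kinase")
  if (dist_like) net <- add_param(net, "k_off", 6, "dissoc")
  if (rebind) {
    net <- add_param(net, "kon2", 10, "assoc")
    net <- add_param(net, "koff2", 1, "dissoc")
    net <- add_param(net, "kcat2", 2, "kinase")
  }
  net <- add_param(net, "kcat_ptp3", 5,  "phosphatase")
  net <- add_param(net, "Km_ptp3", 0.3,  "km")
  net <- add_param(net, "kcat_ptp2", 5,  "phosphatase")
  net <- add_param(net, "Km_ptp2", 0.3,  "km")
  net <- add_param(net, "ptc_c", 0.02,   "phosphatase")
  net <- add_param(net, "ptc_n", 0.02,   "phosphatase")
  net <- add_param(net, "k_imp", 0.05,   "transport")
  net <- add_param(net, "k_exp", 0.1,    "transport")
  net <- add_param(net, "k_imp_pp", 0.5, "transport")
  net <- add_param(net, "k_exp_pp", 0.05, "transport")
  ## volume module (independently parameterised on cell-area data; fixed)
  net <- add_param(net, "vol_kpv", 0.02,    "volume", fixed = TRUE)
  net <- add_param(net, "vol_Pt0", 0.2,     "volume", fixed = TRUE)
  net <- add_param(net, "vol_Vlp", 0.85,    "volume", fixed = TRUE)
  net <- add_param(net, "vol_osmi", 0.4,    "volume", fixed = TRUE)
  net <- add_param(net, "vol_vhog", 1e-3,   "volume", fixed = TRUE)
  net <- add_param(net, "vol_vind", 1.5e-4, "volume", fixed = TRUE)
  net <- add_param(net, "vol_kglyout", 2e-3, "volume", fixed = TRUE)
  net <- add_param(net, "vol_v0gly", 8e-5,  "volume", fixed = TRUE)
  net <- add_param(net, "osm_baseline", 0.25, "volume", fixed = TRUE)

  ## derived feedback-modified rates (products of base rate and multiplier)
  if (pbs2_fb) {
    aff <- if (has_aff) "fb_aff" else character(0)
    cat_ <- if (has_cat) "fb_cat" else character(0)
    net$derived <- c(net$derived, list(
      kon1_fb = c("kon1", aff),
      kcat1_fb = c("kcat1", cat_),
      k_phospho_feed = if (proc_like) c("k_phospho", cat_) else NULL))
    if (rebind)
      net$derived <- c(net$derived,
                       list(kon2_fb = c("kon2", aff),
                            kcat2_fb = c("kcat2", cat_)))
    net$derived <- Filter(Negate(is.null), net$derived)
  }

  ## --- reactions -------------------------------------------------------
  ## Sln1 relay: stress (turgor loss) inactivates Sln1; active Sln1
  ## represses Ssk1 (collapsed histidine relay)
  net <- add_reaction(net, r1(Sln1 = 1), r1(Sln1i = 1), "signal", "k_sln1_off")
  net <- add_reaction(net, r1(Sln1i = 1), r1(Sln1 = 1), "mass_action", "k_sln1_on")
  net <- add_reaction(net, r1(Ssk1 = 1), r1(Ssk1a = 1), "mass_action", "k_ssk1_act")
  net <- add_reaction(net, r1(Ssk1a = 1, Sln1 = 1), r1(Ssk1 = 1, Sln1 = 1),
                      "mass_action", "k_ssk1_deact_sln1")
  net <- add_reaction(net, r1(Ssk1a = 1), r1(Ssk1 = 1), "mass_action", "k_ssk1_deact0")
  net <- add_reaction(net, r1(Ssk2 = 1, Ssk1a = 1), r1(Ssk2a = 1, Ssk1a = 1),
                      "mass_action", "k_ssk2_act")
  net <- add_reaction(net, r1(Ssk2a = 1), r1(Ssk2 = 1), "mass_action", "k_ssk2_deact")
  if (topology$negative_feedback)
    net <- add_reaction(net, r1(Ssk2a = 1, Hog1PPc = 1),
                        r1(Ssk2 = 1, Hog1PPc = 1),
                        "mass_action", "k_nfb", tag = "negative_feedback")

  ## Sho1 branch (Ste50 lumped into the scaffolded activation step)
  net <- add_reaction(net, r1(Sho1 = 1), r1(Sho1a = 1), "signal", "k_sho1_act")
  net <- add_reaction(net, r1(Sho1a = 1), r1(Sho1 = 1), "mass_action", "k_sho1_deact")
  net <- add_reaction(net, r1(Sho1a = 1, Ste20 = 1), r1(Sho1aSte20 = 1),
                      "mass_action", "kon_ste20")
  net <- add_reaction(net, r1(Sho1aSte20 = 1), r1(Sho1a = 1, Ste20 = 1),
                      "mass_action", "koff_ste20")
  net <- add_reaction(net, r1(Ste11 = 1, Sho1aSte20 = 1),
                      r1(Ste11a = 1, Sho1aSte20 = 1),
                      "mass_action", "k_ste11_act")
  net <- add_reaction(net, r1(Ste11a = 1), r1(Ste11 = 1), "mass_action", "k_ste11_deact")

  ## Pbs2 activation by either MAPKKK (enzyme saturated by its substrate,
  ## so active Pbs2 does not scale freely with Pbs2 abundance)
  net <- add_reaction(net, r1(Pbs2 = 1), r1(Pbs2PP = 1),
                      "michaelis_menten", c("k_pbs2_ssk2", "Km_pbs2"),
                      enzyme = "Ssk2a")
  net <- add_reaction(net, r1(Pbs2 = 1), r1(Pbs2PP = 1),
                      "michaelis_menten", c("k_pbs2_ste11", "Km_pbs2"),
                      enzyme = "Ste11a")
  net <- add_reaction(net, r1(Pbs2PP = 1), r1(Pbs2 = 1), "mass_action", "k_pbs2_deact")

  ## positive feedback: Hog1-PP converts the target to a feedback form.
  ## The conversion is Michaelis-Menten in the target (the Hog1 kinase
  ## saturates when Pbs2 is abundant), so overexpressing the target dilutes
  ## the feedback-modified fraction.
  if (pbs2_fb) {
    net <- add_reaction(net, r1(Pbs2PP = 1),
                        r1(Pbs2PP_feedback = 1),
                        "michaelis_menten", c("k_fb_on", "Km_fb"),
                        enzyme = "Hog1PPc", tag = "positive_feedback")
    net <- add_reaction(net, r1(Pbs2PP_feedback = 1), r1(Pbs2PP = 1),
                        "mass_action", "k_fb_off")
    net <- add_reaction(net, r1(Pbs2PP_feedback = 1), r1(Pbs2 = 1),
                        "mass_action", "k_pbs2_deact")
  }

  ## constitutive scaffold binding of Hog1 to unphosphorylated Pbs2
  ## (a catalytically dead reservoir; strong binding titrates Hog1 away
  ## when Pbs2 is in excess)
  net <- add_reaction(net, r1(Pbs2 = 1, Hog1c = 1), r1(Pbs2Hog1 = 1),
                      "mass_action", "kon_scaf")
  net <- add_reaction(net, r1(Pbs2Hog1 = 1), r1(Pbs2 = 1, Hog1c = 1),
                      "mass_action", "koff_scaf")

  ## Hog1-Pbs2 binding and phosphorylation (base scaffold)
  hog_core <- function(net, pbs2, c0, c1, c1r, kon1, kcat1, kph, kon2, kcat2) {
    net <- add_reaction(net, r1_(pbs2, "Hog1c", c0), r1n(c0), "mass_action", kon1)
    net <- add_reaction(net, r1n(c0), r1_(pbs2, "Hog1c", c0), "mass_action", "koff0")
    net <- add_reaction(net, r1n(c0), r1n(c1), "mass_action", kcat1)
    if (proc_like)
      net <- add_reaction(net, r1n(c1), r1b(pbs2, "Hog1PPc"), "mass_action", kph,
                          tag = "immediate_second_step")
    if (dist_like)
      net <- add_reaction(net, r1n(c1), r1b(pbs2, "Hog1Pc"), "mass_action", "k_off",
                          tag = "monophospho_dissociation")
    if (rebind) {
      net <- add_reaction(net, r1b(pbs2, "Hog1Pc"), r1n(c1r), "mass_action", kon2)
      net <- add_reaction(net, r1n(c1r), r1b(pbs2, "Hog1Pc"), "mass_action", "koff2")
      net <- add_reaction(net, r1n(c1r), r1b(pbs2, "Hog1PPc"), "mass_action", kcat2)
    }
    net
  }
  r1_ <- function(pbs2, hog, cplx) stats::setNames(c(1, 1), c(pbs2, hog))
  r1b <- function(pbs2, hog) stats::setNames(c(1, 1), c(pbs2, hog))
  r1n <- function(cplx) stats::setNames(1, cplx)

  net <- hog_core(net, "Pbs2PP", "Pbs2PPHog1", "Pbs2PPHog1P", "Pbs2PPHog1P_re",
                  "kon1", "kcat1", "k_phospho", "kon2", "kcat2")
  if (pbs2_fb)
    net <- hog_core(net, "Pbs2PP_feedback", "Pbs2PPHog1_feedback",
                    "Pbs2PPHog1P_feedback", "Pbs2PPHog1P_re_feedback",
                    "kon1_fb", "kcat1_fb", "k_phospho_feed", "kon2_fb", "kcat2_fb")

  ## alternative positive-feedback targets (used in target-ranking fits)
  if (pf %in% c("sln1_and_ste20", "ssk1_and_ste20")) {
    aff <- if (has_aff) "fb_aff" else character(0)
    cat_ <- if (has_cat) "fb_cat" else character(0)
    net$derived <- c(net$derived, list(
      kon_ste20_fb = c("kon_ste20", aff),
      k_ste11_act_fb = c("k_ste11_act", cat_)))
    net <- add_reaction(net, r1(Ste20 = 1, Hog1PPc = 1),
                        r1(Ste20_feedback = 1, Hog1PPc = 1),
                        "mass_action", "k_fb_on", tag = "positive_feedback")
    net <- add_reaction(net, r1(Ste20_feedback = 1), r1(Ste20 = 1),
                        "mass_action", "k_fb_off")
    net <- add_reaction(net, r1(Sho1a = 1, Ste20_feedback = 1),
                        r1(Sho1aSte20_feedback = 1), "mass_action", "kon_ste20_fb")
    net <- add_reaction(net, r1(Sho1aSte20_feedback = 1),
                        r1(Sho1a = 1, Ste20_feedback = 1),
                        "mass_action", "koff_ste20")
    net <- add_reaction(net, r1(Ste11 = 1, Sho1aSte20_feedback = 1),
                        r1(Ste11a = 1, Sho1aSte20_feedback = 1),
                        "mass_action", "k_ste11_act_fb")
    if (pf == "sln1_and_ste20") {
      ## feedback weakens the repressive Sln1 relay
      net <- add_param(net, "k_ssk1_deact_sln1_red", 10, "kinase")
      net <- add_reaction(net, r1(Sln1 = 1, Hog1PPc = 1),
                          r1(Sln1_feedback = 1, Hog1PPc = 1),
                          "mass_action", "k_fb_on", tag = "positive_feedback")
      net <- add_reaction(net, r1(Sln1_feedback = 1), r1(Sln1 = 1),
                          "mass_action", "k_fb_off")
      net <- add_reaction(net, r1(Sln1_feedback = 1), r1(Sln1i = 1),
                          "signal", "k_sln1_off")
      net <- add_reaction(net, r1(Ssk1a = 1, Sln1_feedback = 1),
                          r1(Ssk1 = 1, Sln1_feedback = 1),
                          "mass_action", "k_ssk1_deact_sln1_red")
    } else {
      net$derived <- c(net$derived, list(k_ssk2_act_fb = c("k_ssk2_act", cat_)))
      net <- add_reaction(net, r1(Ssk1a = 1, Hog1PPc = 1),
                          r1(Ssk1a_feedback = 1, Hog1PPc = 1),
                          "mass_action", "k_fb_on", tag = "positive_feedback")
      net <- add_reaction(net, r1(Ssk1a_feedback = 1), r1(Ssk1a = 1),
                          "mass_action", "k_fb_off")
      net <- add_reaction(net, r1(Ssk2 = 1, Ssk1a_feedback = 1),
                          r1(Ssk2a = 1, Ssk1a_feedback = 1),
                          "mass_action", "k_ssk2_act_fb")
      net <- add_reaction(net, r1(Ssk1a_feedback = 1), r1(Ssk1 = 1),
                          "mass_action", "k_ssk1_deact0")
    }
  }

  ## phosphatases: Ptp3 cytosolic, Ptp2 nuclear (MM), Ptc background
  net <- add_reaction(net, r1(Hog1PPc = 1), r1(Hog1Pc = 1), "michaelis_menten",
                      c("kcat_ptp3", "Km_ptp3"), enzyme = "Ptp3")
  net <- add_reaction(net, r1(Hog1Pc = 1), r1(Hog1c = 1), "michaelis_menten",
                      c("kcat_ptp3", "Km_ptp3"), enzyme = "Ptp3")
  net <- add_reaction(net, r1(Hog1PPc = 1), r1(Hog1Pc = 1), "mass_action", "ptc_c")
  net <- add_reaction(net, r1(Hog1Pc = 1), r1(Hog1c = 1), "mass_action", "ptc_c")
  net <- add_reaction(net, r1(Hog1PPn = 1), r1(Hog1Pn = 1), "michaelis_menten",
                      c("kcat_ptp2", "Km_ptp2"), enzyme = "Ptp2")
  net <- add_reaction(net, r1(Hog1Pn = 1), r1(Hog1n = 1), "michaelis_menten",
                      c("kcat_ptp2", "Km_ptp2"), enzyme = "Ptp2")
  net <- add_reaction(net, r1(Hog1PPn = 1), r1(Hog1Pn = 1), "mass_action", "ptc_n")
  net <- add_reaction(net, r1(Hog1Pn = 1), r1(Hog1n = 1), "mass_action", "ptc_n")

  ## nucleocytoplasmic shuttling (Hog1-PP import faster than unphosphorylated)
  net <- add_reaction(net, r1(Hog1c = 1), r1(Hog1n = 1), "mass_action", "k_imp")
  net <- add_reaction(net, r1(Hog1n = 1), r1(Hog1c = 1), "mass_action", "k_exp")
  net <- add_reaction(net, r1(Hog1Pc = 1), r1(Hog1Pn = 1), "mass_action", "k_imp")
  net <- add_reaction(net, r1(Hog1Pn = 1), r1(Hog1Pc = 1), "mass_action", "k_exp")
  net <- add_reaction(net, r1(Hog1PPc = 1), r1(Hog1PPn = 1), "mass_action", "k_imp_pp")
  net <- add_reaction(net, r1(Hog1PPn = 1), r1(Hog1PPc = 1), "mass_action", "k_exp_pp")

  ## conserved totals
  sp <- net$species$name
  memb <- function(pat) sp[grepl(pat, sp)]
  cplx <- sp[grepl("^Pbs2(PP)?Hog1", sp)]
  net$conserved <- list(
    Hog1 = unique(c(sp[grepl("^Hog1", sp)], cplx)),
    Pbs2 = unique(c(sp[grepl("^Pbs2($|PP)", sp)], cplx)),
    Ssk2 = c("Ssk2", "Ssk2a"),
    Sln1 = sp[grepl("^Sln1", sp)],
    Ssk1 = sp[grepl("^Ssk1", sp)],
    Sho1 = sp[grepl("^Sho1", sp)],
    Ste20 = sp[grepl("Ste20", sp)],
    Ste11 = c("Ste11", "Ste11a"),
    Ptp2 = "Ptp2",
    Ptp3 = "Ptp3")
  net$hog1pp_drive <- c("Hog1PPc", "Hog1PPn")

  check_network(net)
  net
}

## structural sanity: every referenced parameter resolvable exactly once
check_network <- function(net) {
  refs <- referenced_params(net)
  known <- c(net$parameters$name, names(net$derived))
  if (any(duplicated(net$parameters$name)))
    stop("duplicate parameter definitions: ",
         paste(unique(net$parameters$name[duplicated(net$parameters$name)]),
               collapse = ", "))
  missing <- setdiff(refs, known)
  if (length(missing))
    stop("reactions reference undefined parameter(s): ",
         paste(missing, collapse = ", "))
  spn <- net$species$name
  for (rx in net$reactions) {
    bad <- setdiff(c(names(rx$reactants), names(rx$products), rx$enzyme), spn)
    if (length(bad))
      stop("reaction references unknown species: ", paste(bad, collapse = ", "))
  }
  invisible(net)
}

#' @export
print.hog_network <- function(x, ...) {
  cat("HOG reaction network:", nrow(x$species), "species,",
      length(x$reactions), "reactions,", nrow(x$parameters), "parameters\n")
  if (!is.null(x$topology)) cat("  topology:", format(x$topology), "\n")
  if (!is.null(x$strain)) cat("  strain:  ", format(x$strain), "\n")
  cat("  volume module:", if (x$volume) "on" else "off", "\n")
  invisible(x)
}

#' Apply a strain specification to a network
#'
#' Gene deletions zero the protein's conserved total; overexpression
#' multiplies initial totals; `S248A` removes the affinity component of the
#' Pbs2 feedback (sets the affinity multiplier to 1, catalytic component
#' untouched); `S248E` fixes the Hog1-association parameters at their
#' feedback-modified values from the start; Hog1 inhibition zeroes all
#' Hog1-catalysed rates while leaving binding and Hog1's own phosphorylation
#' intact; `ssk2_feedback_dead` removes the negative-feedback reaction.
#' Returns a new network; the input is unchanged.
#'
#' @param network a `"hog_network"`.
#' @param strain a [hog_strain()].
#' @return A modified `"hog_network"` with the strain recorded.
#' @export
apply_strain <- function(network, strain) {
  stopifnot(inherits(network, "hog_network"), inherits(strain, "hog_strain"))
  net <- network
  del_map <- c(PBS2 = "Pbs2", SLN1 = "Sln1", SHO1 = "Sho1", SSK2 = "Ssk2",
               PTP2 = "Ptp2", PTP3 = "Ptp3")
  for (d in strain$deletions) {
    prot <- del_map[[d]]
    if (is.null(net$conserved[[prot]]))
      stop("cannot delete ", d, ": protein absent from the network")
    net$species$init[net$species$name %in% net$conserved[[prot]]] <- 0
  }
  for (prot in names(strain$overexpression)) {
    if (is.null(net$conserved[[prot]]))
      stop("cannot overexpress ", prot, ": protein absent from the network")
    memb <- net$conserved[[prot]]
    net$species$init[net$species$name %in% memb] <-
      net$species$init[net$species$name %in% memb] * strain$overexpression[[prot]]
  }
  set_par <- function(net, name, log10val, fix = TRUE) {
    i <- match(name, net$parameters$name)
    if (!is.na(i)) {
      net$parameters$log10[i] <- log10val
      if (fix) net$parameters$fixed[i] <- TRUE
    }
    net
  }
  if (strain$pbs2_s248 == "S248A") {
    ## affinity feedback abolished: multiplier collapses to 1
    net <- set_par(net, "fb_aff", 0)
  } else if (strain$pbs2_s248 == "S248E") {
    ## phosphomimetic: Pbs2 is constitutively in the S248-phosphorylated
    ## (feedback-modified) state, so Hog1-association parameters sit at
    ## their feedback values from the start: the Hog1-PP-dependent
    ## conversion is replaced by a fast constitutive one
    is_conv <- vapply(net$reactions, function(r)
      identical(r$tag, "positive_feedback") &&
        "Pbs2PP" %in% names(r$reactants), TRUE)
    if (any(is_conv)) {
      net <- add_param(net, "k_s248e_conv", 100, "other", fixed = TRUE)
      j <- which(is_conv)[1]
      net$reactions[[j]] <- list(reactants = c(Pbs2PP = 1),
                                 products = c(Pbs2PP_feedback = 1),
                                 kind = "mass_action",
                                 params = "k_s248e_conv",
                                 enzyme = NULL, tag = "positive_feedback")
    }
  }
  if (strain$hog1_inhibited) {
    for (nm in intersect(c("k_fb_on", "k_nfb"), net$parameters$name))
      net <- set_par(net, nm, -30)
    net <- set_par(net, "vol_vhog", -30)
  }
  if (strain$ssk2_feedback_dead) {
    keep <- vapply(net$reactions,
                   function(r) !identical(r$tag, "negative_feedback"), TRUE)
    net$reactions <- net$reactions[keep]
  }
  net$strain <- strain
  check_network(net)
  net
}

#' Build a basic three-tiered MAPK cascade
#'
#' A Huang-Ferrell-style MAPKKK -> MAPKK -> MAPK cascade with dual
#' phosphorylation at the lower two tiers, a phosphatase at each tier and no
#' feedback.  The MAPK tier uses the requested dual-phosphorylation
#' mechanism; the input acts directly on MAPKKK activation (no volume
#' module).
#'
#' @param mechanism `"distributive"` or `"processive"`.
#' @return A `"hog_network"` (volume module off; the stimulus protocol value
#'   is the cascade input `u`).
#' @export
build_basic_cascade <- function(mechanism = c("distributive", "processive")) {
  mechanism <- match.arg(mechanism)
  dist <- mechanism == "distributive"
  net <- new_network(topology = NULL, volume = FALSE, signal_mode = 1L)

  for (s in c("KKK", "KK", "K")) net <- add_species(net, s, "cytosol", 1)
  for (s in c("KKKa", "KKp", "KKpp", "Kp", "Kpp", "KKppK", "KKppKp"))
    net <- add_species(net, s, "cytosol", 0)
  if (dist) net <- add_species(net, "KKppKp_re", "cytosol", 0)

  defaults <- c(k1 = 1, d1 = 0.25, a2 = 1, a2b = 1, d2 = 0.3, d2b = 0.3,
                kon1 = 5, koff0 = 1, kcat1 = 3, p3 = 0.3, p3b = 0.3)
  for (nm in names(defaults)) net <- add_param(net, nm, defaults[[nm]])
  if (!dist) net <- add_param(net, "k_phospho", 3)
  if (dist) {
    net <- add_param(net, "k_off", 3)
    net <- add_param(net, "kon2", 5)
    net <- add_param(net, "koff2", 1)
    net <- add_param(net, "kcat2", 3)
  }

  net <- add_reaction(net, r1(KKK = 1), r1(KKKa = 1), "signal", "k1")
  net <- add_reaction(net, r1(KKKa = 1), r1(KKK = 1), "mass_action", "d1")
  net <- add_reaction(net, r1(KK = 1, KKKa = 1), r1(KKp = 1, KKKa = 1),
                      "mass_action", "a2")
  net <- add_reaction(net, r1(KKp = 1, KKKa = 1), r1(KKpp = 1, KKKa = 1),
                      "mass_action", "a2b")
  net <- add_reaction(net, r1(KKp = 1), r1(KK = 1), "mass_action", "d2")
  net <- add_reaction(net, r1(KKpp = 1), r1(KKp = 1), "mass_action", "d2b")
  net <- add_reaction(net, r1(KKpp = 1, K = 1), r1(KKppK = 1), "mass_action", "kon1")
  net <- add_reaction(net, r1(KKppK = 1), r1(KKpp = 1, K = 1), "mass_action", "koff0")
  net <- add_reaction(net, r1(KKppK = 1), r1(KKppKp = 1), "mass_action", "kcat1")
  if (!dist)
    net <- add_reaction(net, r1(KKppKp = 1), r1(Kpp = 1, KKpp = 1),
                        "mass_action", "k_phospho", tag = "immediate_second_step")
  if (dist) {
    net <- add_reaction(net, r1(KKppKp = 1), r1(KKpp = 1, Kp = 1),
                        "mass_action", "k_off", tag = "monophospho_dissociation")
    net <- add_reaction(net, r1(KKpp = 1, Kp = 1), r1(KKppKp_re = 1),
                        "mass_action", "kon2")
    net <- add_reaction(net, r1(KKppKp_re = 1), r1(KKpp = 1, Kp = 1),
                        "mass_action", "koff2")
    net <- add_reaction(net, r1(KKppKp_re = 1), r1(Kpp = 1, KKpp = 1),
                        "mass_action", "kcat2")
  }
  net <- add_reaction(net, r1(Kpp = 1), r1(Kp = 1), "mass_action", "p3")
  net <- add_reaction(net, r1(Kp = 1), r1(K = 1), "mass_action", "p3b")

  sp <- net$species$name
  net$conserved <- list(
    KKK = c("KKK", "KKKa"),
    KK = c("KK", "KKp", "KKpp", sp[grepl("^KKppK", sp)]),
    K = c("K", "Kp", "Kpp", sp[grepl("^KKppK", sp)]))
  net$mechanism <- mechanism
  check_network(net)
  net
}

#' Export a network as a plain-text reaction table
#'
#' One reaction per line: reactants, products, rate-law kind and parameter
#' names, tab-separated.
#'
#' @param network a `"hog_network"`.
#' @param path file path, or `""` to return the lines invisibly.
#' @return Invisibly, the character vector of lines.
#' @export
write_reaction_table <- function(network, path = "") {
  side <- function(v) {
    if (!length(v)) return("0")
    paste(ifelse(v == 1, names(v), paste0(v, " ", names(v))), collapse = " + ")
  }
  lines <- vapply(network$reactions, function(rx) {
    paste(side(rx$reactants), "->", side(rx$products),
          paste0("[", rx$kind,
                 if (!is.null(rx$enzyme)) paste0(" enzyme=", rx$enzyme) else "",
                 "]"),
          paste(rx$params, collapse = ","), sep = "\t")
  }, character(1))
  header <- "reactants\t->\tproducts\trate_law\tparameters"
  out <- c(header, lines)
  if (nzchar(path)) writeLines(out, path)
  invisible(out)
}
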