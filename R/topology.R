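#' Define a HOG-pathway submodel topology
#'
#' A topology is a switchboard selecting one submodel of the overcomplete
#' HOG reaction network: the Hog1 dual-phosphorylation mechanism, the target
#' and components of the Hog1-dependent positive feedback, the presence of
#' negative feedback on Ssk2, and the parameter-bounds mode used in fitting.
#'
#' @param mechanism Hog1 phosphorylation mechanism. `"distributive"`: Hog1
#'   dissociates from Pbs2 after every phosphorylation step and must rebind
#'   for the second one; `"processive"`: the second step immediately follows
#'   the first without dissociation; `"mixed"`: both routes coexist, with
#'   rate constants `k_phospho` (immediate second step) and `k_off`
#'   (dissociation) setting the effective processivity.
#' @param positive_feedback target of the Hog1-PP-dependent positive
#'   feedback: `"pbs2"`, `"sln1_and_ste20"`, `"ssk1_and_ste20"` or `"none"`.
#' @param feedback_components character subset of
#'   `c("catalytic", "affinity")`; must be empty when
#'   `positive_feedback = "none"`.
#' @param negative_feedback logical; Hog1-PP-dependent deactivation of Ssk2.
#' @param bounds `"unconstrained"` (log10 bounds -3..3 for all kinetic
#'   parameters) or `"physiological"` (class-wise bounds for kinase,
#'   phosphatase and association rates).
#' @param processive_rebinding logical; whether a purely processive variant
#'   permits rebinding of free mono-phosphorylated Hog1 to Pbs2.  Default
#'   `FALSE` (de novo binding of unphosphorylated Hog1 only), recorded in
#'   the object.
#' @return An object of class `"hog_topology"`.
#' @seealso [enumerate_topologies()], [build_network()]
#' @export
hog_topology <- function(mechanism = c("mixed", "distributive", "processive"),
                         positive_feedback = c("pbs2", "none",
                                               "sln1_and_ste20",
                                               "ssk1_and_ste20"),
                         feedback_components = c("catalytic", "affinity"),
                         negative_feedback = TRUE,
                         bounds = c("unconstrained", "physiological"),
                         processive_rebinding = FALSE) {
  mechanism <- match.arg(mechanism)
  positive_feedback <- match.arg(positive_feedback)
  bounds <- match.arg(bounds)
  if (positive_feedback == "none") {
    if (!missing(feedback_components) && length(feedback_components) > 0)
      stop("feedback_components must be empty when positive_feedback is \"none\"")
    feedback_components <- character(0)
  } else {
    feedback_components <- match.arg(feedback_components, several.ok = TRUE)
  }
  stopifnot(is.logical(negative_feedback), length(negative_feedback) == 1L)
  structure(
    list(mechanism = mechanism,
         positive_feedback = positive_feedback,
         feedback_components = sort(feedback_components),
         negative_feedback = isTRUE(negative_feedback),
         bounds = bounds,
         processive_rebinding = isTRUE(processive_rebinding)),
    class = "hog_topology")
}

#' @export
format.hog_topology <- function(x, ...) {
  fb <- if (x$positive_feedback == "none") "no positive feedback"
        else sprintf("positive feedback on %s (%s)", x$positive_feedback,
                     paste(x$feedback_components, collapse = "+"))
  sprintf("%s | %s | negative feedback %s | %s bounds",
          x$mechanism, fb, if (x$negative_feedback) "on" else "off", x$bounds)
}

#' @export
print.hog_topology <- function(x, ...) {
  cat("HOG submodel topology:", format(x), "\n")
  invisible(x)
}

#' Enumerate the canonical submodel topologies
#'
#' Returns the canonical enumeration of submodels of the overcomplete HOG
#' model: the eight combinations of \{distributive, processive\} mechanism,
#' positive feedback on Pbs2 (with both catalytic and affinity components)
#' or none, and negative feedback on Ssk2 on or off.  With
#' `include_mixed = TRUE` the four mixed-mechanism combinations are added.
#'
#' @param include_mixed logical; also return mixed-mechanism variants.
#' @param bounds bounds mode applied to every configuration.
#' @return A list of [hog_topology()] objects (8, or 12 with mixed).
#' @export
enumerate_topologies <- function(include_mixed = FALSE,
                                 bounds = "unconstrained") {
  mechs <- c("distributive", "processive")
  if (include_mixed) mechs <- c(mechs, "mixed")
  out <- list()
  for (m in mechs) {
    for (pf in c("pbs2", "none")) {
      for (nf in c(TRUE, FALSE)) {
        out[[length(out) + 1L]] <-
          if (pf == "none")
            hog_topology(m, "none", negative_feedback = nf, bounds = bounds)
          else
            hog_topology(m, pf, c("catalytic", "affinity"),
                         negative_feedback = nf, bounds = bounds)
      }
    }
  }
  out
}

#' Specify a yeast strain (genetic background) for simulation
#'
#' @param deletions character vector of deleted genes, a subset of
#'   `c("PBS2", "SLN1", "SHO1", "SSK2", "PTP2", "PTP3")`.
#' @param pbs2_s248 Pbs2 serine-248 allele: wild type (`"wt"`),
#'   non-phosphorylatable (`"S248A"`, removes the affinity component of the
#'   positive feedback) or phosphomimetic (`"S248E"`, Hog1-association
#'   parameters fixed at their feedback-modified values).
#' @param ssk2_feedback_dead logical; remove the negative-feedback reaction
#'   (non-phosphorylatable Ssk2 feedback site).
#' @param hog1_inhibited logical; ATP-analog inhibition of Hog1 kinase
#'   activity: all Hog1-catalysed (feedback and glycerol-production) rates
#'   are zeroed while Hog1 binding and its own phosphorylation are intact.
#' @param overexpression named numeric vector of positive factors applied to
#'   initial protein totals, e.g. `c(Pbs2 = 10)`.
#' @return An object of class `"hog_strain"`.
#' @export
hog_strain <- function(deletions = character(0),
                       pbs2_s248 = c("wt", "S248A", "S248E"),
                       ssk2_feedback_dead = FALSE,
                       hog1_inhibited = FALSE,
                       overexpression = numeric(0)) {
  pbs2_s248 <- match.arg(pbs2_s248)
  allowed <- c("PBS2", "SLN1", "SHO1", "SSK2", "PTP2", "PTP3")
  deletions <- toupper(as.character(deletions))
  if (length(deletions) && !all(deletions %in% allowed))
    stop("unknown deletion(s): ",
         paste(setdiff(deletions, allowed), collapse = ", "))
  if (length(overexpression)) {
    if (is.null(names(overexpression)) || any(!nzchar(names(overexpression))))
      stop("overexpression must be a named vector")
    if (any(overexpression <= 0))
      stop("overexpression factors must be > 0")
  }
  structure(
    list(deletions = unique(deletions),
         pbs2_s248 = pbs2_s248,
         ssk2_feedback_dead = isTRUE(ssk2_feedback_dead),
         hog1_inhibited = isTRUE(hog1_inhibited),
         overexpression = overexpression),
    class = "hog_strain")
}

#' @export
format.hog_strain <- function(x, ...) {
  parts <- character(0)
  if (length(x$deletions))
    parts <- c(parts, paste0(tolower(x$deletions), "Δ"))
  if (x$pbs2_s248 != "wt") parts <- c(parts, paste0("pbs2-", x$pbs2_s248))
  if (x$ssk2_feedback_dead) parts <- c(parts, "ssk2-feedback-dead")
  if (x$hog1_inhibited) parts <- c(parts, "Hog1-inhibited")
  if (length(x$overexpression))
    parts <- c(parts, paste0(names(x$overexpression), "x",
                             x$overexpression, collapse = " "))
  if (!length(parts)) "wild type" else paste(parts, collapse = " ")
}

#' @export
print.hog_strain <- function(x, ...) {
  cat("Strain:", format(x), "\n")
  invisible(x)
}
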