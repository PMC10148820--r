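## Dataset TSV dialect
##
## Columns: dataset_id, strain, protocol_id, modality, time_s, value,
## sigma, error_class, use (fit|test); unknown extra columns are preserved.
## Numeric fields are written with 17 significant digits so that a
## write/read round trip is value-exact.

DATASET_COLUMNS <- c("dataset_id", "strain", "protocol_id", "modality",
                     "time_s", "value", "sigma", "error_class", "use")

#' Validate a dataset data frame
#'
#' Checks the column contract of the dataset dialect; violations are
#' reported with row numbers.
#'
#' @param dataset data frame.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_dataset <- function(dataset) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0)
    stop("empty dataset")
  missing <- setdiff(DATASET_COLUMNS, colnames(dataset))
  if (length(missing))
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(dataset$sigma) | dataset$sigma <= 0)
  if (length(bad))
    stop("sigma must be > 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!dataset$use %in% c("fit", "test"))
  if (length(bad))
    stop("use must be \"fit\" or \"test\"; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(dataset$time_s))
  if (length(bad))
    stop("non-finite time_s; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Read a dataset TSV
#'
#' @param path file path.
#' @return Validated dataset data frame (extra columns preserved).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty dataset file: ", path)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_dataset(d)
  d
}

#' Write a dataset TSV
#'
#' Numeric columns are serialised with 17 significant digits for an exact
#' round trip.
#'
#' @param dataset dataset data frame.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  d <- dataset
  for (cl in colnames(d))
    if (is.numeric(d[[cl]]))
      d[[cl]] <- formatC(d[[cl]], digits = 17, format = "g")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------
## configuration round trip (YAML or JSON by extension)

#' Write a topology (+ optional strain) configuration file
#'
#' @param topology a [hog_topology()].
#' @param path `.yaml`/`.yml` or `.json` path.
#' @param strain optional [hog_strain()].
#' @return Invisibly, `path`.
#' @export
write_topology_config <- function(topology, path, strain = NULL) {
  cfg <- list(mechanism = topology$mechanism,
              positive_feedback_target = topology$positive_feedback,
              feedback_components = as.list(topology$feedback_components),
              negative_feedback_ssk2 = topology$negative_feedback,
              bounds_mode = topology$bounds)
  if (!is.null(strain))
    cfg$strain <- list(deletions = as.list(strain$deletions),
                       pbs2_s248 = strain$pbs2_s248,
                       ssk2_feedback_dead = strain$ssk2_feedback_dead,
                       hog1_inhibited = strain$hog1_inhibited,
                       overexpression = as.list(strain$overexpression))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a topology configuration file
#'
#' @param path `.yaml`/`.yml` or `.json` file written by
#'   [write_topology_config()].
#' @return List with `topology` ([hog_topology()]) and `strain`
#'   ([hog_strain()] or `NULL`).
#' @export
read_topology_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("mechanism", "positive_feedback_target", "negative_feedback_ssk2")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config lacks field(s): ", paste(missing, collapse = ", "))
  topo <- hog_topology(
    mechanism = cfg$mechanism,
    positive_feedback = cfg$positive_feedback_target,
    feedback_components = unlist(cfg$feedback_components),
    negative_feedback = isTRUE(cfg$negative_feedback_ssk2),
    bounds = cfg$bounds_mode %||% "unconstrained")
  strain <- NULL
  if (!is.null(cfg$strain)) {
    s <- cfg$strain
    ov <- unlist(s$overexpression)
    strain <- hog_strain(
      deletions = unlist(s$deletions) %||% character(0),
      pbs2_s248 = s$pbs2_s248 %||% "wt",
      ssk2_feedback_dead = isTRUE(s$ssk2_feedback_dead),
      hog1_inhibited = isTRUE(s$hog1_inhibited),
      overexpression = if (is.null(ov)) numeric(0) else ov)
  }
  list(topology = topo, strain = strain)
}

## small deterministic string hash (FNV-1a, 32 bit) for run manifests
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Write a results artifact with a reproducibility manifest
#'
#' Serialises the artifact to JSON together with a machine-readable
#' manifest (configuration hash, seed, package version) sufficient to
#' regenerate it; the output contains no timestamps, so identical inputs
#' give byte-identical files.
#'
#' @param path output `.json` path.
#' @param artifact a JSON-serialisable list/data frame.
#' @param config the configuration object the artifact was produced from.
#' @param seed the seed used.
#' @return Invisibly, `path`.
#' @export
write_results <- function(path, artifact, config = NULL, seed = NULL) {
  out <- list(
    manifest = list(config_hash = config_hash(config),
                    seed = seed,
                    package = "hogmix",
                    version = as.character(utils::packageVersion("hogmix"))),
    results = artifact)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialise a fit to JSON
#'
#' Parameters as a name -> log10 value map plus goodness of fit, k, AIC
#' and the per-round history.
#'
#' @param fit a `"hog_fit"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  art <- list(topology = format(fit$topology),
              parameters_log10 = as.list(coef(fit)),
              goodness_of_fit = fit$value,
              k = fit$k, aic = fit$aic,
              history = fit$history, rounds = fit$rounds,
              n_points = fit$n_points)
  write_results(path, art, config = fit$topology, seed = fit$seed)
}
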