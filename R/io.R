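# Configuration loading and result serialisation.

#' Load a model configuration
#'
#' Resolves a parameter set from three layers, in increasing precedence:
#' the packaged defaults ([sleep_params()]), a flat `key: value` YAML file,
#' and programmatic/CLI overrides. Pathway weights use the keys `g_RRe`,
#' `g_RWe`, `g_WNi`, `g_WRi`, `g_NRi`, `g_NWi`. Unknown keys and
#' sign-convention violations are rejected with a message naming the key.
#'
#' @param path path to a YAML config file, or `NULL` for defaults only. An
#'   empty file resolves to the packaged defaults.
#' @param overrides named list (or named numeric vector) of final overrides.
#' @return A validated [sleep_params()] object.
#' @examples
#' cfg <- system.file("extdata", "default_config.yaml", package = "sleepnet")
#' p <- load_config(cfg, overrides = list(g_WNi = -4))
#' p$weights[["WNi"]]
#' @export
load_config <- function(path = NULL, overrides = list()) {
  p <- sleep_params()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- modifyList(vals, as.list(overrides))
  scalar_fields <- setdiff(param_field_names(), "weights")
  for (key in names(vals)) {
    v <- vals[[key]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("config key '", key, "' must be a single number", call. = FALSE)
    if (key %in% scalar_fields) {
      p[[key]] <- as.numeric(v)
    } else if (grepl("^g_", key) && sub("^g_", "", key) %in% PATHWAYS) {
      p$weights[sub("^g_", "", key)] <- as.numeric(v)
    } else {
      stop("unknown config key '", key, "'", call. = FALSE)
    }
  }
  validate_params(p)
}

#' Write a resolved configuration to YAML
#'
#' Flat `key: value` rendering (weights as `g_<pathway>`), readable by
#' [load_config()].
#'
#' @param p a [sleep_params()] object.
#' @param path output file.
#' @export
write_config <- function(p, path) {
  yaml::write_yaml(params_to_flat(p), path)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record written alongside results: resolved-config digest,
#' seeds, package version, RNG algorithm, timestamp and output paths.
#'
#' @param params a [sleep_params()] object.
#' @param seeds integer seeds used (may be `NA` for noise-free runs).
#' @param outputs named character vector of files the bundle contains.
#' @return Named list of class `"run_manifest"`.
#' @export
run_manifest <- function(params, seeds = NA_integer_, outputs = character(0)) {
  structure(list(
    config_digest = config_digest(params),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("sleepnet")),
    rng = paste(RNGkind(), collapse = "/"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  ), class = "run_manifest")
}

#' Write a results bundle
#'
#' Deterministic file layout under `dir`: `manifest.json` (always),
#' `config.yaml`, plus whichever of `timeseries.tsv`, `hypnogram_<i>.csv`,
#' `metrics.csv` and `stats.csv` were supplied. Re-running with identical
#' inputs reproduces every non-manifest byte (timestamps live only in the
#' manifest).
#'
#' @param dir output directory (created if needed).
#' @param params resolved [sleep_params()].
#' @param timeseries optional `"sleep_sim"`.
#' @param hypnograms optional list of [hypnogram()]s.
#' @param metrics optional metrics data.frame.
#' @param stats optional data.frame of statistics rows.
#' @param seeds seeds to record in the manifest.
#' @return The manifest, invisibly.
#' @export
write_results_bundle <- function(dir, params, timeseries = NULL,
                                 hypnograms = NULL, metrics = NULL,
                                 stats = NULL, seeds = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- c(config = "config.yaml")
  write_config(params, file.path(dir, "config.yaml"))
  if (!is.null(timeseries)) {
    write_timeseries(timeseries, file.path(dir, "timeseries.tsv"))
    outputs["timeseries"] <- "timeseries.tsv"
  }
  if (!is.null(hypnograms)) {
    for (i in seq_along(hypnograms)) {
      f <- sprintf("hypnogram_%d.csv", i)
      write_hypnogram(hypnograms[[i]], file.path(dir, f))
      outputs[paste0("hypnogram_", i)] <- f
    }
  }
  if (!is.null(metrics)) {
    write_metrics(metrics, file.path(dir, "metrics.csv"))
    outputs["metrics"] <- "metrics.csv"
  }
  if (!is.null(stats)) {
    write.csv(stats, file.path(dir, "stats.csv"), row.names = FALSE)
    outputs["stats"] <- "stats.csv"
  }
  man <- run_manifest(params, seeds = seeds, outputs = outputs)
  jsonlite::write_json(unclass(man), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}
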