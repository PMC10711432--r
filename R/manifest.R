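# Run manifests: enough metadata to reproduce any output byte-identically.

write_manifest <- function(path, kind, seed, config, outputs) {
  config_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(as.character(config_json), tf)
  manifest <- list(
    package = "dpcrepair",
    package_version = as.character(packageVersion("dpcrepair")),
    kind = kind,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tf)),
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  unlink(tf)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a seeded simulation and write its Ct table plus manifest
#'
#' Generates the Ct table for every scenario of a resolved configuration
#' under the configuration's master seed, writes it as CSV, and writes a run
#' manifest (package version, seed, full resolved configuration, MD5
#' checksums of the outputs) sufficient to reproduce the run byte-identically
#' via [reproduce_run()].
#'
#' @param config A resolved configuration from [load_config()], or a path /
#'   built-in name that will be passed to it.
#' @param out Output CSV path.
#' @param manifest Manifest path (default `<out>.manifest.json`).
#' @param seed Optional seed overriding the configuration's.
#' @param stochastic Passed to [generate_scenario_dataset()].
#' @return Invisibly, the manifest path.
#' @export
run_simulation <- function(config, out,
                           manifest = paste0(out, ".manifest.json"),
                           seed = NULL, stochastic = TRUE) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!length(config$scenarios)) stop("configuration has no scenarios", call. = FALSE)
  tabs <- lapply(config$scenarios, generate_scenario_dataset,
                 seed = config$seed, stochastic = stochastic)
  write_ct_table(do.call(rbind, tabs), out)
  write_manifest(manifest, kind = "simulate", seed = config$seed,
                 config = list(
                   seed = config$seed,
                   stochastic = stochastic,
                   scenarios = lapply(config$scenarios, scenario_to_list)),
                 outputs = out)
  invisible(manifest)
}

#' Reproduce a simulation from its manifest
#'
#' Re-runs the simulation described by a run manifest (using the embedded
#' resolved configuration and seed) into a scratch directory and compares the
#' MD5 checksum of every regenerated output with the one recorded at run
#' time.
#'
#' @param manifest_path Path to a manifest written by [run_simulation()].
#' @param workdir Directory for the regenerated outputs.
#' @return Logical: `TRUE` if every output is byte-identical, with a
#'   `comparison` data-frame attribute.
#' @export
reproduce_run <- function(manifest_path, workdir = tempfile("reproduce")) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(m$kind, "simulate")) {
    stop("can only reproduce 'simulate' manifests", call. = FALSE)
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- lapply(m$config$scenarios, function(lst) {
    lst$timepoints <- as.numeric(unlist(lst$timepoints))
    lst$assays <- as.character(unlist(lst$assays))
    lst$antibodies <- as.character(unlist(lst$antibodies))
    scenario_from_list(lst, where = "manifest scenario")
  })
  cfg <- list(seed = as.integer(m$seed), panels = character(),
              scenarios = scenarios)
  comparisons <- do.call(rbind, lapply(m$outputs, function(o) {
    new_path <- file.path(workdir, o$file)
    run_simulation(cfg, new_path, manifest = file.path(workdir, "manifest.json"),
                   stochastic = isTRUE(m$config$stochastic))
    data.frame(file = o$file, recorded_md5 = o$md5,
               reproduced_md5 = unname(tools::md5sum(new_path)),
               stringsAsFactors = FALSE)
  }))
  ok <- all(comparisons$recorded_md5 == comparisons$reproduced_md5)
  structure(ok, comparison = comparisons)
}
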