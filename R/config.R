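SCENARIO_KEYS <- c("scenario_id", "condition", "timepoints", "replicates",
                   "assays", "antibodies", "n_molecules", "rates", "qpcr",
                   "sspe", "precip", "ip_capture_efficiency",
                   "ip_background_rate")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

scenario_from_list <- function(lst, where = "scenario") {
  if (is.null(lst$scenario_id)) {
    stop("missing scenario_id in ", where, call. = FALSE)
  }
  check_keys(lst, SCENARIO_KEYS, paste0(where, " '", lst$scenario_id, "'"))
  for (sub in c("condition", "rates", "qpcr", "sspe", "precip")) {
    if (!is.null(lst[[sub]])) {
      allowed <- names(formals(switch(sub,
                                      condition = dpc_condition,
                                      rates = rate_set, qpcr = qpcr_params,
                                      sspe = sspe_params, precip = precip_params)))
      check_keys(lst[[sub]], allowed,
                 paste0(where, " '", lst$scenario_id, "' $", sub))
    }
  }
  tryCatch(do.call(dpc_scenario, lst),
           error = function(e) stop("in ", where, " '", lst$scenario_id, "': ",
                                    conditionMessage(e), call. = FALSE))
}

scenario_to_list <- function(sc) {
  list(scenario_id = sc$scenario_id,
       condition = unclass(sc$condition),
       timepoints = sc$timepoints, replicates = sc$replicates,
       assays = sc$assays, antibodies = sc$antibodies,
       n_molecules = sc$n_molecules,
       rates = unclass(sc$rates), qpcr = unclass(sc$qpcr),
       sspe = unclass(sc$sspe), precip = unclass(sc$precip),
       ip_capture_efficiency = sc$ip_capture_efficiency,
       ip_background_rate = sc$ip_background_rate)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing the seed and the scenarios/panels
#' to run, validates it strictly against the schema (unknown keys anywhere
#' are rejected, with the offending key named), and resolves every default.
#' Top-level keys: `seed` (mandatory -- no implicit entropy), `panels`
#' (character vector of built-in panel ids, see [panel_library()]) and/or
#' `scenarios` (list of scenario definitions; see [dpc_scenario()] for the
#' fields).
#'
#' The name `"paper_panels"` resolves to the packaged configuration listing
#' all ten built-in panels.
#'
#' @param path Path to a YAML file, or the name of a built-in configuration.
#' @return List with `seed` (integer), `panels` (character, possibly empty)
#'   and `scenarios` (list of resolved [dpc_scenario()] objects, including
#'   one per panel arm).
#' @export
load_config <- function(path) {
  if (identical(path, "paper_panels")) {
    path <- system.file("extdata", "paper_panels.yaml", package = "dpcrepair",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  resolve_config(raw, where = path)
}

resolve_config <- function(raw, where = "config") {
  check_keys(raw, c("seed", "panels", "scenarios"), where)
  if (is.null(raw$seed)) {
    stop("config must set a seed (no implicit entropy): ", where, call. = FALSE)
  }
  if (!is.numeric(raw$seed) || length(raw$seed) != 1L ||
      raw$seed != round(raw$seed)) {
    stop("config key 'seed' must be a single integer", call. = FALSE)
  }
  panels <- as.character(raw$panels %||% character())
  if (length(panels)) panel_library(panels)  # validates ids
  scenarios <- lapply(seq_along(raw$scenarios), function(i) {
    scenario_from_list(raw$scenarios[[i]], where = sprintf("scenarios[%d]", i))
  })
  # Expand panel arms into runnable scenarios (arm ids prefixed by panel id).
  for (pid in panels) {
    panel <- panel_library(pid)[[1]]
    for (aid in names(panel$arms)) {
      sc <- panel_arm_scenario(panel, paste(pid, aid, sep = "."),
                               panel$arms[[aid]], rate_set(), qpcr_params(),
                               sspe_params(), precip_params(), 10000L)
      scenarios[[length(scenarios) + 1L]] <- sc
    }
  }
  list(seed = as.integer(raw$seed), panels = panels, scenarios = scenarios)
}
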