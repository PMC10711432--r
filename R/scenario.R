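# Deterministic child-seed derivation: one master seed per run, child streams
# per (timepoint index, replicate). Deliberately independent of the scenario
# identity so that arms of a panel share random-number streams (paired
# simulation; see the methods vignette).
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (tok in list(...)) {
    k <- if (is.character(tok)) sum(utf8ToInt(tok)) else as.numeric(tok)
    h <- (h * 69069 + k + 1) %% 2147483647
  }
  as.integer(h)
}

#' Define an experimental scenario
#'
#' A scenario bundles an experimental condition with the timepoints,
#' replicate count, assays and nuisance parameters needed to forward-simulate
#' a full experiment, mirroring one bar/arm of a figure panel.
#'
#' @param scenario_id Short identifier (used in output tables).
#' @param condition A [dpc_condition()] or a named list of its fields.
#' @param timepoints Numeric vector of collection times (hours).
#' @param replicates Number of independent experiment repeats (each repeat is
#'   one fresh pathway simulation plus one readout of each assay). Default 3,
#'   the study's usual design; 5 for the B02 panel.
#' @param assays Character subset of `c("sspe", "kcl_sds", "ip")`.
#' @param antibodies Antibodies to read out when `"ip"` is among `assays`.
#' @param n_molecules Simulated population size per repeat.
#' @param rates A [rate_set()] or named list of overrides.
#' @param qpcr,sspe,precip Parameter objects (or named override lists) for
#'   [qpcr_params()], [sspe_params()], [precip_params()].
#' @param ip_capture_efficiency,ip_background_rate IP capture parameters
#'   shared across the requested antibodies.
#' @return Object of class `dpc_scenario`.
#' @export
dpc_scenario <- function(scenario_id,
                         condition = dpc_condition(),
                         timepoints = 1,
                         replicates = 3,
                         assays = c("sspe", "kcl_sds", "ip"),
                         antibodies = "pan_ub",
                         n_molecules = 10000,
                         rates = rate_set(),
                         qpcr = qpcr_params(),
                         sspe = sspe_params(),
                         precip = precip_params(),
                         ip_capture_efficiency = 0.5,
                         ip_background_rate = 0.01) {
  if (!is.character(scenario_id) || length(scenario_id) != 1L || !nzchar(scenario_id)) {
    stop("scenario_id must be a non-empty string", call. = FALSE)
  }
  assays <- match.arg(assays, several.ok = TRUE)
  antibodies <- match.arg(antibodies, c("pan_ub", "k48", "k63"), several.ok = TRUE)
  if (!is.numeric(timepoints) || !length(timepoints) || any(timepoints < 0)) {
    stop("timepoints must be non-negative hours", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  cfg <- list(
    scenario_id = scenario_id,
    condition = as_condition(condition),
    timepoints = as.numeric(timepoints),
    replicates = as.integer(replicates),
    assays = assays,
    antibodies = antibodies,
    n_molecules = as.integer(n_molecules),
    rates = as_rate_set(rates),
    qpcr = if (inherits(qpcr, "dpc_qpcr_params")) qpcr else do.call(qpcr_params, qpcr),
    sspe = if (inherits(sspe, "dpc_sspe_params")) sspe else do.call(sspe_params, sspe),
    precip = if (inherits(precip, "dpc_precip_params")) precip else do.call(precip_params, precip),
    ip_capture_efficiency = ip_capture_efficiency,
    ip_background_rate = ip_background_rate
  )
  structure(cfg, class = "dpc_scenario")
}

empty_ct_table <- function() {
  data.frame(sample_id = character(), scenario_id = character(),
             assay = character(), tube = character(),
             replicate = integer(), timepoint = numeric(), ct = numeric(),
             stringsAsFactors = FALSE)
}

ct_rows <- function(scenario_id, sample_id, assay, cts, replicate, timepoint) {
  data.frame(sample_id = sample_id, scenario_id = scenario_id, assay = assay,
             tube = names(cts), replicate = replicate, timepoint = timepoint,
             ct = as.numeric(cts), stringsAsFactors = FALSE, row.names = NULL)
}

#' Forward-simulate a scenario into a Ct table
#'
#' Runs one fresh, independent pathway simulation per (timepoint, replicate)
#' and converts the resulting state distribution into noisy Ct records for
#' each requested assay. Fully reproducible given `seed`: a child seed is
#' derived per (timepoint, replicate), and the pathway simulation plus all
#' assay noise for that repeat share one RNG stream.
#'
#' @param scenario A [dpc_scenario()].
#' @param seed Master integer seed (mandatory).
#' @param stochastic If `TRUE` (default) propagate by per-molecule Gillespie
#'   simulation; if `FALSE`, use exact matrix-exponential propagation (useful
#'   for noise-free closed-form checks).
#' @return A Ct record `data.frame` with columns `sample_id`, `scenario_id`,
#'   `assay`, `tube`, `replicate`, `timepoint`, `ct`. IP tubes are labelled
#'   `"<antibody>.<fragment>_<pool>"`.
#' @export
generate_scenario_dataset <- function(scenario, seed, stochastic = TRUE) {
  stopifnot(inherits(scenario, "dpc_scenario"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a finite integer master seed is required", call. = FALSE)
  }
  gen <- build_generator(scenario$rates, scenario$condition)
  out <- list()
  for (ti in seq_along(scenario$timepoints)) {
    t <- scenario$timepoints[ti]
    for (r in seq_len(scenario$replicates)) {
      set.seed(derive_seed(seed, ti, r))
      dist <- if (stochastic) {
        state_distribution(gillespie_counts(gen, t, scenario$n_molecules),
                           time = t, type = "count")
      } else {
        propagate_exact(gen, t)
      }
      sid <- sprintf("%s_t%g_r%d", scenario$scenario_id, t, r)
      if ("sspe" %in% scenario$assays) {
        cts <- sspe_readout(dist, scenario$sspe, scenario$qpcr)
        names(cts) <- c("pre_amplified", "reference")
        out[[length(out) + 1L]] <- ct_rows(scenario$scenario_id, sid, "sspe", cts, r, t)
      }
      if ("kcl_sds" %in% scenario$assays) {
        cts <- kcl_sds_readout(dist, scenario$precip, scenario$qpcr)
        names(cts) <- c("b_supernatant", "c_supernatant")
        out[[length(out) + 1L]] <- ct_rows(scenario$scenario_id, sid, "kcl_sds", cts, r, t)
      }
      if ("ip" %in% scenario$assays) {
        for (ab in scenario$antibodies) {
          ipp <- ip_params(ab, scenario$ip_capture_efficiency,
                           scenario$ip_background_rate)
          cts <- ip_readout(dist, ipp, scenario$qpcr)
          names(cts) <- paste(ab, c("b_eluate", "c_eluate", "b_input", "c_input"),
                              sep = ".")
          out[[length(out) + 1L]] <- ct_rows(scenario$scenario_id, sid, "ip", cts, r, t)
        }
      }
    }
  }
  if (!length(out)) return(empty_ct_table())
  do.call(rbind, out)
}

#' Read / write Ct record tables
#'
#' The single interchange format between the simulator and the estimators:
#' comma-separated, `.` decimal separator, UTF-8, LF newlines, with header
#' `sample_id,scenario_id,assay,tube,replicate,timepoint,ct`.
#'
#' @param x A Ct record `data.frame`.
#' @param path File path.
#' @return `read_ct_table()` returns the validated `data.frame`;
#'   `write_ct_table()` returns `path` invisibly.
#' @export
write_ct_table <- function(x, path) {
  validate_ct_table(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(x, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(x)
}

validate_ct_table <- function(x) {
  required <- c("sample_id", "scenario_id", "assay", "tube", "replicate", "ct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"timepoint" %in% names(x)) x$timepoint <- 0
  if (nrow(x)) {
    if (any(!is.finite(x$ct)) || any(x$ct <= 0)) {
      stop("ct values must be finite and > 0 (first bad row: ",
           which(!is.finite(x$ct) | x$ct <= 0)[1], ")", call. = FALSE)
    }
    key <- paste(x$sample_id, x$assay, x$tube, x$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (sample, assay, tube, replicate) key at row ",
           which(duplicated(key))[1], call. = FALSE)
    }
  }
  invisible(x)
}
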