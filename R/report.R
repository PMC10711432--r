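#' Build figure-style scenario reports
#'
#' Simulates every arm of the requested panels, quantifies the readouts, and
#' assembles per-panel tables of replicate estimates, group summaries
#' (mean, SEM) and t-tests. Sidedness follows the study's rule
#' automatically: comparisons against the untransfected baseline are
#' one-tailed, comparisons between transfected arms two-tailed.
#'
#' Arms within a panel share random-number streams (child seeds depend only
#' on the replicate, not the arm), so arms whose generators coincide -- the
#' SPRTN toggle everywhere, the MG132 toggle on the HR arm -- produce
#' identical simulated values, making those structural no-ops exact in the
#' report.
#'
#' @param panels Character vector of panel ids (see [panel_library()]), or
#'   `"all"`.
#' @param seed Master integer seed (mandatory).
#' @param rates A [rate_set()] shared by all arms (the K341R variant factor
#'   is applied per-arm through each arm's condition).
#' @param qpcr,sspe,precip Assay parameter objects shared by all arms.
#' @param n_molecules Simulated population size per replicate.
#' @param stochastic Propagate per-molecule (default) or exactly.
#' @return Named list (one element per panel) of lists with `panel_id`,
#'   `measure`, `estimates`, `summary`, `tests`.
#' @export
build_report <- function(panels = "all", seed, rates = rate_set(),
                         qpcr = qpcr_params(), sspe = sspe_params(),
                         precip = precip_params(), n_molecules = 10000,
                         stochastic = TRUE) {
  if (missing(seed)) stop("a master seed is required", call. = FALSE)
  if (identical(panels, "all")) panels <- PANEL_IDS
  lib <- panel_library(panels)
  out <- lapply(lib, function(panel) {
    report_panel(panel, seed, rates, qpcr, sspe, precip, n_molecules, stochastic)
  })
  names(out) <- panels
  out
}

panel_arm_scenario <- function(panel, arm_id, arm_def, rates, qpcr, sspe,
                               precip, n_molecules, timepoint = panel$timepoint) {
  dpc_scenario(
    scenario_id = arm_id,
    condition = arm_def$condition,
    timepoints = timepoint,
    replicates = panel$replicates,
    assays = panel$assay,
    antibodies = arm_def$antibody,
    n_molecules = n_molecules,
    rates = rates, qpcr = qpcr, sspe = sspe, precip = precip
  )
}

panel_measure_values <- function(panel, ds) {
  q <- quantify_table(ds)
  est <- switch(panel$measure,
                percent_repair = q$repair,
                percent_removal = q$removal,
                fold_enrichment = q$enrichment)
  est
}

report_panel <- function(panel, seed, rates, qpcr, sspe, precip,
                         n_molecules, stochastic) {
  panel_seed <- derive_seed(seed, panel$panel_id)
  needs_untransfected <- any(vapply(panel$comparisons,
                                    function(cp) cp[2] == "untransfected",
                                    logical(1)))
  arm_ids <- names(panel$arms)
  estimates <- list()
  for (aid in arm_ids) {
    sc <- panel_arm_scenario(panel, aid, panel$arms[[aid]], rates, qpcr,
                             sspe, precip, n_molecules)
    ds <- generate_scenario_dataset(sc, panel_seed, stochastic = stochastic)
    estimates[[aid]] <- panel_measure_values(panel, ds)
  }
  if (needs_untransfected) {
    # The input substrate: no cellular exposure, t = 0, so every molecule is
    # still NASCENT; readout noise is still drawn.
    ab <- unique(vapply(panel$arms, function(a) a$antibody, character(1)))[1]
    sc0 <- panel_arm_scenario(panel, "untransfected",
                              arm(list(ner_functional = FALSE), antibody = ab),
                              rates, qpcr, sspe, precip, n_molecules,
                              timepoint = 0)
    ds0 <- generate_scenario_dataset(sc0, panel_seed, stochastic = stochastic)
    estimates[["untransfected"]] <- panel_measure_values(panel, ds0)
  }
  est_df <- do.call(rbind, estimates)
  rownames(est_df) <- NULL
  smry <- summarize_estimates(est_df, panel$measure,
                              by = intersect(c("scenario_id", "antibody"),
                                             names(est_df)))
  tests <- do.call(rbind, lapply(panel$comparisons, function(cp) {
    a <- est_df[[panel$measure]][est_df$scenario_id == cp[1]]
    b <- est_df[[panel$measure]][est_df$scenario_id == cp[2]]
    side <- auto_sidedness(cp[2])
    tt <- pooled_t_test(a, b, side)
    data.frame(group_a = cp[1], group_b = cp[2], sidedness = side,
               t_statistic = tt$t_statistic,
               degrees_of_freedom = tt$degrees_of_freedom,
               p_value = tt$p_value, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  }))
  list(panel_id = panel$panel_id, measure = panel$measure,
       estimates = est_df, summary = smry, tests = tests)
}

#' Write a report to disk
#'
#' Writes one estimates/summary/tests CSV triple per panel plus a JSON run
#' manifest (package version, seed, panel list, per-file MD5 checksums).
#'
#' @param report Result of [build_report()].
#' @param dir Output directory (created if needed).
#' @param seed The master seed the report was built with (recorded in the
#'   manifest).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (panel in report) {
    for (part in c("estimates", "summary", "tests")) {
      path <- file.path(dir, sprintf("%s_%s.csv", panel$panel_id, part))
      con <- file(path, open = "wb")
      write.csv(panel[[part]], con, row.names = FALSE, quote = FALSE, eol = "\n")
      close(con)
      files <- c(files, path)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  write_manifest(manifest, kind = "report", seed = seed,
                 config = list(panels = names(report)), outputs = files)
  invisible(manifest)
}
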