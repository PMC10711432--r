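#' Delta-Ct for the SSPE repair assay
#'
#' `delta_ct = ct_reference_tube - ct_pre_amplified`: the Ct of the tube kept
#' on ice minus the Ct of the tube that underwent strand-specific
#' pre-amplification. Positive when pre-amplification helped, i.e. when
#' repaired (extension-competent) templates are present; measurement noise
#' can make it negative and it is deliberately not clamped.
#'
#' @param ct_reference_tube,ct_pre_amplified Ct values (cycles).
#' @return Delta-Ct in cycles.
#' @export
delta_ct <- function(ct_reference_tube, ct_pre_amplified) {
  ct_reference_tube - ct_pre_amplified
}

#' Percent undamaged DNA from delta-Ct
#'
#' `percent_undamaged = 2^delta_ct / 2^3 * 100`, normalizing the observed
#' pre-amplification gain to the nominal gain of eight strand-specific
#' rounds. Not clamped to `[0, 100]`.
#'
#' @param dct Delta-Ct in cycles.
#' @return Percent.
#' @export
percent_undamaged <- function(dct) {
  2^dct / 2^3 * 100
}

#' Percent repair
#'
#' Difference between percent-undamaged at the collection timepoint and at
#' the t0 baseline (the un-transfected input substrate). Not clamped.
#'
#' @param pu_at_t,pu_at_t0 Percent-undamaged values.
#' @return Percent repair.
#' @export
percent_repair <- function(pu_at_t, pu_at_t0) {
  pu_at_t - pu_at_t0
}

#' Relative abundance of the lesion fragment
#'
#' `efficiency^(ct_c - ct_b)`: the abundance of the crosslink-site fragment b
#' relative to the distal control fragment c, from their respective Ct
#' values.
#'
#' @param ct_b,ct_c Ct values of fragments b and c (cycles).
#' @param efficiency qPCR amplification factor per cycle, in `(1, 2]`.
#'   Defaults to 2 (the `2^delta-Ct` arithmetic of the assay assumes perfect
#'   efficiency).
#' @return Dimensionless abundance ratio.
#' @export
relative_abundance <- function(ct_b, ct_c, efficiency = 2) {
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("efficiency must be in (1, 2]", call. = FALSE)
  }
  efficiency^(ct_c - ct_b)
}

#' Percent removal from supernatant abundance ratios
#'
#' Baseline-anchored linear rescaling of the supernatant b/c abundance ratio:
#' the pre-transfection, fully crosslinked baseline ratio `a_t0` maps to 0%
#' and the ratio of a fully protein-free control `a_full` maps to 100%:
#' `(a_t - a_t0) / (a_full - a_t0) * 100`. This is the unique affine map
#' consistent with quantifying removal "prior to and following transfection";
#' it also makes the estimate independent of the precipitation capture
#' probability when the baseline is measured under the same conditions.
#'
#' @param a_t Observed abundance ratio at the collection timepoint.
#' @param a_t0 Pre-transfection (fully crosslinked) baseline ratio.
#' @param a_full Ratio of a fully protein-free control (default 1).
#' @return Percent removal (not clamped).
#' @export
percent_removal <- function(a_t, a_t0, a_full = 1) {
  if (any(a_t0 < 0) || any(a_full <= a_t0)) {
    stop("degenerate baseline: need a_full > a_t0 >= 0", call. = FALSE)
  }
  (a_t - a_t0) / (a_full - a_t0) * 100
}

#' Fold enrichment from IP abundance ratios
#'
#' Eluate b/c abundance ratio divided by the input-control b/c ratio. A value
#' of 1 means the antibody captured the lesion fragment no better than the
#' control fragment (no specific enrichment).
#'
#' @param a_eluate,a_input Abundance ratios (from [relative_abundance()]).
#' @return Dimensionless fold enrichment.
#' @export
fold_enrichment <- function(a_eluate, a_input) {
  if (any(a_input <= 0)) stop("a_input must be > 0", call. = FALSE)
  a_eluate / a_input
}

empty_repair_df <- function() {
  data.frame(scenario_id = character(), timepoint = numeric(),
             replicate = integer(), delta_ct = numeric(),
             percent_undamaged = numeric(), percent_repair = numeric(),
             stringsAsFactors = FALSE)
}
empty_removal_df <- function() {
  data.frame(scenario_id = character(), timepoint = numeric(),
             replicate = integer(), relative_abundance = numeric(),
             percent_removal = numeric(), stringsAsFactors = FALSE)
}
empty_enrichment_df <- function() {
  data.frame(scenario_id = character(), timepoint = numeric(),
             antibody = character(), replicate = integer(),
             fold_enrichment = numeric(), stringsAsFactors = FALSE)
}

#' Quantify a Ct record table into per-replicate estimates
#'
#' Dispatches each assay's records to its estimator: SSPE rows become repair
#' estimates (delta-Ct, percent undamaged, percent repair against the
#' `pu_t0` baseline), KCl-SDS rows become removal estimates, IP rows become
#' fold-enrichment estimates (input-normalized by default). Replicate groups
#' with missing tubes are skipped with a warning, never imputed.
#'
#' @param records Ct record table (see [generate_scenario_dataset()] /
#'   [read_ct_table()]).
#' @param efficiency qPCR efficiency assumed by the estimators (default 2,
#'   independent of whatever efficiency generated the data).
#' @param pu_t0 Percent-undamaged baseline of the un-transfected input
#'   substrate. Default 12.5, the analytic noise-free floor of the default
#'   assay chemistry (`100 * damaged_leak / 8` with `damaged_leak = 1`).
#' @param a_t0 Pre-transfection supernatant abundance-ratio baseline
#'   (default 0.02, the analytic value under the default capture
#'   probability).
#' @param a_full Protein-free control abundance ratio (default 1).
#' @param input_normalized If `FALSE`, report the raw eluate b/c ratio as
#'   the enrichment instead of normalizing by the input control.
#' @return List of data frames `repair`, `removal`, `enrichment` (empty
#'   frames when an assay is absent).
#' @export
quantify_table <- function(records, efficiency = 2, pu_t0 = 12.5,
                           a_t0 = 0.02, a_full = 1, input_normalized = TRUE) {
  records <- validate_ct_table(records)
  repair <- list(); removal <- list(); enrichment <- list()

  grp_key <- function(df) paste(df$scenario_id, df$timepoint, df$replicate,
                                df$sample_id, sep = "\r")
  skip <- function(what, key) {
    warning("skipping ", what, " group with missing tube(s): ",
            gsub("\r", " / ", key), call. = FALSE)
  }

  sspe <- records[records$assay == "sspe", , drop = FALSE]
  if (nrow(sspe)) {
    for (key in unique(grp_key(sspe))) {
      g <- sspe[grp_key(sspe) == key, , drop = FALSE]
      if (!all(c("pre_amplified", "reference") %in% g$tube)) { skip("sspe", key); next }
      dct <- delta_ct(g$ct[g$tube == "reference"], g$ct[g$tube == "pre_amplified"])
      pu <- percent_undamaged(dct)
      repair[[length(repair) + 1L]] <- data.frame(
        scenario_id = g$scenario_id[1], timepoint = g$timepoint[1],
        replicate = g$replicate[1], delta_ct = dct, percent_undamaged = pu,
        percent_repair = percent_repair(pu, pu_t0), stringsAsFactors = FALSE)
    }
  }

  kcl <- records[records$assay == "kcl_sds", , drop = FALSE]
  if (nrow(kcl)) {
    for (key in unique(grp_key(kcl))) {
      g <- kcl[grp_key(kcl) == key, , drop = FALSE]
      if (!all(c("b_supernatant", "c_supernatant") %in% g$tube)) { skip("kcl_sds", key); next }
      a <- relative_abundance(g$ct[g$tube == "b_supernatant"],
                              g$ct[g$tube == "c_supernatant"], efficiency)
      removal[[length(removal) + 1L]] <- data.frame(
        scenario_id = g$scenario_id[1], timepoint = g$timepoint[1],
        replicate = g$replicate[1], relative_abundance = a,
        percent_removal = percent_removal(a, a_t0, a_full),
        stringsAsFactors = FALSE)
    }
  }

  ip <- records[records$assay == "ip", , drop = FALSE]
  if (nrow(ip)) {
    ab <- sub("\\..*$", "", ip$tube)
    part <- sub("^[^.]*\\.", "", ip$tube)
    for (key in unique(paste(grp_key(ip), ab, sep = "\r"))) {
      sel <- paste(grp_key(ip), ab, sep = "\r") == key
      g <- ip[sel, , drop = FALSE]
      gp <- part[sel]
      need <- c("b_eluate", "c_eluate", "b_input", "c_input")
      if (!all(need %in% gp)) { skip("ip", key); next }
      a_el <- relative_abundance(g$ct[gp == "b_eluate"], g$ct[gp == "c_eluate"],
                                 efficiency)
      a_in <- relative_abundance(g$ct[gp == "b_input"], g$ct[gp == "c_input"],
                                 efficiency)
      fe <- if (input_normalized) fold_enrichment(a_el, a_in) else a_el
      enrichment[[length(enrichment) + 1L]] <- data.frame(
        scenario_id = g$scenario_id[1], timepoint = g$timepoint[1],
        antibody = ab[sel][1], replicate = g$replicate[1],
        fold_enrichment = fe, stringsAsFactors = FALSE)
    }
  }

  list(
    repair = if (length(repair)) do.call(rbind, repair) else empty_repair_df(),
    removal = if (length(removal)) do.call(rbind, removal) else empty_removal_df(),
    enrichment = if (length(enrichment)) do.call(rbind, enrichment) else empty_enrichment_df()
  )
}
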