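#' qPCR instrument parameters
#'
#' Nuisance parameters of the threshold-cycle readout shared by all three
#' assays: the per-cycle amplification factor (2 = perfect doubling), the Ct
#' observed at unit relative template abundance, and the Gaussian Ct
#' measurement noise.
#'
#' @param efficiency Amplification factor per cycle, in `(1, 2]`.
#' @param ct_reference Ct at unit template abundance (cycles).
#' @param ct_noise_sd Standard deviation of Gaussian Ct noise (cycles).
#' @return Object of class `dpc_qpcr_params`.
#' @export
qpcr_params <- function(efficiency = 2.0, ct_reference = 30.0,
                        ct_noise_sd = 0.15) {
  if (!is.numeric(efficiency) || efficiency <= 1 || efficiency > 2) {
    stop("efficiency must be in (1, 2]", call. = FALSE)
  }
  if (!is.numeric(ct_noise_sd) || ct_noise_sd < 0) {
    stop("ct_noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(ct_reference) || !is.finite(ct_reference) || ct_reference <= 0) {
    stop("ct_reference must be a positive number", call. = FALSE)
  }
  structure(list(efficiency = efficiency, ct_reference = ct_reference,
                 ct_noise_sd = ct_noise_sd), class = "dpc_qpcr_params")
}

#' Strand-specific pre-amplification (SSPE) parameters
#'
#' The repair assay splits each sample into two tubes; one undergoes eight
#' rounds of single-primer, strand-specific PCR before the ordinary qPCR.
#' Repaired templates support this linear pre-amplification (effective
#' `gain`); templates still blocked by the lesion pass through with relative
#' weight `damaged_leak` (1 = present but un-amplified, 0 = excluded).
#' The default gain of 8 mirrors the estimator's `2^3` normalization.
#'
#' @param cycles Number of strand-specific pre-amplification rounds.
#' @param gain Effective amplification factor for repaired templates.
#' @param damaged_leak Relative weight of unrepaired templates after
#'   pre-amplification, in `[0, 1]`.
#' @return Object of class `dpc_sspe_params`.
#' @export
sspe_params <- function(cycles = 8, gain = 8, damaged_leak = 1) {
  if (!is.numeric(cycles) || cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  if (!is.numeric(gain) || gain < 1) stop("gain must be >= 1", call. = FALSE)
  if (!is.numeric(damaged_leak) || damaged_leak < 0 || damaged_leak > 1) {
    stop("damaged_leak must be in [0, 1]", call. = FALSE)
  }
  structure(list(cycles = cycles, gain = gain, damaged_leak = damaged_leak),
            class = "dpc_sspe_params")
}

#' KCl-SDS precipitation parameters
#'
#' KCl/SDS selectively precipitates protein-crosslinked restriction
#' fragments; the supernatant retains protein-free fragments. `capture_prob`
#' is the probability that a crosslink-bearing fragment precipitates;
#' `nonspecific_loss` the probability that any fragment is lost to the pellet
#' nonspecifically.
#'
#' @param capture_prob,nonspecific_loss Probabilities in `[0, 1]`.
#' @return Object of class `dpc_precip_params`.
#' @export
precip_params <- function(capture_prob = 0.98, nonspecific_loss = 0.02) {
  for (v in c(capture_prob, nonspecific_loss)) {
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("precipitation parameters must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  structure(list(capture_prob = capture_prob, nonspecific_loss = nonspecific_loss),
            class = "dpc_precip_params")
}

#' Immunoprecipitation parameters
#'
#' Antibody capture of ubiquitin-tagged fragments with linkage-specific
#' selectivity plus a nonspecific background that pulls down every fragment
#' at a low rate. The `pan_ub` and `k63` antibodies capture K63-tagged states
#' (which include the doubly tagged state); the `k48` antibody captures only
#' the doubly tagged state.
#'
#' @param antibody One of `"pan_ub"`, `"k48"`, `"k63"`.
#' @param capture_efficiency Probability a tagged fragment is captured, in
#'   `(0, 1]`.
#' @param background_rate Nonspecific capture probability, in `(0, 1)` and
#'   strictly below `capture_efficiency`.
#' @return Object of class `dpc_ip_params`.
#' @export
ip_params <- function(antibody = c("pan_ub", "k48", "k63"),
                      capture_efficiency = 0.5, background_rate = 0.01) {
  antibody <- match.arg(antibody)
  if (!is.numeric(capture_efficiency) || capture_efficiency <= 0 ||
      capture_efficiency > 1) {
    stop("capture_efficiency must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(background_rate) || background_rate <= 0 ||
      background_rate >= 1 || background_rate >= capture_efficiency) {
    stop("background_rate must be in (0, 1) and below capture_efficiency",
         call. = FALSE)
  }
  structure(list(antibody = antibody, capture_efficiency = capture_efficiency,
                 background_rate = background_rate), class = "dpc_ip_params")
}

# Relative template abundance below which an analytically empty pool is
# floored, mimicking late nonspecific amplification rather than a censored
# "no Ct". Small enough that the floor contributes < 1e-6 percentage points
# to any downstream estimate.
PSEUDO_ABUNDANCE_FLOOR <- 1e-9

floor_abundance <- function(x) pmax(x, PSEUDO_ABUNDANCE_FLOOR)

#' Threshold cycle from relative template abundance
#'
#' Standard qPCR relation: `ct = ct_reference - log(abundance) /
#' log(efficiency)` plus Gaussian noise, truncated below at cycle 1.
#' Vectorized over `abundance`; noise draws consume the current RNG stream,
#' so callers control reproducibility via seeding.
#'
#' @param abundance Relative template amount(s), strictly positive. Callers
#'   must floor analytically empty pools (the readout functions apply a
#'   pseudo-abundance floor of 1e-9).
#' @param qp A [qpcr_params()].
#' @return Ct value(s) in cycles.
#' @export
ct_from_template <- function(abundance, qp = qpcr_params()) {
  if (!is.numeric(abundance) || any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("abundance must be strictly positive and finite", call. = FALSE)
  }
  ct <- qp$ct_reference - log(abundance) / log(qp$efficiency)
  if (qp$ct_noise_sd > 0) ct <- ct + rnorm(length(abundance), 0, qp$ct_noise_sd)
  pmax(ct, 1)
}

#' Forward model of the SSPE-qPCR repair readout
#'
#' Splits the sample into a reference tube (kept on ice, template weight 1)
#' and a pre-amplified tube whose template weight is
#' `(1 - f) * damaged_leak + gain * f`, where `f` is the repaired fraction of
#' the population; both are converted to Ct values.
#'
#' @param dist A [state_distribution()].
#' @param sp A [sspe_params()].
#' @param qp A [qpcr_params()].
#' @return Named numeric: `ct_pre_amplified`, `ct_reference`.
#' @export
sspe_readout <- function(dist, sp = sspe_params(), qp = qpcr_params()) {
  f <- population_summary(dist)[["repaired_fraction"]]
  pre <- floor_abundance((1 - f) * sp$damaged_leak + sp$gain * f)
  cts <- ct_from_template(c(pre, 1), qp)
  c(ct_pre_amplified = cts[1], ct_reference = cts[2])
}

#' Forward model of the KCl-SDS removal readout
#'
#' After restriction digestion, the crosslink-bearing fragment b
#' co-precipitates with the protein while the distal control fragment c
#' stays in the supernatant. With removed fraction `r` (protein degraded or
#' strand repaired; a residual peptide adduct does not precipitate unless
#' `proteolyzed_precipitates`), supernatant abundances are
#' `b = (r + (1 - r)(1 - capture_prob)) (1 - nonspecific_loss)` and
#' `c = 1 - nonspecific_loss`.
#'
#' @inheritParams sspe_readout
#' @param pp A [precip_params()].
#' @param proteolyzed_precipitates If `TRUE`, the peptide adduct left after
#'   proteasomal degradation still precipitates the fragment (default
#'   `FALSE`).
#' @return Named numeric: `ct_fragment_b`, `ct_fragment_c` (supernatant).
#' @export
kcl_sds_readout <- function(dist, pp = precip_params(), qp = qpcr_params(),
                            proteolyzed_precipitates = FALSE) {
  s <- population_summary(dist)
  r <- if (proteolyzed_precipitates) s[["repaired_fraction"]] else s[["removed_fraction"]]
  b <- floor_abundance((r + (1 - r) * (1 - pp$capture_prob)) * (1 - pp$nonspecific_loss))
  cc <- floor_abundance(1 - pp$nonspecific_loss)
  cts <- ct_from_template(c(b, cc), qp)
  c(ct_fragment_b = cts[1], ct_fragment_c = cts[2])
}

#' Forward model of the IP-qPCR enrichment readout
#'
#' The antibody captures the ubiquitin-tagged fraction `u` of lesion
#' fragments (predicate set by the antibody's linkage selectivity) with
#' efficiency `capture_efficiency`, plus every fragment at
#' `background_rate`. Eluate abundances are `b = u * capture_efficiency +
#' background_rate` and `c = background_rate`; the saved input control has
#' unit abundance for both fragments.
#'
#' @inheritParams sspe_readout
#' @param ip An [ip_params()].
#' @param proteolyzed_retains_tags If `TRUE`, the residual peptide adduct
#'   retains its ubiquitin chains and remains capturable (default `FALSE`:
#'   tags are assumed lost with the degraded protein).
#' @return Named numeric: `ct_b_eluate`, `ct_c_eluate`, `ct_b_input`,
#'   `ct_c_input`.
#' @export
ip_readout <- function(dist, ip = ip_params(), qp = qpcr_params(),
                       proteolyzed_retains_tags = FALSE) {
  s <- population_summary(dist)
  u <- switch(ip$antibody,
              pan_ub = s[["pan_ub_fraction"]],
              k63    = s[["k63_fraction"]],
              k48    = s[["k48_fraction"]])
  if (proteolyzed_retains_tags) {
    p <- as_probability(dist)
    u <- u + as.numeric(p)[match("PROTEOLYZED", PATHWAY_STATES)]
  }
  el_b <- floor_abundance(u * ip$capture_efficiency + ip$background_rate)
  el_c <- floor_abundance(ip$background_rate)
  cts <- ct_from_template(c(el_b, el_c, 1, 1), qp)
  c(ct_b_eluate = cts[1], ct_c_eluate = cts[2],
    ct_b_input = cts[3], ct_c_input = cts[4])
}
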