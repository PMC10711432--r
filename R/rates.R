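#' Kinetic rate set for the repair model
#'
#' First-order rate constants (per hour) for the five transitions of the
#' pathway model, plus the multiplicative factors through which drug
#' treatments and the ubiquitination-deficient OGG1 variant act. The
#' end-point assays this model emulates yield no kinetic constants, so the
#' defaults here are a calibration of
#' the model such that NER-proficient protein removal at 1 h is roughly 45%
#' and NER-deficient, homologous-donor-driven measured repair at 3 h is
#' roughly 73% (see the methods vignette). They are calibration values, not
#' measured quantities, and every one can be overridden.
#'
#' @param k63_rate Rate of initial K63 polyubiquitination of the nascent DPC.
#' @param k48_rate Rate of subsequent K48 polyubiquitination (NER-proficient
#'   cells only).
#' @param proteolysis_rate Rate of proteasomal degradation of the doubly
#'   tagged crosslinked protein.
#' @param ner_excision_rate Rate of NER excision of the residual peptide
#'   adduct.
#' @param hr_rate Rate of homologous-recombination repair of a K63-tagged
#'   lesion (requires a homologous donor).
#' @param b02_factor Multiplicative factor applied to `hr_rate` under the
#'   Rad51 inhibitor B02; in `[0, 1]`. Default 0.25 models the observed
#'   partial (roughly two-fold at the readout), not complete, inhibition.
#' @param mg132_factor Factor applied to `proteolysis_rate` under the
#'   proteasome inhibitor MG132; in `[0, 1]`.
#' @param k341r_ub_factor Factor applied to both ubiquitination rates when
#'   the crosslinked protein is the K341R OGG1 variant, whose ubiquitination
#'   is about two-fold lower; default 0.5.
#' @return Object of class `dpc_rate_set` (a validated named list).
#' @seealso [dpc_condition()], [build_generator()]
#' @export
rate_set <- function(k63_rate = 2, k48_rate = 2.5, proteolysis_rate = 3,
                     ner_excision_rate = 1, hr_rate = 0.75,
                     b02_factor = 0.25, mg132_factor = 0.25,
                     k341r_ub_factor = 0.5) {
  rs <- list(
    k63_rate = k63_rate, k48_rate = k48_rate,
    proteolysis_rate = proteolysis_rate,
    ner_excision_rate = ner_excision_rate, hr_rate = hr_rate,
    b02_factor = b02_factor, mg132_factor = mg132_factor,
    k341r_ub_factor = k341r_ub_factor
  )
  for (nm in names(rs)) {
    v <- rs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("rate_set field '", nm, "' must be a finite number", call. = FALSE)
    }
    if (v < 0) stop("rate_set field '", nm, "' must be >= 0", call. = FALSE)
    if (grepl("_factor$", nm) && v > 1) {
      stop("rate_set factor '", nm, "' must be in [0, 1]", call. = FALSE)
    }
  }
  structure(rs, class = "dpc_rate_set")
}

#' Experimental condition
#'
#' The genotype/donor/drug/variant switches that gate the model's effective
#' transition rates: NER proficiency (lost in XPD patient cells and XPA
#' knockouts), the co-transfected donor molecule, Rad51 inhibition (B02),
#' proteasome inhibition (MG132), and the OGG1 ubiquitination-site variant.
#' `sprtn_deficient` is carried for scenario fidelity but, encoding the
#' observation that SPRTN loss does not affect removal of this
#' replication-independent substrate, it never influences any computed rate.
#'
#' @param ner_functional Logical; `FALSE` for XPD or XPA-knockout cells.
#' @param donor One of `"none"`, `"heterologous"`, `"homologous"`. Only a
#'   homologous donor enables the HR arm; a heterologous donor behaves like
#'   no donor.
#' @param rad51_inhibited Logical; B02 pretreatment.
#' @param proteasome_inhibited Logical; MG132 pretreatment.
#' @param ogg1_variant `"K341"` (wild type) or `"R341"`
#'   (ubiquitination-impaired).
#' @param sprtn_deficient Logical; structurally inert (see above).
#' @return Object of class `dpc_condition`.
#' @export
dpc_condition <- function(ner_functional = TRUE,
                          donor = c("none", "heterologous", "homologous"),
                          rad51_inhibited = FALSE,
                          proteasome_inhibited = FALSE,
                          ogg1_variant = c("K341", "R341"),
                          sprtn_deficient = FALSE) {
  donor <- match.arg(donor)
  ogg1_variant <- match.arg(ogg1_variant)
  for (nm in c("ner_functional", "rad51_inhibited", "proteasome_inhibited",
               "sprtn_deficient")) {
    v <- get(nm)
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      stop("condition field '", nm, "' must be TRUE or FALSE", call. = FALSE)
    }
  }
  structure(
    list(ner_functional = ner_functional, donor = donor,
         rad51_inhibited = rad51_inhibited,
         proteasome_inhibited = proteasome_inhibited,
         ogg1_variant = ogg1_variant, sprtn_deficient = sprtn_deficient),
    class = "dpc_condition"
  )
}

as_rate_set <- function(x) {
  if (inherits(x, "dpc_rate_set")) return(x)
  if (is.list(x)) return(do.call(rate_set, x))
  stop("expected a rate_set or a named list of overrides", call. = FALSE)
}

as_condition <- function(x) {
  if (inherits(x, "dpc_condition")) return(x)
  if (is.list(x)) return(do.call(dpc_condition, x))
  stop("expected a dpc_condition or a named list of fields", call. = FALSE)
}
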