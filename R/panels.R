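# Built-in scenario library: one entry per figure panel of the study design.
# Each panel lists its readout, collection timepoint, replicate count, arms
# (condition + antibody) and the comparisons to test. "untransfected" is a
# pseudo-arm: the input substrate, read out without any cellular exposure
# (all molecules NASCENT), which anchors the one-tailed comparisons.

PANEL_IDS <- c("fig1a", "fig1b", "fig2b", "fig3b", "fig3c", "fig4",
               "fig5a", "fig5b", "supp_xpa", "supp_sprtn")

arm <- function(condition, antibody = "pan_ub") {
  list(condition = condition, antibody = antibody)
}

#' The built-in panel library
#'
#' Returns the definitions of the ten scenario panels mirroring the study's
#' figure panels: HR repair rescue by a homologous donor in NER-deficient
#' cells (fig1a), its Rad51 dependence (fig1b), donor-dependence of protein
#' removal (fig2b), pan-ubiquitin enrichment (fig3b), the
#' ubiquitination-deficient OGG1 variant (fig3c), proteasome dependence
#' (fig4), linkage-selective enrichment in NER-proficient (fig5a) and
#' NER-deficient (fig5b) cells, the XPA-knockout replication (supp_xpa) and
#' the SPRTN no-op control (supp_sprtn).
#'
#' @param ids Panel ids to return (default: all ten).
#' @return Named list of panel definition lists (`panel_id`, `measure`,
#'   `assay`, `timepoint`, `replicates`, `arms`, `comparisons`).
#' @export
panel_library <- function(ids = PANEL_IDS) {
  bad <- setdiff(ids, PANEL_IDS)
  if (length(bad)) {
    stop("unknown panel id(s): ", paste(bad, collapse = ", "),
         "; available panels: ", paste(PANEL_IDS, collapse = ", "),
         call. = FALSE)
  }
  xpd  <- function(donor, ...) list(ner_functional = FALSE, donor = donor, ...)
  prof <- function(donor, ...) list(ner_functional = TRUE, donor = donor, ...)

  lib <- list(
    fig1a = list(
      measure = "percent_repair", assay = "sspe", timepoint = 3, replicates = 3,
      arms = list(
        xpd_heterologous = arm(xpd("heterologous")),
        xpd_homologous   = arm(xpd("homologous"))),
      comparisons = list(c("xpd_heterologous", "untransfected"),
                         c("xpd_homologous", "untransfected"))),
    fig1b = list(
      measure = "percent_repair", assay = "sspe", timepoint = 3, replicates = 5,
      arms = list(
        xpd_hom_untreated = arm(xpd("homologous")),
        xpd_hom_b02       = arm(xpd("homologous", rad51_inhibited = TRUE))),
      comparisons = list(c("xpd_hom_untreated", "untransfected"),
                         c("xpd_hom_b02", "untransfected"))),
    fig2b = list(
      measure = "percent_removal", assay = "kcl_sds", timepoint = 1, replicates = 3,
      arms = list(
        xpdc_heterologous = arm(prof("heterologous")),
        hek_heterologous  = arm(prof("heterologous")),
        xpd_heterologous  = arm(xpd("heterologous")),
        xpd_homologous    = arm(xpd("homologous"))),
      comparisons = list(c("xpdc_heterologous", "untransfected"),
                         c("hek_heterologous", "untransfected"),
                         c("xpd_heterologous", "untransfected"),
                         c("xpd_homologous", "untransfected"))),
    fig3b = list(
      measure = "fold_enrichment", assay = "ip", timepoint = 1, replicates = 3,
      arms = list(
        xpdc_heterologous = arm(prof("heterologous")),
        hek_heterologous  = arm(prof("heterologous")),
        xpd_heterologous  = arm(xpd("heterologous")),
        xpd_homologous    = arm(xpd("homologous"))),
      comparisons = list(c("xpdc_heterologous", "untransfected"),
                         c("hek_heterologous", "untransfected"),
                         c("xpd_heterologous", "untransfected"),
                         c("xpd_homologous", "untransfected"))),
    fig3c = list(
      measure = "percent_removal", assay = "kcl_sds", timepoint = 1, replicates = 3,
      arms = list(
        ner_k341 = arm(prof("none")),
        ner_r341 = arm(prof("none", ogg1_variant = "R341")),
        hr_k341  = arm(xpd("homologous")),
        hr_r341  = arm(xpd("homologous", ogg1_variant = "R341"))),
      comparisons = list(c("ner_k341", "ner_r341"),
                         c("hr_k341", "hr_r341"))),
    fig4 = list(
      measure = "percent_removal", assay = "kcl_sds", timepoint = 1, replicates = 3,
      arms = list(
        ner_untreated = arm(prof("heterologous")),
        ner_mg132     = arm(prof("heterologous", proteasome_inhibited = TRUE)),
        hr_untreated  = arm(xpd("homologous")),
        hr_mg132      = arm(xpd("homologous", proteasome_inhibited = TRUE))),
      comparisons = list(c("ner_untreated", "ner_mg132"),
                         c("hr_untreated", "hr_mg132"))),
    fig5a = list(
      measure = "fold_enrichment", assay = "ip", timepoint = 1, replicates = 3,
      arms = list(
        hek_k48 = arm(prof("none"), antibody = "k48"),
        hek_k63 = arm(prof("none"), antibody = "k63")),
      comparisons = list(c("hek_k48", "untransfected"),
                         c("hek_k63", "untransfected"))),
    fig5b = list(
      measure = "fold_enrichment", assay = "ip", timepoint = 3, replicates = 3,
      arms = list(
        xpd_het_k48 = arm(xpd("heterologous"), antibody = "k48"),
        xpd_het_k63 = arm(xpd("heterologous"), antibody = "k63"),
        xpd_hom_k48 = arm(xpd("homologous"), antibody = "k48"),
        xpd_hom_k63 = arm(xpd("homologous"), antibody = "k63")),
      comparisons = list(c("xpd_het_k48", "untransfected"),
                         c("xpd_het_k63", "untransfected"),
                         c("xpd_hom_k48", "untransfected"),
                         c("xpd_hom_k63", "untransfected"))),
    supp_xpa = list(
      measure = "percent_removal", assay = "kcl_sds", timepoint = 1, replicates = 3,
      arms = list(
        ht1080_wt_het = arm(prof("heterologous")),
        xpa_ko_het    = arm(xpd("heterologous")),
        xpa_ko_hom    = arm(xpd("homologous"))),
      comparisons = list(c("ht1080_wt_het", "untransfected"),
                         c("xpa_ko_het", "untransfected"),
                         c("xpa_ko_hom", "untransfected"))),
    supp_sprtn = list(
      measure = "percent_removal", assay = "kcl_sds", timepoint = 1, replicates = 3,
      arms = list(
        mef5_wt    = arm(prof("none")),
        mef7_sprtn = arm(prof("none", sprtn_deficient = TRUE))),
      comparisons = list(c("mef5_wt", "untransfected"),
                         c("mef7_sprtn", "untransfected"),
                         c("mef5_wt", "mef7_sprtn")))
  )
  out <- lib[ids]
  for (id in ids) out[[id]]$panel_id <- id
  out
}
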