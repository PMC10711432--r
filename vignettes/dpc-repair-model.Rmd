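---
title: "A stochastic state-machine model of DNA-protein crosslink repair and its qPCR readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic state-machine model of DNA-protein crosslink repair and its qPCR readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrepair)
```

## The biological system and the model

A DNA-protein crosslink (DPC) is a protein covalently trapped on DNA -- here,
the ~37 kDa glycosylase OGG1 fixed at a single defined site on a
double-stranded, non-replicating M13 plasmid and transfected into human
cells. Two canonical pathways can clear such a lesion: nucleotide excision
repair (NER), which cannot act on a full-sized protein adduct and needs the
crosslinked protein pre-processed to a small peptide, and homologous
recombination (HR), which needs an undamaged homologous donor molecule and
active Rad51. Ubiquitin signaling orchestrates the choice: the crosslinked
protein is rapidly K63-polyubiquitinated on recognition; in NER-proficient
cells it additionally acquires K48 chains that recruit the proteasome, which
degrades the protein and leaves a peptide adduct small enough for NER; in
NER-deficient cells no K48 chains appear, the K63 mark persists, and only a
homologous donor lets HR remove and repair the lesion.

`dpcrepair` encodes that orchestration as a continuous-time Markov chain
over six per-molecule states,

```
NASCENT -> K63_TAGGED -> K48_K63_TAGGED -> PROTEOLYZED -> NER_REPAIRED
                   \-> HR_REPAIRED
```

with `NER_REPAIRED` and `HR_REPAIRED` absorbing. The experimental condition
gates the edges: the K48, proteolysis and excision edges exist only when NER
is functional; the HR edge exists only with a homologous donor (a
heterologous donor is structurally identical to no donor); MG132 and B02
scale the proteolysis and HR rates by factors in [0, 1]; the
ubiquitination-deficient OGG1 variant (K341R) scales both ubiquitination
rates by a factor defaulting to 0.5, reflecting its roughly two-fold lower
ubiquitination -- the assays do not localize which conjugation step is
impaired, so both are scaled. SPRTN deficiency is a condition field that no
rate computation reads, deliberately encoding its observed irrelevance for
this replication-independent substrate.

Two consequences of this structure are exact, not statistical: without NER
and without a homologous donor the chain stalls in `K63_TAGGED` (repaired
fraction identically zero, K63 occupancy approaching 1), and no parameter of
the proteasome branch can influence an HR-only trajectory.

### Deliberate simplifications

* De-ubiquitination is not a separate transition. Whether the K63 chain is
  actively removed before HR or lost as a by-product of repair is
  experimentally undetermined; the model makes K63 loss implicit in entry to
  `HR_REPAIRED`. A consequence worth knowing: at intermediate times a
  NER-deficient population with a heterologous donor is almost entirely
  K63-tagged, so the model predicts strong pan-ubiquitin enrichment there,
  whereas the motivating measurements saw substantial pan-ubiquitin signal
  mainly under repair-permissive conditions. The model favors structural
  parsimony over reproducing that panel.
* `PROTEOLYZED` means protein-removed but strand-unrepaired. It counts
  toward the removal readout (KCl-SDS precipitation responds to the bulky
  protein, not the residual peptide) but not toward the repair readout. Both
  assumptions are single-switch options (`proteolyzed_precipitates`,
  `proteolyzed_retains_tags`) because the residual adduct's precipitation
  and ubiquitin status are not directly observed.
* Replication- and transcription-coupled repair, chromatin and SPRTN
  mechanics are out of scope; the substrate is a naked, non-replicating
  plasmid.

## Kinetic parameters

The assays behind this model report end-point percentages, not rate
constants, so the default `rate_set()` is a calibration, chosen once so that
the model's reference arms land near the benchmark readouts (roughly 45%
protein removal at 1 h in NER-proficient cells, and roughly 73% measured
repair at 3 h in NER-deficient cells with a homologous donor):

| parameter | default | meaning |
|---|---|---|
| `k63_rate` | 2.0 /h | initial K63 polyubiquitination (fast recognition) |
| `k48_rate` | 2.5 /h | K48 conjugation, NER-proficient only |
| `proteolysis_rate` | 3.0 /h | proteasomal degradation of the tagged protein |
| `ner_excision_rate` | 1.0 /h | excision of the residual peptide adduct |
| `hr_rate` | 0.75 /h | donor-dependent recombinational repair |
| `b02_factor`, `mg132_factor` | 0.25 | drug effects as multiplicative rate factors |
| `k341r_ub_factor` | 0.5 | variant effect on both ubiquitination rates |

Drugs are factors rather than hard zeros because the motivating experiments
observe roughly two-fold, not complete, reductions at the readout. All
values are per-hour and user-settable; nothing downstream assumes them.

## Propagation: exact and stochastic

`propagate_exact()` solves the master equation with the matrix exponential
(via the Matrix package); `simulate_gillespie()` runs the exact stochastic
simulation algorithm per molecule, vectorized. The two are mutual checks:
the test suite and the acceptance script verify total-variation agreement
below 0.02 at 10,000 molecules across random rate sets. Exact propagation
renormalizes away the ~1e-15 drift of the exponential; occupancy vectors are
validated to sum to 1 within 1e-9.

## The three forward-modelled readouts

All three assays reduce the state distribution to a scalar fraction, push it
through a template-abundance model, and read out threshold cycles with the
standard relation `ct = ct_reference - log(abundance)/log(efficiency)` plus
Gaussian noise (default sd 0.15 cycles), truncated below at cycle 1.
Analytically empty pools are floored at a pseudo-abundance of 1e-9 --
modelling late nonspecific amplification rather than a censored "no Ct",
keeping downstream arithmetic total while contributing less than 1e-6
percentage points to any estimate.

**Repair (SSPE-qPCR).** The sample splits into a reference tube (template
weight 1) and a tube given eight rounds of strand-specific pre-amplification
in which repaired templates gain a factor `gain` (default 8 = 2^3, matching
the estimator's normalization; eight ideal linear rounds would give nine
copies, and the discrepancy is deliberately exposed as the `gain`
parameter). Unrepaired templates pass through with weight `damaged_leak`.
The default `damaged_leak = 1` (present, un-amplified) makes the noise-free
measured repair `87.5 f` for true repaired fraction `f` after baseline
subtraction -- a baseline exists precisely because unrepaired templates
still amplify in the final qPCR, which is why the estimator subtracts a t0
measurement at all. The alternative chemistry `damaged_leak = 0` yields
`100 f`; both are supported and round-trip-tested.

**Removal (KCl-SDS-qPCR).** After restriction digestion, KCl/SDS
precipitates protein-crosslinked fragments. The supernatant abundance of the
crosslink-site fragment b relative to the distal control fragment c is
`r + (1 - r)(1 - capture_prob)` for removed fraction `r` (default capture
probability 0.98, nonspecific loss 0.02, both invented nuisance values). The
estimator maps the observed ratio through the unique affine transform
anchoring the pre-transfection (fully crosslinked) ratio to 0% and a
protein-free control to 100%; with a consistently measured baseline this
cancels the capture probability exactly, which is why the noise-free round
trip recovers `100 r` regardless of it.

**Enrichment (IP-qPCR).** An antibody captures the tagged fraction `u`
(pan-ubiquitin and K63-selective antibodies match K63-tagged states; the
K48-selective antibody matches only the doubly tagged state -- so pan
capture is always at least K48 capture) at efficiency 0.5 plus a nonspecific
background of 0.01; fold enrichment is the eluate b/c ratio normalized by
the saved input control's b/c ratio, so no specific capture reads as exactly 1.
The un-normalized eluate ratio is available as an option.

## Estimators and statistics

The estimators mirror the assay arithmetic: `delta_ct`, `percent_undamaged
= 2^dCt / 2^3 x 100`, `percent_repair` as a t0-subtracted difference,
`relative_abundance = efficiency^(ct_c - ct_b)`, the baseline-anchored
`percent_removal`, and input-normalized `fold_enrichment`. Estimates are
never clamped to [0, 100]: noise must be allowed to push them negative or
past 100, or the replicate t-tests would see a censored error structure. The
estimator's efficiency defaults to 2 independently of the simulator's, so
estimator bias under imperfect amplification efficiency can be studied
directly.

Replicates aggregate as mean and SEM (sample sd / sqrt(n), missing for
n = 1). Hypothesis tests are pooled-variance (homoscedastic) Student t-tests
with `n_a + n_b - 2` degrees of freedom, implemented directly and
cross-checked against `stats::t.test(var.equal = TRUE)` to 1e-9 in the test
suite. Sidedness follows the design rule of the underlying study: arms
compared to the untransfected input substrate are one-tailed (alternative:
the treated arm exceeds the baseline, which is the direction every such
comparison is asking about), arms compared to other transfected arms are
two-tailed. No multiple-testing correction is applied, matching the
per-panel raw p-values being emulated; the exact pairing of multi-bar panels
to printed p-values is ambiguous, so reports label every configured pairwise
test explicitly rather than guessing.

## The synthetic-data generator as a study design

`generate_scenario_dataset()` performs one fresh, independent pathway
simulation per (timepoint, replicate) -- each replicate emulates one whole
wet-lab repeat (fresh substrate, one transfection, one readout), which is
why Ct noise is independent across tubes and no replicate-level random
effect is modelled: the emulated error bars are SEMs over whole-experiment
repeats. Defaults are the study conditions: 3 replicates (5 for the
Rad51-inhibition panel), collection at 1 h for removal/enrichment panels and
3 h for repair panels, 10,000 molecules per replicate (large enough that
population sampling noise is small against Ct noise, small enough that a
full ten-panel report builds in seconds).

Seeding is single-sourced and deliberately arm-blind: child streams derive
from (master seed, timepoint index, replicate) but *not* from the scenario
identity, so all arms of a panel consume common random numbers. Two arms
whose generators coincide -- the SPRTN toggle anywhere, the MG132 toggle on
the HR arm -- therefore produce *identical* simulated values, making the
model's structural no-ops exact in every report rather than statistical.
This is a paired-simulation design choice; independent streams per arm would
only blur qualitative contrasts with noise.

What passing tests on these synthetic data do **not** show: the generator
draws Gaussian Ct noise with equal fragment efficiencies, no plate effects,
no melt-curve artifacts, no day-to-day biological variance, and no recovery
(HIRT) losses. Agreement here demonstrates the estimators invert the assumed
forward models and the model reproduces the qualitative repair logic -- not
that real qPCR data obey these error models.

## Numerical choices

* Empty pools: pseudo-abundance floor 1e-9 (see above); applied only when a
  pool is analytically empty.
* Exact propagation at `t = 0` short-circuits to the input (semigroup
  identity), and clamps negative round-off mass at 0 before renormalizing.
* Degenerate t-tests: zero pooled variance with equal means gives t = 0
  (one-tailed p 0.5, two-tailed 1.0); with unequal means the p-value is
  reported at the smallest positive double and flagged `degenerate` rather
  than reported as 0.
* Child seeds are mixed with a small multiplicative congruence kept below
  2^31 so they remain valid R integer seeds on all platforms.

## Reproducibility

Every simulation run writes a manifest (package version, seed, the full
resolved configuration, MD5 checksums of outputs); `reproduce_run()` re-runs
from the manifest alone and verifies byte-identity. Configurations are
strict-schema YAML: a mandatory seed, unknown keys rejected by name, every
default overridable. The `dpc_cli()` entry point (wrapped by
`exec/dpcrepair`) drives `simulate`, `quantify`, `report` and `recover` --
the last a round-trip parameter-recovery study across a grid of true
repaired fractions, used both as a user-facing diagnostic and in the
acceptance checks (noise-free recovery exact to 1e-6; at Ct noise sd 0.15
with 3 replicates the mean absolute error stays under 5 percentage points
across 20 seeds).
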