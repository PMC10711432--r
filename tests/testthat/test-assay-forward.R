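test_that("threshold-cycle relation matches its closed form", {
  qp <- noise_free_qpcr()
  expect_equal(ct_from_template(1, qp), 30)
  expect_equal(ct_from_template(8, qp), 27)  # log2(8) = 3 cycles earlier
  qp19 <- qpcr_params(efficiency = 1.9, ct_noise_sd = 0)
  expect_equal(ct_from_template(3, qp19), 30 - log(3) / log(1.9), tolerance = 1e-9)
  expect_error(ct_from_template(0, qp), "positive")
  expect_error(ct_from_template(-1, qp), "positive")
})

test_that("SSPE readout matches its closed form without noise", {
  qp <- noise_free_qpcr()
  # f = 1: pre-amplified tube gains the full factor of 8.
  cts <- sspe_readout(dist_with_repaired(1), sspe_params(), qp)
  expect_equal(delta_ct(cts[["ct_reference"]], cts[["ct_pre_amplified"]]), 3)
  # f = 0: both tubes hold the same template.
  cts <- sspe_readout(dist_with_repaired(0), sspe_params(), qp)
  expect_equal(delta_ct(cts[["ct_reference"]], cts[["ct_pre_amplified"]]), 0)
  # f = 0.5: (1-f) + 8f = 4.5.
  cts <- sspe_readout(dist_with_repaired(0.5), sspe_params(), qp)
  expect_equal(delta_ct(cts[["ct_reference"]], cts[["ct_pre_amplified"]]),
               log2(4.5), tolerance = 1e-9)
  # General grid, both chemistries, to 1e-9.
  for (leak in c(1, 0)) {
    sp <- sspe_params(damaged_leak = leak)
    for (f in seq(0.1, 1, by = 0.3)) {
      cts <- sspe_readout(dist_with_repaired(f), sp, qp)
      expect_equal(delta_ct(cts[["ct_reference"]], cts[["ct_pre_amplified"]]),
                   log2((1 - f) * leak + 8 * f), tolerance = 1e-9)
    }
  }
})

test_that("KCl-SDS readout matches its closed form without noise", {
  qp <- noise_free_qpcr()
  # Fully removed: fragments b and c survive the precipitation equally.
  cts <- kcl_sds_readout(dist_with_repaired(1), precip_params(), qp)
  expect_equal(cts[["ct_fragment_b"]], cts[["ct_fragment_c"]])
  # Nothing removed, complete capture: fragment b is analytically absent.
  cts <- kcl_sds_readout(dist_with_repaired(0), precip_params(capture_prob = 1), qp)
  expect_gt(cts[["ct_fragment_b"]], cts[["ct_fragment_c"]] + 10)
  # r = 0.5, capture 0.98, no nonspecific loss.
  cts <- kcl_sds_readout(dist_with_removed(0.5),
                         precip_params(capture_prob = 0.98, nonspecific_loss = 0), qp)
  expect_equal(cts[["ct_fragment_c"]] - cts[["ct_fragment_b"]], log2(0.51),
               tolerance = 1e-9)
  # A residual peptide adduct counts as removed by default, not if the
  # precipitation switch says it still precipitates.
  cts <- kcl_sds_readout(dist_with_removed(0.5), precip_params(1, 0), qp)
  expect_equal(2^(cts[["ct_fragment_c"]] - cts[["ct_fragment_b"]]), 0.5,
               tolerance = 1e-9)
  cts <- kcl_sds_readout(dist_with_removed(0.5), precip_params(1, 0), qp,
                         proteolyzed_precipitates = TRUE)
  expect_gt(cts[["ct_fragment_b"]], cts[["ct_fragment_c"]] + 10)
})

test_that("IP readout matches its closed form and antibody selectivity", {
  qp <- noise_free_qpcr()
  # No tagged material: both eluate fragments sit at background.
  cts <- ip_readout(dist_with_repaired(1), ip_params("pan_ub"), qp)
  expect_equal(cts[["ct_b_eluate"]], cts[["ct_c_eluate"]])
  # u = 0.5 with defaults: eluate ratio (0.5*0.5 + 0.01)/0.01 = 26.
  cts <- ip_readout(dist_with_k63(0.5), ip_params("pan_ub"), qp)
  expect_equal(2^(cts[["ct_c_eluate"]] - cts[["ct_b_eluate"]]), 26, tolerance = 1e-9)
  # K48-selective antibody sees nothing in a K63-only population.
  cts <- ip_readout(dist_with_k63(0.9), ip_params("k48"), qp)
  expect_equal(cts[["ct_b_eluate"]], cts[["ct_c_eluate"]])
  # The peptide adduct is tag-free by default; the switch restores capture.
  cts <- ip_readout(dist_with_removed(0.6), ip_params("pan_ub"), qp)
  expect_equal(cts[["ct_b_eluate"]], cts[["ct_c_eluate"]])
  cts <- ip_readout(dist_with_removed(0.6), ip_params("pan_ub"), qp,
                    proteolyzed_retains_tags = TRUE)
  expect_lt(cts[["ct_b_eluate"]], cts[["ct_c_eluate"]])
})

test_that("scenario datasets are reproducible and carry the right replication", {
  sc <- dpc_scenario("fig1a_homologous",
                     dpc_condition(ner_functional = FALSE, donor = "homologous"),
                     timepoints = 3, assays = "sspe", n_molecules = 2000)
  a <- generate_scenario_dataset(sc, 7)
  b <- generate_scenario_dataset(sc, 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_scenario_dataset(sc, 8)))

  # Five repeats give five rows per tube.
  sc5 <- dpc_scenario("repair5", dpc_condition(ner_functional = FALSE,
                                               donor = "homologous"),
                      timepoints = 3, replicates = 5, assays = "sspe",
                      n_molecules = 500)
  ds <- generate_scenario_dataset(sc5, 1)
  expect_equal(sum(ds$tube == "pre_amplified"), 5)
  expect_equal(sum(ds$tube == "reference"), 5)

  # No kinetics: the repair readout is centered at delta-Ct 0.
  sc0 <- dpc_scenario("inert", rates = rate_set(0, 0, 0, 0, 0),
                      timepoints = 3, assays = "sspe", n_molecules = 500)
  ds <- generate_scenario_dataset(sc0, 3)
  dct <- ds$ct[ds$tube == "reference"] - ds$ct[ds$tube == "pre_amplified"]
  expect_lt(abs(mean(dct)), 3 * 0.15 * sqrt(2) / sqrt(3))
})
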