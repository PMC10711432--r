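test_that("estimator formulas evaluate exactly", {
  expect_equal(delta_ct(25, 22), 3)
  expect_equal(delta_ct(25, 25), 0)
  expect_equal(delta_ct(22, 25), -3)  # noise can invert the tubes; not clamped

  expect_equal(percent_undamaged(3), 100)
  expect_equal(percent_undamaged(0), 12.5)
  expect_equal(percent_undamaged(2), 50)

  expect_equal(percent_repair(100, 12.5), 87.5)
  expect_equal(percent_repair(12.5, 12.5), 0)

  expect_equal(relative_abundance(25, 25), 1)
  expect_equal(relative_abundance(24, 25), 2)
  expect_equal(relative_abundance(23, 25, efficiency = 1.9), 1.9^2)
  expect_error(relative_abundance(25, 25, efficiency = 2.5), "efficiency")

  expect_equal(percent_removal(0.02, 0.02), 0)
  expect_equal(percent_removal(1, 0.02), 100)
  expect_error(percent_removal(0.5, 1, a_full = 1), "baseline")

  expect_equal(fold_enrichment(2, 2), 1)
  expect_error(fold_enrichment(1, 0), "a_input")
})

test_that("estimators are monotone in their inputs", {
  dct <- seq(-2, 5, by = 0.25)
  expect_true(all(diff(percent_undamaged(dct)) > 0))
  ct_b <- seq(20, 30, by = 0.5)
  expect_true(all(diff(relative_abundance(ct_b, 25)) < 0))
  # Fold enrichment is non-decreasing in the tagged fraction.
  qp <- noise_free_qpcr()
  fe <- vapply(seq(0, 1, by = 0.1), function(u) {
    cts <- ip_readout(dist_with_k63(u), ip_params("pan_ub"), qp)
    fold_enrichment(relative_abundance(cts[["ct_b_eluate"]], cts[["ct_c_eluate"]]),
                    relative_abundance(cts[["ct_b_input"]], cts[["ct_c_input"]]))
  }, numeric(1))
  expect_true(all(diff(fe) >= 0))
})

test_that("noise-free simulate-then-quantify round trips recover the truth", {
  qp <- noise_free_qpcr()
  # Repair, default chemistry (leak 1 -> 87.5 f) and leak 0 (-> 100 f).
  for (leak in c(1, 0)) {
    res <- recover_study(seq(0, 1, by = 0.1), noise_sd = 0, seed = 1,
                         sspe = sspe_params(damaged_leak = leak))
    expect_true(all(res$abs_error < 1e-6))
    expect_equal(res$true_percent_repair,
                 res$fraction * (if (leak == 1) 87.5 else 100))
  }
  # Removal: 100 r through the Ct table path.
  for (r in seq(0, 1, by = 0.2)) {
    cts <- kcl_sds_readout(dist_with_removed(r), precip_params(), qp)
    names(cts) <- c("b_supernatant", "c_supernatant")
    tab <- data.frame(sample_id = "s", scenario_id = "s", assay = "kcl_sds",
                      tube = names(cts), replicate = 1L, timepoint = 1,
                      ct = as.numeric(cts))
    est <- quantify_table(tab)$removal
    expect_equal(est$percent_removal, 100 * r, tolerance = 1e-6)
  }
  # Enrichment: (u c + b) / b.
  for (u in seq(0, 1, by = 0.25)) {
    cts <- ip_readout(dist_with_k63(u), ip_params("pan_ub"), qp)
    names(cts) <- paste("pan_ub", c("b_eluate", "c_eluate", "b_input", "c_input"),
                        sep = ".")
    tab <- data.frame(sample_id = "s", scenario_id = "s", assay = "ip",
                      tube = names(cts), replicate = 1L, timepoint = 1,
                      ct = as.numeric(cts))
    est <- quantify_table(tab)$enrichment
    expect_equal(est$fold_enrichment, (u * 0.5 + 0.01) / 0.01, tolerance = 1e-6)
  }
})

test_that("noisy repair estimates stay close to their noise-free values", {
  errs <- vapply(1:5, function(s) {
    mean(recover_study(seq(0, 1, by = 0.25), noise_sd = 0.15, seed = s,
                       replicates = 3)$abs_error)
  }, numeric(1))
  expect_lt(mean(errs), 5)
})

test_that("quantify_table enforces its schema and skips incomplete groups", {
  sc <- dpc_scenario("demo", dpc_condition(ner_functional = FALSE,
                                           donor = "homologous"),
                     timepoints = 3, assays = c("sspe", "kcl_sds"),
                     n_molecules = 500)
  ds <- generate_scenario_dataset(sc, 2)
  full <- quantify_table(ds)
  expect_equal(nrow(full$repair), 3)
  expect_equal(nrow(full$removal), 3)

  # Dropping one tube loses that replicate, with a warning.
  drop <- ds[!(ds$tube == "reference" & ds$replicate == 2), ]
  expect_warning(part <- quantify_table(drop), "missing tube")
  expect_equal(nrow(part$repair), 2)
  expect_false(2 %in% part$repair$replicate)

  # Duplicate keys are a schema error naming the row.
  expect_error(quantify_table(rbind(ds, ds[1, ])), "duplicate")
  # Empty input succeeds with empty outputs.
  empty <- quantify_table(ds[0, ])
  expect_equal(nrow(empty$repair), 0)
  expect_equal(nrow(empty$enrichment), 0)
})
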