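test_that("generator encodes condition gating and is well-formed", {
  conditions <- list(
    dpc_condition(),
    dpc_condition(ner_functional = FALSE, donor = "heterologous"),
    dpc_condition(ner_functional = FALSE, donor = "homologous"),
    dpc_condition(donor = "homologous", rad51_inhibited = TRUE),
    dpc_condition(proteasome_inhibited = TRUE),
    dpc_condition(ogg1_variant = "R341", donor = "homologous")
  )
  set.seed(42)
  for (cond in conditions) {
    for (rs in list(rate_set(), random_rate_set())) {
      Q <- build_generator(rs, cond)
      off <- Q; diag(off) <- 0
      expect_true(all(off >= 0))
      expect_true(all(abs(rowSums(Q)) < 1e-12))
      expect_true(all(Q[c("NER_REPAIRED", "HR_REPAIRED"), ] == 0))
    }
  }

  # NER-deficient, no homologous donor: the chain can only reach K63_TAGGED.
  Q <- build_generator(rate_set(),
                       dpc_condition(ner_functional = FALSE, donor = "heterologous"))
  off <- Q; diag(off) <- 0
  expect_identical(which(off != 0), which(outer(PATHWAY_STATES, PATHWAY_STATES,
    function(a, b) a == "NASCENT" & b == "K63_TAGGED")))

  # All rates 1, NER arm only: four edges on the linear path.
  Q <- build_generator(rate_set(k63_rate = 1, k48_rate = 1, proteolysis_rate = 1,
                                ner_excision_rate = 1, hr_rate = 1),
                       dpc_condition(donor = "none"))
  off <- Q; diag(off) <- 0
  expect_equal(sum(off != 0), 4)

  # Heterologous donor behaves exactly like no donor.
  expect_equal(
    unclass(build_generator(rate_set(), dpc_condition(donor = "none"))),
    unclass(build_generator(rate_set(), dpc_condition(donor = "heterologous"))))

  # The variant factor scales both ubiquitination edges.
  Qr <- build_generator(rate_set(k341r_ub_factor = 0.5),
                        dpc_condition(ogg1_variant = "R341", donor = "homologous"))
  Qk <- build_generator(rate_set(),
                        dpc_condition(ogg1_variant = "K341", donor = "homologous"))
  expect_equal(Qr["NASCENT", "K63_TAGGED"], 0.5 * Qk["NASCENT", "K63_TAGGED"])
  expect_equal(Qr["K63_TAGGED", "K48_K63_TAGGED"],
               0.5 * Qk["K63_TAGGED", "K48_K63_TAGGED"])
})

test_that("SPRTN deficiency never influences the generator", {
  set.seed(7)
  for (i in 1:5) {
    rs <- random_rate_set()
    for (ner in c(TRUE, FALSE)) for (donor in c("none", "homologous")) {
      a <- build_generator(rs, dpc_condition(ner, donor, sprtn_deficient = FALSE))
      b <- build_generator(rs, dpc_condition(ner, donor, sprtn_deficient = TRUE))
      expect_identical(a, b)
    }
  }
})

test_that("rate and condition validation rejects bad inputs", {
  expect_error(rate_set(k63_rate = -1), "k63_rate")
  expect_error(rate_set(b02_factor = 1.5), "b02_factor")
  expect_error(dpc_condition(rad51_inhibited = "yes"), "rad51_inhibited")
  expect_error(dpc_condition(donor = "plasmid"))
})

test_that("exact propagation matches closed forms", {
  # t = 0 is the identity of the semigroup.
  init <- state_distribution(c(NASCENT = 0.4, K63_TAGGED = 0.6))
  expect_equal(as.numeric(propagate_exact(build_generator(), 0, init)),
               as.numeric(init))

  # Two-state chain: p_K63(t) = 1 - exp(-k63 t).
  gen <- build_generator(rate_set(k63_rate = 1.7),
                         dpc_condition(ner_functional = FALSE, donor = "heterologous"))
  for (t in c(0.1, 0.5, 1, 3)) {
    p <- propagate_exact(gen, t)
    expect_equal(p[["K63_TAGGED"]], 1 - exp(-1.7 * t), tolerance = 1e-9)
    expect_equal(p[["NASCENT"]], exp(-1.7 * t), tolerance = 1e-9)
  }

  # Single-path chain with all rates equal: Poisson-stage (Erlang) occupancy.
  gen <- build_generator(rate_set(k63_rate = 1, k48_rate = 1, proteolysis_rate = 1,
                                  ner_excision_rate = 1),
                         dpc_condition(donor = "none"))
  for (t in c(0.5, 2, 4)) {
    p <- as.numeric(propagate_exact(gen, t))
    expect_equal(p[1:4], dpois(0:3, t), tolerance = 1e-9)
    expect_equal(p[5], 1 - ppois(3, t), tolerance = 1e-9)
  }

  expect_error(propagate_exact(build_generator(), Inf), "finite")
  expect_error(propagate_exact(build_generator(), -1), "finite")
})

test_that("propagation conserves probability and absorbing mass is monotone", {
  set.seed(11)
  for (i in 1:5) {
    gen <- build_generator(random_rate_set(), full_condition())
    grid <- seq(0, 6, by = 0.5)
    prev_rep <- -1; prev_rem <- -1
    for (t in grid) {
      p <- propagate_exact(gen, t)
      expect_lt(abs(sum(p) - 1), 1e-9)
      s <- population_summary(p)
      expect_gte(s[["repaired_fraction"]], prev_rep - 1e-12)
      expect_gte(s[["removed_fraction"]], prev_rem - 1e-12)
      prev_rep <- s[["repaired_fraction"]]
      prev_rem <- s[["removed_fraction"]]
    }
  }
})

test_that("Gillespie simulation is deterministic and agrees with exact propagation", {
  gen <- build_generator()
  a <- simulate_gillespie(gen, 1, 500, seed = 99)
  b <- simulate_gillespie(gen, 1, 500, seed = 99)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(sum(a), 500)

  # All rates zero: nothing moves.
  g0 <- build_generator(rate_set(0, 0, 0, 0, 0), dpc_condition())
  d0 <- simulate_gillespie(g0, 5, 200, seed = 1)
  expect_equal(d0[["NASCENT"]], 200)

  set.seed(23)
  for (i in 1:2) {
    gen <- build_generator(random_rate_set(), full_condition())
    d <- simulate_gillespie(gen, 1, 10000, seed = 1000 + i)
    expect_lt(tv_distance(d, propagate_exact(gen, 1)), 0.02)
  }
})

test_that("structural no-ops: MG132 without NER, and the stall without NER or donor", {
  rs <- rate_set()
  cond <- function(mg) dpc_condition(ner_functional = FALSE, donor = "heterologous",
                                     proteasome_inhibited = mg)
  expect_identical(build_generator(rs, cond(FALSE)), build_generator(rs, cond(TRUE)))
  a <- simulate_gillespie(build_generator(rs, cond(FALSE)), 2, 1000, seed = 5)
  b <- simulate_gillespie(build_generator(rs, cond(TRUE)), 2, 1000, seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))

  # Stall: no repair ever; K63 occupancy approaches 1.
  gen <- build_generator(rs, cond(FALSE))
  for (t in c(0.5, 2, 8)) {
    s <- population_summary(propagate_exact(gen, t))
    expect_equal(s[["repaired_fraction"]], 0)
  }
  late <- propagate_exact(gen, 1e4 / rs$k63_rate)
  expect_lt(abs(late[["K63_TAGGED"]] - 1), 1e-6)
})

test_that("population summary reads out the assay-relevant fractions", {
  s <- population_summary(state_distribution(c(NASCENT = 1)))
  expect_true(all(s == 0))
  s <- population_summary(state_distribution(c(PROTEOLYZED = 1)))
  expect_equal(s[["removed_fraction"]], 1)
  expect_equal(s[["repaired_fraction"]], 0)
  s <- population_summary(state_distribution(c(K63_TAGGED = 0.5, HR_REPAIRED = 0.5)))
  expect_equal(unname(s[c("pan_ub_fraction", "repaired_fraction", "removed_fraction")]),
               c(0.5, 0.5, 0.5))
  # K48-tagged states are a subset of K63-tagged states.
  set.seed(3)
  for (i in 1:20) {
    occ <- runif(6); occ <- occ / sum(occ)
    s <- population_summary(state_distribution(occ))
    expect_gte(s[["pan_ub_fraction"]], s[["k48_fraction"]])
  }
})
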