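# Shared fixtures: all inputs are built in code.

# A random but valid rate set (caller seeds the RNG).
random_rate_set <- function() {
  rate_set(
    k63_rate = runif(1, 0.5, 3), k48_rate = runif(1, 0.5, 3),
    proteolysis_rate = runif(1, 0.5, 3), ner_excision_rate = runif(1, 0.2, 2),
    hr_rate = runif(1, 0.2, 2), b02_factor = runif(1),
    mg132_factor = runif(1), k341r_ub_factor = runif(1)
  )
}

# Condition in which every model edge is active.
full_condition <- function() {
  dpc_condition(ner_functional = TRUE, donor = "homologous")
}

# Distribution with a given repaired fraction (mass split NASCENT/repaired).
dist_with_repaired <- function(f) {
  state_distribution(c(NASCENT = 1 - f, NER_REPAIRED = f))
}

# Distribution with a given removed-but-unrepaired fraction.
dist_with_removed <- function(r) {
  state_distribution(c(NASCENT = 1 - r, PROTEOLYZED = r))
}

# Distribution with a given K63-tagged (but not K48-tagged) fraction.
dist_with_k63 <- function(u) {
  state_distribution(c(NASCENT = 1 - u, K63_TAGGED = u))
}

noise_free_qpcr <- function() qpcr_params(ct_noise_sd = 0)
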