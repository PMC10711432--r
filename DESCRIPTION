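Package: dpcrepair
Title: Stochastic Modelling of DNA-Protein Crosslink Repair with qPCR Readout Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the repair of a site-specific DNA-protein crosslink (DPC) on a
    transfected plasmid as a six-state continuous-time Markov chain in which
    K63- and K48-linked polyubiquitination gate nucleotide excision repair
    (proteasome-dependent) and homologous recombination (donor-dependent) arms.
    Provides exact (matrix-exponential) and stochastic (Gillespie) propagation,
    forward simulators for three qPCR-based readouts (strand-specific
    pre-amplification repair assay, KCl-SDS precipitation removal assay, and
    linkage-selective immunoprecipitation enrichment), the corresponding
    delta-Ct estimators, replicate statistics with pooled-variance t-tests, a
    library of experimental scenario panels, and a reproducible command-line
    pipeline with seeded synthetic-data generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
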