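Package: tmekin
Title: Data-Driven Kinetics of the Colon Tumor Immune Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative-systems model of the colon cancer immune
    microenvironment: a 14-variable ordinary-differential-equation network
    of naive/helper/cytotoxic/regulatory T cells, dendritic cells,
    macrophages, cancer and necrotic cells, and five cytokine pools
    (HMGB1, carcinogenic interleukins, immunosuppressive agents,
    interferon-gamma, TGF-beta). Cluster-specific rate constants are
    derived by balancing production against loss at printed steady-state
    densities under a versioned assumption config, tumors are simulated
    from small-tumor initial conditions with a stiff integrator, and
    steady-state sensitivities of cancer density, total cell density and
    the convergence eigenvalue are computed by implicit differentiation
    and finite differences. A cohort stage maps immune-deconvolution
    fraction tables plus tumor dimensions to model variables, clusters
    patients by immune pattern with K-means, and extracts per-cluster
    steady states and initial conditions; a seeded generator produces
    synthetic cohorts with planted cluster structure so the whole
    pipeline runs end-to-end without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
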