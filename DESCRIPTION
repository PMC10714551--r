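Package: peripagen
Title: Multi-Locus Demographic Inference for Two-Deme Peripatric Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-locus population-genetic analysis of a pair of
    diverging populations (or varieties) sampled at phased nuclear loci and
    organellar sequence. Provides per-locus diversity summaries and
    neutrality tests (Tajima's D, Fu and Li's D* and F*, Fu's FS, Fay and
    Wu's H, multilocus HKA), AMOVA-based PhiST with permutation testing,
    site-frequency-spectrum construction, a two-deme structured-coalescent
    simulator with an event grammar covering founder/bottleneck/expansion
    scenario families and epoch-restricted migration, approximate Bayesian
    computation (rejection and logistic regression) for scenario choice,
    composite-likelihood fitting of scenarios to the joint site frequency
    spectrum with AIC comparison and parametric-bootstrap confidence
    intervals, and mutation-rate/time scaling utilities. A synthetic-data
    module generates study-shaped datasets for end-to-end exercise of the
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
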