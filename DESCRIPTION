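Package: megseqmem
Title: Simulation and Analysis of MEG Auditory Sequence Recognition Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recognition memory of auditory (musical)
    sequences with magnetoencephalography. Provides a synthetic-cohort
    simulator (spherical head geometry, analytic current-dipole forward
    model, condition- and band-specific source effects, behavioral
    responses), event-related-field preprocessing (zero-phase band-pass
    filtering, epoching, baseline correction, planar-gradiometer
    combination), sensor- and source-level mass-univariate statistics with
    cluster-based Monte-Carlo permutation correction, an LCMV beamformer
    inverse solution with a two-level GLM, n-gram models of melodic
    expectation yielding per-tone information content and entropy, and
    behavioral ANOVA with Bonferroni-corrected post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
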