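Package: pelvitherm
Title: Accuracy Benchmarking and Imaging-Based Session Selection for
    PRFS MR Thermometry in Pelvic Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating proton resonance frequency shift (PRFS)
    magnetic-resonance thermometry during deep pelvic hyperthermia.
    Implements the full processing chain (phase-difference temperature
    maps, low-SNR masking, fat-referenced B0 drift correction,
    optimisation-based outlier exclusion and ROI averaging), benchmarks
    the reconstructed temperatures against intraluminal probe traces
    (accuracy, temporal precision, bias), computes imaging-based session
    features (Jaccard air-motion coefficient, air and fat volume, minimum
    air-to-ROI distance) and evaluates them as predictors of acceptable
    thermometry via ROC analysis with resampling-based inference. A
    synthetic-session generator emulates the clinical acquisition so the
    whole chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
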