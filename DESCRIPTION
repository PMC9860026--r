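Package: met2star
Title: Monopolar Versus Bipolar Multi-Echo GRE Readouts for T2* Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing monopolar and bipolar readout gradients in
    multi-echo gradient-echo (GRE) T2* relaxometry. Models echo-train timing
    for both readout polarities, simulates spoiled-GRE digital-phantom
    magnitude images with Rician noise, fits per-voxel mono-exponential T2*
    under a Rician likelihood with iterative correction of parity-dependent
    amplitude modulation, predicts estimator precision from the Fisher
    information (Cramer-Rao lower bound) under Rician or Gaussian noise, and
    orchestrates flip-angle/TR, TE-range, echo-spacing, and bandwidth sweep
    experiments that tabulate accuracy and precision for both readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
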