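Package: ufscreen
Title: Affinity Ultrafiltration-HPLC Screening with Competitive Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for affinity-based ultrafiltration
    liquid-chromatography screens of multi-target systems. Reads
    three-condition chromatograms (blank, experimental, probe-blocked
    control), performs baseline correction, peak detection, integration and
    cross-run peak matching, and computes the signal-to-noise (S/N) and
    specific signal-to-noise (S-S/N) ratios used to call target-specific
    ligands. Includes a mass-action competitive-binding equilibrium solver
    and a Gaussian-peak chromatogram synthesizer so that every stage of the
    pipeline can be exercised on simulated screens with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
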