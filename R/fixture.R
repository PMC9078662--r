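#' Peak areas of the Danshen worked example
#'
#' True per-run peak areas (mAU.min) for the four major tanshinones of a
#' Danshen ethanol extract screened against CYP1A2, CYP2C9 and CYP3A4.
#' The blank-run area of every compound is normalised to 1.0 mAU.min; the
#' experimental and control areas are set so that the screen ratios equal
#' the published values for this extract (S/N 1.16, 1.88, 1.33, 2.34 and
#' the matching per-target S-S/N). Only the ratios are data-anchored; the
#' absolute scale, retention times and peak shapes are simulation choices.
#'
#' @return Data frame with columns `compound_id`, `reference_rt`, `A_b`,
#'   `A_a` and `A_c_<target>` for the three CYP targets.
#' @export
danshen4_areas <- function() {
  data.frame(
    compound_id = c("dihydrotanshinone", "tanshinone_I",
                    "cryptotanshinone", "tanshinone_IIA"),
    reference_rt = c(78.4, 84.1, 88.9, 96.2),
    A_b = c(1.00, 1.00, 1.00, 1.00),
    A_a = c(1.16, 1.88, 1.33, 2.34),
    A_c_CYP1A2 = c(1.07, 1.84, 0.82, 1.72),
    A_c_CYP2C9 = c(1.23, 1.72, 0.86, 1.72),
    A_c_CYP3A4 = c(1.37, 1.75, 0.79, 1.95),
    stringsAsFactors = FALSE
  )
}

# Matrix peaks present with identical area in all five runs (retention
# times and areas are arbitrary but fixed).
danshen4_background <- function() {
  data.frame(rt = c(12.3, 24.7, 33.5, 46.2, 58.8, 69.4),
             area = c(1.8, 0.9, 2.5, 1.2, 0.7, 1.5))
}

#' Write the Danshen worked-example dataset
#'
#' Synthesizes the five chromatograms of the three-target Danshen screen
#' (blank, experimental, and one probe-blocked control per CYP target) on a
#' 0-105 min grid sampled every 0.01 min, with Gaussian peaks of width
#' 0.15 min, 0.05 mAU detector noise, 2 mAU linear drift and a fixed noise
#' seed, plus six background matrix peaks with identical areas in every
#' run. Also writes the design manifest, the four-compound panel, and the
#' expected-ratio table. Byte-identical across calls with the same seed.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer noise seed (default 1, the fixture's defining
#'   value; run `k` draws with `seed * 10 + k`).
#' @return Invisibly, a list with `manifest`, `panel`, `expected` (file
#'   paths), `files` (chromatogram paths by run id), `areas`
#'   (the true area table) and `design`.
#' @export
danshen4_fixture <- function(outdir, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- danshen4_areas()
  targets <- c("CYP1A2", "CYP2C9", "CYP3A4")
  probes <- c(CYP1A2 = "alpha-naphthoflavone", CYP2C9 = "sulfaphenazole",
              CYP3A4 = "ketoconazole")
  design <- standard_design(targets, probes, rt_tolerance = 0.2)
  rts <- stats::setNames(tab$reference_rt, tab$compound_id)
  area_of_run <- function(run_id, group, control_target) {
    switch(group,
           blank = tab$A_b,
           experimental = tab$A_a,
           control = tab[[paste0("A_c_", control_target)]])
  }
  runs <- design$runs
  files <- character(nrow(runs))
  names(files) <- runs$run_id
  for (k in seq_len(nrow(runs))) {
    areas <- stats::setNames(
      area_of_run(runs$run_id[k], runs$group[k], runs$control_target[k]),
      tab$compound_id)
    chrom <- synthesize_chromatogram(
      areas, rts, sigma = 0.15, background = danshen4_background(),
      noise_sd = 0.05, drift = 2, seed = seed * 10 + k,
      t_max = 105, dt = 0.01, run_id = runs$run_id[k], group = runs$group[k],
      control_target = runs$control_target[k])
    files[k] <- file.path(outdir, paste0(runs$run_id[k], ".csv"))
    write_chromatogram(chrom, files[k])
  }
  design$runs$file <- basename(files[design$runs$run_id])
  panel_path <- file.path(outdir, "panel.csv")
  write_panel(compound_panel(tab[c("compound_id", "reference_rt")],
                             rt_tolerance = 0.2), panel_path)
  manifest_path <- file.path(outdir, "manifest.yaml")
  write_design(design, manifest_path, panel = panel_path)
  expected_path <- file.path(outdir, "expected_ratios.csv")
  expected <- data.frame(
    compound_id = tab$compound_id,
    sn = tab$A_a / tab$A_b,
    ssn_CYP1A2 = (tab$A_a - tab$A_c_CYP1A2) / tab$A_b,
    ssn_CYP2C9 = (tab$A_a - tab$A_c_CYP2C9) / tab$A_b,
    ssn_CYP3A4 = (tab$A_a - tab$A_c_CYP3A4) / tab$A_b,
    stringsAsFactors = FALSE
  )
  utils::write.csv(expected, expected_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest_path, panel = panel_path,
                 expected = expected_path, files = files, areas = tab,
                 design = design))
}
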