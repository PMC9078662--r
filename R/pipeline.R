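#' Run the full screening pipeline on a set of chromatograms
#'
#' Detects and integrates peaks in every run, matches them to the compound
#' panel, and scores the screen: S/N, per-target S-S/N, and the two-criterion
#' specific-ligand calls.
#'
#' @param design A [screen_design()] whose `runs` carry a `file` column of
#'   chromatogram paths (e.g. from [read_design()] on a manifest).
#' @param panel A [compound_panel()].
#' @param window Baseline window in minutes (see [estimate_baseline()]).
#' @param min_snr Peak-detection threshold in noise units (see
#'   [detect_peaks()]).
#' @param digits Precision at which the selection criteria are applied (see
#'   [classify_ligand()]).
#' @return A list with `peak_tables` (named list of [peak_table()]),
#'   `triples` (from [match_peaks()]) and `scores` (a `screen_scores`
#'   object from [score_screen()]).
#' @export
run_screen <- function(design, panel, window = 2, min_snr = 5, digits = 2) {
  stopifnot(inherits(design, "screen_design"), inherits(panel, "compound_panel"))
  if (!"file" %in% names(design$runs) || any(is.na(design$runs$file))) {
    stop("every design run needs a chromatogram file path", call. = FALSE)
  }
  tables <- list()
  for (k in seq_len(nrow(design$runs))) {
    r <- design$runs[k, ]
    if (!file.exists(r$file)) {
      stop(sprintf("chromatogram file missing for run '%s': %s", r$run_id, r$file),
           call. = FALSE)
    }
    chrom <- read_chromatogram(r$file, run_id = r$run_id, group = r$group,
                               control_target = r$control_target)
    tables[[r$run_id]] <- detect_peaks(chrom, min_snr = min_snr, window = window)
  }
  triples <- match_peaks(tables, panel, design)
  scores <- score_screen(triples, design, digits = digits)
  list(peak_tables = tables, triples = triples, scores = scores)
}

#' Score a screen described by a manifest file
#'
#' Convenience wrapper: reads the manifest ([read_design()]) and its panel,
#' runs [run_screen()], and optionally writes the peak tables, area
#' triples, scores and per-target plot data to an output directory.
#'
#' @param manifest Path to a YAML/JSON screen manifest with run `file`
#'   entries and a `panel` path.
#' @param outdir Optional output directory for report files.
#' @inheritParams run_screen
#' @return The [run_screen()] result, invisibly when `outdir` is given.
#' @export
score_manifest <- function(manifest, outdir = NULL, window = 2, min_snr = 5,
                           digits = 2) {
  design <- read_design(manifest)
  panel_path <- attr(design, "panel")
  if (is.null(panel_path)) {
    stop("manifest does not name a compound panel", call. = FALSE)
  }
  panel <- read_panel(panel_path, rt_tolerance = design$rt_tolerance)
  res <- run_screen(design, panel, window = window, min_snr = min_snr,
                    digits = digits)
  if (is.null(outdir)) return(res)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$peak_tables)) {
    write_peak_table(res$peak_tables[[id]],
                     file.path(outdir, paste0("peaks_", id, ".csv")))
  }
  utils::write.csv(as.data.frame(res$triples),
                   file.path(outdir, "area_triples.csv"), row.names = FALSE)
  utils::write.csv(res$scores$scores, file.path(outdir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$scores$calls, file.path(outdir, "calls.csv"),
                   row.names = FALSE)
  for (tg in design$targets) {
    utils::write.csv(screen_plot_data(res$scores, tg),
                     file.path(outdir, paste0("plot_data_", tg, ".csv")),
                     row.names = FALSE)
  }
  invisible(res)
}
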