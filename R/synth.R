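# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a chromatogram from peak areas
#'
#' The trace is a sum of Gaussian peaks (each with the requested area and a
#' common width), a linear baseline drift, and i.i.d. Gaussian detector
#' noise: `signal(t) = sum_k area_k / (sigma sqrt(2 pi)) *
#' exp(-(t - rt_k)^2 / (2 sigma^2)) + drift * t / t_max + noise`.
#' Deterministic for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param areas Named numeric vector of peak areas (mAU.min, >= 0); names
#'   are compound ids.
#' @param rts Named numeric vector of apex retention times (minutes), same
#'   names as `areas`, inside the time grid.
#' @param sigma Common Gaussian peak width (minutes); must be at least 5
#'   sampling intervals so peaks are resolvable on the grid.
#' @param background Optional data frame with columns `rt`, `area`:
#'   additional matrix peaks present identically in every run.
#' @param noise_sd Detector noise standard deviation (mAU).
#' @param drift Linear baseline rise over the whole run (mAU).
#' @param seed Integer seed for the noise draw (`NULL` for no seeding).
#' @param t_max Run length in minutes (grid spans 0 to `t_max`).
#' @param dt Sampling interval in minutes.
#' @inheritParams chromatogram
#' @return A [chromatogram()].
#' @export
synthesize_chromatogram <- function(areas, rts, sigma = 0.15, background = NULL,
                                    noise_sd = 0, drift = 0, seed = NULL,
                                    t_max = 105, dt = 0.01,
                                    run_id = "synthetic", group = "blank",
                                    control_target = NA_character_) {
  areas <- c(areas)
  rts <- rts[names(areas)]
  if (any(is.na(rts))) stop("every area needs a retention time", call. = FALSE)
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  if (!is.null(background) && nrow(background)) {
    areas <- c(areas, background$area)
    rts <- c(rts, background$rt)
  }
  if (sigma < 5 * dt) {
    stop("sigma must be at least 5 sampling intervals", call. = FALSE)
  }
  time <- seq(0, t_max, by = dt)
  if (length(rts) && (min(rts) < 0 || max(rts) > t_max)) {
    stop("retention time outside the grid", call. = FALSE)
  }
  signal <- drift * time / t_max
  for (k in seq_along(areas)) {
    if (areas[k] == 0) next
    signal <- signal + areas[k] / (sigma * sqrt(2 * pi)) *
      exp(-(time - rts[k])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
  }
  chromatogram(time, signal, run_id = run_id, group = group,
               control_target = control_target)
}

#' Generate a complete simulated screen dataset
#'
#' Runs the equilibrium model under every condition of the design, converts
#' retained amounts to true peak areas ([simulate_retentate()]), and
#' synthesizes one chromatogram file per run. Also writes the design
#' manifest, the compound panel, and a ground-truth table with the model's
#' noiseless S/N, per-target S-S/N and the true specificity labels
#' ([model_truth()]). Changing `seed` changes the detector noise only, not
#' the underlying true areas.
#'
#' @param system A [binding_system()].
#' @param design A [screen_design()] whose targets are the system's enzyme
#'   ids.
#' @param outdir Output directory (created if needed).
#' @inheritParams synthesize_chromatogram
#' @param seed Integer master seed; run `k` uses `seed * 100 + k` for its
#'   noise draw.
#' @return Invisibly, a list with `manifest`, `panel`, `truth` (file
#'   paths), `files` (chromatogram paths by run_id) and `truth_table`.
#' @export
generate_screen_dataset <- function(system, design, outdir, sigma = 0.15,
                                    background = NULL, noise_sd = 0.05,
                                    drift = 2, seed = 1, t_max = 105, dt = 0.01) {
  stopifnot(inherits(system, "binding_system"), inherits(design, "screen_design"))
  if (!setequal(design$targets, system$enzymes$enzyme_id)) {
    stop("design targets must match the system's enzymes", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  runs <- design$runs
  files <- character(nrow(runs))
  names(files) <- runs$run_id
  for (k in seq_len(nrow(runs))) {
    grp <- runs$group[k]
    tgt <- runs$control_target[k]
    ret <- simulate_retentate(system,
                              condition = grp,
                              target = if (grp == "control") tgt else NULL)
    areas <- stats::setNames(ret$area, ret$ligand_id)
    rts <- stats::setNames(ret$reference_rt, ret$ligand_id)
    chrom <- synthesize_chromatogram(
      areas, rts, sigma = sigma, background = background, noise_sd = noise_sd,
      drift = drift, seed = if (is.null(seed)) NULL else seed * 100 + k,
      t_max = t_max, dt = dt, run_id = runs$run_id[k], group = grp,
      control_target = if (grp == "control") tgt else NA_character_)
    files[k] <- file.path(outdir, paste0(runs$run_id[k], ".csv"))
    write_chromatogram(chrom, files[k])
  }
  design$runs$file <- basename(files[design$runs$run_id])
  panel_path <- file.path(outdir, "panel.csv")
  write_panel(compound_panel(
    data.frame(compound_id = system$ligands$ligand_id,
               reference_rt = system$ligands$reference_rt),
    rt_tolerance = design$rt_tolerance), panel_path)
  manifest_path <- file.path(outdir, "manifest.yaml")
  write_design(design, manifest_path, panel = panel_path)
  truth <- model_truth(system)
  truth_path <- file.path(outdir, "ground_truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest_path, panel = panel_path,
                 truth = truth_path, files = files, truth_table = truth))
}

#' Demonstration binding system
#'
#' A compact three-enzyme system exercising every qualitative behaviour the
#' screen distinguishes: a two-target orthosteric binder, a single-target
#' orthosteric binder, an allosteric binder (high affinity but not
#' displaceable by the probe), and a non-binder retained only by the
#' membrane. No two orthosteric ligands share an enzyme, so displacing one
#' ligand in a control run cannot indirectly alter another ligand's bound
#' pool and each compound-target pair has an unambiguous expected call.
#' Concentrations follow the incubation scale of the assay: ~1 uM enzyme
#' per isoform, ligand totals of a few uM (an extract at 0.1 mg/mL),
#' probes at 500 uM -- far above their 0.1 uM dissociation constants, so
#' controls block the orthosteric site essentially completely.
#'
#' @return A [binding_system()].
#' @export
demo_system <- function() {
  enzymes <- data.frame(enzyme_id = c("E1", "E2", "E3"),
                        total_conc = c(1, 1, 1))
  ligands <- data.frame(
    ligand_id = c("lig_multi", "lig_single", "lig_allo", "lig_none"),
    total_conc = c(5, 3, 4, 6),
    response_factor = c(8, 16, 12, 10),
    nonspecific_fraction = c(0.20, 0.15, 0.18, 0.15),
    reference_rt = c(6, 11, 16, 21),
    stringsAsFactors = FALSE
  )
  affinities <- data.frame(
    ligand_id = c("lig_multi", "lig_multi", "lig_single", "lig_allo"),
    enzyme_id = c("E1", "E2", "E3", "E2"),
    kd = c(0.5, 0.8, 0.2, 0.3),
    site = c("orthosteric", "orthosteric", "orthosteric", "allosteric"),
    stringsAsFactors = FALSE
  )
  probes <- data.frame(enzyme_id = c("E1", "E2", "E3"),
                       probe_id = c("probe1", "probe2", "probe3"),
                       total_conc = c(500, 500, 500),
                       kd = c(0.1, 0.1, 0.1),
                       stringsAsFactors = FALSE)
  binding_system(enzymes, ligands, affinities, probes)
}

#' Standard three-condition design for a set of targets
#'
#' One blank run, one experimental run and one probe-blocked control run
#' per target, with conventional run ids.
#'
#' @param targets Character vector of target ids.
#' @param probes Named character vector target -> probe name (defaults to
#'   `probe_<target>`).
#' @inheritParams screen_design
#' @return A [screen_design()].
#' @export
standard_design <- function(targets, probes = NULL, rt_tolerance = 0.2) {
  if (is.null(probes)) {
    probes <- stats::setNames(paste0("probe_", targets), targets)
  }
  runs <- data.frame(
    run_id = c("blank", "experimental", paste0("control_", targets)),
    group = c("blank", "experimental", rep("control", length(targets))),
    control_target = c(NA_character_, NA_character_, targets),
    stringsAsFactors = FALSE
  )
  screen_design(targets, probes, runs, rt_tolerance = rt_tolerance)
}
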