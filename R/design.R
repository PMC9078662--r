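#' Construct a screen design
#'
#' The design binds runs to their roles in the three-condition screen:
#' exactly one blank run (no enzyme source), exactly one experimental run
#' (with the enzyme source), and exactly one probe-blocked control run per
#' target. Every target must have a named competitive probe.
#'
#' @param targets Character vector of target identifiers
#'   (e.g. `c("CYP1A2", "CYP2C9", "CYP3A4")`).
#' @param probes Named character vector mapping each target to its
#'   competitive probe compound.
#' @param runs Data frame with columns `run_id`, `group` and
#'   `control_target` (`NA` except for control runs). An optional `file`
#'   column carries the chromatogram path for each run.
#' @param rt_tolerance Retention-time matching tolerance in minutes used
#'   downstream when peaks are matched across runs (default 0.2).
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(targets, probes, runs, rt_tolerance = 0.2) {
  targets <- as.character(targets)
  if (length(targets) == 0L) stop("at least one target is required", call. = FALSE)
  if (anyDuplicated(targets)) stop("duplicate target identifiers", call. = FALSE)
  if (is.null(names(probes)) || !setequal(names(probes), targets)) {
    stop("probes must be a named vector with exactly one probe per target",
         call. = FALSE)
  }
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  if (!all(c("run_id", "group") %in% names(runs))) {
    stop("runs must have run_id and group columns", call. = FALSE)
  }
  if (!"control_target" %in% names(runs)) runs$control_target <- NA_character_
  runs$run_id <- as.character(runs$run_id)
  runs$group <- as.character(runs$group)
  runs$control_target <- as.character(runs$control_target)
  runs$control_target[!is.na(runs$control_target) & !nzchar(runs$control_target)] <- NA_character_
  if (anyDuplicated(runs$run_id)) stop("run_ids must be unique", call. = FALSE)
  bad_group <- setdiff(unique(runs$group), c("blank", "experimental", "control"))
  if (length(bad_group)) {
    stop(sprintf("unknown group label '%s'", bad_group[1L]), call. = FALSE)
  }
  if (sum(runs$group == "blank") != 1L) {
    stop("exactly one blank run required", call. = FALSE)
  }
  if (sum(runs$group == "experimental") != 1L) {
    stop("exactly one experimental run required", call. = FALSE)
  }
  ctrl <- runs[runs$group == "control", , drop = FALSE]
  if (any(is.na(ctrl$control_target))) {
    stop("every control run must name its control_target", call. = FALSE)
  }
  if (any(!is.na(runs$control_target[runs$group != "control"]))) {
    stop("control_target is only meaningful for control runs", call. = FALSE)
  }
  unknown <- setdiff(ctrl$control_target, targets)
  if (length(unknown)) {
    stop(sprintf("control run names unknown target '%s'", unknown[1L]), call. = FALSE)
  }
  counts <- table(factor(ctrl$control_target, levels = targets))
  if (any(counts != 1L)) {
    off <- names(counts)[counts != 1L][1L]
    stop(sprintf("exactly one control run required per target ('%s' has %d)",
                 off, counts[[off]]), call. = FALSE)
  }
  if (!(rt_tolerance > 0)) stop("rt_tolerance must be positive", call. = FALSE)
  structure(
    list(targets = targets, probes = probes[targets], runs = runs,
         rt_tolerance = rt_tolerance),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("<screen_design> %d targets (%s), %d runs, rt_tolerance = %g min\n",
              length(x$targets), paste(x$targets, collapse = ", "),
              nrow(x$runs), x$rt_tolerance))
  invisible(x)
}

#' Read a screen design manifest
#'
#' Manifests are YAML or JSON (chosen by file extension) with keys
#' `targets`, `probes` (map target to probe name), `runs` (list of run
#' records with `run_id`, `group`, optional `control_target` and `file`),
#' and optional `rt_tolerance` and `panel` (path to a compound panel CSV).
#' Relative `file`/`panel` paths are resolved against the manifest's
#' directory.
#'
#' @param path Path to the manifest file.
#' @return A validated [screen_design()]; if the manifest carries file
#'   paths they are available in `$runs$file`, and a panel path in
#'   `attr(design, "panel")`.
#' @export
read_design <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$targets) || is.null(raw$probes) || is.null(raw$runs)) {
    stop("manifest must define targets, probes and runs", call. = FALSE)
  }
  runs <- do.call(rbind, lapply(raw$runs, function(r) {
    data.frame(run_id = as.character(r$run_id %||% NA_character_),
               group = as.character(r$group %||% NA_character_),
               control_target = as.character(r$control_target %||% NA_character_),
               file = as.character(r$file %||% NA_character_),
               stringsAsFactors = FALSE)
  }))
  base <- dirname(path)
  rel <- !is.na(runs$file) & !grepl("^(/|[A-Za-z]:)", runs$file)
  runs$file[rel] <- file.path(base, runs$file[rel])
  design <- screen_design(
    targets = unlist(raw$targets),
    probes = unlist(raw$probes),
    runs = runs,
    rt_tolerance = raw$rt_tolerance %||% 0.2
  )
  if (!is.null(raw$panel)) {
    panel <- as.character(raw$panel)
    if (!grepl("^(/|[A-Za-z]:)", panel)) panel <- file.path(base, panel)
    attr(design, "panel") <- panel
  }
  design
}

#' Write a screen design manifest
#'
#' @param design A [screen_design()].
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @param panel Optional panel file path recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, panel = NULL) {
  stopifnot(inherits(design, "screen_design"))
  runs <- lapply(seq_len(nrow(design$runs)), function(i) {
    r <- design$runs[i, ]
    out <- list(run_id = r$run_id, group = r$group)
    if (!is.na(r$control_target)) out$control_target <- r$control_target
    if (!is.null(r$file) && !is.na(r$file)) out$file <- basename(r$file)
    out
  })
  obj <- list(
    targets = as.list(design$targets),
    probes = as.list(design$probes),
    rt_tolerance = design$rt_tolerance,
    runs = runs
  )
  if (!is.null(panel)) obj$panel <- basename(panel)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
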