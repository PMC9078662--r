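#' Construct a chromatogram
#'
#' A chromatogram is a uniformly sampled detector trace from one
#' ultrafiltration run, together with the run's role in the screen design:
#' `blank` (incubated without the enzyme source), `experimental` (incubated
#' with the enzyme source) or `control` (enzyme source with the named
#' target's active site pre-blocked by its competitive probe).
#'
#' @param time Numeric vector of retention times in minutes. Must be strictly
#'   increasing and uniformly spaced (to within 1e-9 min).
#' @param signal Numeric vector of detector response in mAU, same length as
#'   `time` (at least 2 samples).
#' @param run_id Character scalar identifying the run.
#' @param group One of `"blank"`, `"experimental"`, `"control"`.
#' @param control_target Target identifier whose probe was used to block the
#'   enzyme in this run. Required iff `group = "control"`.
#' @return An object of class `chromatogram`: a list with fields `run_id`,
#'   `group`, `control_target`, `time`, `signal` and `sampling_interval`
#'   (minutes).
#' @examples
#' chrom <- chromatogram(seq(0, 1, by = 0.01), rnorm(101, 0, 0.01), "demo", "blank")
#' chrom$sampling_interval
#' @export
chromatogram <- function(time, signal, run_id,
                         group = c("blank", "experimental", "control"),
                         control_target = NA_character_) {
  group <- match.arg(group)
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal)) {
    stop("time and signal must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a chromatogram needs at least 2 samples", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("non-monotone time at sample %d", bad), call. = FALSE)
  }
  interval <- stats::median(dt)
  if (max(abs(dt - interval)) > 1e-9) {
    stop("time grid is not uniform (tolerance 1e-9 min); resampling is not supported",
         call. = FALSE)
  }
  has_target <- !is.na(control_target) && nzchar(control_target)
  if (group == "control" && !has_target) {
    stop("control runs require a control_target", call. = FALSE)
  }
  if (group != "control" && has_target) {
    stop("control_target is only meaningful for control runs", call. = FALSE)
  }
  structure(
    list(
      run_id = as.character(run_id),
      group = group,
      control_target = if (group == "control") as.character(control_target) else NA_character_,
      time = time,
      signal = signal,
      sampling_interval = interval
    ),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  tgt <- if (!is.na(x$control_target)) paste0(" [", x$control_target, "]") else ""
  cat(sprintf("<chromatogram> run '%s' (%s%s): %d samples, %.4g-%.4g min, dt = %g min\n",
              x$run_id, x$group, tgt, length(x$time),
              x$time[1], x$time[length(x$time)], x$sampling_interval))
  invisible(x)
}

#' Read a chromatogram from a delimited text file
#'
#' Files are two-column (time in minutes, signal in mAU) comma- or
#' tab-separated text; the delimiter is auto-detected. Lines starting with
#' `#` and blank lines are skipped, and a single non-numeric header line is
#' tolerated. Non-uniform time grids are rejected, not resampled.
#'
#' @param path Path to the file.
#' @inheritParams chromatogram
#' @return A validated [chromatogram()].
#' @export
read_chromatogram <- function(path, run_id, group, control_target = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop(sprintf("'%s': no data lines", path), call. = FALSE)
  }
  sep <- if (grepl("\t", lines[idx[1L]])) "\t" else ","
  parts <- strsplit(lines[idx], sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(parts[[1L]][1L])))
  if (is.na(first)) {        # header line
    idx <- idx[-1L]
    parts <- parts[-1L]
  }
  if (length(idx) < 2L) {
    stop(sprintf("'%s': fewer than 2 samples", path), call. = FALSE)
  }
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    stop(sprintf("'%s': malformed row at line %d", path, idx[which(nfield < 2L)[1L]]),
         call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 1L))))
  signal <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2L))))
  bad <- which(is.na(time) | is.na(signal))
  if (length(bad)) {
    stop(sprintf("'%s': non-numeric value at line %d", path, idx[bad[1L]]), call. = FALSE)
  }
  mono <- diff(time) <= 0
  if (any(mono)) {
    stop(sprintf("'%s': non-monotone time at line %d", path, idx[which(mono)[1L] + 1L]),
         call. = FALSE)
  }
  chromatogram(time, signal, run_id = run_id, group = group,
               control_target = control_target)
}

#' Write a chromatogram to a CSV file
#'
#' Writes a `time,signal` header and full-precision values so that
#' `read_chromatogram()` round-trips the object exactly.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time,signal", con)
  writeLines(paste(format(chrom$time, digits = 15, trim = TRUE, scientific = FALSE),
                   format(chrom$signal, digits = 15, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}
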