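#' Construct a peak table
#'
#' Detected, baseline-corrected peaks from a single run, sorted by apex
#' retention time with non-overlapping integration intervals.
#'
#' @param peaks Data frame with columns `apex_rt`, `start_rt`, `end_rt`
#'   (minutes), `height` (mAU) and `area` (mAU.min). May have zero rows.
#' @param run_id,group,control_target Run metadata, as in [chromatogram()].
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(peaks, run_id, group, control_target = NA_character_) {
  cols <- c("apex_rt", "start_rt", "end_rt", "height", "area")
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) {
    peaks <- data.frame(apex_rt = numeric(0), start_rt = numeric(0),
                        end_rt = numeric(0), height = numeric(0),
                        area = numeric(0))
  }
  if (!all(cols %in% names(peaks))) {
    stop("peaks must have columns apex_rt, start_rt, end_rt, height, area",
         call. = FALSE)
  }
  peaks <- peaks[cols]
  for (cl in cols) peaks[[cl]] <- as.numeric(peaks[[cl]])
  if (nrow(peaks)) {
    if (any(!(peaks$start_rt < peaks$apex_rt & peaks$apex_rt < peaks$end_rt))) {
      stop("each peak requires start_rt < apex_rt < end_rt", call. = FALSE)
    }
    if (any(peaks$area < 0) || any(peaks$height < 0)) {
      stop("peak height and area must be non-negative", call. = FALSE)
    }
    peaks <- peaks[order(peaks$apex_rt), , drop = FALSE]
    rownames(peaks) <- NULL
    if (nrow(peaks) > 1L) {
      overlap <- peaks$end_rt[-nrow(peaks)] > peaks$start_rt[-1L] + 1e-12
      if (any(overlap)) {
        stop(sprintf("overlapping peaks at apex_rt %.4g and %.4g min",
                     peaks$apex_rt[which(overlap)[1L]],
                     peaks$apex_rt[which(overlap)[1L] + 1L]), call. = FALSE)
      }
    }
  }
  group <- match.arg(group, c("blank", "experimental", "control"))
  has_target <- !is.na(control_target) && nzchar(control_target)
  if (group == "control" && !has_target) {
    stop("control runs require a control_target", call. = FALSE)
  }
  structure(
    list(run_id = as.character(run_id), group = group,
         control_target = if (group == "control") as.character(control_target) else NA_character_,
         peaks = peaks),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> run '%s' (%s): %d peaks\n", x$run_id, x$group,
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10L))
  invisible(x)
}

#' Write / read a peak table
#'
#' CSV files carry the columns `run_id`, `group`, `control_target`,
#' `apex_rt`, `start_rt`, `end_rt`, `height`, `area` (one row per peak; an
#' empty table writes the header only). A `.json` extension writes a JSON
#' mirror of the same fields. Reading re-validates all peak-table
#' invariants, so overlapping or inverted intervals are rejected.
#'
#' @param table A [peak_table()].
#' @param path File path (`.csv` or `.json`).
#' @return `write_peak_table()` returns `path` invisibly;
#'   `read_peak_table()` returns a validated [peak_table()].
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(run_id = table$run_id, group = table$group,
                control_target = table$control_target, peaks = table$peaks)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    df <- table$peaks
    meta <- data.frame(run_id = rep(table$run_id, nrow(df)),
                       group = rep(table$group, nrow(df)),
                       control_target = rep(table$control_target, nrow(df)),
                       stringsAsFactors = FALSE)
    out <- if (nrow(df)) cbind(meta, format(df, digits = 15, trim = TRUE)) else
      data.frame(run_id = character(0), group = character(0),
                 control_target = character(0), apex_rt = character(0),
                 start_rt = character(0), end_rt = character(0),
                 height = character(0), area = character(0))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_peak_table
#' @param run_id,group,control_target Metadata used when reading a CSV whose
#'   rows are empty (header-only file); ignored otherwise unless missing
#'   from the file.
#' @export
read_peak_table <- function(path, run_id = NULL, group = NULL,
                            control_target = NA_character_) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    peaks <- as.data.frame(obj$peaks, stringsAsFactors = FALSE)
    return(peak_table(peaks, run_id = obj$run_id, group = obj$group,
                      control_target = obj$control_target %||% NA_character_))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(run_id = "character", group = "character",
                                       control_target = "character"))
  if (nrow(df) == 0L) {
    if (is.null(run_id) || is.null(group)) {
      stop("empty peak table file: supply run_id and group", call. = FALSE)
    }
    return(peak_table(df, run_id = run_id, group = group,
                      control_target = control_target))
  }
  ct <- df$control_target[1L]
  if (is.null(ct) || identical(ct, "NA") || identical(ct, "")) ct <- NA_character_
  peak_table(df[c("apex_rt", "start_rt", "end_rt", "height", "area")],
             run_id = df$run_id[1L], group = df$group[1L], control_target = ct)
}

#' Construct a compound panel
#'
#' The panel lists the compounds tracked across runs and the reference
#' retention time of each; peaks are assigned to a compound when their apex
#' falls within `rt_tolerance` of the reference.
#'
#' @param compounds Data frame with columns `compound_id` and
#'   `reference_rt` (minutes).
#' @param rt_tolerance Matching half-window in minutes (> 0). Reference
#'   retention times must be unique to within `2 * rt_tolerance` so that no
#'   peak can satisfy two compounds at once.
#' @return An object of class `compound_panel`.
#' @export
compound_panel <- function(compounds, rt_tolerance = 0.2) {
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "reference_rt") %in% names(compounds))) {
    stop("panel needs compound_id and reference_rt columns", call. = FALSE)
  }
  compounds$compound_id <- as.character(compounds$compound_id)
  compounds$reference_rt <- as.numeric(compounds$reference_rt)
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicate compound_id in panel", call. = FALSE)
  }
  if (!(rt_tolerance > 0)) stop("rt_tolerance must be positive", call. = FALSE)
  rt <- sort(compounds$reference_rt)
  if (length(rt) > 1L && any(diff(rt) < 2 * rt_tolerance)) {
    stop("reference_rt values must be separated by at least 2 * rt_tolerance",
         call. = FALSE)
  }
  structure(list(compounds = compounds[c("compound_id", "reference_rt")],
                 rt_tolerance = rt_tolerance),
            class = "compound_panel")
}

#' Read a compound panel from CSV
#'
#' @param path CSV with columns `compound_id`, `reference_rt`.
#' @inheritParams compound_panel
#' @export
read_panel <- function(path, rt_tolerance = 0.2) {
  compound_panel(utils::read.csv(path, stringsAsFactors = FALSE), rt_tolerance)
}

#' Write a compound panel to CSV
#'
#' @param panel A [compound_panel()].
#' @param path Output CSV path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "compound_panel"))
  utils::write.csv(panel$compounds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
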