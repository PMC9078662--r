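#' Estimate a chromatogram baseline
#'
#' Two-pass baseline. Pass one is morphological: a rolling minimum of the
#' lightly smoothed signal followed by a rolling mean, both over the same
#' window, recentred so that the median residual over the run is zero (the
#' minimum filter tracks drift underneath peaks but sits systematically
#' below the noise floor; the recentring removes that offset). Pass two
#' refits the baseline without the minimum filter's noise bias: samples
#' whose pass-one residual exceeds three noise standard deviations are
#' masked as peak (with a small dilation to catch tails) and a stiff
#' smoothing spline is fitted through the remaining baseline samples.
#' Peak-excluded refitting is what keeps baseline-subtracted peak areas
#' unbiased at the few-per-mil level the screening ratios require; on a
#' peak-free trace the two passes agree.
#'
#' @param chrom A [chromatogram()].
#' @param window Window width in minutes for the pass-one rolling operators
#'   (default 2). Must be at least 3 sampling intervals and less than the
#'   run length.
#' @return Numeric baseline trace on the same grid as `chrom$time`, in mAU.
#' @export
estimate_baseline <- function(chrom, window = 2) {
  stopifnot(inherits(chrom, "chromatogram"))
  dt <- chrom$sampling_interval
  span <- chrom$time[length(chrom$time)] - chrom$time[1L]
  if (window < 3 * dt) {
    stop("baseline window must be at least 3 sampling intervals", call. = FALSE)
  }
  if (window >= span) {
    stop("baseline window must be smaller than the run length", call. = FALSE)
  }
  x <- chrom$signal
  n <- length(x)
  w <- as.integer(round(window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(w, 3L)
  half <- (w - 1L) %/% 2L
  pad <- function(v) c(rep(v[1L], half), v, rep(v[length(v)], half))
  xs <- if (n >= 5L) smooth_ma(x) else x
  bmin <- zoo::rollapply(pad(xs), width = w, FUN = min, align = "center")
  rough <- zoo::rollmean(pad(bmin), k = w, align = "center")
  rough <- rough + stats::median(x - rough)
  resid <- x - rough
  noise <- if (n >= 10L) estimate_noise(resid) else 0
  thr <- max(3 * noise, 1e-6 * max(abs(x), 1e-300))
  mask <- resid > thr
  if (!any(mask)) return(rough)
  # dilate the peak mask to cover tails
  grow <- max(1L, as.integer(round(w / 8)))
  idx <- which(mask)
  lo <- pmax(idx - grow, 1L)
  hi <- pmin(idx + grow, n)
  for (k in seq_along(idx)) mask[lo[k]:hi[k]] <- TRUE
  un <- which(!mask)
  if (length(un) < max(10L, n %/% 10L)) return(rough)
  df <- max(4, min(20, round(span / 10)))
  fit <- stats::smooth.spline(chrom$time[un], x[un], df = df)
  stats::predict(fit, chrom$time)$y
}

#' Estimate detector noise from a baseline-subtracted trace
#'
#' Robust scale estimate from lag-1 first differences:
#' `1.4826 * median(|diff(residual)|) / sqrt(2)`. Differencing removes slow
#' structure and the median makes the estimate insensitive to sparse peaks,
#' so it can be applied to the whole residual trace without masking.
#'
#' @param residual Numeric baseline-subtracted trace (at least 10 samples).
#' @return Estimated noise standard deviation in mAU (0 for a flat trace).
#' @export
estimate_noise <- function(residual) {
  residual <- as.numeric(residual)
  if (length(residual) < 10L) {
    stop("noise estimation needs at least 10 samples", call. = FALSE)
  }
  1.4826 * stats::median(abs(diff(residual))) / sqrt(2)
}

# Centred 5-sample moving average with replicated ends.
smooth_ma <- function(x, k = 5L) {
  half <- (k - 1L) %/% 2L
  padded <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2L))[(half + 1L):(half + length(x))]
}

# Walk outward from an apex over the smoothed residual until either a
# flanking valley (a local minimum after which the trace rises by more
# than 1.5 noise standard deviations, so shallow noise dips on a flank do
# not split a peak) or a sustained (3-sample) drop below the noise floor,
# whichever comes first; returns the stopping index.
walk_bound <- function(s, apex, noise, dir) {
  n <- length(s)
  rise <- 1.5 * noise
  vmin <- s[apex]
  jmin <- apex
  k <- apex
  repeat {
    k <- k + dir
    if (k <= 1L || k >= n) return(min(max(k, 1L), n))
    k2 <- min(max(k + dir, 1L), n)
    k3 <- min(max(k + 2L * dir, 1L), n)
    if (noise > 0 && s[k] < noise && s[k2] < noise && s[k3] < noise) return(k)
    if (s[k] < vmin) {
      vmin <- s[k]
      jmin <- k
    } else if (s[k] - vmin > rise && jmin != apex) {
      return(jmin)
    }
  }
}

#' Detect peaks in a chromatogram
#'
#' The signal is baseline-subtracted ([estimate_baseline()]), lightly
#' smoothed with a 5-sample moving average, and scanned for local maxima
#' whose smoothed height is at least `min_snr` times the noise level
#' ([estimate_noise()]). Peak bounds extend from the apex to the nearest
#' flanking local minimum of the smoothed residual, or to the first
#' sustained drop below one noise standard deviation, whichever is closer
#' to the apex. Candidate maxima falling inside an already-accepted peak's
#' bounds are absorbed into that peak (tallest first), so noise ripple near
#' an apex never splits a peak. Areas are trapezoidal integrals of the
#' baseline-subtracted signal over the bounds ([integrate_peak()]).
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Minimum apex height in noise-standard-deviation units
#'   (default 5).
#' @param window Baseline window in minutes, passed to
#'   [estimate_baseline()].
#' @return A [peak_table()] (possibly empty) carrying the run metadata of
#'   `chrom`.
#' @export
detect_peaks <- function(chrom, min_snr = 5, window = 2) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (!(min_snr > 0)) stop("min_snr must be positive", call. = FALSE)
  baseline <- estimate_baseline(chrom, window)
  resid <- chrom$signal - baseline
  noise <- estimate_noise(resid)
  s <- smooth_ma(resid)
  n <- length(s)
  i <- 2:(n - 1L)
  cand <- i[s[i] > s[i - 1L] & s[i] >= s[i + 1L] & s[i] > 0 & s[i] >= min_snr * noise]
  if (length(cand) == 0L) {
    return(peak_table(NULL, run_id = chrom$run_id, group = chrom$group,
                      control_target = chrom$control_target))
  }
  cand <- cand[order(s[cand], decreasing = TRUE)]
  claimed <- logical(n)
  rows <- list()
  for (apex in cand) {
    if (claimed[apex]) next
    lo <- walk_bound(s, apex, noise, -1L)
    hi <- walk_bound(s, apex, noise, +1L)
    if (lo >= apex || hi <= apex) next
    claimed[lo:hi] <- TRUE
    rows[[length(rows) + 1L]] <- c(apex = apex, lo = lo, hi = hi)
  }
  if (length(rows) == 0L) {
    return(peak_table(NULL, run_id = chrom$run_id, group = chrom$group,
                      control_target = chrom$control_target))
  }
  m <- do.call(rbind, rows)
  m <- m[order(m[, "apex"]), , drop = FALSE]
  # resolve any residual overlap between adjacent peaks at the valley
  if (nrow(m) > 1L) {
    for (k in seq_len(nrow(m) - 1L)) {
      if (m[k, "hi"] > m[k + 1L, "lo"]) {
        valley <- m[k, "apex"] + which.min(s[m[k, "apex"]:m[k + 1L, "apex"]]) - 1L
        m[k, "hi"] <- valley
        m[k + 1L, "lo"] <- valley
      }
    }
  }
  peaks <- data.frame(
    apex_rt = chrom$time[m[, "apex"]],
    start_rt = chrom$time[m[, "lo"]],
    end_rt = chrom$time[m[, "hi"]],
    height = pmax(s[m[, "apex"]], 0),
    area = vapply(seq_len(nrow(m)), function(k) {
      integrate_peak(chrom, baseline, chrom$time[m[k, "lo"]], chrom$time[m[k, "hi"]])
    }, numeric(1))
  )
  peak_table(peaks, run_id = chrom$run_id, group = chrom$group,
             control_target = chrom$control_target)
}

#' Integrate a peak above a baseline
#'
#' Trapezoidal integral of `signal - baseline` between two retention times,
#' with negative residual samples clipped at zero so that areas feeding the
#' screening ratios are always non-negative.
#'
#' @param chrom A [chromatogram()].
#' @param baseline Baseline trace on the same grid (e.g. from
#'   [estimate_baseline()]).
#' @param start_rt,end_rt Integration bounds in minutes, inside the time
#'   grid, with `start_rt < end_rt`.
#' @return Peak area in mAU.min (>= 0).
#' @export
integrate_peak <- function(chrom, baseline, start_rt, end_rt) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (length(baseline) != length(chrom$signal)) {
    stop("baseline must be on the chromatogram grid", call. = FALSE)
  }
  if (!(start_rt < end_rt)) stop("start_rt must be before end_rt", call. = FALSE)
  t <- chrom$time
  eps <- chrom$sampling_interval / 2
  if (start_rt < t[1L] - eps || end_rt > t[length(t)] + eps) {
    stop("integration bounds outside the time grid", call. = FALSE)
  }
  i0 <- which.min(abs(t - start_rt))
  i1 <- which.min(abs(t - end_rt))
  if (i1 <= i0) stop("integration bounds collapse onto one sample", call. = FALSE)
  y <- pmax(chrom$signal[i0:i1] - baseline[i0:i1], 0)
  sum((y[-1L] + y[-length(y)]) / 2) * chrom$sampling_interval
}

#' Match peaks across runs into per-compound area triples
#'
#' For each panel compound and each run, the peak whose apex is nearest the
#' compound's reference retention time and within the panel tolerance is
#' assigned (ties broken toward the smaller apex retention time); a missing
#' peak contributes area 0. Each peak may serve at most one compound per
#' run; two compounds claiming the same peak is an error (prevented by the
#' panel spacing invariant, but re-checked here).
#'
#' @param tables Named list of [peak_table()] objects, one per design run
#'   (names are run_ids).
#' @param panel A [compound_panel()].
#' @param design A [screen_design()].
#' @return A data frame of class `peak_area_triples` with one row per panel
#'   compound and columns `compound_id`, `A_a` (experimental area), `A_b`
#'   (blank area) and `A_c_<target>` (area in each target's probe-blocked
#'   control run), all in mAU.min.
#' @export
match_peaks <- function(tables, panel, design) {
  stopifnot(inherits(panel, "compound_panel"), inherits(design, "screen_design"))
  missing_runs <- setdiff(design$runs$run_id, names(tables))
  if (length(missing_runs)) {
    stop(sprintf("missing peak table for run '%s'", missing_runs[1L]), call. = FALSE)
  }
  tol <- panel$rt_tolerance
  comp <- panel$compounds
  assign_run <- function(tab) {
    pk <- tab$peaks
    areas <- numeric(nrow(comp))
    owner <- rep(NA_integer_, nrow(pk))
    for (ci in seq_len(nrow(comp))) {
      if (nrow(pk) == 0L) next
      d <- abs(pk$apex_rt - comp$reference_rt[ci])
      ok <- which(d <= tol)
      if (length(ok) == 0L) next
      best <- ok[order(d[ok], pk$apex_rt[ok])][1L]
      if (!is.na(owner[best])) {
        stop(sprintf("peak at %.4g min claimed by both '%s' and '%s'",
                     pk$apex_rt[best], comp$compound_id[owner[best]],
                     comp$compound_id[ci]), call. = FALSE)
      }
      owner[best] <- ci
      areas[ci] <- pk$area[best]
    }
    areas
  }
  runs <- design$runs
  blank_id <- runs$run_id[runs$group == "blank"]
  exp_id <- runs$run_id[runs$group == "experimental"]
  out <- data.frame(compound_id = comp$compound_id,
                    A_a = assign_run(tables[[exp_id]]),
                    A_b = assign_run(tables[[blank_id]]),
                    stringsAsFactors = FALSE)
  for (tg in design$targets) {
    ctrl_id <- runs$run_id[runs$group == "control" & runs$control_target == tg]
    out[[paste0("A_c_", tg)]] <- assign_run(tables[[ctrl_id]])
  }
  class(out) <- c("peak_area_triples", "data.frame")
  attr(out, "targets") <- design$targets
  out
}
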