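#' Signal-to-noise ratio of an ultrafiltration screen peak
#'
#' `S/N = A_a / A_b`, the ratio of a compound's peak area in the
#' experimental run (incubated with the enzyme source) to its area in the
#' blank run (incubated without it). The blank area measures non-specific
#' membrane retention, so S/N above 1 indicates binding affinity towards
#' the target mixture.
#'
#' @param A_a Peak area in the experimental run (mAU.min).
#' @param A_b Peak area in the blank run (mAU.min). Compounds with
#'   `A_b <= 0` are not evaluable (the ratio is undefined) and return `NA`.
#' @return `A_a / A_b`, or `NA_real_` where `A_b <= 0`. Vectorised.
#' @export
compute_sn <- function(A_a, A_b) {
  out <- ifelse(A_b > 0, A_a / A_b, NA_real_)
  as.numeric(out)
}

#' Specific signal-to-noise ratio against a probe-blocked control
#'
#' `S-S/N = (A_a - A_c) / A_b`, where `A_c` is the compound's peak area in
#' the control run whose expected target was pre-blocked with a competitive
#' probe. A positive value means the probe displaced part of the compound's
#' bound pool, i.e. the compound competes at the blocked site; values near
#' zero or negative mean its binding is not displaceable there.
#'
#' @inheritParams compute_sn
#' @param A_c Peak area in the probe-blocked control run (mAU.min).
#' @return `(A_a - A_c) / A_b` (may be negative), or `NA_real_` where
#'   `A_b <= 0`. Vectorised.
#' @export
compute_ssn <- function(A_a, A_b, A_c) {
  out <- ifelse(A_b > 0, (A_a - A_c) / A_b, NA_real_)
  as.numeric(out)
}

#' Classify a compound-target pair from its screening ratios
#'
#' Applies the two selection criteria: a compound is a binder when
#' `S/N > 1` and a specific ligand of the target when additionally
#' `S-S/N > 0` for that target's control. Both are strict inequalities
#' applied at the reported precision: the ratios are rounded to `digits`
#' decimals first, so a ratio that would print as 1.00 (or an S-S/N that
#' would print as 0.00) does not produce a call. This guards the strict
#' thresholds against sub-precision integration noise on what are exact
#' ties in expectation; `digits = Inf` applies the criteria to the raw
#' ratios.
#'
#' @param sn S/N ratio(s).
#' @param ssn S-S/N ratio(s) for the target under consideration.
#' @param digits Decimal places at which the criteria are applied
#'   (default 2, the precision at which the ratios are reported).
#' @return A data frame with logical columns `is_binder` and `is_specific`
#'   (`is_specific` implies `is_binder`); `NA` ratios give `NA` calls.
#' @export
classify_ligand <- function(sn, ssn, digits = 2) {
  if (is.finite(digits)) {
    sn_r <- round(sn, digits)
    ssn_r <- round(ssn, digits)
  } else {
    sn_r <- sn
    ssn_r <- ssn
  }
  is_binder <- sn_r > 1
  data.frame(is_binder = is_binder, is_specific = is_binder & ssn_r > 0)
}

#' Score a screen from matched peak-area triples
#'
#' Computes S/N ([compute_sn()]) and per-target S-S/N ([compute_ssn()]) for
#' every compound, and the binder / specific-ligand calls
#' ([classify_ligand()]) for every compound-target pair. Compounds absent
#' from the blank run (`A_b <= 0`) are flagged not evaluable and receive no
#' calls.
#'
#' @param triples A `peak_area_triples` data frame from [match_peaks()] (or
#'   any data frame with columns `compound_id`, `A_a`, `A_b` and one
#'   `A_c_<target>` column per design target).
#' @param design A [screen_design()].
#' @param digits Precision at which the selection criteria are applied; see
#'   [classify_ligand()].
#' @return An object of class `screen_scores`: a list with
#'   \describe{
#'     \item{scores}{one row per compound: `compound_id`, `evaluable`,
#'       `sn`, and `ssn_<target>` columns (full floating precision);}
#'     \item{calls}{one row per compound-target pair: `compound_id`,
#'       `target`, `sn`, `ssn`, `is_binder`, `is_specific`.}
#'   }
#' @export
score_screen <- function(triples, design, digits = 2) {
  stopifnot(inherits(design, "screen_design"))
  triples <- as.data.frame(triples)
  need <- c("compound_id", "A_a", "A_b", paste0("A_c_", design$targets))
  miss <- setdiff(need, names(triples))
  if (length(miss)) {
    stop(sprintf("triples lack column '%s' for this design", miss[1L]), call. = FALSE)
  }
  sn <- compute_sn(triples$A_a, triples$A_b)
  scores <- data.frame(compound_id = triples$compound_id,
                       evaluable = triples$A_b > 0,
                       sn = sn, stringsAsFactors = FALSE)
  calls <- NULL
  for (tg in design$targets) {
    if (nrow(triples) == 0L) {
      scores[[paste0("ssn_", tg)]] <- numeric(0)
      next
    }
    ssn <- compute_ssn(triples$A_a, triples$A_b, triples[[paste0("A_c_", tg)]])
    scores[[paste0("ssn_", tg)]] <- ssn
    cl <- classify_ligand(sn, ssn, digits = digits)
    cl$is_binder[!scores$evaluable] <- NA
    cl$is_specific[!scores$evaluable] <- NA
    calls <- rbind(calls, data.frame(compound_id = triples$compound_id,
                                     target = tg, sn = sn, ssn = ssn,
                                     cl, stringsAsFactors = FALSE))
  }
  if (is.null(calls)) {
    calls <- data.frame(compound_id = character(0), target = character(0),
                        sn = numeric(0), ssn = numeric(0),
                        is_binder = logical(0), is_specific = logical(0))
  }
  rownames(calls) <- NULL
  structure(list(scores = scores, calls = calls, digits = digits,
                 targets = design$targets),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("<screen_scores> %d compounds x %d targets; %d specific-ligand calls\n",
              nrow(x$scores), length(x$targets),
              sum(x$calls$is_specific, na.rm = TRUE)))
  print(x$scores, digits = 4)
  invisible(x)
}

#' Scatter-plot data for one target
#'
#' One row per evaluable compound with its S/N, the S-S/N for the requested
#' target, and the specific-ligand flag; suitable for an S/N versus S-S/N
#' scatter with criterion lines at `sn = 1` and `ssn = 0`.
#'
#' @param scores A `screen_scores` object from [score_screen()].
#' @param target A target identifier present in the scores.
#' @return Data frame with columns `compound_id`, `sn`, `ssn`, `selected`.
#' @export
screen_plot_data <- function(scores, target) {
  stopifnot(inherits(scores, "screen_scores"))
  if (!target %in% scores$targets) {
    stop(sprintf("unknown target '%s'", target), call. = FALSE)
  }
  cl <- scores$calls[scores$calls$target == target, , drop = FALSE]
  out <- data.frame(compound_id = cl$compound_id, sn = cl$sn, ssn = cl$ssn,
                    selected = cl$is_specific, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Plot S/N versus S-S/N for one target
#'
#' Scatter of the screening ratios with the two selection-criterion lines;
#' specific ligands are highlighted. Requires ggplot2.
#'
#' @inheritParams screen_plot_data
#' @return A ggplot object.
#' @export
plot_screen_scores <- function(scores, target) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_screen_scores requires ggplot2", call. = FALSE)
  }
  df <- screen_plot_data(scores, target)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sn, y = .data$ssn,
                                   colour = .data$selected)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey40"),
                                 na.value = "grey70", name = "specific") +
    ggplot2::labs(x = "S/N", y = paste0("S-S/N (", target, ")"), title = target) +
    ggplot2::theme_minimal()
}
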