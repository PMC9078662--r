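#' Construct a competitive-binding system
#'
#' Mass-action model of a multi-compound extract incubated with a pool of
#' enzymes. Each ligand may bind each enzyme at one of two independent
#' saturable site classes -- orthosteric (the substrate/probe site) or
#' allosteric -- with a 1:1 dissociation constant. Each enzyme has a
#' competitive probe that always binds its orthosteric site; the probe is
#' only present in that enzyme's control condition. A per-ligand
#' non-specific fraction models condition-independent retention on the
#' ultrafiltration membrane and guarantees a blank-run peak for every
#' ligand.
#'
#' @param enzymes Data frame with columns `enzyme_id`, `total_conc` (uM).
#' @param ligands Data frame with columns `ligand_id`, `total_conc` (uM),
#'   `response_factor` (mAU.min per uM retained), `nonspecific_fraction`
#'   (in `[0, 1)`), `reference_rt` (minutes).
#' @param affinities Data frame with columns `ligand_id`, `enzyme_id`, `kd`
#'   (uM, > 0) and `site` (`"orthosteric"` or `"allosteric"`); pairs absent
#'   from this table do not bind.
#' @param probes Data frame with columns `enzyme_id`, `probe_id`,
#'   `total_conc` (uM) and `kd` (uM, > 0), one row per enzyme.
#' @return An object of class `binding_system`.
#' @export
binding_system <- function(enzymes, ligands, affinities, probes) {
  enzymes <- as.data.frame(enzymes, stringsAsFactors = FALSE)
  ligands <- as.data.frame(ligands, stringsAsFactors = FALSE)
  affinities <- as.data.frame(affinities, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  stopifnot(all(c("enzyme_id", "total_conc") %in% names(enzymes)),
            all(c("ligand_id", "total_conc", "response_factor",
                  "nonspecific_fraction", "reference_rt") %in% names(ligands)),
            all(c("enzyme_id", "probe_id", "total_conc", "kd") %in% names(probes)))
  if (nrow(affinities) == 0L) {
    affinities <- data.frame(ligand_id = character(0), enzyme_id = character(0),
                             kd = numeric(0), site = character(0))
  }
  stopifnot(all(c("ligand_id", "enzyme_id", "kd", "site") %in% names(affinities)))
  for (cl in c("total_conc")) enzymes[[cl]] <- as.numeric(enzymes[[cl]])
  for (cl in c("total_conc", "response_factor", "nonspecific_fraction",
               "reference_rt")) ligands[[cl]] <- as.numeric(ligands[[cl]])
  for (cl in c("total_conc", "kd")) probes[[cl]] <- as.numeric(probes[[cl]])
  if (nrow(affinities)) affinities$kd <- as.numeric(affinities$kd)
  if (anyDuplicated(enzymes$enzyme_id)) stop("duplicate enzyme_id", call. = FALSE)
  if (anyDuplicated(ligands$ligand_id)) stop("duplicate ligand_id", call. = FALSE)
  if (any(enzymes$total_conc < 0) || any(ligands$total_conc < 0) ||
      any(probes$total_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(ligands$nonspecific_fraction < 0) || any(ligands$nonspecific_fraction >= 1)) {
    stop("nonspecific_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (nrow(affinities) && any(affinities$kd <= 0)) {
    stop("dissociation constants must be positive", call. = FALSE)
  }
  if (any(probes$kd <= 0)) stop("probe kd must be positive", call. = FALSE)
  if (nrow(affinities)) {
    if (!all(affinities$site %in% c("orthosteric", "allosteric"))) {
      stop("site must be 'orthosteric' or 'allosteric'", call. = FALSE)
    }
    if (!all(affinities$ligand_id %in% ligands$ligand_id) ||
        !all(affinities$enzyme_id %in% enzymes$enzyme_id)) {
      stop("affinities refer to unknown ligand or enzyme", call. = FALSE)
    }
    if (anyDuplicated(affinities[c("ligand_id", "enzyme_id")])) {
      stop("one affinity entry per ligand-enzyme pair", call. = FALSE)
    }
  }
  if (!setequal(probes$enzyme_id, enzymes$enzyme_id) ||
      anyDuplicated(probes$enzyme_id)) {
    stop("exactly one probe per enzyme", call. = FALSE)
  }
  structure(list(enzymes = enzymes, ligands = ligands,
                 affinities = affinities,
                 probes = probes[match(enzymes$enzyme_id, probes$enzyme_id), ]),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat(sprintf("<binding_system> %d ligands x %d enzymes, %d binding pairs\n",
              nrow(x$ligands), nrow(x$enzymes), nrow(x$affinities)))
  invisible(x)
}

#' Closed-form 1:1 bound concentration
#'
#' Exact solution of the single-ligand, single-enzyme mass-action
#' quadratic:
#' `bound = ((E_T + L_T + Kd) - sqrt((E_T + L_T + Kd)^2 - 4 E_T L_T)) / 2`.
#' Used as the independent oracle for [solve_equilibrium()].
#'
#' @param E_T,L_T Total enzyme and ligand concentrations (uM, >= 0).
#' @param Kd Dissociation constant (uM, > 0).
#' @return Bound complex concentration in uM.
#' @export
closed_form_pair <- function(E_T, L_T, Kd) {
  stopifnot(all(E_T >= 0), all(L_T >= 0), all(Kd > 0))
  s <- E_T + L_T + Kd
  (s - sqrt(s^2 - 4 * E_T * L_T)) / 2
}

#' Solve the competitive-binding equilibrium
#'
#' Damped fixed-point iteration on the free site concentrations. At each
#' enzyme, the orthosteric and allosteric pools are independent saturable
#' sites, each with capacity equal to the enzyme total; occupants of a pool
#' compete by mass action (`bound_ij = free_site_j * free_ligand_i /
#' Kd_ij`). Given the free sites, every free ligand concentration is
#' eliminated analytically from its mass balance,
#' `free_i = total_i / (1 + sum_j free_site_{j, site(i,j)} / Kd_ij)`,
#' and likewise for the probe, so the iteration runs only over the site
#' concentrations. Conditions: `blank` zeroes all enzyme totals;
#' `experimental` has no probe; `control` adds the named target's probe to
#' that enzyme's orthosteric competition.
#'
#' @param system A [binding_system()].
#' @param condition `"blank"`, `"experimental"` or `"control"`.
#' @param target Target (enzyme) id whose probe is present; required iff
#'   `condition = "control"`.
#' @param tol Relative fixed-point residual at convergence (default 1e-12).
#' @param max_iter Iteration cap (default 10000).
#' @return An object of class `equilibrium_state`: list with `free_enzyme`
#'   (enzyme x site matrix, uM), `free_ligand` (named vector, uM), `bound`
#'   (ligand x enzyme matrix, uM), `bound_probe` (named vector, uM) and
#'   `iterations`.
#' @export
solve_equilibrium <- function(system, condition = c("experimental", "blank", "control"),
                              target = NULL, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(system, "binding_system"))
  condition <- match.arg(condition)
  enz <- system$enzymes
  lig <- system$ligands
  nE <- nrow(enz)
  nL <- nrow(lig)
  ET <- if (condition == "blank") rep(0, nE) else enz$total_conc
  LT <- lig$total_conc
  Kd <- matrix(Inf, nL, nE, dimnames = list(lig$ligand_id, enz$enzyme_id))
  ortho <- matrix(TRUE, nL, nE)
  aff <- system$affinities
  if (nrow(aff)) {
    li <- match(aff$ligand_id, lig$ligand_id)
    ej <- match(aff$enzyme_id, enz$enzyme_id)
    Kd[cbind(li, ej)] <- aff$kd
    ortho[cbind(li, ej)] <- aff$site == "orthosteric"
  }
  PT <- rep(0, nE)
  Kdp <- system$probes$kd
  if (condition == "control") {
    if (is.null(target) || !target %in% enz$enzyme_id) {
      stop("control condition requires a valid target enzyme id", call. = FALSE)
    }
    j <- match(target, enz$enzyme_id)
    PT[j] <- system$probes$total_conc[j]
  }
  invKd <- 1 / Kd                       # 0 where no binding
  ortho_w <- invKd * ortho              # ligand x enzyme, orthosteric links
  allo_w <- invKd * (!ortho)
  # fixed-point map on the stacked free-site vector c(Fo, Fa)
  fp_map <- function(x) {
    Fo <- x[seq_len(nE)]
    Fa <- x[nE + seq_len(nE)]
    denomL <- 1 + as.numeric(ortho_w %*% Fo) + as.numeric(allo_w %*% Fa)
    L <- LT / denomL
    Pfree <- PT / (1 + Fo / Kdp)
    occ_o <- as.numeric(t(ortho_w) %*% L) + Pfree / Kdp
    occ_a <- as.numeric(t(allo_w) %*% L)
    c(ET / (1 + occ_o), ET / (1 + occ_a))
  }
  scale <- pmax(rep(ET, 2L), 1e-300)
  x <- rep(ET, 2L)
  iter <- 0L
  res <- Inf
  # damped fixed point; tight-binding regimes contract slowly, so follow up
  # with Newton steps on g(x) = x - map(x) (numeric Jacobian; the system is
  # tiny) whenever plain iteration has not reached tol
  repeat {
    iter <- iter + 1L
    x_new <- fp_map(x)
    res <- max(abs(x_new - x) / scale)
    x <- (x + x_new) / 2
    if (res < 1e-8 || iter >= min(max_iter, 2000L)) break
  }
  if (res > 0) {
    # polish to machine precision: the fixed-point step size understates the
    # true error when the contraction factor approaches 1
    g <- function(x) x - fp_map(x)
    best_x <- x
    best_res <- max(abs(g(x)) / scale)
    for (newton in seq_len(50L)) {
      gx <- g(x)
      res <- max(abs(gx) / scale)
      if (res < best_res) {
        best_res <- res
        best_x <- x
      }
      if (res < 1e-15) break
      J <- matrix(0, 2L * nE, 2L * nE)
      for (k in seq_len(2L * nE)) {
        h <- max(abs(x[k]), scale[k]) * 1e-7
        xp <- x
        xp[k] <- xp[k] + h
        J[, k] <- (g(xp) - gx) / h
      }
      step <- tryCatch(solve(J, gx), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      while (any(x - lambda * step < 0) && lambda > 1e-8) lambda <- lambda / 2
      x <- x - lambda * step
    }
    res <- max(abs(g(x)) / scale)
    if (res > best_res) {
      x <- best_x
      res <- best_res
    }
    if (res >= tol) {
      stop(sprintf("equilibrium solver failed to converge (residual %.3g)", res),
           call. = FALSE)
    }
  }
  Fo <- x[seq_len(nE)]
  Fa <- x[nE + seq_len(nE)]
  denomL <- 1 + as.numeric(ortho_w %*% Fo) + as.numeric(allo_w %*% Fa)
  L <- LT / denomL
  Pfree <- PT / (1 + Fo / Kdp)
  bound <- (L %o% Fo) * ortho_w + (L %o% Fa) * allo_w
  dimnames(bound) <- list(lig$ligand_id, enz$enzyme_id)
  free_enzyme <- cbind(orthosteric = Fo, allosteric = Fa)
  rownames(free_enzyme) <- enz$enzyme_id
  bound_probe <- Fo * Pfree / Kdp
  names(bound_probe) <- enz$enzyme_id
  names(L) <- lig$ligand_id
  structure(list(free_enzyme = free_enzyme, free_ligand = L, bound = bound,
                 bound_probe = bound_probe, iterations = iter),
            class = "equilibrium_state")
}

#' Simulate the membrane retentate of one incubation condition
#'
#' The amount of each ligand retained on the ultrafiltration membrane is
#' its total enzyme-bound concentration at equilibrium plus a
#' condition-independent non-specific fraction of its total (the quantity
#' the blank run measures). True peak area is the retained amount times the
#' ligand's detector response factor.
#'
#' @inheritParams solve_equilibrium
#' @return Data frame with columns `ligand_id`, `retained` (uM), `area`
#'   (mAU.min) and `reference_rt` (minutes).
#' @export
simulate_retentate <- function(system, condition = c("experimental", "blank", "control"),
                               target = NULL) {
  condition <- match.arg(condition)
  state <- solve_equilibrium(system, condition, target)
  lig <- system$ligands
  retained <- rowSums(state$bound) + lig$nonspecific_fraction * lig$total_conc
  data.frame(ligand_id = lig$ligand_id,
             retained = as.numeric(retained),
             area = as.numeric(lig$response_factor * retained),
             reference_rt = lig$reference_rt,
             stringsAsFactors = FALSE)
}

#' Model-truth screening ratios of a binding system
#'
#' Computes the noiseless S/N and per-target S-S/N implied by the
#' equilibrium model (areas from [simulate_retentate()] under each
#' condition), together with the ground-truth specificity labels: a ligand
#' is truly specific for an enzyme iff it binds that enzyme orthosterically
#' (the probe can displace it there).
#'
#' @param system A [binding_system()].
#' @return Data frame with one row per ligand-enzyme pair: `compound_id`,
#'   `target`, `model_sn`, `model_ssn`, `true_specific`.
#' @export
model_truth <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  blank <- simulate_retentate(system, "blank")
  expr <- simulate_retentate(system, "experimental")
  sn <- compute_sn(expr$area, blank$area)
  out <- NULL
  for (tg in system$enzymes$enzyme_id) {
    ctrl <- simulate_retentate(system, "control", target = tg)
    ssn <- compute_ssn(expr$area, blank$area, ctrl$area)
    aff <- system$affinities
    spec <- system$ligands$ligand_id %in%
      aff$ligand_id[aff$enzyme_id == tg & aff$site == "orthosteric"]
    out <- rbind(out, data.frame(compound_id = system$ligands$ligand_id,
                                 target = tg, model_sn = sn, model_ssn = ssn,
                                 true_specific = spec, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Read a binding system from a YAML/JSON config
#'
#' The config mirrors the [binding_system()] arguments: keys `enzymes`,
#' `ligands`, `affinities`, `probes`, each a list of records.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [binding_system()].
#' @export
read_binding_system <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_df <- function(x) {
    if (is.data.frame(x)) x else do.call(rbind, lapply(x, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  binding_system(as_df(raw$enzymes), as_df(raw$ligands),
                 if (is.null(raw$affinities)) NULL else as_df(raw$affinities),
                 as_df(raw$probes))
}
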