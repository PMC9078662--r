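# helper: one-ligand/one-enzyme system
pair_system <- function(E_T, L_T, Kd, nu = 0.1, site = "orthosteric",
                        probe_conc = 500, probe_kd = 0.1) {
  binding_system(
    data.frame(enzyme_id = "E1", total_conc = E_T),
    data.frame(ligand_id = "L1", total_conc = L_T, response_factor = 1,
               nonspecific_fraction = nu, reference_rt = 5),
    data.frame(ligand_id = "L1", enzyme_id = "E1", kd = Kd, site = site),
    data.frame(enzyme_id = "E1", probe_id = "p", total_conc = probe_conc,
               kd = probe_kd)
  )
}

rand_system <- function(nL, nE, seed) {
  set.seed(seed)
  enz <- data.frame(enzyme_id = paste0("E", 1:nE),
                    total_conc = runif(nE, 0.2, 3))
  lig <- data.frame(ligand_id = paste0("L", 1:nL),
                    total_conc = runif(nL, 0.5, 10),
                    response_factor = runif(nL, 5, 15),
                    nonspecific_fraction = runif(nL, 0.02, 0.3),
                    reference_rt = seq(5, by = 5, length.out = nL))
  pairs <- expand.grid(ligand_id = lig$ligand_id, enzyme_id = enz$enzyme_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < 0.7, ]
  pairs$kd <- 10^runif(nrow(pairs), -2, 2)
  pairs$site <- sample(c("orthosteric", "allosteric"), nrow(pairs),
                       replace = TRUE, prob = c(0.8, 0.2))
  probes <- data.frame(enzyme_id = enz$enzyme_id,
                       probe_id = paste0("p", 1:nE),
                       total_conc = runif(nE, 100, 800),
                       kd = 10^runif(nE, -2, 0))
  binding_system(enz, lig, pairs, probes)
}

test_that("closed-form 1:1 binding matches its quadratic", {
  expect_equal(closed_form_pair(1, 1, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(closed_form_pair(0, 4, 2), 0)
  expect_equal(closed_form_pair(3, 0, 2), 0)
  # bound never exceeds either total
  expect_lt(closed_form_pair(2, 5, 1e-6), 2 + 1e-9)
})

test_that("equilibrium solver agrees with the closed form on random single pairs", {
  set.seed(31)
  for (k in 1:100) {
    E_T <- runif(1, 0.01, 10)
    L_T <- runif(1, 0.01, 10)
    Kd <- 10^runif(1, -3, 3)
    st <- solve_equilibrium(pair_system(E_T, L_T, Kd), "experimental")
    expect_lt(abs(st$bound[1, 1] - closed_form_pair(E_T, L_T, Kd)), 1e-9)
  }
})

test_that("mass is conserved in random multi-ligand multi-enzyme systems", {
  for (seed in 1:20) {
    sys <- rand_system(nL = 5, nE = 3, seed = seed)
    cond <- c("blank", "experimental", "control")[(seed %% 3) + 1]
    tgt <- if (cond == "control") sys$enzymes$enzyme_id[1] else NULL
    st <- solve_equilibrium(sys, cond, target = tgt)
    # ligand balance: free + sum over enzymes of bound = total
    lig_tot <- st$free_ligand + rowSums(st$bound)
    expect_lt(max(abs(lig_tot - sys$ligands$total_conc) /
                    pmax(sys$ligands$total_conc, 1e-12)), 1e-9)
    # per-enzyme, per-site balance: free site + occupants = enzyme total
    aff <- sys$affinities
    ET <- if (cond == "blank") rep(0, nrow(sys$enzymes)) else sys$enzymes$total_conc
    for (j in seq_len(nrow(sys$enzymes))) {
      ej <- sys$enzymes$enzyme_id[j]
      o_lig <- aff$ligand_id[aff$enzyme_id == ej & aff$site == "orthosteric"]
      a_lig <- aff$ligand_id[aff$enzyme_id == ej & aff$site == "allosteric"]
      occ_o <- sum(st$bound[rownames(st$bound) %in% o_lig, ej]) + st$bound_probe[ej]
      occ_a <- sum(st$bound[rownames(st$bound) %in% a_lig, ej])
      expect_lt(abs(st$free_enzyme[ej, "orthosteric"] + occ_o - ET[j]),
                1e-9 * max(ET[j], 1))
      expect_lt(abs(st$free_enzyme[ej, "allosteric"] + occ_a - ET[j]),
                1e-9 * max(ET[j], 1))
    }
    expect_true(all(st$bound >= 0) && all(st$free_ligand >= 0))
  }
})

test_that("limiting conditions behave as mass action dictates", {
  # blank condition: no enzyme, nothing bound
  st <- solve_equilibrium(pair_system(1, 1, 1), "blank")
  expect_true(all(st$bound == 0))
  expect_equal(unname(st$free_ligand), 1)
  # vanishing affinity: bound vanishes relative to totals
  st2 <- solve_equilibrium(pair_system(1, 1, 1e9), "experimental")
  expect_lt(st2$bound[1, 1], 1e-6)
  # retentate areas: blank area is the non-specific fraction of the total
  ret <- simulate_retentate(pair_system(1, 10, 1, nu = 0.1), "blank")
  expect_equal(ret$area, 1)
})

test_that("probe displacement is monotone for orthosteric and absent for allosteric ligands", {
  ssn_at_probe <- function(site, probe_conc) {
    sys <- pair_system(1, 2, 0.5, nu = 0.1, site = site,
                       probe_conc = probe_conc)
    tr <- model_truth(sys)
    tr$model_ssn[1]
  }
  probe_grid <- c(0.01, 0.1, 1, 10, 100, 500)
  ssn_o <- vapply(probe_grid, function(p) ssn_at_probe("orthosteric", p),
                  numeric(1))
  expect_true(all(diff(ssn_o) >= -1e-9))
  expect_gt(ssn_o[length(ssn_o)], 0.5)   # strong probe displaces nearly all
  ssn_a <- vapply(probe_grid, function(p) ssn_at_probe("allosteric", p),
                  numeric(1))
  expect_lt(max(abs(ssn_a)), 1e-9)
  # probe -> infinity drives the control area to the blank area,
  # so model S-S/N -> S/N - 1
  sys_inf <- pair_system(1, 2, 0.5, nu = 0.1, probe_conc = 1e9)
  tr <- model_truth(sys_inf)
  expect_equal(tr$model_ssn[1], tr$model_sn[1] - 1, tolerance = 1e-6)
})

test_that("binding-system configs round-trip through YAML", {
  sys <- demo_system()
  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    enzymes = unname(apply(sys$enzymes, 1, as.list)),
    ligands = unname(lapply(seq_len(nrow(sys$ligands)), function(i)
      as.list(sys$ligands[i, ]))),
    affinities = unname(lapply(seq_len(nrow(sys$affinities)), function(i)
      as.list(sys$affinities[i, ]))),
    probes = unname(lapply(seq_len(nrow(sys$probes)), function(i)
      as.list(sys$probes[i, ])))
  ), p)
  back <- read_binding_system(p)
  expect_equal(back$ligands$total_conc, sys$ligands$total_conc)
  expect_equal(back$affinities$kd, sys$affinities$kd)
  st1 <- solve_equilibrium(sys, "experimental")
  st2 <- solve_equilibrium(back, "experimental")
  expect_equal(st1$bound, st2$bound, tolerance = 1e-12)
})

test_that("invalid systems are rejected", {
  expect_error(pair_system(1, 1, -2), "positive")
  expect_error(pair_system(1, 1, 1, nu = 1), "\\[0, 1\\)")
  expect_error(binding_system(
    data.frame(enzyme_id = "E1", total_conc = 1),
    data.frame(ligand_id = "L1", total_conc = 1, response_factor = 1,
               nonspecific_fraction = 0.1, reference_rt = 5),
    data.frame(ligand_id = "L1", enzyme_id = "E9", kd = 1, site = "orthosteric"),
    data.frame(enzyme_id = "E1", probe_id = "p", total_conc = 1, kd = 0.1)),
    "unknown")
})
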