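# Shared helpers: small synthetic chromatograms and a cached copy of the
# Danshen worked-example dataset (generated once per test session).

gaussian_trace <- function(t, h, rt, sigma) {
  h * exp(-(t - rt)^2 / (2 * sigma^2))
}

# Chromatogram with a single Gaussian peak on an optional drift/noise floor.
single_peak_chrom <- function(h = 20, rt = 10, sigma = 0.1, t_max = 20,
                              dt = 0.01, drift = 0, noise_sd = 0, seed = NULL,
                              run_id = "test", group = "blank") {
  area <- h * sigma * sqrt(2 * pi)
  synthesize_chromatogram(stats::setNames(area, "pk"), stats::setNames(rt, "pk"),
                          sigma = sigma, noise_sd = noise_sd, drift = drift,
                          seed = seed, t_max = t_max, dt = dt,
                          run_id = run_id, group = group)
}

local_fixture_cache <- new.env(parent = emptyenv())

# danshen4 fixture + scored pipeline result, computed once and reused.
danshen_cached <- function() {
  if (is.null(local_fixture_cache$res)) {
    dir <- file.path(tempdir(), "ufscreen-danshen4")
    fx <- danshen4_fixture(dir)
    res <- score_manifest(fx$manifest)
    local_fixture_cache$res <- list(fixture = fx, result = res)
  }
  local_fixture_cache$res
}

# Minimal valid three-target design (no files).
toy_design <- function() {
  standard_design(c("CYP1A2", "CYP2C9", "CYP3A4"),
                  c(CYP1A2 = "alpha-naphthoflavone",
                    CYP2C9 = "sulfaphenazole",
                    CYP3A4 = "ketoconazole"))
}
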