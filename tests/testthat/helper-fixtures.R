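# Small landscapes and model fixtures shared across tests.

# a fast 8 x 8 km landscape (64 coarse cells, 320 x 320 fine cells)
tiny_config <- function(seed = 1L, ...) {
  landscape_config(extent_km = 8, climate_smooth_km = 3, seed = seed, ...)
}

tiny_landscape <- function(seed = 1L, n_sites = 40, process = abundance_process()) {
  cfg <- tiny_config(seed)
  env <- generate_environment(cfg)
  comp <- align_to_coarse(env$landcover, env$climate[[1L]],
                          class_names = cfg$land_classes)
  surface <- generate_abundance_surface(env$climate, comp, process, cfg)
  sites <- sample_sites(surface, n_sites, cfg, process)
  list(config = cfg, env = env, composition = comp, surface = surface,
       sites = sites)
}

# regression fixture: response an exact function of one covariate, the rest
# pure noise
separable_sites <- function(n = 200, p_noise = 4, seed = 42L) {
  withr::with_seed(seed, {
    d <- as.data.frame(matrix(rnorm(n * p_noise), n,
                              dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
    d$driver <- runif(n, 0, 10)
    d$mean_count <- round(exp(0.5 * d$driver))
    d$category <- categorize(d$mean_count)
    d
  })
}

fixture_covariates <- function(d) setdiff(names(d), c("mean_count", "category"))
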