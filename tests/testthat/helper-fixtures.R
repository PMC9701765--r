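# Shared fixtures: small in-code observation tables and quick generator
# configurations.

quick_ctrl <- meta_control(restarts = 0)

# a tiny well-formed observation table (short decimals so CSV round trips
# are exact)
tiny_observations <- function() {
  data.frame(
    obs_id = c("o1", "o2", "o3"),
    study_id = c("s1", "s1", "s2"),
    site_id = c("s1_a", "s1_a", ""),
    plot_id = c("p1", "", ""),
    plant_species = c("Triticum aestivum", "Triticum aestivum",
                      "Zostera marina"),
    trophic_group = c("plant", "disease", "plant"),
    response_category = c("plant_growth", "disease_spread",
                          "plant_reproduction"),
    mean_treat = c(6.5, 2.25, 10),
    mean_ctrl = c(5, 4.5, 9.5),
    sd_treat = c(1.5, 1.25, 2),
    sd_ctrl = c(1.25, 1, 2.5),
    n_treat = c(10L, 8L, 6L),
    n_ctrl = c(10L, 8L, 6L),
    n_genotypes_added = c(4L, 4L, 2L),
    ecosystem = c("agroecosystem", "agroecosystem", "marine"),
    life_form = c("herbaceous", "herbaceous", "herbaceous"),
    experiment_type = c("plot", "plot", "plot"),
    climate_zone = c("temperate", "temperate", "temperate"),
    latitude = c(48.5, 48.5, NA),
    longitude = c(9.1, 9.1, NA),
    stringsAsFactors = FALSE
  )
}

# balanced six-group config with no species heterogeneity, for calibration
# simulations (fast mode: g, v drawn from the SMD sampling distribution)
balanced_config <- function(seed, n_studies = 50L, true_means = NULL,
                            obs_per_study = c(2L, 3L), ...) {
  groups <- trophic_groups()
  if (is.null(true_means)) true_means <- setNames(rep(0, 6), groups)
  synthetic_config(
    seed = seed, n_studies = n_studies, obs_per_study = obs_per_study,
    group_probs = setNames(rep(1 / 6, 6), groups),
    true_means = true_means, tau2_species = 0, fast = TRUE, ...
  )
}

# simulated effect-size table ready for fit_meta (standard, non-fast mode)
simulated_effects <- function(seed, n_studies = 30L, ...) {
  cfg <- synthetic_config(seed = seed, n_studies = n_studies, ...)
  d <- validate_observations(simulate_observations(cfg))$records
  add_effect_sizes(d)
}
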