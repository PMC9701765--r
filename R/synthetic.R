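# Synthetic-data generator: hierarchical effect-size data with the exact
# statistical structure the analyses assume, so every pipeline stage is
# testable without external data.

#' Configuration of the synthetic-data generator
#'
#' Defaults define the reference study conditions used throughout the
#' test-suite: 150 studies of 1-5 observations, six trophic groups with
#' true mean standardized effects echoing published syntheses of plant
#' genetic diversity experiments, between-study / between-observation /
#' between-species heterogeneity, a Yule species tree with Brownian
#' phylogenetic signal on half the species variance, and per-arm group
#' sizes of 4-30.
#'
#' @param seed integer seed for the global stream (forked per study, so
#'   adding studies does not perturb earlier ones).
#' @param n_studies number of studies.
#' @param obs_per_study integer range (min, max) of observations drawn per
#'   study.
#' @param group_probs named probabilities over [trophic_groups()].
#' @param true_means named true mean standardized effect per group.
#' @param b_genotypes slope of the true effect on `log2(n_genotypes)`.
#' @param tau2_study,tau2_obs,tau2_species variance components.
#' @param phylo_signal mixing weight in `[0, 1]` of the phylogenetic
#'   correlation (vs identity) in the species covariance.
#' @param n_species number of species; `birth_rate` Yule birth rate of
#'   the simulated tree.
#' @param n_range per-arm sample-size range; `sd_range` raw-scale SD
#'   range.
#' @param genotype_levels set of genotype-addition levels sampled for the
#'   diversity treatments.
#' @param paths named path coefficients of the trophic-interaction DAG:
#'   `div_enemy`, `div_herb`, `div_plant`, `enemy_herb`, `herb_plant`
#'   (tri-trophic) and `div_antag`, `antag_plant` (bi-trophic).
#' @param path_noise_sd exogenous noise SD of the DAG equations.
#' @param censor_prob probability of suppressing an effect in
#'   `censor_direction` (publication-bias mechanism; 0 = none).
#' @param censor_direction `"negative"` or `"positive"`.
#' @param censor_rule `"small_v"` suppresses effects in the disfavoured
#'   direction whose sampling variance is below the sample median;
#'   `"nonsig"` suppresses nonsignificant effects in that direction.
#' @param fast if TRUE, emit `(g, v)` directly from the SMD sampling
#'   distribution instead of drawing raw arms (for large calibration
#'   runs).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 20221127L,
    n_studies = 150L,
    obs_per_study = c(1L, 5L),
    group_probs = c(plant = 0.35, herbivore = 0.25, natural_enemy = 0.10,
                    weed = 0.07, nematode = 0.03, disease = 0.20),
    true_means = c(plant = 0.344, herbivore = -0.606, natural_enemy = 0.778,
                   weed = -0.071, nematode = -2.118, disease = -1.087),
    b_genotypes = 0,
    tau2_study = 0.10, tau2_obs = 0.05, tau2_species = 0.05,
    phylo_signal = 0.5,
    n_species = 40L, birth_rate = 1,
    n_range = c(4L, 30L), sd_range = c(0.5, 2),
    genotype_levels = c(2L, 3L, 4L, 6L, 8L),
    paths = c(div_enemy = 0.7, div_herb = -0.8, div_plant = 0.9,
              enemy_herb = 0, herb_plant = 0,
              div_antag = -0.54, antag_plant = -0.2),
    path_noise_sd = 1,
    censor_prob = 0, censor_direction = "negative",
    censor_rule = c("small_v", "nonsig"),
    fast = FALSE) {
  censor_rule <- match.arg(censor_rule)
  stopifnot(
    abs(sum(group_probs) - 1) < 1e-8,
    setequal(names(group_probs), trophic_groups()),
    setequal(names(true_means), trophic_groups()),
    tau2_study >= 0, tau2_obs >= 0, tau2_species >= 0,
    phylo_signal >= 0, phylo_signal <= 1,
    n_species >= 2, obs_per_study[1] >= 1,
    obs_per_study[2] >= obs_per_study[1],
    n_range[1] >= 2, n_range[2] >= n_range[1],
    sd_range[1] > 0, sd_range[2] >= sd_range[1],
    length(genotype_levels) >= 1, all(genotype_levels >= 2),
    censor_prob >= 0, censor_prob < 1
  )
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a Yule species tree
#'
#' Pure-birth tree with `n_species` tips labelled `sp_1 ... sp_n`,
#' reproducible under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return Newick string.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  phy <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
  phy$tip.label <- paste0("sp_", seq_len(config$n_species))
  ape::write.tree(phy)
}

.categories_of <- function(group) {
  names(.response_map)[.response_map == group]
}

# sample() treats a scalar first argument as 1:x; this does not
.resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

# sampling distribution of Hedges' g given true standardized effect theta:
# d ~ N(theta, (nt+nc)/(nt nc) + theta^2 / (2 m)), g = J(m) d
.fast_g <- function(theta, nt, nc) {
  m <- nt + nc - 2
  j <- smd_correction(m)
  vd <- (nt + nc) / (nt * nc) + theta^2 / (2 * m)
  g <- j * rnorm(length(theta), theta, sqrt(vd))
  v <- (nt + nc) / (nt * nc) + (1 - (m - 2) / (m * j^2)) * g^2
  data.frame(g = g, v = v, m = m, j = j)
}

# raw two-arm draw carrying standardized difference theta
.arm_summaries <- function(theta, nt, nc, sigma) {
  xt <- rnorm(nt, mean = theta * sigma, sd = sigma)
  xc <- rnorm(nc, mean = 0, sd = sigma)
  c(mean_treat = mean(xt), mean_ctrl = mean(xc),
    sd_treat = sd(xt), sd_ctrl = sd(xc))
}

.draw_species_effects <- function(config, R) {
  Sigma <- config$tau2_species *
    (config$phylo_signal * R + (1 - config$phylo_signal) * diag(nrow(R)))
  L <- chol(Sigma + diag(1e-10, nrow(R)))
  drop(crossprod(L, rnorm(nrow(R))))
}

.study_moderators <- function() {
  eco <- sample(ecosystems(), 1L,
                prob = c(0.70, 0.08, 0.06, 0.05, 0.04, 0.04, 0.03))
  exp_type <- sample(c("plot", "pot", "indoor"), 1L, prob = c(0.75, 0.18, 0.07))
  clim <- if (exp_type == "indoor") "indoor" else
    sample(c("temperate", "tropical"), 1L, prob = c(0.85, 0.15))
  life <- sample(c("herbaceous", "woody"), 1L, prob = c(0.82, 0.18))
  list(ecosystem = eco, experiment_type = exp_type,
       climate_zone = clim, life_form = life)
}

#' Simulate a hierarchical observation table
#'
#' For each observation the true standardized effect is
#' `theta = mu_group + b log2(genotypes) + u_species + u_study + u_obs`,
#' with species effects multivariate normal under the mixed
#' phylogenetic/iid covariance; raw treatment and control samples are then
#' drawn with that standardized difference and summarized, so the
#' effect-size stage is exercised end to end. In fast mode `(g, v)` are
#' drawn from the SMD sampling distribution directly.
#'
#' @param config a [synthetic_config()].
#' @param tree optional Newick string (defaults to [simulate_tree()]
#'   under the same config).
#' @return Data frame of observation records ([observation_schema()]
#'   layout; in fast mode raw summaries are replaced by computed `g`,
#'   `v`, `m`, `j` columns). Attribute `truth` records every planted
#'   parameter and the per-observation `theta`.
#' @export
simulate_observations <- function(config, tree = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(tree)) tree <- simulate_tree(config)
  R <- phylo_correlation(tree)
  set.seed(config$seed)
  u_sp <- .draw_species_effects(config, R)
  names(u_sp) <- rownames(R)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies)

  rows <- vector("list", config$n_studies)
  thetas <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    set.seed(study_seeds[s])  # forked stream per study
    sid <- sprintf("study_%03d", s)
    sp_s <- sample(rownames(R), 1L)
    mods <- .study_moderators()
    u_st <- rnorm(1, 0, sqrt(config$tau2_study))
    k <- .resample(seq(config$obs_per_study[1], config$obs_per_study[2]), 1L)
    grp <- sample(names(config$group_probs), k, replace = TRUE,
                  prob = config$group_probs)
    geno <- .resample(config$genotype_levels, k)
    u_ob <- rnorm(k, 0, sqrt(config$tau2_obs))
    theta <- config$true_means[grp] + config$b_genotypes * log2(geno) +
      u_sp[sp_s] + u_st + u_ob
    nt <- .resample(seq(config$n_range[1], config$n_range[2]), k)
    nc <- .resample(seq(config$n_range[1], config$n_range[2]), k)
    cat_of <- vapply(grp, function(g) sample(.categories_of(g), 1L),
                     character(1))
    base <- data.frame(
      obs_id = sprintf("%s_obs_%02d", sid, seq_len(k)),
      study_id = sid,
      site_id = paste0(sid, "_site_1"),
      plot_id = NA_character_,
      plant_species = sp_s,
      trophic_group = grp,
      response_category = cat_of,
      stringsAsFactors = FALSE
    )
    if (config$fast) {
      es <- .fast_g(theta, nt, nc)
      base <- cbind(base, es)
    } else {
      sigma <- runif(k, config$sd_range[1], config$sd_range[2])
      summ <- t(vapply(seq_len(k), function(i) {
        .arm_summaries(theta[i], nt[i], nc[i], sigma[i])
      }, numeric(4)))
      base <- cbind(base, as.data.frame(summ))
    }
    base$n_treat <- nt
    base$n_ctrl <- nc
    base$n_genotypes_added <- geno
    base$ecosystem <- mods$ecosystem
    base$life_form <- mods$life_form
    base$experiment_type <- mods$experiment_type
    base$climate_zone <- mods$climate_zone
    base$latitude <- NA_real_
    base$longitude <- NA_real_
    rows[[s]] <- base
    thetas[[s]] <- unname(theta)
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  theta_all <- unlist(thetas)

  if (config$censor_prob > 0) {
    # publication-bias mechanism: suppress nonsignificant effects in the
    # disfavoured direction with probability censor_prob
    gv <- if (config$fast) d[, c("g", "v")] else {
      es <- smd(d$mean_treat, d$mean_ctrl, d$sd_treat, d$sd_ctrl,
                d$n_treat, d$n_ctrl)
      es[, c("g", "v")]
    }
    wrong_dir <- if (config$censor_direction == "negative") gv$g < 0 else gv$g > 0
    at_risk <- if (config$censor_rule == "small_v") {
      gv$v < stats::median(gv$v)
    } else {
      abs(gv$g / sqrt(gv$v)) < 1.96
    }
    set.seed(config$seed + 1L)
    drop <- wrong_dir & at_risk & runif(nrow(d)) < config$censor_prob
    d <- d[!drop, , drop = FALSE]
    theta_all <- theta_all[!drop]
    rownames(d) <- NULL
  }

  attr(d, "truth") <- list(
    true_means = config$true_means, b_genotypes = config$b_genotypes,
    tau2_study = config$tau2_study, tau2_obs = config$tau2_obs,
    tau2_species = config$tau2_species, phylo_signal = config$phylo_signal,
    theta = theta_all, tree = tree, seed = config$seed
  )
  d
}

#' Simulate co-measured trophic interaction observations
#'
#' Generates one diversity contrast per study with co-measured trophic
#' responses linked by the configured path coefficients of the linear DAG
#' (exogenous noise SD `path_noise_sd`): tri-trophic
#' (enemy, herbivore, plant) or bi-trophic (antagonist, plant). Emits
#' long-format observation records so the pairing/tripling stage is
#' exercised end to end; the planted structure is recorded in the
#' `truth` attribute.
#'
#' @param config a [synthetic_config()].
#' @param type `"tri"` or `"bi"`.
#' @return Observation data frame (fast mode layout if `config$fast`),
#'   with attribute `truth` listing planted paths, per-study latent
#'   effects and the planted contrast count.
#' @export
simulate_trophic_links <- function(config, type = c("tri", "bi")) {
  stopifnot(inherits(config, "synthetic_config"))
  type <- match.arg(type)
  set.seed(config$seed)
  p <- config$paths
  ns <- config$n_studies
  div <- rep(1, ns)  # every contrast is diversity vs monoculture
  noise <- function() rnorm(ns, 0, config$path_noise_sd)
  if (type == "tri") {
    th_enemy <- p[["div_enemy"]] * div + noise()
    th_herb <- p[["div_herb"]] * div + p[["enemy_herb"]] * th_enemy + noise()
    th_plant <- p[["div_plant"]] * div + p[["herb_plant"]] * th_herb + noise()
    latent <- data.frame(natural_enemy = th_enemy, herbivore = th_herb,
                         plant = th_plant)
    cats <- c(natural_enemy = "predator_abundance",
              herbivore = "herbivore_abundance", plant = "plant_growth")
  } else {
    th_ant <- p[["div_antag"]] * div + noise()
    th_plant <- p[["div_plant"]] * div + p[["antag_plant"]] * th_ant + noise()
    latent <- data.frame(herbivore = th_ant, plant = th_plant)
    cats <- c(herbivore = "herbivore_abundance", plant = "plant_growth")
  }
  species <- paste0("sp_", sample.int(config$n_species, ns, replace = TRUE))
  geno <- .resample(config$genotype_levels, ns)
  rows <- list()
  for (s in seq_len(ns)) {
    sid <- sprintf("study_%03d", s)
    for (node in names(latent)) {
      theta <- latent[[node]][s]
      nt <- .resample(seq(config$n_range[1], config$n_range[2]), 1L)
      nc <- .resample(seq(config$n_range[1], config$n_range[2]), 1L)
      base <- data.frame(
        obs_id = paste0(sid, "_", node),
        study_id = sid, site_id = paste0(sid, "_site_1"),
        plot_id = NA_character_,
        plant_species = species[s],
        trophic_group = node, response_category = cats[[node]],
        stringsAsFactors = FALSE
      )
      if (config$fast) {
        base <- cbind(base, .fast_g(theta, nt, nc))
      } else {
        sigma <- runif(1, config$sd_range[1], config$sd_range[2])
        base <- cbind(base,
                      as.data.frame(t(.arm_summaries(theta, nt, nc, sigma))))
      }
      base$n_treat <- nt; base$n_ctrl <- nc
      base$n_genotypes_added <- geno[s]
      base$ecosystem <- "agroecosystem"; base$life_form <- "herbaceous"
      base$experiment_type <- "plot"; base$climate_zone <- "temperate"
      base$latitude <- NA_real_; base$longitude <- NA_real_
      rows[[length(rows) + 1L]] <- base
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  attr(d, "truth") <- list(paths = p, type = type, latent = latent,
                           n_contrasts = ns, seed = config$seed)
  d
}
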