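# Independent REML oracle for a single observation-level component:
# V = diag(v) + tau2 I, restricted likelihood computed directly with
# solve() and determinant(), maximized by grid search.
.reml_ll_direct <- function(tau2, y, X, v) {
  n <- length(y); p <- ncol(X)
  V <- diag(v + tau2)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            as.numeric(t(r) %*% Vi %*% r)) +
    0.5 * as.numeric(determinant(t(X) %*% X)$modulus)
}

test_that("with all variance components at zero beta is the inverse-variance mean", {
  set.seed(1)
  d <- data.frame(g = rnorm(20, 0.3, 0.4), v = runif(20, 0.05, 0.4),
                  study_id = rep(sprintf("s%02d", 1:10), each = 2),
                  plant_species = "sp", obs = 1:20)
  f <- fit_meta(d, ~ 1, random = "obs", tau2 = c(obs = 0))
  expect_equal(unname(f$beta), sum(d$g / d$v) / sum(1 / d$v),
               tolerance = 1e-10)
  # equal sampling variances: plain arithmetic mean
  d$v <- 0.1
  f2 <- fit_meta(d, ~ 1, random = "obs", tau2 = c(obs = 0))
  expect_equal(unname(f2$beta), mean(d$g), tolerance = 1e-10)
})

test_that("REML matches a brute-force grid search on a toy set", {
  set.seed(2)
  d <- data.frame(g = c(0.1, 0.6, 0.4, -0.2, 0.9, 0.35),
                  v = c(0.05, 0.10, 0.20, 0.08, 0.15, 0.12),
                  study_id = rep(c("s1", "s2"), each = 3),
                  plant_species = "sp", obs = 1:6)
  f <- fit_meta(d, ~ 1, random = "obs")
  Xd <- matrix(1, 6, 1)
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(t2) .reml_ll_direct(t2, d$g, Xd, d$v),
               numeric(1))
  tau2_grid <- grid[which.max(ll)]
  expect_lt(abs(unname(f$tau2["obs"]) - tau2_grid), 1e-4)
  expect_gte(f$loglik, max(ll) - 1e-8)
})

test_that("full multilevel phylogenetic fit agrees with the reference implementation", {
  cfg <- synthetic_config(seed = 21L, n_studies = 30L)
  tree <- simulate_tree(cfg)
  d <- simulated_effects(21L, n_studies = 30L)
  R <- phylo_correlation(tree, unique(d$plant_species))
  d <- d[d$plant_species %in% rownames(R), ]
  f <- fit_meta(d, ~ 1, random = c("species_phylo", "species", "study", "obs"),
                R = R)
  d$sp2 <- d$plant_species
  ref <- metafor::rma.mv(g, v,
                         random = list(~ 1 | plant_species, ~ 1 | sp2,
                                       ~ 1 | study_id, ~ 1 | obs),
                         R = list(plant_species = R), data = d,
                         method = "REML", control = list(rel.tol = 1e-10))
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(f$beta), as.numeric(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(f$se), as.numeric(ref$se), tolerance = 1e-4)
})

test_that("identity phylogeny is equivalent to the iid species component", {
  d <- simulated_effects(22L, n_studies = 25L)
  sp <- unique(d$plant_species)
  I_R <- diag(length(sp)); dimnames(I_R) <- list(sp, sp)
  fa <- fit_meta(d, ~ 1, random = c("species_phylo", "study", "obs"), R = I_R)
  fb <- fit_meta(d, ~ 1, random = c("species", "study", "obs"))
  expect_equal(fa$loglik, fb$loglik, tolerance = 1e-6)
  expect_equal(fa$beta, fb$beta, tolerance = 1e-6)
})

test_that("results are invariant to row permutation", {
  d <- simulated_effects(23L, n_studies = 20L)
  f1 <- fit_meta(d, ~ 0 + trophic_group, random = c("study", "obs"))
  set.seed(9)
  f2 <- fit_meta(d[sample(nrow(d)), ], ~ 0 + trophic_group,
                 random = c("study", "obs"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("the returned optimum dominates random perturbations of tau2", {
  d <- simulated_effects(24L, n_studies = 25L)
  f <- fit_meta(d, ~ 1, random = c("species", "study", "obs"))
  expect_true(isTRUE(check_local_optimum(f, n_perturb = 64L)))
})

test_that("likelihood-ratio test handles identical models and misuse", {
  d <- simulated_effects(25L, n_studies = 20L)
  f <- fit_meta(d, ~ 1, random = c("study", "obs"))
  same <- lrt(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  g <- fit_meta(d, ~ 0 + trophic_group, random = c("study", "obs"))
  expect_error(lrt(f, g), "not nested")
  expect_error(lrt(g, fit_meta(d[-1, ], ~ 1, random = c("study", "obs"))),
               "different numbers of observations")
})

test_that("moderator LRT detects a strong planted group effect", {
  # true group means far apart: the trophic-group term should be found
  hits <- 0L
  for (i in 1:20) {
    d <- simulate_observations(balanced_config(
      400L + i, n_studies = 80L,
      true_means = setNames(c(0.35, -0.6, 0.78, -0.07, -0.3, 0.5),
                            trophic_groups())))
    full <- fit_meta(d, ~ 0 + trophic_group, random = c("study", "obs"),
                     method = "ML", control = quick_ctrl)
    red <- fit_meta(d, ~ 1, random = c("study", "obs"), method = "ML",
                    control = quick_ctrl)
    if (lrt(full, red)$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 20, 0.8)
})

test_that("category estimates expose per-level means with t inference", {
  d <- simulated_effects(26L, n_studies = 20L)
  f <- fit_meta(d, ~ 1, random = c("study", "obs"))
  ce <- category_estimates(f)
  expect_equal(ce$effect, unname(f$beta))
  expect_equal(ce$t, unname(f$beta / f$se))
  expect_equal(ce$p, unname(2 * pt(-abs(f$beta / f$se), f$df_resid)))

  d$trophic_group <- factor(d$trophic_group)
  fg <- fit_meta(d, ~ 0 + trophic_group, random = c("study", "obs"))
  cg <- category_estimates(fg, term = "trophic_group")
  expect_setequal(cg$label, as.character(unique(d$trophic_group)))
  expect_equal(sum(cg$k_obs), nrow(d))
  expect_true(all(cg$ci_low <= cg$effect & cg$effect <= cg$ci_high))
  expect_error(category_estimates(f, term = "trophic_group"), "inestimable")
})

test_that("rank-deficient designs raise a design error naming aliased columns", {
  d <- simulated_effects(27L, n_studies = 15L)
  d$dup <- as.numeric(d$n_treat)
  d$dup2 <- 2 * d$dup
  expect_error(fit_meta(d, ~ dup + dup2, random = c("study", "obs")),
               "aliased")
})

test_that("doubling the study-level heterogeneity doubles its estimate", {
  t1 <- t2 <- numeric(100)
  for (i in 1:100) {
    d1 <- simulate_observations(balanced_config(600L + i, n_studies = 60L,
                                                tau2_study = 0.10))
    d2 <- simulate_observations(balanced_config(9600L + i, n_studies = 60L,
                                                tau2_study = 0.20))
    t1[i] <- fit_meta(d1, ~ 1, random = c("study", "obs"),
                      control = quick_ctrl)$tau2["study"]
    t2[i] <- fit_meta(d2, ~ 1, random = c("study", "obs"),
                      control = quick_ctrl)$tau2["study"]
  }
  # ratio of the mean estimates across replicates
  expect_gt(mean(t2) / mean(t1), 1.6)
  expect_lt(mean(t2) / mean(t1), 2.4)
})
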