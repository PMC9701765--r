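test_that("DAG validation and the d-separation basis set", {
  expect_error(sem_spec(c("a", "b"), rbind(c("a", "b"), c("b", "a"))),
               "cyclic")
  expect_error(sem_spec("a", rbind(c("a", "a"))), "self-loop")

  # saturated three-node DAG: empty basis set
  sat <- bi_trophic_spec()
  expect_length(basis_set(sat), 0L)

  # chain x -> m -> y: single claim x _||_ y | m
  chain <- sem_spec(c("x", "m", "y"), rbind(c("x", "m"), c("m", "y")))
  bs <- basis_set(chain)
  expect_length(bs, 1L)
  expect_equal(bs[[1]]$a, "x")
  expect_equal(bs[[1]]$b, "y")
  expect_equal(bs[[1]]$conditioning, "m")
})

test_that("tri-trophic basis set matches brute-force enumeration", {
  spec <- tri_trophic_spec()
  bs <- basis_set(spec)
  # independent oracle: enumerate all unordered non-adjacent pairs
  nodes <- spec$nodes
  adj <- apply(spec$edges, 1, paste, collapse = "|")
  oracle <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    a <- nodes[i]; b <- nodes[j]
    if (paste(a, b, sep = "|") %in% adj || paste(b, a, sep = "|") %in% adj) next
    oracle[[length(oracle) + 1L]] <- sort(c(a, b))
  }
  expect_length(bs, length(oracle))
  got <- lapply(bs, function(cl) sort(c(cl$a, cl$b)))
  expect_setequal(vapply(got, paste, "", collapse = "|"),
                  vapply(oracle, paste, "", collapse = "|"))
  # the single claim: enemy _||_ plant | {diversity, herbivore}
  expect_equal(bs[[1]]$conditioning, c("diversity", "herbivore"))
})

test_that("Fisher's C combines claim p-values", {
  f1 <- fishers_c(1)
  expect_equal(f1$C, 0)
  expect_equal(f1$p, 1)
  f2 <- fishers_c(c(0.5, 0.5))
  expect_equal(f2$C, -2 * (log(0.5) + log(0.5)))
  expect_equal(f2$df, 4L)
  expect_warning(f0 <- fishers_c(c(0, 0.5)), "clipped")
  expect_true(f0$p < 1e-10)
  expect_error(fishers_c(numeric(0)), "no p-values")
  expect_error(fishers_c(1.2))
})

test_that("component models agree with the reference mixed meta-regression", {
  cfg <- synthetic_config(seed = 51L, n_studies = 60L, fast = TRUE)
  d <- simulate_trophic_links(cfg, "bi")
  pairs <- build_pairs(d, "plant", "herbivore")
  comp <- fit_component(pairs, "lower", c("diversity", "upper"),
                        random = "study")
  ref <- metafor::rma.mv(g_lower, v_lower, mods = ~ g_upper,
                         random = ~ 1 | study_id, data = pairs,
                         method = "REML", control = list(rel.tol = 1e-10))
  expect_equal(comp$coefficients$estimate,
               as.numeric(coef(ref)), tolerance = 1e-5)
  expect_equal(comp$coefficients$se, as.numeric(ref$se), tolerance = 1e-4)
  # constant exogenous parent resolves to the intercept path
  expect_equal(unname(comp$path_term["diversity"]), "(Intercept)")
  expect_equal(unname(comp$path_term["upper"]), "upper")
})

test_that("SEM statistics are invariant to consistent node relabeling", {
  cfg <- synthetic_config(seed = 52L, n_studies = 50L, fast = TRUE)
  d <- simulate_trophic_links(cfg, "tri")
  trip <- build_triples(d)
  r1 <- run_sem(tri_trophic_spec(), trip)

  ren <- trip
  names(ren)[names(ren) == "g_enemy"] <- "g_carnivore"
  names(ren)[names(ren) == "v_enemy"] <- "v_carnivore"
  spec2 <- sem_spec(c("diversity", "carnivore", "herbivore", "plant"),
                    rbind(c("diversity", "carnivore"),
                          c("diversity", "herbivore"),
                          c("diversity", "plant"),
                          c("carnivore", "herbivore"),
                          c("herbivore", "plant")))
  r2 <- run_sem(spec2, ren)
  expect_equal(r1$paths$estimate, r2$paths$estimate, tolerance = 1e-12)
  expect_equal(r1$fisher_c, r2$fisher_c, tolerance = 1e-12)
})

test_that("saturated DAGs emit no global test and row order does not matter", {
  cfg <- synthetic_config(seed = 53L, n_studies = 40L, fast = TRUE)
  d <- simulate_trophic_links(cfg, "bi")
  pairs <- build_pairs(d, "plant", "antagonist")
  r <- run_sem(bi_trophic_spec(), pairs)
  expect_equal(r$fisher_df, 0L)
  expect_true(is.na(r$fisher_c))
  expect_null(r$dsep)

  set.seed(7)
  r2 <- run_sem(bi_trophic_spec(), pairs[sample(nrow(pairs)), ])
  expect_equal(r$paths$estimate, r2$paths$estimate, tolerance = 1e-10)
})

test_that("planted bi-trophic paths and the indirect effect are recovered", {
  ests <- matrix(NA_real_, 60, 3)
  ind <- numeric(60)
  for (i in 1:60) {
    cfg <- synthetic_config(seed = 5400L + i, n_studies = 80L, fast = TRUE)
    d <- simulate_trophic_links(cfg, "bi")
    pairs <- build_pairs(d, "plant", "antagonist")
    r <- run_sem(bi_trophic_spec(), pairs)
    pick <- function(from, to) {
      r$paths$estimate[r$paths$from == from & r$paths$to == to]
    }
    ests[i, ] <- c(pick("diversity", "upper"), pick("diversity", "lower"),
                   pick("upper", "lower"))
    ind[i] <- indirect_effect(r, c("diversity", "upper", "lower"))
  }
  truth <- synthetic_config()$paths
  expect_lt(abs(mean(ests[, 1]) - truth[["div_antag"]]), 0.1)
  expect_lt(abs(mean(ests[, 2]) - truth[["div_plant"]]), 0.1)
  expect_lt(abs(mean(ests[, 3]) - truth[["antag_plant"]]), 0.1)
  expect_lt(abs(mean(ind) - truth[["div_antag"]] * truth[["antag_plant"]]),
            0.08)
})
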