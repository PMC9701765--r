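# End-to-end orchestration: validate -> effect sizes -> meta-regression
# -> genotype trend -> piecewise SEM -> publication bias, with
# deterministic CSV/JSON artifacts and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param input path to an observations CSV, or a data frame, or NULL to
#'   run on synthetic data generated from `synthetic`.
#' @param tree optional Newick file/string for the phylogenetic
#'   correlation; NULL fits the iid species structure only.
#' @param synthetic a [synthetic_config()] used when `input` is NULL.
#' @param filters named list of moderator filters applied before
#'   analysis, e.g. `list(ecosystem = "agroecosystem")`.
#' @param out_dir output directory for report tables.
#' @param alpha significance level (0.05).
#' @param seed integer seed (propagated to the synthetic generator).
#' @param schema optional column map for [read_observations()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, tree = NULL,
                            synthetic = synthetic_config(),
                            filters = list(), out_dir = NULL,
                            alpha = 0.05, seed = NULL, schema = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(list(input = input, tree = tree, synthetic = synthetic,
                 filters = filters, out_dir = out_dir, alpha = alpha,
                 schema = schema),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `input`, `tree`, `out_dir`, `alpha`, `seed`,
#' `filters` (map), and `synthetic` (map of [synthetic_config()]
#' arguments).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic %||% list()
  if (!is.null(syn_args$group_probs)) syn_args$group_probs <- unlist(syn_args$group_probs)
  if (!is.null(syn_args$true_means)) syn_args$true_means <- unlist(syn_args$true_means)
  if (!is.null(syn_args$paths)) syn_args$paths <- unlist(syn_args$paths)
  pipeline_config(
    input = y$input, tree = y$tree,
    synthetic = do.call(synthetic_config, syn_args),
    filters = y$filters %||% list(),
    out_dir = y$out_dir, alpha = y$alpha %||% 0.05, seed = y$seed,
    schema = if (!is.null(y$schema)) unlist(y$schema)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.apply_filters <- function(d, filters) {
  for (col in names(filters)) {
    stopifnot(col %in% names(d))
    d <- d[d[[col]] %in% filters[[col]], , drop = FALSE]
  }
  d
}

# write a report table with fixed 6-significant-digit formatting so
# reruns are byte-identical
.write_table <- function(d, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) signif(x, 6))
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input (or on synthetic data)
#' and, when `out_dir` is set, writes the report tables
#' (`effect_sizes`, `category_estimates`, `variance_components`,
#' `model_comparison`, `trend`, `trend_predictions`, `sem_paths`,
#' `sem_dsep`, `sem_global`, `bias`, `rejects`), a machine-readable
#' `summary.json` and a `manifest.json` with input/config hashes.
#'
#' @param config a [pipeline_config()].
#' @return List with the fitted objects and summary tables (invisibly
#'   written to disk when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  # ---- data ------------------------------------------------------------
  if (is.null(config$input)) {
    raw <- simulate_observations(config$synthetic)
    tree <- attr(raw, "truth")$tree
    rejects <- raw[0, ]
    records <- raw
    if (!config$synthetic$fast) {
      val <- validate_observations(raw)
      records <- val$records
      rejects <- val$rejects
    }
  } else {
    if (is.data.frame(config$input)) {
      val <- validate_observations(config$input)
    } else {
      val <- read_observations(config$input, schema = config$schema)
    }
    records <- val$records
    rejects <- val$rejects
    tree <- config$tree
  }
  records <- .apply_filters(records, config$filters)
  if (nrow(records) < 10L) stop("fewer than 10 valid observations",
                                call. = FALSE)

  es <- if ("g" %in% names(records)) {
    records$obs <- records$obs_id
    records
  } else {
    add_effect_sizes(records)
  }

  # ---- meta-regression -------------------------------------------------
  R <- if (!is.null(tree)) phylo_correlation(tree, unique(es$plant_species))
  random <- if (is.null(R)) c("species", "study", "obs") else
    c("species_phylo", "species", "study", "obs")
  es$trophic_group <- factor(es$trophic_group)
  base_fit <- fit_meta(es, ~ 0 + trophic_group, random = random, R = R)
  cats <- category_estimates(base_fit, term = "trophic_group")

  # antagonist aggregate: refit on the aggregated grouping so the
  # aggregate mean is a model coefficient
  es$agg_group <- ifelse(es$trophic_group %in% antagonist_groups(),
                         "antagonist", as.character(es$trophic_group))
  agg_fit <- fit_meta(es, ~ 0 + agg_group, random = random, R = R)
  cats_agg <- category_estimates(agg_fit, term = "agg_group")
  cats <- rbind(cats, cats_agg[cats_agg$label == "antagonist", ])

  # moderator LRT (single-term addition of ecosystem, as in the base
  # model comparisons); skipped when the stratum has a single level
  comparisons <- NULL
  if (length(unique(es$ecosystem)) > 1L) {
    full <- fit_meta(es, ~ 0 + trophic_group + ecosystem, random = random,
                     R = R)
    cmp <- lrt(full, base_fit)
    comparisons <- data.frame(term = "ecosystem", statistic = cmp$statistic,
                              df = cmp$df, p = cmp$p)
  }

  vc <- data.frame(component = names(base_fit$tau2),
                   tau2 = unname(base_fit$tau2))

  # ---- genotype-number trend ------------------------------------------
  trend <- trend_by_group(es)
  ant <- es[es$trophic_group %in% antagonist_groups(), ]
  grid <- seq(min(log_genotypes(ant$n_genotypes_added)),
              max(log_genotypes(ant$n_genotypes_added)), length.out = 25)
  trend_fit <- fit_gls_varexp(log_genotypes(ant$n_genotypes_added), ant$g)
  band <- predict_with_band(trend_fit, grid)

  # ---- piecewise SEM ---------------------------------------------------
  pairs_ap <- build_pairs(es, "plant", "antagonist")
  sem_bi <- NULL
  if (nrow(pairs_ap) >= 10L && length(unique(pairs_ap$study_id)) >= 2L) {
    sem_bi <- run_sem(bi_trophic_spec(), pairs_ap)
  }
  triples <- build_triples(es)
  sem_tri <- NULL
  if (nrow(triples) >= 10L && length(unique(triples$study_id)) >= 2L) {
    names(triples)[names(triples) == "g_enemy"] <- "g_enemy"
    sem_tri <- run_sem(tri_trophic_spec(), triples)
  }

  # ---- publication bias ------------------------------------------------
  bias <- regression_bias_test(base_fit)
  fsn <- failsafe_from_effects(es)

  # ---- artifacts -------------------------------------------------------
  .write_table(rejects, dir, "rejects")
  .write_table(es, dir, "effect_sizes")
  .write_table(cats, dir, "category_estimates")
  .write_table(vc, dir, "variance_components")
  if (!is.null(comparisons)) .write_table(comparisons, dir, "model_comparison")
  .write_table(trend, dir, "trend")
  .write_table(band, dir, "trend_predictions")
  if (!is.null(sem_bi)) {
    .write_table(sem_bi$paths, dir, "sem_paths")
    if (!is.null(sem_bi$dsep)) .write_table(sem_bi$dsep, dir, "sem_dsep")
  }
  if (!is.null(sem_tri)) {
    .write_table(sem_tri$paths, dir, "sem_paths_tri")
    if (!is.null(sem_tri$dsep)) .write_table(sem_tri$dsep, dir, "sem_dsep_tri")
    .write_table(data.frame(fisher_c = sem_tri$fisher_c,
                            df = sem_tri$fisher_df, p = sem_tri$fisher_p),
                 dir, "sem_global")
  }
  .write_table(data.frame(slope_v = bias$slope_v, t_v = bias$t_v,
                          p_v = bias$p_v, failsafe_n = fsn$failsafe_n),
               dir, "bias")

  summary <- list(
    n_obs = nrow(es), n_studies = length(unique(es$study_id)),
    n_rejects = nrow(rejects),
    category_estimates = cats,
    tau2 = as.list(base_fit$tau2),
    trend_t_antagonist = trend_fit$t_slope,
    trend_df_antagonist = trend_fit$df_resid,
    bias_p = bias$p_v, failsafe_n = fsn$failsafe_n
  )
  if (!is.null(dir)) {
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = 8, dataframe = "rows")
    files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
    manifest <- list(
      config_hash = .hash_object(unclass(config)[setdiff(names(config),
                                                         "out_dir")]),
      tables = as.list(setNames(unname(tools::md5sum(files)),
                                basename(files)))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(
    records = records, rejects = rejects, effects = es,
    base_fit = base_fit, agg_fit = agg_fit,
    category_estimates = cats, model_comparison = comparisons,
    trend = trend, trend_fit = trend_fit, trend_band = band,
    sem_bi = sem_bi, sem_tri = sem_tri,
    bias = bias, failsafe = fsn, summary = summary
  ))
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(x, digits.d = 12)), f)
  unname(tools::md5sum(f))
}
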