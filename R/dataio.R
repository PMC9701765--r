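# ---- controlled vocabularies --------------------------------------------

#' Controlled vocabularies for the observation table
#'
#' `trophic_groups()` returns the six concrete trophic groups; the plant
#' antagonist aggregate (herbivores, weeds, plant-feeding nematodes and
#' plant diseases) is a derived flag, not a seventh group, and is obtained
#' with [antagonist_groups()] / [map_response_to_group()].
#'
#' @return Character vectors of allowed level names.
#' @export
trophic_groups <- function() {
  c("plant", "herbivore", "natural_enemy", "weed", "nematode", "disease")
}

#' @rdname trophic_groups
#' @export
antagonist_groups <- function() {
  c("herbivore", "weed", "nematode", "disease")
}

#' @rdname trophic_groups
#' @export
ecosystems <- function() {
  c("agroecosystem", "grassland", "forest", "old_field", "marine",
    "wetland", "shrubland")
}

#' @rdname trophic_groups
#' @export
response_categories <- function() {
  names(.response_map)
}

# fixed mapping: response category -> trophic group
.response_map <- c(
  plant_growth        = "plant",
  plant_reproduction  = "plant",
  plant_quality       = "plant",
  herbivore_abundance = "herbivore",
  herbivore_damage    = "herbivore",
  herbivore_diversity = "herbivore",
  predator_abundance  = "natural_enemy",
  predator_diversity  = "natural_enemy",
  parasitoid_abundance = "natural_enemy",
  parasitoid_diversity = "natural_enemy",
  parasitism          = "natural_enemy",
  weed_growth         = "weed",
  weed_diversity      = "weed",
  nematode_abundance  = "nematode",
  disease_spread      = "disease",
  disease_damage      = "disease"
)

#' Map a response category to its trophic group
#'
#' The aggregate "plant antagonist" flag is true for the union of the
#' herbivore, weed, nematode and disease groups.
#'
#' @param response_category character vector of response categories.
#' @return A data frame with columns `response_category`, `trophic_group`
#'   and logical `antagonist`.
#' @export
map_response_to_group <- function(response_category) {
  unknown <- setdiff(unique(response_category), names(.response_map))
  if (length(unknown) > 0L) {
    stop("unknown response categor", if (length(unknown) > 1L) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  grp <- unname(.response_map[response_category])
  data.frame(
    response_category = response_category,
    trophic_group = grp,
    antagonist = grp %in% antagonist_groups(),
    stringsAsFactors = FALSE
  )
}

# ---- schema --------------------------------------------------------------

#' Observation-table schema
#'
#' Column names of the canonical long-format observation table. Optional
#' columns may be absent or NA.
#'
#' @return Named list with `required` and `optional` column names.
#' @export
observation_schema <- function() {
  list(
    required = c("obs_id", "study_id", "plant_species", "trophic_group",
                 "response_category", "mean_treat", "mean_ctrl",
                 "sd_treat", "sd_ctrl", "n_treat", "n_ctrl",
                 "n_genotypes_added", "ecosystem", "life_form",
                 "experiment_type", "climate_zone"),
    optional = c("site_id", "plot_id", "latitude", "longitude")
  )
}

.all_columns <- function() {
  s <- observation_schema()
  c(s$required[1:2], "site_id", "plot_id", s$required[-(1:2)],
    "latitude", "longitude")
}

# ---- validation ----------------------------------------------------------

# Row-level validation; returns character vector of reasons ("" = valid).
.validate_rows <- function(d) {
  n <- nrow(d)
  reasons <- character(n)
  add <- function(bad, why) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], why, sep = "; "), why)
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  for (col in c("mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl",
                "n_treat", "n_ctrl", "n_genotypes_added")) {
    add(is.na(num(d[[col]])), paste0("non-numeric ", col))
  }
  sdt <- num(d$sd_treat); sdc <- num(d$sd_ctrl)
  nt <- num(d$n_treat); nc <- num(d$n_ctrl)
  add(!is.na(sdt) & sdt < 0, "negative sd_treat")
  add(!is.na(sdc) & sdc < 0, "negative sd_ctrl")
  add(!is.na(nt) & (nt < 2 | nt != round(nt)), "insufficient df")
  add(!is.na(nc) & (nc < 2 | nc != round(nc)), "insufficient df")
  add(!is.na(nt) & !is.na(nc) & nt >= 2 & nc >= 2 & (nt + nc < 5),
      "insufficient df")
  add(!is.na(sdt) & !is.na(sdc) & sdt == 0 & sdc == 0,
      "degenerate: both SDs zero")
  ng <- num(d$n_genotypes_added)
  add(!is.na(ng) & (ng < 1 | ng != round(ng)), "invalid n_genotypes_added")

  add(!(d$trophic_group %in% trophic_groups()), "unknown trophic_group")
  add(!(d$response_category %in% response_categories()),
      "unknown response_category")
  known <- d$response_category %in% response_categories()
  mapped <- rep(NA_character_, n)
  mapped[known] <- unname(.response_map[d$response_category[known]])
  add(known & !is.na(mapped) & mapped != d$trophic_group,
      "trophic_group inconsistent with response_category")

  add(!(d$ecosystem %in% ecosystems()), "unknown ecosystem")
  add(!(d$life_form %in% c("herbaceous", "woody")), "unknown life_form")
  add(!(d$experiment_type %in% c("plot", "pot", "indoor")),
      "unknown experiment_type")
  add(!(d$climate_zone %in% c("temperate", "tropical", "indoor")),
      "unknown climate_zone")
  reasons
}

#' Validate an observation table
#'
#' Splits a raw table into validated records and a rejects report. Rows
#' failing any invariant are reported with a reason, never silently
#' dropped.
#'
#' @param d data frame in the [observation_schema()] layout.
#' @return List with elements `records` (validated data frame, numeric
#'   columns coerced) and `rejects` (offending rows plus a `reason`
#'   column).
#' @export
validate_observations <- function(d) {
  stopifnot(is.data.frame(d))
  missing_cols <- setdiff(observation_schema()$required, names(d))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in observation_schema()$optional) {
    if (is.null(d[[col]])) d[[col]] <- NA
  }
  d <- d[, .all_columns(), drop = FALSE]
  reasons <- .validate_rows(d)
  ok <- !nzchar(reasons)
  records <- d[ok, , drop = FALSE]
  for (col in c("mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl",
                "latitude", "longitude")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  for (col in c("n_treat", "n_ctrl", "n_genotypes_added")) {
    records[[col]] <- as.integer(round(as.numeric(records[[col]])))
  }
  rejects <- d[!ok, , drop = FALSE]
  if (nrow(rejects) > 0L) rejects$reason <- reasons[!ok] else rejects$reason <- character(0)
  rownames(records) <- NULL
  rownames(rejects) <- NULL
  list(records = records, rejects = rejects)
}

#' Read an observation table from CSV
#'
#' @param path CSV file with a header row (comma separator, `.` decimal,
#'   UTF-8).
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(mean_treat = "Mt", mean_ctrl = "Mc")`.
#' @return As [validate_observations()]: list with `records` and
#'   `rejects`.
#' @export
read_observations <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", encoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(d)) {
        stop("schema maps '", canon, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(d)[names(d) == src] <- canon
    }
  }
  validate_observations(d)
}

#' Write an observation (or any tabular) result to CSV
#'
#' Fixed column order, header row, no row names; numbers written at full
#' precision so a write/read round trip is lossless.
#'
#' @param d data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- pairing -------------------------------------------------------------

# inverse-variance weighted aggregation of several effect sizes of the same
# trophic group within one pairing key
.pool_effects <- function(g, v) {
  w <- 1 / v
  c(g = sum(w * g) / sum(w), v = 1 / sum(w))
}

.pair_key <- function(d) {
  site <- ifelse(is.na(d$site_id) | d$site_id == "", "-", as.character(d$site_id))
  paste(d$study_id, site, d$n_genotypes_added, sep = "\r")
}

#' Build paired bi-trophic effect-size records
#'
#' Pairs effect sizes of two trophic groups measured in the same study for
#' the same diversity contrast. Pairing key: (study_id, site_id,
#' n_genotypes_added). Several observations of the same group within one
#' key are combined by inverse-variance weighted mean before pairing.
#'
#' @param d data frame of validated observations augmented with effect
#'   sizes (columns `g`, `v`; see [add_effect_sizes()]).
#' @param lower_group,upper_group trophic group names (lower = closer to
#'   the plant in the cascade, e.g. `"plant"` and `"herbivore"`). For the
#'   plant-antagonist aggregate use `upper_group = "antagonist"`.
#' @return Data frame with one row per (study, site, contrast) in which
#'   both groups were measured: identifiers, `log2_genotypes`,
#'   `diversity` (always 1: every effect size is a diversity-vs-monoculture
#'   contrast), and `g_lower`, `v_lower`, `g_upper`, `v_upper`. Attributes
#'   `n_pairs` and `n_studies` record the audit counts.
#' @export
build_pairs <- function(d, lower_group, upper_group) {
  stopifnot(all(c("g", "v") %in% names(d)))
  pick <- function(group) {
    if (identical(group, "antagonist")) {
      d[d$trophic_group %in% antagonist_groups(), , drop = FALSE]
    } else {
      stopifnot(group %in% trophic_groups())
      d[d$trophic_group == group, , drop = FALSE]
    }
  }
  lo <- pick(lower_group); up <- pick(upper_group)
  agg <- function(x) {
    if (nrow(x) == 0L) {
      return(data.frame(key = character(0), g = numeric(0), v = numeric(0)))
    }
    key <- .pair_key(x)
    out <- do.call(rbind, lapply(split(seq_len(nrow(x)), key), function(i) {
      p <- .pool_effects(x$g[i], x$v[i])
      data.frame(key = key[i[1]], study_id = x$study_id[i[1]],
                 site_id = x$site_id[i[1]],
                 plant_species = x$plant_species[i[1]],
                 n_genotypes_added = x$n_genotypes_added[i[1]],
                 g = p[["g"]], v = p[["v"]], stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  a <- agg(lo); b <- agg(up)
  m <- merge(a, b, by = "key", suffixes = c("_lower", "_upper"))
  if (nrow(m) == 0L) {
    res <- data.frame(study_id = character(0), site_id = character(0),
                      plant_species = character(0),
                      n_genotypes_added = integer(0),
                      diversity = numeric(0), log2_genotypes = numeric(0),
                      g_lower = numeric(0), v_lower = numeric(0),
                      g_upper = numeric(0), v_upper = numeric(0))
  } else {
    res <- data.frame(
      study_id = m$study_id_lower,
      site_id = m$site_id_lower,
      plant_species = m$plant_species_lower,
      n_genotypes_added = m$n_genotypes_added_lower,
      diversity = 1,
      log2_genotypes = log_genotypes(m$n_genotypes_added_lower),
      g_lower = m$g_lower, v_lower = m$v_lower,
      g_upper = m$g_upper, v_upper = m$v_upper,
      stringsAsFactors = FALSE
    )
    res <- res[order(res$study_id, res$site_id, res$n_genotypes_added), ]
    rownames(res) <- NULL
  }
  attr(res, "n_pairs") <- nrow(res)
  attr(res, "n_studies") <- length(unique(res$study_id))
  attr(res, "roles") <- c(lower = lower_group, upper = upper_group)
  res
}

#' Build tri-trophic effect-size triples
#'
#' One row per (study, site, contrast) where natural enemies, herbivores
#' and plants were all measured.
#'
#' @inheritParams build_pairs
#' @return Data frame with `g_enemy/v_enemy`, `g_herbivore/v_herbivore`,
#'   `g_plant/v_plant` plus identifiers; attributes `n_triples`,
#'   `n_studies`.
#' @export
build_triples <- function(d) {
  ph <- build_pairs(d, "plant", "herbivore")
  pe <- build_pairs(d, "plant", "natural_enemy")
  kh <- paste(ph$study_id, ph$site_id, ph$n_genotypes_added, sep = "\r")
  ke <- paste(pe$study_id, pe$site_id, pe$n_genotypes_added, sep = "\r")
  i <- match(kh, ke)
  keep <- which(!is.na(i))
  res <- data.frame(
    study_id = ph$study_id[keep],
    site_id = ph$site_id[keep],
    plant_species = ph$plant_species[keep],
    n_genotypes_added = ph$n_genotypes_added[keep],
    diversity = rep(1, length(keep)),
    log2_genotypes = ph$log2_genotypes[keep],
    g_plant = ph$g_lower[keep], v_plant = ph$v_lower[keep],
    g_herbivore = ph$g_upper[keep], v_herbivore = ph$v_upper[keep],
    g_enemy = pe$g_upper[i[keep]], v_enemy = pe$v_upper[i[keep]],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "n_triples") <- nrow(res)
  attr(res, "n_studies") <- length(unique(res$study_id))
  res
}
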