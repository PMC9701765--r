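# Piecewise structural equation models over effect-size subsets.
#
# Each endogenous node (a trophic group's SMD) gets one component model:
# a weighted mixed model with the sampling variance of the response as
# fixed residual variance (prior weights 1/v, residual scale 1) plus
# random study intercepts. Global fit is tested through the d-separation
# basis set and Fisher's C.

#' Define a DAG for piecewise SEM
#'
#' Nodes are either endogenous trophic responses (with `g_<node>` /
#' `v_<node>` columns in the data) or exogenous predictors (a plain data
#' column, e.g. `diversity` or `log2_genotypes`). Every effect size in the
#' data already encodes the diversity-vs-monoculture contrast, so when the
#' exogenous node is the constant diversity indicator its path into a
#' child is the child model's intercept: the mean SMD of that response in
#' the subset.
#'
#' @param nodes character vector of node names.
#' @param edges two-column character matrix (or list of length-2 vectors),
#'   `from` -> `to`.
#' @return Object of class `sem_spec` with a validated acyclic edge set
#'   and topological node order.
#' @export
sem_spec <- function(nodes, edges) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  stopifnot(all(edges %in% nodes), !anyDuplicated(nodes))
  if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge set", call. = FALSE)

  # Kahn topological sort; failure means a cycle
  order <- character(0)
  remaining <- nodes
  e <- edges
  while (length(remaining) > 0L) {
    has_parent <- remaining %in% e[, 2]
    roots <- remaining[!has_parent]
    if (length(roots) == 0L) stop("edge set is cyclic", call. = FALSE)
    order <- c(order, roots)
    remaining <- setdiff(remaining, roots)
    e <- e[!(e[, 1] %in% roots), , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges, order = order),
            class = "sem_spec")
}

.parents <- function(spec, node) {
  unique(spec$edges[spec$edges[, 2] == node, 1])
}

#' d-separation basis set of a DAG
#'
#' All non-adjacent node pairs, ordered causally, each conditioned on the
#' union of the parents of the two nodes (Shipley's basis). Deterministic
#' canonical ordering by topological position.
#'
#' @param spec a [sem_spec()].
#' @return List of claims, each `list(a, b, conditioning)` asserting
#'   `a` independent of `b` given `conditioning`; `b` is the causally
#'   later node.
#' @export
basis_set <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  ord <- spec$order
  adjacent <- paste(spec$edges[, 1], spec$edges[, 2])
  claims <- list()
  if (length(ord) >= 2L) {
    for (i in seq_len(length(ord) - 1L)) {
      for (j in seq((i + 1L), length(ord))) {
        a <- ord[i]; b <- ord[j]
        if (paste(a, b) %in% adjacent || paste(b, a) %in% adjacent) next
        cond <- setdiff(union(.parents(spec, a), .parents(spec, b)), c(a, b))
        claims[[length(claims) + 1L]] <- list(a = a, b = b,
                                              conditioning = sort(cond))
      }
    }
  }
  claims
}

# resolve a node to (response vector, variance vector or NULL) in the data
.node_values <- function(data, node) {
  gcol <- paste0("g_", node)
  if (gcol %in% names(data)) {
    list(y = data[[gcol]], v = data[[paste0("v_", node)]], endogenous = TRUE)
  } else if (node %in% names(data)) {
    list(y = data[[node]], v = NULL, endogenous = FALSE)
  } else {
    stop("node '", node, "' has no g_/plain column in the data",
         call. = FALSE)
  }
}

#' Fit one SEM component model
#'
#' Weighted mixed model for one endogenous response: fixed residual
#' variance equal to the response's sampling variance (prior weights
#' `1/v`, residual scale 1) plus random study intercepts (and a species
#' intercept when several species are present). Wald t inference on
#' `n - p` residual degrees of freedom.
#'
#' @param data subset from [build_pairs()] / [build_triples()].
#' @param response node name of the endogenous response.
#' @param parents character vector of parent node names (constant
#'   predictors are absorbed into the intercept, whose coefficient is then
#'   the corresponding path).
#' @param random variance components to try, in order; components whose
#'   grouping structure is degenerate in the subset are dropped.
#' @return List with `coefficients` (term, estimate, se, t, p), the
#'   underlying `meta_fit`, and `df_resid`.
#' @export
fit_component <- function(data, response, parents,
                          random = c("species", "study")) {
  rv <- .node_values(data, response)
  if (!rv$endogenous) stop("response must be an endogenous node", call. = FALSE)
  df <- data.frame(.y = rv$y, .v = rv$v,
                   study_id = data$study_id,
                   plant_species = if ("plant_species" %in% names(data))
                     data$plant_species else data$study_id,
                   stringsAsFactors = FALSE)
  terms <- character(0)
  path_term <- setNames(character(length(parents)), parents)
  for (pn in parents) {
    pv <- .node_values(data, pn)
    if (length(unique(pv$y)) <= 1L) {
      path_term[pn] <- "(Intercept)"  # constant exogenous contrast
    } else {
      df[[pn]] <- pv$y
      terms <- c(terms, pn)
      path_term[pn] <- pn
    }
  }
  keep <- random
  if (length(unique(df$plant_species)) < 2L) keep <- setdiff(keep, "species")
  fixed <- stats::reformulate(if (length(terms)) terms else "1",
                              intercept = TRUE)
  fit <- fit_meta(df, fixed = fixed, random = keep, yi = ".y", vi = ".v")
  est <- fit$beta; se <- fit$se
  tval <- est / se
  pval <- 2 * pt(-abs(tval), fit$df_resid)
  list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    path_term = path_term,
    fit = fit,
    df_resid = fit$df_resid
  )
}

#' Fisher's C statistic from d-separation p-values
#'
#' `C = -2 sum(log p_i)`, chi-squared with `2k` degrees of freedom under
#' correct specification. Zero p-values are clipped to 1e-16 with a
#' warning.
#'
#' @param p vector of independence-claim p-values in (0, 1].
#' @return List `C`, `df`, `p`.
#' @export
fishers_c <- function(p) {
  if (length(p) == 0L) stop("no p-values supplied", call. = FALSE)
  stopifnot(all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("p-value of 0 clipped to 1e-16")
    p[p == 0] <- 1e-16
  }
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Fits one component model per endogenous node, evaluates every
#' d-separation claim in the basis set, and combines the claim p-values
#' into Fisher's C. For a saturated DAG the basis set is empty and no
#' global test is emitted (`fisher_c` is NA with `fisher_df` 0).
#'
#' @param spec a [sem_spec()].
#' @param data subset from [build_pairs()] / [build_triples()].
#' @param random variance components passed to [fit_component()].
#' @return Object of class `sem_result`: `paths` (from, to, estimate, se,
#'   t, p, magnitude), `dsep` (a, b, conditioning, p), `fisher_c`,
#'   `fisher_df`, `fisher_p`, `n_obs`, `n_studies`, and the component
#'   fits.
#' @export
run_sem <- function(spec, data, random = c("species", "study")) {
  stopifnot(inherits(spec, "sem_spec"))
  endo <- unique(spec$edges[, 2])
  endo <- spec$order[spec$order %in% endo]
  components <- list()
  paths <- NULL
  for (node in endo) {
    pa <- .parents(spec, node)
    comp <- tryCatch(
      fit_component(data, node, pa, random = random),
      error = function(e) stop("component model for '", node, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    components[[node]] <- comp
    co <- comp$coefficients
    idx <- match(comp$path_term[pa], co$term)
    paths <- rbind(paths, data.frame(
      from = pa, to = node,
      estimate = co$estimate[idx], se = co$se[idx],
      t = co$t[idx], p = co$p[idx],
      stringsAsFactors = FALSE
    ))
  }
  paths$magnitude <- abs(paths$estimate)

  claims <- basis_set(spec)
  dsep <- NULL
  for (cl in claims) {
    # test the causally-earlier node's coefficient in a model for the
    # later node given the conditioning set
    comp <- fit_component(data, cl$b, c(cl$a, cl$conditioning),
                          random = random)
    co <- comp$coefficients
    i <- match(comp$path_term[[cl$a]], co$term)
    dsep <- rbind(dsep, data.frame(
      a = cl$a, b = cl$b,
      conditioning = paste(cl$conditioning, collapse = "+"),
      estimate = co$estimate[i], p = co$p[i], stringsAsFactors = FALSE
    ))
  }
  if (is.null(dsep)) {
    fc <- list(C = NA_real_, df = 0L, p = NA_real_)
  } else {
    fc <- fishers_c(dsep$p)
  }
  structure(list(
    paths = paths, dsep = dsep,
    fisher_c = fc$C, fisher_df = fc$df, fisher_p = fc$p,
    n_obs = nrow(data), n_studies = length(unique(data$study_id)),
    components = components, spec = spec
  ), class = "sem_result")
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("Piecewise SEM: %d obs, %d studies\n", x$n_obs, x$n_studies))
  print(transform(x$paths, estimate = round(estimate, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 3),
                  magnitude = round(magnitude, 3)))
  if (x$fisher_df > 0L) {
    cat(sprintf("Fisher's C = %.3f, df = %d, p = %.4f\n",
                x$fisher_c, x$fisher_df, x$fisher_p))
  } else {
    cat("Saturated model: no independence claims to test\n")
  }
  invisible(x)
}

#' Indirect effects as products of path coefficients
#'
#' @param result a `sem_result`.
#' @param route character vector of nodes along the route, e.g.
#'   `c("diversity", "antagonist", "plant")`.
#' @return The product of the estimated coefficients along the route.
#' @export
indirect_effect <- function(result, route) {
  stopifnot(inherits(result, "sem_result"), length(route) >= 2L)
  prod(vapply(seq_len(length(route) - 1L), function(i) {
    row <- result$paths$from == route[i] & result$paths$to == route[i + 1L]
    if (!any(row)) stop("no path ", route[i], " -> ", route[i + 1L],
                        call. = FALSE)
    result$paths$estimate[row]
  }, numeric(1)))
}

#' The bi- and tri-trophic DAGs used throughout
#'
#' `bi_trophic_spec()`: diversity -> antagonist, diversity -> plant,
#' antagonist -> plant (saturated). `tri_trophic_spec()`: diversity into
#' all three levels, enemy -> herbivore, herbivore -> plant (one
#' independence claim: enemy and plant, given diversity and herbivore).
#'
#' @param exposure name of the exogenous diversity node (`"diversity"` or
#'   `"log2_genotypes"`).
#' @return A [sem_spec()].
#' @export
bi_trophic_spec <- function(exposure = "diversity") {
  sem_spec(c(exposure, "upper", "lower"),
           rbind(c(exposure, "upper"), c(exposure, "lower"),
                 c("upper", "lower")))
}

#' @rdname bi_trophic_spec
#' @export
tri_trophic_spec <- function(exposure = "diversity") {
  sem_spec(c(exposure, "enemy", "herbivore", "plant"),
           rbind(c(exposure, "enemy"), c(exposure, "herbivore"),
                 c(exposure, "plant"), c("enemy", "herbivore"),
                 c("herbivore", "plant")))
}
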