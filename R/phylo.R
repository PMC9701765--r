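# Phylogenetic correlation structure for species random effects.

#' Brownian-motion correlation matrix from a phylogeny
#'
#' Builds the expected correlation of species-level effects under Brownian
#' motion: shared branch length from the root, rescaled to unit diagonal.
#' Species in `species` that are not tips of the tree are dropped from the
#' matrix with a warning; downstream they receive only the iid species
#' component.
#'
#' @param tree an `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param species optional character vector of species to keep (order of
#'   the returned matrix follows this vector where matched).
#' @return A symmetric positive-semidefinite correlation matrix with unit
#'   diagonal, dimnames = species labels.
#' @export
phylo_correlation <- function(tree, species = NULL) {
  phy <- .as_phylo(tree)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  V <- ape::vcv(phy, corr = TRUE)
  if (!is.null(species)) {
    keep <- intersect(species, rownames(V))
    missing <- setdiff(species, rownames(V))
    if (length(missing) > 0L) {
      warning(length(missing), " species not found in tree: ",
              paste(utils::head(missing, 5L), collapse = ", "),
              if (length(missing) > 5L) ", ...",
              "; they receive the iid species component only")
    }
    if (length(keep) < 2L) {
      stop("fewer than 2 data species match tree tips", call. = FALSE)
    }
    V <- V[keep, keep]
  }
  # guard against tiny negative eigenvalues from rounding
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  diag(V) <- 1
  V
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    phy <- if (file.exists(tree)) {
      tryCatch(ape::read.tree(tree), error = function(e) NULL)
    } else {
      tryCatch(ape::read.tree(text = tree), error = function(e) NULL)
    }
    if (is.null(phy)) stop("could not parse Newick tree", call. = FALSE)
    return(phy)
  }
  stop("'tree' must be a phylo object, Newick string or file path",
       call. = FALSE)
}
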