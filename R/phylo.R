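#' Read a rooted phylogenetic tree (Newick or NEXUS)
#'
#' Thin wrapper around [ape::read.tree()] / [ape::read.nexus()] that
#' validates tip labels and branch lengths. Multi-tree files return a
#' `multiPhylo`; use [select_tree()] to pick one.
#'
#' @param path tree file.
#' @param format `"auto"` (by extension/content), `"newick"` or `"nexus"`.
#' @return an [ape::phylo] (or `multiPhylo` for multi-tree files).
#' @export
read_phylo <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tr <- tryCatch(
    suppressWarnings(
      if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)),
    error = function(e) abort(paste0("could not parse ", format, " file ",
                                     path, ": ", conditionMessage(e)))
  )
  if (is.null(tr)) abort(paste0("could not parse ", format, " file: ", path))
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, check_phylo)
  } else {
    check_phylo(tr)
  }
  tr
}

check_phylo <- function(tr) {
  if (!inherits(tr, "phylo")) abort("not a phylo object")
  if (length(tr$tip.label) < 2L) abort("tree must have at least 2 tips")
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate tip label(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(tr$edge.length)) abort("tree has no branch lengths")
  if (any(tr$edge.length < 0)) abort("negative branch length(s)")
  invisible(tr)
}

#' Select one tree from a multi-tree file or multiPhylo
#'
#' The clade analyses use a single tree drawn from a posterior set of trees;
#' the index (or seed for a random draw) is surfaced so sensitivity reruns
#' with other trees are one argument away.
#'
#' @param trees `multiPhylo` or list of `phylo`, or a single `phylo`
#'   (returned as-is).
#' @param index 1-based tree index; if `NULL`, drawn uniformly using `seed`.
#' @param seed RNG seed for the random draw.
#' @return a single `phylo`.
#' @export
select_tree <- function(trees, index = NULL, seed = NULL) {
  if (inherits(trees, "phylo")) return(trees)
  n <- length(trees)
  if (is.null(index)) {
    if (!is.null(seed)) set.seed(seed)
    index <- sample.int(n, 1L)
  }
  if (index < 1L || index > n) abort(paste0("tree index out of range 1..", n))
  tr <- trees[[index]]
  attr(tr, "tree_index") <- as.integer(index)
  tr
}

#' Prune a tree to a set of tip species
#'
#' Returns the induced subtree on the requested tips, with unifurcations
#' suppressed and their branch lengths summed, so all pairwise patristic
#' distances among the kept tips are preserved.
#'
#' @param tree `phylo`.
#' @param species character vector of tip labels to keep (spaces and
#'   underscores are interchangeable).
#' @return pruned `phylo`.
#' @export
prune_to_species <- function(tree, species) {
  check_phylo(tree)
  want <- match_tips(tree, species)
  ape::keep.tip(tree, want)
}

match_tips <- function(tree, species) {
  tips <- tree$tip.label
  idx <- match(species, tips)
  alt <- match(species_to_tip(species), tips)
  idx[is.na(idx)] <- alt[is.na(idx)]
  alt2 <- match(gsub("_", " ", species), tips)
  idx[is.na(idx)] <- alt2[is.na(idx)]
  if (anyNA(idx)) {
    abort(paste0("species not in tree: ",
                 paste(species[is.na(idx)], collapse = ", ")))
  }
  tips[idx]
}

#' Brownian-motion phylogenetic correlation matrix
#'
#' Under Brownian evolution along the tree, the covariance of species-level
#' effects is the shared root-to-MRCA path length; the correlation is that
#' shared path normalised by `sqrt(depth_i * depth_j)`. For an ultrametric
#' tree this reduces to shared path / total depth. Star trees (no shared
#' history) give the identity matrix; multiplying all branch lengths by a
#' constant leaves the correlation unchanged.
#'
#' @param tree `phylo` spanning `species`.
#' @param species species order for the matrix rows/columns; defaults to the
#'   tree's tip order. The tree is pruned to these tips first.
#' @return correlation matrix with `species` dimnames (underscores in tip
#'   labels are reported as spaces).
#' @export
brownian_correlation <- function(tree, species = NULL) {
  check_phylo(tree)
  if (!is.null(species)) {
    tree <- prune_to_species(tree, species)
    ord <- match_tips(tree, species)
  } else {
    ord <- tree$tip.label
  }
  V <- ape::vcv(tree)                      # shared root-to-MRCA path lengths
  V <- V[ord, ord, drop = FALSE]
  d <- diag(V)
  if (any(d <= 0)) {
    abort(paste0("zero root-to-tip depth for: ",
                 paste(ord[d <= 0], collapse = ", ")))
  }
  C <- V / sqrt(outer(d, d))
  diag(C) <- 1
  lab <- if (is.null(species)) gsub("_", " ", ord) else species
  dimnames(C) <- list(lab, lab)
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) abort(sprintf("correlation matrix not PSD (min eigenvalue %.3g)", ev))
  C
}

# documented jitter added to the diagonal before any Cholesky factorization
avm_chol_jitter <- function() 1e-8

chol_corr <- function(C) {
  t(chol(C + diag(avm_chol_jitter(), nrow(C))))   # lower-triangular factor
}

#' Export a correlation matrix as CSV with a species header column
#' @param C correlation matrix with dimnames.
#' @param path output path.
#' @export
write_corr <- function(C, path) {
  df <- tibble::as_tibble(C, rownames = "species")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
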