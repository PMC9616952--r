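# independent oracle: per-pair shared root-to-MRCA path length computed by
# brute-force ancestor sets walked directly over the edge table
oracle_shared_depth <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  ancestors <- function(node) {
    out <- node
    while (node != root) {
      node <- parent[node]
      out <- c(out, node)
    }
    out
  }
  V <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      if (i == j) {
        V[i, j] <- depth_of(i)
      } else {
        common <- intersect(ancestors(i), ancestors(j))
        V[i, j] <- max(vapply(common, depth_of, numeric(1)))
      }
    }
  }
  V
}

test_that("newick parsing and basic validation", {
  tr <- read_phylo(write_newick("((A:1,B:1):1,C:2);"))
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
  expect_error(read_phylo(write_newick("((A:1,A:1):1,C:2);")), "duplicate")
  expect_error(read_phylo(write_newick("((A:1,B:1")), "parse")
})

test_that("NEXUS and newick readers agree on the same topology", {
  nwk <- "((A:1,B:1):1,C:2);"
  nex <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TREES;",
               paste0("  TREE one = ", nwk), "END;"), nex)
  t1 <- read_phylo(write_newick(nwk))
  t2 <- read_phylo(nex)
  expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = TRUE))
})

test_that("select_tree retrieves a tree by index from a multi-tree file", {
  trees <- lapply(1:5, function(i) simulate_tree(6, "yule", seed = i))
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(do.call(c, lapply(trees, list)) |>
                    structure(class = "multiPhylo"), path)
  got <- select_tree(read_phylo(path), index = 3)
  expect_true(ape::all.equal.phylo(got, trees[[3]], use.edge.length = TRUE,
                                   tolerance = 1e-6))
  expect_equal(attr(got, "tree_index"), 3L)
  expect_error(select_tree(read_phylo(path), index = 9), "out of range")
  # random selection is seed-reproducible
  a <- select_tree(read_phylo(path), seed = 11)
  b <- select_tree(read_phylo(path), seed = 11)
  expect_equal(attr(a, "tree_index"), attr(b, "tree_index"))
})

test_that("pruning preserves patristic distances among kept tips", {
  tr <- read_phylo(write_newick("((A:1,B:1):1,C:2);"))
  pr <- prune_to_species(tr, c("A", "B"))
  expect_equal(length(pr$tip.label), 2)
  expect_equal(unname(ape::cophenetic.phylo(pr)["A", "B"]), 2)

  # identity prune
  same <- prune_to_species(tr, c("A", "B", "C"))
  expect_true(ape::all.equal.phylo(tr, same))

  # random Yule tree: all pairwise path lengths conserved after pruning
  big <- simulate_tree(10, "yule", seed = 5)
  keep <- big$tip.label[c(1, 4, 7, 9)]
  small <- prune_to_species(big, keep)
  expect_equal(ape::cophenetic.phylo(small)[keep, keep],
               ape::cophenetic.phylo(big)[keep, keep])

  expect_error(prune_to_species(tr, c("A", "Z")), "Z")
})

test_that("brownian correlation matches closed-form small cases", {
  star <- simulate_tree(5, "star")
  expect_equal(unname(brownian_correlation(star)), diag(5))

  tr <- read_phylo(write_newick("((A:1,B:1):1,C:2);"))
  C <- brownian_correlation(tr, c("A", "B", "C"))
  expect_equal(unname(C["A", "B"]), 0.5)
  expect_equal(unname(C["A", "C"]), 0)
  expect_equal(unname(C["B", "C"]), 0)
  expect_equal(unname(diag(C)), rep(1, 3))
})

test_that("brownian correlation equals the brute-force ancestor-set oracle", {
  tr <- simulate_tree(20, "yule", seed = 8)
  V <- oracle_shared_depth(tr)
  d <- diag(V)
  C_oracle <- V / sqrt(outer(d, d))
  diag(C_oracle) <- 1
  C <- brownian_correlation(tr)
  dimnames(C_oracle) <- dimnames(C) <- NULL
  expect_equal(C, C_oracle, tolerance = 1e-10)
})

test_that("brownian correlation invariances hold", {
  tr <- simulate_tree(12, "yule", seed = 3)
  sp <- gsub("_", " ", tr$tip.label)
  C <- brownian_correlation(tr, sp)
  # permutation of the requested order permutes rows/columns identically
  perm <- sample(seq_along(sp))
  C2 <- brownian_correlation(tr, sp[perm])
  expect_equal(unname(C2), unname(C[perm, perm]))
  # rescaling all branch lengths leaves the correlation unchanged
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 37.5
  expect_equal(brownian_correlation(tr2, sp), C, tolerance = 1e-12)
  # PSD for an ultrametric tree
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)
  # entries are correlations
  expect_true(all(C >= 0 & C <= 1 + 1e-12))
})

test_that("zero-depth tips are rejected", {
  star <- ape::stree(3, type = "star")
  star$edge.length <- c(0, 1, 1)
  star$tip.label <- c("A", "B", "C")
  expect_error(brownian_correlation(star), "zero root-to-tip depth")
})

test_that("correlation matrices export round-trip via CSV", {
  tr <- simulate_tree(5, "yule", seed = 2)
  C <- brownian_correlation(tr)
  path <- tempfile(fileext = ".csv")
  write_corr(C, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$species, rownames(C))
  expect_equal(as.matrix(back[, -1]), C, ignore_attr = TRUE,
               tolerance = 1e-12)
})
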