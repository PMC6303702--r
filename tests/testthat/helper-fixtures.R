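# Shared fixtures, built in code.

# the worked 4-tip tree: ((A:1,B:1):1,(C:1,D:1):1); traits 0, 4, 0, -4
balanced4 <- function() {
  tree <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  traits <- matrix(c(0, 4, 0, -4), 4L, 1L,
                   dimnames = list(c("A", "B", "C", "D"), "x"))
  list(tree = tree, traits = traits)
}

random_shape <- function(k = 10L) {
  matrix(rnorm(2L * k), k, 2L)
}

# apply a random similarity transform (rotation + scale + translation)
similarity_transform <- function(shape, angle = runif(1, -pi, pi),
                                 scale = exp(runif(1, -1, 1)),
                                 shift = rnorm(2, 0, 5)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  sweep(scale * (shape %*% R), 2L, shift, "+")
}

# brute-force patristic distance by explicit LCA walk
patristic_oracle <- function(tree, i, j) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  anc <- function(nd) {
    out <- nd
    while (nd != ntip + 1L) { nd <- parent[nd]; out <- c(out, nd) }
    out
  }
  ai <- anc(i); aj <- anc(j)
  lca <- ai[min(which(ai %in% aj))]
  up <- function(nd) { s <- 0; while (nd != lca) { s <- s + elen[nd]; nd <- parent[nd] }; s }
  up(i) + up(j)
}

# depths computed iteratively (independent of node_depths)
depth_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  d <- numeric(ntip + tree$Nnode)
  for (e in ape::reorder.phylo(tree, "cladewise", index.only = TRUE))
    d[tree$edge[e, 2L]] <- d[tree$edge[e, 1L]] + tree$edge.length[e]
  d
}
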