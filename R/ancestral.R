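# Branch-length-weighted squared-change parsimony: internal states minimize
# sum over edges of (x_child - x_parent)^2 / length, per trait. With
# positive weights this is the Brownian-motion ML interior reconstruction,
# solved exactly via the sparse Laplacian normal equations.

# internal: reusable factorized solver; the Cholesky factor depends only on
# the tree, so simulation nulls can re-reconstruct ancestors cheaply.
scp_factor <- function(tree, weighted = TRUE) {
  validate_phylo(tree)
  ntip <- ape::Ntip(tree); nint <- tree$Nnode
  len <- tree$edge.length
  if (weighted && any(len <= 0)) {
    eps <- 1e-8 * max(node_depths(tree))
    warning(sprintf("zero-length branch(es) replaced by epsilon %.3g for reconstruction", eps))
    len[len <= 0] <- eps
  }
  w <- if (weighted) 1 / len else rep(1, length(len))
  pa <- tree$edge[, 1L] - ntip            # parents are always internal
  ch <- tree$edge[, 2L]
  is_int <- ch > ntip
  # Laplacian over internal nodes
  ii <- c(pa, pa[is_int], ch[is_int] - ntip, ch[is_int] - ntip)
  jj <- c(pa, ch[is_int] - ntip, pa[is_int], ch[is_int] - ntip)
  xx <- c(w, -w[is_int], -w[is_int], w[is_int])
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nint, nint))
  # tip coupling: rhs = Wt %*% y_tips
  Wt <- Matrix::sparseMatrix(i = pa[!is_int], j = ch[!is_int], x = w[!is_int],
                             dims = c(nint, ntip))
  chol_L <- Matrix::Cholesky(Matrix::forceSymmetric(L), LDL = FALSE)
  list(ntip = ntip, nint = nint, chol = chol_L, Wt = Wt)
}

scp_solve <- function(fac, tip_values) {
  y <- as.matrix(tip_values)
  as.matrix(Matrix::solve(fac$chol, fac$Wt %*% y))
}

#' Squared-change parsimony ancestral reconstruction
#'
#' Reconstructs internal-node trait values minimizing the summed squared
#' changes along branches, weighted by inverse branch length (the default;
#' equivalent to the Brownian-motion ML interior states) or unweighted.
#' Traits are reconstructed independently.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait numeric matrix, rownames = tip labels
#'   covering every tip.
#' @param weighted divide squared changes by branch length (default TRUE).
#' @return (ntip + nnode) x trait matrix over all node ids: rows 1..ntip are
#'   the observed tip values (tree tip order), the rest the reconstruction.
#' @export
squared_change_parsimony <- function(tree, traits, weighted = TRUE) {
  traits <- as_trait_matrix(traits, tree)
  fac <- scp_factor(tree, weighted = weighted)
  anc <- scp_solve(fac, traits)
  out <- rbind(traits, anc)
  rownames(out) <- c(tree$tip.label,
                     as.character(seq_len(tree$Nnode) + fac$ntip))
  out
}

# internal: align a trait table to the tree's tips, error on mismatch
as_trait_matrix <- function(traits, tree) {
  m <- as.matrix(traits)
  if (is.null(rownames(m)))
    stop("trait matrix must have species rownames", call. = FALSE)
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing))
    stop(sprintf("missing trait values for tip(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  m <- m[tree$tip.label, , drop = FALSE]
  if (any(!is.finite(m))) stop("non-finite trait values", call. = FALSE)
  m
}

#' Phylomorphospace layout
#'
#' Projects tips and reconstructed ancestors onto two trait axes and returns
#' one line segment per branch, connecting parent and child node positions.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param anc ancestral states from [squared_change_parsimony()]; computed
#'   if NULL.
#' @param axes pair of trait column indices (default first two).
#' @return list with `points` (node x 2 matrix over all node ids) and
#'   `segments` (data.frame parent, child, x0, y0, x1, y1).
#' @export
phylomorphospace <- function(tree, traits, anc = NULL, axes = c(1L, 2L)) {
  traits <- as_trait_matrix(traits, tree)
  if (any(axes < 1L | axes > ncol(traits)))
    stop("axis index out of range", call. = FALSE)
  if (is.null(anc)) anc <- squared_change_parsimony(tree, traits)
  pts <- anc[, axes, drop = FALSE]
  colnames(pts) <- colnames(traits)[axes]
  seg <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                    x0 = pts[tree$edge[, 1L], 1L], y0 = pts[tree$edge[, 1L], 2L],
                    x1 = pts[tree$edge[, 2L], 1L], y1 = pts[tree$edge[, 2L], 2L])
  list(points = pts, segments = seg)
}
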