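#' @useDynLib ouconv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize rnorm runif setNames cov sd var quantile
#' @importFrom utils read.csv write.csv combn
NULL

# Trees are carried as ape "phylo" objects (cladewise edge order as parsed).
# All tie-breaking elsewhere in the package references ape's postorder edge
# ordering, which is a pure function of the stored topology.

#' Parse a Newick string into a validated phylogeny
#'
#' A strict reader for rooted, time-calibrated trees: every non-root edge
#' must carry a finite, non-negative branch length, tip labels must be
#' unique and non-empty, the root must be bifurcating (an unrooted
#' trifurcating root is rejected), and square-bracket comments are stripped.
#' Malformed input fails with the character position of the offending token.
#'
#' @param text a Newick string (one tree, terminated by `;`).
#' @return an object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' patristic_matrix(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\[[^]]*\\]", "", text)  # comments carry no structure here
  s <- sub(";\\s*$", ";", s)
  n <- nchar(s)
  pos <- 1L

  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  skip_ws <- function() {
    while (pos <= n && grepl("^\\s$", substr(s, pos, pos))) pos <<- pos + 1L
  }
  perr <- function(msg, at = pos) {
    stop(sprintf("newick parse error at position %d: %s", at, msg),
         call. = FALSE)
  }
  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      start <- pos; pos <<- pos + 1L; out <- character()
      repeat {
        if (pos > n) perr("unterminated quoted label", start)
        ch <- substr(s, pos, pos)
        if (ch == "'") {
          if (pos + 1L <= n && substr(s, pos + 1L, pos + 1L) == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { out <- c(out, ch); pos <<- pos + 1L }
      }
      paste(out, collapse = "")
    } else {
      m <- regmatches(substr(s, pos, n),
                      regexpr("^[^,:;()[:space:]]+", substr(s, pos, n)))
      if (length(m) == 0L) return("")
      pos <<- pos + nchar(m)
      m
    }
  }
  read_length <- function() {
    skip_ws()
    if (peek() != ":") return(NULL)
    pos <<- pos + 1L
    m <- regmatches(substr(s, pos, n),
                    regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
                            substr(s, pos, n)))
    if (length(m) == 0L) perr("expected a number after ':'")
    pos <<- pos + nchar(m)
    as.numeric(m)
  }

  # each node: list(label, length, children = list of nodes)
  read_subtree <- function(depth) {
    skip_ws()
    if (peek() == "(") {
      open_at <- pos
      pos <<- pos + 1L
      children <- list(read_subtree(depth + 1L))
      repeat {
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; children <- c(children, list(read_subtree(depth + 1L))) }
        else if (peek() == ")") { pos <<- pos + 1L; break }
        else perr(sprintf("expected ',' or ')' for group opened at %d", open_at))
      }
      if (length(children) < 2L) perr("internal node with a single child", open_at)
      lab <- read_label()
      len <- read_length()
      list(label = lab, length = len, children = children, at = open_at)
    } else {
      at <- pos
      lab <- read_label()
      if (!nzchar(lab)) perr("expected a tip label")
      len <- read_length()
      list(label = lab, length = len, children = NULL, at = at)
    }
  }

  root <- read_subtree(0L)
  skip_ws()
  if (peek() != ";") perr("expected ';' at end of tree")
  if (length(root$children) == 0L) perr("tree has a single tip", root$at)
  if (length(root$children) > 2L)
    perr("unrooted (trifurcating) root is not supported", root$at)

  # flatten: tips numbered in parse order, internals preorder from root
  tips <- character(); internal_count <- 0L
  count <- function(nd) {
    if (is.null(nd$children)) tips <<- c(tips, nd$label)
    else { internal_count <<- internal_count + 1L; for (ch in nd$children) count(ch) }
  }
  count(root)
  dup <- tips[duplicated(tips)]
  if (length(dup))
    stop(sprintf("duplicate tip label(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  ntip <- length(tips)

  edge <- matrix(0L, 0L, 2L); elen <- numeric(); nlab <- character(internal_count)
  next_tip <- 0L; next_int <- ntip
  assign_ids <- function(nd) {
    if (is.null(nd$children)) { next_tip <<- next_tip + 1L; next_tip }
    else {
      next_int <<- next_int + 1L; id <- next_int
      nlab[id - ntip] <<- if (is.null(nd$label)) "" else nd$label
      for (ch in nd$children) {
        cid <- assign_ids(ch)
        if (is.null(ch$length))
          perr("missing branch length on a non-root edge", ch$at)
        if (!is.finite(ch$length) || ch$length < 0)
          perr("branch length must be finite and >= 0", ch$at)
        edge <<- rbind(edge, c(id, cid)); elen <<- c(elen, ch$length)
      }
      id
    }
  }
  assign_ids(root)

  tr <- list(edge = edge, edge.length = elen, Nnode = internal_count,
             tip.label = tips)
  if (any(nzchar(nlab))) tr$node.label <- nlab
  if (!is.null(root$length)) tr$root.edge <- root$length
  class(tr) <- "phylo"
  # edges were appended child-first during recursion; store parent-first
  ape::reorder.phylo(tr, "cladewise")
}

#' Serialize a phylogeny to Newick
#'
#' Branch lengths are printed with at least 10 significant digits so that a
#' parse/write round trip preserves structure and lengths.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10L) {
  validate_phylo(tree)
  ape::write.tree(tree, digits = digits)
}

#' Prune a phylogeny to a set of tips
#'
#' Drops all tips not in `keep`, collapsing the resulting unary internal
#' nodes by summing branch lengths, so patristic distances among retained
#' tips are unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown tip label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (length(keep) < 2L)
    stop("need at least 2 tips to keep", call. = FALSE)
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' in the tree's tip order.
#'
#' @param tree a `phylo` object.
#' @return a symmetric numeric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristic_matrix <- function(tree) {
  validate_phylo(tree)
  d <- ape::dist.nodes(tree)[seq_len(ape::Ntip(tree)), seq_len(ape::Ntip(tree)), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Node depths (time from the root)
#'
#' @param tree a `phylo` object.
#' @return numeric vector over all node ids (tips first, ape numbering).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Ultrametricity check
#'
#' @param tree a `phylo` object.
#' @param rel_tol relative tolerance on the tip-depth spread.
#' @return list with `ultrametric` (logical) and `spread`
#'   ((max depth - min depth) / max depth).
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylo(tree)
  td <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  spread <- (max(td) - min(td)) / max(td)
  list(ultrametric = spread <= rel_tol, spread = spread)
}

#' Shared-depth (MRCA depth) matrix among tips
#'
#' Entry (i, j) is the depth of the most recent common ancestor of tips i
#' and j; the diagonal holds tip depths. This is the Brownian-motion trait
#' covariance structure up to the rate.
#'
#' @param tree a `phylo` object.
#' @return symmetric numeric matrix, dimnames = tip labels.
#' @export
shared_depth_matrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  d <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  td <- depth[seq_len(ntip)]
  m <- (outer(td, td, "+") - d) / 2  # depth of MRCA from d_ij = Ti + Tj - 2 t_ij
  diag(m) <- td
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

# internal: invariant checks shared by all entry points
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("tree must have branch lengths on every edge", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  if (ntip < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  invisible(tree)
}

# internal: edge indices in postorder (deterministic tie-break order)
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}

# internal: edge indices with every parent before its children
preorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
}

# internal: for each tip, the vector of node ids on the path root -> tip
# (excluding the root, including the tip), i.e. the child ends of the edges.
root_to_tip_paths <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  lapply(seq_len(ntip), function(tip) {
    path <- integer(); nd <- tip
    while (nd != root) { path <- c(nd, path); nd <- parent[nd] }
    path
  })
}
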