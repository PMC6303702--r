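# Distance-based convergence measures C1-C4 and the frequency-based C5,
# with significance from Brownian-motion simulation nulls. All distances are
# Euclidean in trait (PC-score) space; ancestral states come from weighted
# squared-change parsimony and are re-reconstructed inside every simulation
# so observed and simulated data are treated identically.

# internal: node ids on the path mrca -> tip (inclusive of both)
path_down <- function(tree, mrca, tip) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- tip
  nd <- tip
  while (nd != mrca) { nd <- parent[nd]; path <- c(nd, path) }
  path
}

# internal: total Euclidean ancestor->descendant change over all branches of
# the clade rooted at `node`
clade_total_change <- function(tree, anc, node) {
  ntip <- ape::Ntip(tree)
  # collect edges within the clade by walking the edge list (parent first)
  in_clade <- rep(FALSE, ntip + tree$Nnode)
  in_clade[node] <- TRUE
  total <- 0
  for (e in preorder_edges(tree)) {  # parent before child
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (in_clade[p]) {
      in_clade[ch] <- TRUE
      total <- total + sqrt(sum((anc[ch, ] - anc[p, ])^2))
    }
  }
  total
}

#' Pairwise convergence measures
#'
#' For two tips: `Dtip` is the phenotypic distance between them, `Dmax` the
#' maximum distance between any node on the lineage from their common
#' ancestor to the first tip and any node on the lineage to the second
#' (including the ancestor and the tips). C1 = 1 - Dtip/Dmax is the
#' proportion of the maximal divergence closed by subsequent evolution;
#' C2 = Dmax - Dtip its absolute amount; C3 scales C2 by the total change
#' along the two lineages; C4 by the total change over the whole clade
#' descending from the common ancestor.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param anc ancestral states from [squared_change_parsimony()].
#' @param tipA,tipB tip labels or ids.
#' @return list with c1, c2, c3, c4, dtip, dmax, degenerate flag.
#' @export
pair_c_metrics <- function(tree, traits, anc, tipA, tipB) {
  if (is.character(tipA)) tipA <- match(tipA, tree$tip.label)
  if (is.character(tipB)) tipB <- match(tipB, tree$tip.label)
  if (is.na(tipA) || is.na(tipB) || tipA == tipB)
    stop("tips must be two distinct tree tips", call. = FALSE)
  mrca <- ape::getMRCA(tree, c(tipA, tipB))
  pa <- path_down(tree, mrca, tipA)
  pb <- path_down(tree, mrca, tipB)
  dtip <- sqrt(sum((anc[tipA, ] - anc[tipB, ])^2))
  cross <- outer(seq_along(pa), seq_along(pb), function(i, j)
    sqrt(rowSums((anc[pa[i], , drop = FALSE] - anc[pb[j], , drop = FALSE])^2)))
  dmax <- max(cross)
  if (dmax <= 0) {
    return(list(c1 = 0, c2 = 0, c3 = 0, c4 = 0, dtip = dtip, dmax = 0,
                degenerate = TRUE))
  }
  c2 <- dmax - dtip
  lineage_change <- function(path) {
    if (length(path) < 2L) return(0)
    sum(sqrt(rowSums((anc[path[-1L], , drop = FALSE] -
                        anc[path[-length(path)], , drop = FALSE])^2)))
  }
  ltot <- lineage_change(pa) + lineage_change(pb)
  ctot <- clade_total_change(tree, anc, mrca)
  list(c1 = 1 - dtip / dmax, c2 = c2,
       c3 = if (ltot > 0) c2 / ltot else 0,
       c4 = if (ctot > 0) c2 / ctot else 0,
       dtip = dtip, dmax = dmax, degenerate = FALSE)
}

#' Group convergence measures over a focal taxon set
#'
#' C1-C3 are arithmetic means of the pairwise values over all unordered
#' focal pairs; C4 divides the summed pairwise C2 by the total evolutionary
#' change over the clade rooted at the common ancestor of the whole focal
#' set (so C4 can exceed C3 for spread-out focal sets).
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param focal character vector of focal tip labels (>= 2).
#' @param anc optional precomputed ancestral states.
#' @return list with c1..c4, the pair table, and the focal set.
#' @examples
#' tree <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' traits <- matrix(c(0, 4, 0, -4), 4, 1, dimnames = list(LETTERS[1:4], "x"))
#' group_c_metrics(tree, traits, c("A", "C"))[c("c1", "c2", "c3", "c4")]
#' @export
group_c_metrics <- function(tree, traits, focal, anc = NULL) {
  traits <- as_trait_matrix(traits, tree)
  missing <- setdiff(focal, tree$tip.label)
  if (length(missing))
    stop(sprintf("focal taxa absent from tree: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (length(focal) < 2L) stop("need at least 2 focal taxa", call. = FALSE)
  if (is.null(anc)) anc <- squared_change_parsimony(tree, traits)
  pairs <- combn(focal, 2L)
  pm <- apply(pairs, 2L, function(pr)
    pair_c_metrics(tree, traits, anc, pr[1L], pr[2L]))
  c1 <- mean(vapply(pm, `[[`, numeric(1), "c1"))
  c2v <- vapply(pm, `[[`, numeric(1), "c2")
  c3 <- mean(vapply(pm, `[[`, numeric(1), "c3"))
  mrca_all <- ape::getMRCA(tree, match(focal, tree$tip.label))
  ctot <- clade_total_change(tree, anc, mrca_all)
  list(c1 = c1, c2 = mean(c2v), c3 = c3,
       c4 = if (ctot > 0) sum(c2v) / ctot else 0,
       pairs = pm, focal = focal)
}

# internal: BM rate matrix (per-trait rates + contrast cross-covariances)
# estimated from phylogenetically independent contrasts, plus the GLS root.
estimate_bm_generator <- function(tree, traits) {
  traits <- as_trait_matrix(traits, tree)
  pics <- apply(traits, 2L, function(y)
    ape::pic(setNames(y, rownames(traits)), tree))
  R <- crossprod(as.matrix(pics)) / nrow(as.matrix(pics))
  root <- bm_fit(tree, traits)$z0
  list(rate_matrix = R, root = root)
}

#' Simulation significance for C1-C4
#'
#' Estimates a Brownian-motion generator from the data (per-trait rates and
#' contrast cross-covariances, root at the GLS estimate), simulates `n_sim`
#' datasets on the fixed tree, recomputes the group measures for the same
#' focal labels each time, and reports p = (# simulations >= observed) /
#' n_sim per measure.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param focal focal tip labels.
#' @param n_sim number of simulations (default 500).
#' @param seed RNG seed (required for reproducibility).
#' @return list with observed values, p1..p4, n_sim and the null matrix.
#' @export
c_significance <- function(tree, traits, focal, n_sim = 500L, seed) {
  stopifnot(n_sim >= 1L)
  traits <- as_trait_matrix(traits, tree)
  set.seed(seed)
  gen <- estimate_bm_generator(tree, traits)
  fac <- scp_factor(tree)
  obs_anc <- rbind(traits, scp_solve(fac, traits))
  obs <- group_c_metrics(tree, traits, focal, anc = obs_anc)
  null <- matrix(NA_real_, n_sim, 4L,
                 dimnames = list(NULL, c("c1", "c2", "c3", "c4")))
  for (s in seq_len(n_sim)) {
    sim <- simulate_bm(tree, rate_matrix = gen$rate_matrix, root_state = gen$root)
    sim_anc <- rbind(sim, scp_solve(fac, sim))
    g <- group_c_metrics(tree, sim, focal, anc = sim_anc)
    null[s, ] <- c(g$c1, g$c2, g$c3, g$c4)
  }
  obs_v <- c(obs$c1, obs$c2, obs$c3, obs$c4)
  p <- colMeans(sweep(null, 2L, obs_v, ">="))
  list(c1 = obs$c1, c2 = obs$c2, c3 = obs$c3, c4 = obs$c4,
       p1 = p[[1]], p2 = p[[2]], p3 = p[[3]], p4 = p[[4]],
       n_sim = n_sim, focal = focal, null = null)
}

# ---- C5: lineages entering the focal region of phylomorphospace ----------

# internal: counterclockwise convex hull of a point matrix; collinear /
# degenerate sets get a thin epsilon buffer so the region has interior.
focal_hull <- function(pts, eps_frac = 1e-6) {
  scale <- max(apply(pts, 2L, function(v) diff(range(v))), 1e-12)
  idx <- grDevices::chull(pts)         # clockwise
  hull <- pts[rev(idx), , drop = FALSE]
  area <- polygon_area(hull)
  if (nrow(hull) < 3L || area < (eps_frac * scale)^2) {
    # buffer a segment (or point) into a thin rectangle
    d <- pts[which.max(rowSums(sweep(pts, 2L, colMeans(pts))^2)), ] - colMeans(pts)
    if (sqrt(sum(d^2)) < 1e-15) d <- c(1, 0) else d <- d / sqrt(sum(d^2))
    nrm <- c(-d[2L], d[1L]) * eps_frac * scale
    lo <- pts[which.min(pts %*% d), ]; hi <- pts[which.max(pts %*% d), ]
    hull <- rbind(lo - nrm, hi - nrm, hi + nrm, lo + nrm)
    if (polygon_area(hull) < 0) hull <- hull[4:1, , drop = FALSE]
    warning("degenerate focal hull; using epsilon-buffered region")
  }
  hull
}

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  0.5 * sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
}

# internal: boundary tolerance proportional to the hull's extent (touching
# the boundary counts as inside)
hull_tol <- function(hull) {
  1e-9 * max(apply(hull, 2L, function(v) diff(range(v))), 1e-12)
}

# internal: is point inside (or on boundary of) a ccw convex polygon
point_in_hull <- function(p, hull, tol = hull_tol(hull)) {
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    if ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) < -tol)
      return(FALSE)
  }
  TRUE
}

# internal: parameter interval [tlo, thi] of segment a->b lying inside a ccw
# convex hull (Cyrus-Beck clipping); NULL when the segment misses the hull.
segment_hull_interval <- function(a, b, hull, tol = hull_tol(hull)) {
  tlo <- 0; thi <- 1
  nh <- nrow(hull)
  d <- b - a
  for (i in seq_len(nh)) {
    v <- hull[i, ]; w <- hull[if (i == nh) 1L else i + 1L, ]
    e <- w - v
    # inside means cross(e, p - v) >= -tol; linear in t
    c0 <- e[1] * (a[2] - v[2]) - e[2] * (a[1] - v[1]) + tol
    c1 <- e[1] * d[2] - e[2] * d[1]
    if (abs(c1) < 1e-15) {
      if (c0 < 0) return(NULL)
    } else if (c1 > 0) {
      tlo <- max(tlo, -c0 / c1)
    } else {
      thi <- min(thi, -c0 / c1)
    }
    if (tlo > thi) return(NULL)
  }
  c(max(0, tlo), min(1, thi))
}

# internal: count entries (outside -> inside transitions) of one root-to-tip
# polyline into the hull
count_lineage_entries <- function(points_on_path, hull) {
  tol <- hull_tol(hull)
  inside <- point_in_hull(points_on_path[1L, ], hull, tol)
  entries <- 0L
  for (i in seq_len(nrow(points_on_path) - 1L)) {
    a <- points_on_path[i, ]; b <- points_on_path[i + 1L, ]
    iv <- segment_hull_interval(a, b, hull, tol)
    if (is.null(iv)) { inside <- FALSE; next }
    if (!inside) entries <- entries + 1L
    inside <- iv[2L] >= 1 - 1e-9   # segment ends inside the hull
  }
  entries
}

# internal: observed C5 count for given node coordinates and focal tips
c5_count <- function(tree, pts, focal_idx, paths) {
  hull <- focal_hull(pts[focal_idx, , drop = FALSE])
  root <- ape::Ntip(tree) + 1L
  entering <- vapply(paths, function(path) {
    poly <- pts[c(root, path), , drop = FALSE]
    count_lineage_entries(poly, hull) >= 1L
  }, logical(1))
  list(count = sum(entering), entering = which(entering))
}

#' C5: lineages entering the convergent region of phylomorphospace
#'
#' The region is the convex hull of the focal tips on two phylomorphospace
#' axes; C5 counts the root-to-tip lineages (branch polylines through
#' reconstructed ancestors) that enter the region from outside. Significance
#' comes from Brownian-motion simulations, each defining the hull from its
#' own simulated focal tips.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param focal focal tip labels (>= 2; 3+ for a proper hull).
#' @param anc optional precomputed ancestral states.
#' @param axes pair of trait indices for the phylomorphospace (default 1, 2).
#' @param n_sim number of BM simulations (default 500).
#' @param seed RNG seed.
#' @return list with `c5`, `p`, the entering tip labels and `n_sim`.
#' @export
c5 <- function(tree, traits, focal, anc = NULL, axes = c(1L, 2L),
               n_sim = 500L, seed) {
  traits <- as_trait_matrix(traits, tree)
  focal_idx <- match(focal, tree$tip.label)
  if (anyNA(focal_idx)) stop("focal taxa absent from tree", call. = FALSE)
  if (length(focal) < 2L) stop("need at least 2 focal taxa", call. = FALSE)
  set.seed(seed)
  fac <- scp_factor(tree)
  if (is.null(anc)) anc <- rbind(traits, scp_solve(fac, traits))
  paths <- root_to_tip_paths(tree)
  obs <- c5_count(tree, anc[, axes, drop = FALSE], focal_idx, paths)
  gen <- estimate_bm_generator(tree, traits)
  null <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    sim <- simulate_bm(tree, rate_matrix = gen$rate_matrix, root_state = gen$root)
    sim_anc <- rbind(sim, scp_solve(fac, sim))
    null[s] <- suppressWarnings(
      c5_count(tree, sim_anc[, axes, drop = FALSE], focal_idx, paths)$count)
  }
  list(c5 = obs$count, p = mean(null >= obs$count),
       entering = tree$tip.label[obs$entering], n_sim = n_sim, null = null)
}
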