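# Synthetic-data generators: Yule trees, Brownian and Ornstein-Uhlenbeck
# trait simulation, a paper-like convergence scenario (an old divergent
# lineage joined to a young radiation, with focal taxa pulled to a shared
# optimum), and landmark synthesis for the morphometrics stage. All
# generators are deterministic given `seed`.

#' Simulate a pure-birth (Yule) tree
#'
#' Exponential waiting times between speciation events (rate `birth` per
#' lineage); after the n-th tip appears one further waiting time sets the
#' present, and all branch lengths are rescaled so the tips sit at `depth`.
#'
#' @param n_tips number of tips (>= 2).
#' @param depth tree depth after rescaling (time units, e.g. My).
#' @param birth per-lineage speciation rate (only the shape of the tree
#'   depends on it once depth is rescaled).
#' @param seed optional RNG seed.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, depth = 1, birth = 1, seed = NULL) {
  stopifnot(n_tips >= 2L)
  if (!is.null(seed)) set.seed(seed)
  # active lineages: parent internal node id and birth time
  n_int <- n_tips - 1L
  root <- n_tips + 1L
  act_parent <- c(root, root); act_start <- c(0, 0)
  edges <- matrix(0L, 0L, 2L); elen <- numeric()
  next_int <- root
  t <- 0
  while (length(act_parent) < n_tips) {
    k <- length(act_parent)
    t <- t + rexp(1L, birth * k)
    i <- sample.int(k, 1L)
    next_int <- next_int + 1L
    edges <- rbind(edges, c(act_parent[i], next_int))
    elen <- c(elen, t - act_start[i])
    act_parent <- c(act_parent[-i], next_int, next_int)
    act_start <- c(act_start[-i], t, t)
  }
  t_end <- t + rexp(1L, birth * n_tips)
  for (i in seq_along(act_parent)) {
    edges <- rbind(edges, c(act_parent[i], i))
    elen <- c(elen, t_end - act_start[i])
  }
  tr <- list(edge = edges, edge.length = elen * (depth / t_end),
             Nnode = n_int, tip.label = paste0("t", seq_len(n_tips)))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_phylo(tr)
  tr
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Recursive simulation: each child value is its parent's plus a Gaussian
#' increment with variance rate x branch length. Traits can be independent
#' (`rates`) or cross-correlated (`rate_matrix`).
#'
#' @param tree a `phylo` object.
#' @param rates per-trait rate vector (variance per unit time); ignored when
#'   `rate_matrix` is given.
#' @param rate_matrix m x m increment covariance per unit time.
#' @param root_state numeric vector of root values (recycled to m).
#' @param seed optional RNG seed.
#' @param all_nodes return internal-node values too.
#' @return species x trait matrix (rownames = tip labels); with
#'   `all_nodes = TRUE`, the full (ntip + nnode) x m matrix.
#' @export
simulate_bm <- function(tree, rates = 1, rate_matrix = NULL, root_state = 0,
                        seed = NULL, all_nodes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rate_matrix)) {
    stopifnot(all(rates > 0))
    rate_matrix <- diag(rates, nrow = length(rates))
  }
  m <- nrow(rate_matrix)
  L <- chol(rate_matrix)
  ntip <- ape::Ntip(tree)
  vals <- matrix(NA_real_, ntip + tree$Nnode, m)
  vals[ntip + 1L, ] <- rep_len(root_state, m)
  eps <- (matrix(rnorm(nrow(tree$edge) * m), ncol = m) %*% L) *
    sqrt(tree$edge.length)
  for (e in preorder_edges(tree))  # parent before child
    vals[tree$edge[e, 2L], ] <- vals[tree$edge[e, 1L], ] + eps[e, ]
  colnames(vals) <- paste0("trait", seq_len(m))
  if (all_nodes) return(vals)
  tips <- vals[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

#' Simulate Ornstein-Uhlenbeck trait evolution under a regime painting
#'
#' Exact OU transitions per branch: child ~ N(theta + (parent - theta)
#' exp(-alpha t), sigma^2/(2 alpha) (1 - exp(-2 alpha t))) with theta the
#' branch regime's optimum; the root starts at its regime's optimum.
#'
#' @param tree a `phylo` object.
#' @param painting regime painting (see [paint_from_shifts()]).
#' @param alpha per-trait attraction (recycled to m).
#' @param sigma_sq per-trait diffusion variance (recycled).
#' @param theta regimes x traits matrix of optima.
#' @param seed optional RNG seed.
#' @param all_nodes return internal-node values too.
#' @return species x trait matrix (rownames = tip labels).
#' @export
simulate_hansen <- function(tree, painting, alpha, sigma_sq, theta,
                            seed = NULL, all_nodes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  theta <- as.matrix(theta)
  m <- ncol(theta)
  alpha <- rep_len(alpha, m); sigma_sq <- rep_len(sigma_sq, m)
  stopifnot(all(alpha > 0), all(sigma_sq >= 0))
  ntip <- ape::Ntip(tree)
  vals <- matrix(NA_real_, ntip + tree$Nnode, m)
  vals[ntip + 1L, ] <- theta[painting[ntip + 1L], ]
  for (e in preorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]; len <- tree$edge.length[e]
    th <- theta[painting[ch], ]
    decay <- exp(-alpha * len)
    mu <- th + (vals[p, ] - th) * decay
    vv <- sigma_sq / (2 * alpha) * (1 - decay^2)
    vals[ch, ] <- mu + rnorm(m, 0, sqrt(vv))
  }
  colnames(vals) <- paste0("trait", seq_len(m))
  if (all_nodes) return(vals)
  tips <- vals[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

#' Build the paper-like convergence scenario
#'
#' A young ultrametric radiation (Yule, `tree_depth` deep) is grafted onto a
#' long stem next to a single old divergent tip (`outgroup_depth` from the
#' root), giving `n_tips` species in total. `n_focal` focal taxa — the old
#' lineage plus ingroup tips chosen to be phylogenetically scattered
#' (greedy maximin patristic spread) — get terminal-branch shifts into one
#' shared convergent regime; everything else stays in the base regime.
#' Traits evolve by exact OU simulation. The strong preset separates the
#' optima by many stationary standard deviations (sqrt(sigma^2 / 2 alpha))
#' so regime recovery is expected; the weak preset by about one.
#'
#' @param n_tips total species (default 57).
#' @param n_traits number of traits (default 3).
#' @param n_focal focal taxa (default 6).
#' @param tree_depth ingroup radiation depth in My (default 12).
#' @param outgroup_depth root-to-tip depth in My (default 77).
#' @param preset "strong" or "weak" signal.
#' @param seed RNG seed.
#' @return list with `tree`, `traits`, `focal`, `shifts`, `painting`,
#'   `theta`, `alpha`, `sigma_sq`.
#' @export
make_convergence_scenario <- function(n_tips = 57L, n_traits = 3L,
                                      n_focal = 6L, tree_depth = 12,
                                      outgroup_depth = 77,
                                      preset = c("strong", "weak"),
                                      seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(n_focal <= n_tips, n_focal >= 2L, outgroup_depth > tree_depth)
  set.seed(seed)
  ingroup <- simulate_yule_tree(n_tips - 1L, depth = tree_depth)
  ingroup$tip.label <- paste0("sp", seq_len(n_tips - 1L))
  stem <- outgroup_depth - tree_depth
  nwk <- sprintf("(outgroup:%.10g,%s:%.10g);", outgroup_depth,
                 sub(";$", "", write_newick(ingroup)), stem)
  tree <- parse_newick(nwk)

  # focal = old lineage + scattered ingroup tips (greedy maximin patristic
  # spread). Candidates are restricted to tips whose terminal branch is at
  # least min_focal_branch: a convergent lineage must have spent time under
  # the shifted regime, and a shift painted on a near-zero branch does not
  # instantiate that (threshold relaxed by halving if too few candidates).
  D <- patristic_matrix(tree)
  ing_tips <- setdiff(tree$tip.label, "outgroup")
  term_len <- tree$edge.length[match(match(ing_tips, tree$tip.label),
                                     tree$edge[, 2L])]
  min_focal_branch <- tree_depth / 12
  eligible <- ing_tips[term_len >= min_focal_branch]
  while (length(eligible) < n_focal - 1L) {
    min_focal_branch <- min_focal_branch / 2
    eligible <- ing_tips[term_len >= min_focal_branch]
  }
  first <- sample(eligible, 1L)
  chosen <- first
  while (length(chosen) < n_focal - 1L) {
    rest <- setdiff(eligible, chosen)
    dmin <- apply(D[rest, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, rest[which.max(dmin)])
  }
  focal <- c("outgroup", chosen)

  if (preset == "strong") { alpha <- 3; sigma_sq <- 0.02; sep <- 0.6 }
  else { alpha <- 0.3; sigma_sq <- 0.02; sep <- sqrt(sigma_sq / (2 * 0.3)) }
  theta <- rbind(base = rep(0, n_traits), convergent = rep(sep, n_traits))
  shifts <- setNames(rep(2L, n_focal), as.character(match(focal, tree$tip.label)))
  painting <- paint_from_shifts(tree, shifts)
  traits <- simulate_hansen(tree, painting, alpha, sigma_sq, theta)
  colnames(traits) <- paste0("PC", seq_len(n_traits))
  list(tree = tree, traits = traits, focal = focal, shifts = shifts,
       painting = painting, theta = theta, alpha = rep(alpha, n_traits),
       sigma_sq = rep(sigma_sq, n_traits))
}

# fixed 10-landmark template: a stylized dorsal head outline (snout tip,
# paired nostrils, paired orbit margins, paired temporal points, paired
# occipital corners, parietal midpoint)
default_head_shape <- function() {
  matrix(c(0.0,  1.00,
           -0.18, 0.80,  0.18, 0.80,
           -0.45, 0.35,  0.45, 0.35,
           -0.50, -0.25, 0.50, -0.25,
           -0.30, -0.70, 0.30, -0.70,
           0.0, -0.45),
         ncol = 2L, byrow = TRUE)
}

#' Synthesize landmark configurations
#'
#' Each specimen is the mean shape plus isotropic Gaussian landmark noise,
#' then a random rotation, translation and rescaling (the nuisance
#' parameters Procrustes superimposition must remove).
#'
#' @param mean_shape 10 x 2 template (default [default_head_shape()]).
#' @param n_specimens number of configurations (>= 2).
#' @param shape_noise_sd landmark noise standard deviation, in mean-shape
#'   units.
#' @param rot_range rotation angle drawn uniformly from +/- this (radians).
#' @param trans_range translations drawn uniformly from +/- this.
#' @param scale_range scale factors drawn uniformly from this interval.
#' @param seed optional RNG seed.
#' @return 10 x 2 x n array.
#' @export
synthesize_landmarks <- function(mean_shape = default_head_shape(),
                                 n_specimens, shape_noise_sd = 0.02,
                                 rot_range = pi, trans_range = 1,
                                 scale_range = c(0.5, 2), seed = NULL) {
  stopifnot(n_specimens >= 2L)
  if (!is.null(seed)) set.seed(seed)
  out <- array(NA_real_, c(nrow(mean_shape), 2L, n_specimens),
               dimnames = list(NULL, c("x", "y"),
                               sprintf("spec_%d", seq_len(n_specimens))))
  for (j in seq_len(n_specimens)) {
    shp <- mean_shape + matrix(rnorm(length(mean_shape), 0, shape_noise_sd),
                               ncol = 2L)
    th <- runif(1L, -rot_range, rot_range)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    s <- runif(1L, scale_range[1L], scale_range[2L])
    tr <- runif(2L, -trans_range, trans_range)
    out[, , j] <- sweep(s * (shp %*% R), 2L, tr, "+")
  }
  out
}
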