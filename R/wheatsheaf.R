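# Wheatsheaf strength-of-convergence index: focal species that are
# phenotypically close but phylogenetically distant score high. Traits are
# z-scored across all species; each pairwise Euclidean distance is penalized
# by phylogenetic closeness, d'_ij = d_ij (1 + s_ij) with s_ij the shared
# (MRCA) depth as a fraction of the deepest tip; the index is the ratio of
# the mean penalized distance over all pairs to that over focal pairs.

# internal: penalized distance matrix shared by the index, the null and the
# bootstrap (isolated here so the penalization kernel can be swapped).
penalized_distances <- function(tree, traits) {
  traits <- as_trait_matrix(traits, tree)
  sds <- apply(traits, 2L, sd)
  if (any(sds <= 0)) stop("zero-variance trait", call. = FALSE)
  z <- scale(traits)
  d <- as.matrix(dist(z))
  td <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  s <- shared_depth_matrix(tree) / max(td)
  d * (1 + s)
}

# internal: index from a precomputed penalized distance matrix and focal
# row indices (possibly a multiset, for the bootstrap)
w_from_matrix <- function(dp, idx_all, idx_focal) {
  all_pairs <- dp[idx_all, idx_all][upper.tri(diag(length(idx_all)))]
  foc_pairs <- dp[idx_focal, idx_focal][upper.tri(diag(length(idx_focal)))]
  denom <- mean(foc_pairs)
  if (denom <= 0) return(Inf)
  mean(all_pairs) / denom
}

#' Wheatsheaf index
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix (every trait with nonzero variance).
#' @param focal focal tip labels (2 <= |focal| < number of tips).
#' @return the index (> 1 when focal species are mutually closer, after the
#'   phylogenetic penalty, than species pairs overall); `Inf` with a warning
#'   for phenotypically identical focal species.
#' @export
wheatsheaf_index <- function(tree, traits, focal) {
  ntip <- ape::Ntip(tree)
  idx <- match(focal, tree$tip.label)
  if (anyNA(idx)) stop("focal taxa absent from tree", call. = FALSE)
  if (length(idx) < 2L) stop("need at least 2 focal taxa", call. = FALSE)
  dp <- penalized_distances(tree, traits)
  w <- w_from_matrix(dp, seq_len(ntip), idx)
  if (!is.finite(w)) warning("identical focal phenotypes: index is degenerate (Inf)")
  w
}

#' Wheatsheaf test: bootstrap confidence interval and p-value
#'
#' The null distribution recomputes the index for `n_boot` random focal sets
#' of the same size drawn without replacement from all species;
#' p = (# null >= observed) / n_boot. The 95% CI comes from `n_boot`
#' stratified bootstrap resamples (species resampled with replacement within
#' the focal and non-focal strata; degenerate draws are redrawn).
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param focal focal tip labels.
#' @param n_boot number of replicates (default 1000, minimum 100).
#' @param seed RNG seed.
#' @return list with `w`, `ci_low`, `ci_high`, `p`, `n_boot`, `focal`.
#' @export
wheatsheaf_test <- function(tree, traits, focal, n_boot = 1000L, seed) {
  stopifnot(n_boot >= 100L)
  ntip <- ape::Ntip(tree)
  idx <- match(focal, tree$tip.label)
  if (anyNA(idx)) stop("focal taxa absent from tree", call. = FALSE)
  if (length(idx) >= ntip)
    stop("focal set must be a strict subset of the species", call. = FALSE)
  set.seed(seed)
  dp <- penalized_distances(tree, traits)
  all_idx <- seq_len(ntip)
  w_obs <- w_from_matrix(dp, all_idx, idx)
  # random-focal-set null
  null_w <- vapply(seq_len(n_boot), function(b)
    w_from_matrix(dp, all_idx, sample(all_idx, length(idx))), numeric(1))
  p <- mean(null_w >= w_obs)
  # stratified species bootstrap for the CI
  nonfocal <- setdiff(all_idx, idx)
  boot_w <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    tries <- 0L
    repeat {
      bf <- sample(idx, length(idx), replace = TRUE)
      bn <- sample(nonfocal, length(nonfocal), replace = TRUE)
      w <- w_from_matrix(dp, c(bf, bn), bf)
      tries <- tries + 1L
      if (is.finite(w) || tries >= 100L) break
    }
    if (!is.finite(w))
      stop("bootstrap degenerate: focal phenotypes carry no distance", call. = FALSE)
    boot_w[b] <- w
  }
  ci <- unname(quantile(boot_w, c(0.025, 0.975)))
  list(w = w_obs, ci_low = ci[1L], ci_high = ci[2L], p = p,
       n_boot = n_boot, focal = focal, null = null_w, boot = boot_w)
}
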