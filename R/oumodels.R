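# Brownian-motion and multi-regime Hansen (Ornstein-Uhlenbeck) model fits
# on time-calibrated trees, AICc comparison, and the stepwise
# forward/backward adaptive-regime search.
#
# A regime painting is an integer vector over all node ids (tips first, ape
# numbering): entry v is the regime of the branch subtending node v; the
# root entry is the root regime. Shifts are stored as a named integer
# vector: names = node ids whose subtending branch starts a new regime,
# values = the regime id begun there.

#' Small-sample corrected Akaike information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param p number of free parameters.
#' @param n sample size (here: tips x traits).
#' @return AICc = -2 loglik + 2p + 2p(p+1)/(n-p-1); Inf when n <= p + 1.
#' @export
aicc <- function(loglik, p, n) {
  if (n - p - 1 <= 0) return(Inf)
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Expand a shift set into a full regime painting
#'
#' Every branch inherits its parent branch's regime unless it is a shift
#' branch; the root regime seeds the recursion.
#'
#' @param tree a `phylo` object.
#' @param shifts named integer vector: names = node ids (as character) whose
#'   subtending branch begins a regime, values = regime ids.
#' @param root_regime regime id at the root (default 1).
#' @return integer vector over all node ids.
#' @export
paint_from_shifts <- function(tree, shifts = integer(0), root_regime = 1L) {
  ntip <- ape::Ntip(tree)
  painting <- integer(ntip + tree$Nnode)
  painting[ntip + 1L] <- root_regime
  shift_nodes <- as.integer(names(shifts))
  for (e in preorder_edges(tree)) {  # parent before child
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    hit <- match(ch, shift_nodes)
    painting[ch] <- if (!is.na(hit)) as.integer(shifts[[hit]]) else painting[p]
  }
  painting
}

# internal: relabel regimes to compact 1..k' preserving first-appearance
# order along the node-id sequence (deterministic)
compact_painting <- function(painting) {
  ids <- unique(painting)
  match(painting, ids)
}

#' Regime-shift bookkeeping
#'
#' Summarizes a shift set the way the stepwise search reports its result:
#' `k` counts regime origins — the root regime origin plus every shift (so a
#' single-optimum model has k = 1); `k_prime` is the number of distinct
#' regimes on branches; `delta_k` = k - k'; a regime is convergent when two
#' or more origins lead to it, `c` counts the origins toward convergent
#' regimes, and `k_conv` / `k_nonconv` split `k_prime` accordingly.
#'
#' @param tree a `phylo` object.
#' @param shifts named integer shift vector (see [paint_from_shifts()]).
#' @param root_regime regime id at the root.
#' @return list with k, k_prime, delta_k, c, k_conv, k_nonconv.
#' @export
surface_bookkeeping <- function(tree, shifts, root_regime = 1L) {
  painting <- paint_from_shifts(tree, shifts, root_regime)
  regimes <- unique(painting)
  origins <- c(root_regime, as.integer(shifts))
  k <- length(origins)
  k_prime <- length(regimes)
  arrivals <- table(factor(origins, levels = regimes))
  convergent <- as.integer(names(arrivals)[arrivals >= 2L])
  list(k = k, k_prime = k_prime, delta_k = k - k_prime,
       c = sum(origins %in% convergent), k_conv = length(convergent),
       k_nonconv = k_prime - length(convergent))
}

# internal: per-tip path segment table (fixed per tree): one row per edge on
# each root-to-tip path, with start/end times from the root.
path_table <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  paths <- root_to_tip_paths(tree)
  tip <- rep.int(seq_len(ntip), lengths(paths))
  node <- unlist(paths, use.names = FALSE)
  list(tip = tip, node = node, t0 = depth[parent[node]], t1 = depth[node],
       depth = depth[seq_len(ntip)])
}

#' Hansen model weight matrix (reference implementation)
#'
#' Row i gives the weights with which each regime's optimum enters the
#' expected value of tip i: contributions exp(-a(T-t_end)) - exp(-a(T-t_begin))
#' accumulated over the lineage's branch segments, plus exp(-aT) assigned to
#' the root regime (the root state is fixed at the root regime's optimum).
#' Rows sum to 1 for every alpha and painting.
#'
#' @param tree a `phylo` object.
#' @param painting regime painting (see [paint_from_shifts()]).
#' @param alpha OU attraction strength (> 0), units 1/time.
#' @return tips x regimes matrix.
#' @export
hansen_weights <- function(tree, painting, alpha) {
  pt <- path_table(tree)
  ntip <- ape::Ntip(tree)
  k <- max(painting)
  W <- matrix(0, ntip, k)
  root_reg <- painting[ntip + 1L]
  W[cbind(seq_len(ntip), root_reg)] <- exp(-alpha * pt$depth)
  Tt <- pt$depth[pt$tip]
  contrib <- exp(-alpha * (Tt - pt$t1)) - exp(-alpha * (Tt - pt$t0))
  reg <- painting[pt$node]
  for (s in seq_along(contrib))
    W[pt$tip[s], reg[s]] <- W[pt$tip[s], reg[s]] + contrib[s]
  W
}

#' OU trait covariance among tips (reference implementation)
#'
#' V_ij = (sigma^2 / (2 alpha)) exp(-alpha d_ij) (1 - exp(-2 alpha t_ij))
#' with d_ij the patristic distance and t_ij the shared (MRCA) depth.
#'
#' @param tree a `phylo` object.
#' @param alpha attraction strength.
#' @param sigma_sq diffusion variance.
#' @return tips x tips covariance matrix.
#' @export
hansen_vcv <- function(tree, alpha, sigma_sq) {
  D <- patristic_matrix(tree)
  Tm <- shared_depth_matrix(tree)
  (sigma_sq / (2 * alpha)) * exp(-alpha * D) * (1 - exp(-2 * alpha * Tm))
}

#' Hansen model log-likelihood (reference implementation)
#'
#' Gaussian log-likelihood of the painted OU model, summed over traits.
#' Per-trait parameters: `alpha` and `sigma_sq` are vectors of length m,
#' `theta` a regimes x m matrix of optima.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix (rownames = tips).
#' @param painting regime painting.
#' @param alpha,sigma_sq numeric vectors (length m or 1, recycled).
#' @param theta regimes x traits matrix of optima.
#' @return total log-likelihood.
#' @export
hansen_loglik <- function(tree, traits, painting, alpha, sigma_sq, theta) {
  traits <- as_trait_matrix(traits, tree)
  m <- ncol(traits)
  alpha <- rep_len(alpha, m); sigma_sq <- rep_len(sigma_sq, m)
  theta <- matrix(theta, ncol = m)
  if (any(!is.finite(alpha)) || any(alpha <= 0) ||
      any(!is.finite(sigma_sq)) || any(sigma_sq <= 0))
    stop("alpha and sigma_sq must be finite and > 0", call. = FALSE)
  n <- nrow(traits)
  ll <- 0
  for (j in seq_len(m)) {
    W <- hansen_weights(tree, painting, alpha[j])
    mu <- W %*% theta[, j]
    V <- hansen_vcv(tree, alpha[j], sigma_sq[j])
    R <- chol(V)
    z <- backsolve(R, traits[, j] - mu, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  }
  ll
}

#' Brownian-motion fit
#'
#' Per-trait analytic ML: root state z0 by GLS and rate sigma^2 from GLS
#' residuals under y ~ N(z0 1, sigma^2 C), C = shared-depth matrix.
#'
#' @param tree a `phylo` object (ultrametric expected; warns otherwise).
#' @param traits species x trait matrix.
#' @return list with per-trait `z0`, `sigma_sq`, total `loglik`, `n_params`,
#'   `aicc`.
#' @export
bm_fit <- function(tree, traits) {
  traits <- as_trait_matrix(traits, tree)
  if (!is_ultrametric(tree)$ultrametric)
    warning("tree is not ultrametric; using per-tip depths exactly")
  C <- shared_depth_matrix(tree)
  R <- tryCatch(chol(C), error = function(e)
    stop("singular BM covariance (duplicate zero-length tips?)", call. = FALSE))
  n <- nrow(traits); m <- ncol(traits)
  one <- backsolve(R, rep(1, n), transpose = TRUE)
  z0 <- numeric(m); s2 <- numeric(m); ll <- 0
  for (j in seq_len(m)) {
    y <- backsolve(R, traits[, j], transpose = TRUE)
    z0[j] <- sum(one * y) / sum(one^2)
    rss <- sum((y - z0[j] * one)^2)
    s2[j] <- max(rss / n, 1e-12)
    if (rss / n < 1e-12) warning("degenerate (near-constant) trait; sigma_sq floored")
    ll <- ll - 0.5 * (n * log(2 * pi * s2[j]) + 2 * sum(log(diag(R))) + rss / s2[j])
  }
  p <- 2L * m
  list(z0 = z0, sigma_sq = s2, loglik = ll, n_params = p,
       aicc = aicc(ll, p, n * m))
}

#' Fit a Hansen model for a fixed regime painting
#'
#' Per trait, the likelihood is profiled over alpha on a bounded log scale
#' (alpha in [1e-6/T, 1e3/T] with T the tree depth); at each alpha the
#' optima theta come from generalized least squares and sigma^2 from the GLS
#' residuals. Parameter count p = m(2 + k'); AICc sample size n = tips x
#' traits.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param painting regime painting (see [paint_from_shifts()]).
#' @param prep optional precomputed [hansen_prep()] object (must have been
#'   built from the same tree and traits).
#' @param refine after the grid profile, polish each trait's alpha by
#'   golden-section search within the bracketing grid cell (default TRUE;
#'   the stepwise search turns this off so all candidate fits share the
#'   cached grid factorizations).
#' @return list with `alpha`, `sigma_sq` (per trait), `theta` (regime x
#'   trait), `painting`, `loglik`, `n_params`, `aicc`.
#' @export
hansen_fit <- function(tree, traits, painting, prep = NULL, refine = TRUE) {
  if (is.null(prep)) prep <- hansen_prep(tree, traits)
  ntip <- prep$ntip
  traits <- prep$traits
  if (length(painting) != ntip + tree$Nnode)
    stop("painting length does not match tree", call. = FALSE)
  cp <- compact_painting(painting)
  k <- max(cp)
  if (k >= ntip) stop("more regimes than tips: over-parameterized", call. = FALSE)
  seg_reg <- cp[prep$node] - 1L
  root_reg <- cp[ntip + 1L] - 1L
  fit <- .hansen_grid_fit_cpp(prep$Lcube, prep$Zcube, prep$logdets,
                              prep$alphas, traits, prep$depth,
                              prep$seg_tip, seg_reg, prep$t0, prep$t1,
                              k, root_reg)
  m <- ncol(traits)
  alpha <- as.numeric(fit$alpha); sigma_sq <- as.numeric(fit$sigma_sq)
  theta <- matrix(fit$theta, nrow = k)
  ll_trait <- as.numeric(fit$loglik_by_trait)
  if (refine) {
    g <- length(prep$alphas)
    for (j in seq_len(m)) {
      gi <- fit$grid_index[j]
      ref <- .hansen_fit_cpp(traits[, j, drop = FALSE], prep$D, prep$Tm,
                             prep$depth, prep$seg_tip, seg_reg,
                             prep$t0, prep$t1, k, root_reg,
                             prep$alphas[max(1L, gi - 1L)],
                             prep$alphas[min(g, gi + 1L)],
                             ngrid = 5L, ngolden = 30L)
      if (ref$loglik > ll_trait[j]) {
        ll_trait[j] <- ref$loglik
        alpha[j] <- ref$alpha[1L]; sigma_sq[j] <- ref$sigma_sq[1L]
        theta[, j] <- ref$theta[, 1L]
      }
    }
  }
  loglik <- sum(ll_trait)
  p <- m * (2L + k)
  colnames(theta) <- colnames(traits)
  list(alpha = alpha, sigma_sq = sigma_sq,
       theta = theta, painting = cp, k_prime = k, loglik = loglik,
       n_params = p, aicc = aicc(loglik, p, ntip * m))
}

#' Precompute factorizations for repeated Hansen fits
#'
#' Builds the patristic and shared-depth matrices, the per-tip path segment
#' table, and — for a log-spaced alpha grid spanning [1e-6/T, 1e3/T] — the
#' Cholesky factor of the scaled OU covariance and the whitened traits.
#' The painting only affects the regime weight matrix, so stepwise-search
#' candidate fits reuse all of this.
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param n_grid number of alpha grid points (default 32).
#' @return opaque list consumed by [hansen_fit()].
#' @export
hansen_prep <- function(tree, traits, n_grid = 32L) {
  validate_phylo(tree)
  traits <- as_trait_matrix(traits, tree)
  pt <- path_table(tree)
  Tdepth <- max(pt$depth)
  D <- unname(patristic_matrix(tree))
  Tm <- unname(shared_depth_matrix(tree))
  alphas <- exp(seq(log(1e-6 / Tdepth), log(1e3 / Tdepth), length.out = n_grid))
  n <- nrow(traits)
  Lcube <- array(0, c(n, n, n_grid))
  Zcube <- array(0, c(n, ncol(traits), n_grid))
  logdets <- numeric(n_grid)
  for (g in seq_len(n_grid)) {
    a <- alphas[g]
    V0 <- (1 / (2 * a)) * exp(-a * D) * (1 - exp(-2 * a * Tm))
    Lt <- t(chol(V0))
    Lcube[, , g] <- Lt
    Zcube[, , g] <- forwardsolve(Lt, traits)
    logdets[g] <- 2 * sum(log(diag(Lt)))
  }
  list(ntip = ape::Ntip(tree), traits = traits, D = D, Tm = Tm,
       depth = pt$depth, seg_tip = pt$tip - 1L, node = pt$node,
       t0 = pt$t0, t1 = pt$t1, alphas = alphas,
       Lcube = Lcube, Zcube = Zcube, logdets = logdets)
}

#' Forward phase of the stepwise regime search
#'
#' Starting from a single regime over the whole tree, each step tentatively
#' begins a new regime at every branch that is not already a shift point,
#' refits, and accepts the single best AICc improvement; stops when no
#' candidate lowers AICc. Ties break toward the smallest postorder branch
#' index.
#'
#' @param tree a `phylo` object (>= 4 tips).
#' @param traits species x trait matrix (1-10 traits).
#' @param min_improvement required AICc decrease to accept a step (default 0:
#'   any decrease).
#' @param max_shifts cap on the number of accepted shifts.
#' @param verbose print per-step progress.
#' @return list with `shifts`, `painting`, `fit`, `history` (data.frame
#'   step, node, aicc), and `aicc`.
#' @export
surface_forward <- function(tree, traits, min_improvement = 0,
                            max_shifts = Inf, verbose = FALSE) {
  traits <- as_trait_matrix(traits, tree)
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips", call. = FALSE)
  if (ncol(traits) < 1L || ncol(traits) > 10L)
    stop("need between 1 and 10 traits", call. = FALSE)
  prep <- hansen_prep(tree, traits)
  cand_nodes <- tree$edge[postorder_edges(tree), 2L]
  shifts <- integer(0)
  cur_fit <- hansen_fit(tree, traits, paint_from_shifts(tree, shifts), prep,
                        refine = FALSE)
  history <- data.frame(step = 0L, node = NA_integer_, aicc = cur_fit$aicc)
  step <- 0L
  while (length(shifts) < max_shifts) {
    step <- step + 1L
    new_regime <- length(shifts) + 2L
    best_node <- NA_integer_; best_fit <- NULL; best_aicc <- cur_fit$aicc - min_improvement
    for (b in cand_nodes) {
      if (as.character(b) %in% names(shifts)) next
      cand <- c(shifts, setNames(new_regime, as.character(b)))
      fit <- hansen_fit(tree, traits, paint_from_shifts(tree, cand), prep,
                        refine = FALSE)
      if (fit$aicc < best_aicc) { best_aicc <- fit$aicc; best_node <- b; best_fit <- fit }
    }
    if (is.na(best_node)) break
    shifts <- c(shifts, setNames(new_regime, as.character(best_node)))
    cur_fit <- best_fit
    history <- rbind(history,
                     data.frame(step = step, node = best_node, aicc = cur_fit$aicc))
    if (verbose)
      message(sprintf("forward step %d: shift at node %d, AICc %.4f",
                      step, best_node, cur_fit$aicc))
  }
  list(shifts = shifts, painting = paint_from_shifts(tree, shifts),
       fit = cur_fit, history = history, aicc = cur_fit$aicc)
}

#' Backward (collapse) phase of the stepwise regime search
#'
#' Repeatedly evaluates every unordered pair of regimes merged into one
#' (relabel, refit), accepts the best AICc improvement, and iterates to
#' fixity. Reports the regime bookkeeping plus the four-model comparison:
#' the collapsed convergent model (OUc), the forward-phase multi-regime
#' model (OUnc), the single-optimum model (OU1) and Brownian motion (BM).
#'
#' @param tree a `phylo` object.
#' @param traits species x trait matrix.
#' @param forward result of [surface_forward()].
#' @param min_improvement required AICc decrease to accept a merge.
#' @param verbose print per-step progress.
#' @return list of class `surface_result`: bookkeeping fields (k, k_prime,
#'   delta_k, c, k_conv, k_nonconv), `aicc_ouc`, `aicc_ounc`, `aicc_ou1`,
#'   `aicc_bm`, `shifts`, `painting`, `fit`, `history`.
#' @export
surface_backward <- function(tree, traits, forward, min_improvement = 0,
                             verbose = FALSE) {
  traits <- as_trait_matrix(traits, tree)
  prep <- hansen_prep(tree, traits)
  shifts <- forward$shifts
  cur_fit <- forward$fit
  history <- data.frame(step = 0L, merged = NA_character_, aicc = cur_fit$aicc)
  step <- 0L
  repeat {
    step <- step + 1L
    regimes <- sort(unique(c(1L, as.integer(shifts))))
    if (length(regimes) < 2L) break
    pairs <- combn(regimes, 2L)
    best <- NULL; best_aicc <- cur_fit$aicc - min_improvement
    for (q in seq_len(ncol(pairs))) {
      a <- pairs[1L, q]; b <- pairs[2L, q]
      cand <- shifts
      cand[cand == b] <- a
      root_reg <- 1L
      fit <- hansen_fit(tree, traits, paint_from_shifts(tree, cand, root_reg),
                        prep, refine = FALSE)
      if (fit$aicc < best_aicc) {
        best_aicc <- fit$aicc
        best <- list(shifts = cand, fit = fit, label = sprintf("%d<-%d", a, b))
      }
    }
    if (is.null(best)) break
    shifts <- best$shifts; cur_fit <- best$fit
    history <- rbind(history,
                     data.frame(step = step, merged = best$label, aicc = cur_fit$aicc))
    if (verbose)
      message(sprintf("backward step %d: merged %s, AICc %.4f",
                      step, best$label, cur_fit$aicc))
  }
  book <- surface_bookkeeping(tree, shifts)
  ou1 <- hansen_fit(tree, traits, paint_from_shifts(tree, integer(0)), prep,
                    refine = FALSE)
  bm <- bm_fit(tree, traits)
  book_ounc <- surface_bookkeeping(tree, forward$shifts)
  book_ou1 <- surface_bookkeeping(tree, integer(0))
  book_bm <- lapply(book_ou1, function(x) 0L)  # no OU regimes at all
  out <- c(book,
           list(aicc_ouc = cur_fit$aicc, aicc_ounc = forward$aicc,
                aicc_ou1 = ou1$aicc, aicc_bm = bm$aicc,
                book_ounc = book_ounc, book_ou1 = book_ou1, book_bm = book_bm,
                shifts = shifts,
                painting = paint_from_shifts(tree, shifts),
                fit = cur_fit, history = history,
                forward_history = forward$history))
  class(out) <- "surface_result"
  out
}

#' Full stepwise regime search (forward + backward)
#'
#' @inheritParams surface_forward
#' @return a `surface_result` (see [surface_backward()]).
#' @examples
#' sc <- make_convergence_scenario(n_tips = 16, n_focal = 3, seed = 1)
#' res <- surface_search(sc$tree, sc$traits)
#' res$k_conv                      # convergent regimes found
#' res$painting[match(sc$focal, sc$tree$tip.label)]
#' @export
surface_search <- function(tree, traits, min_improvement = 0,
                           max_shifts = Inf, verbose = FALSE) {
  fw <- surface_forward(tree, traits, min_improvement = min_improvement,
                        max_shifts = max_shifts, verbose = verbose)
  surface_backward(tree, traits, fw, min_improvement = min_improvement,
                   verbose = verbose)
}

#' @export
print.surface_result <- function(x, ...) {
  cat("Stepwise OU regime search\n")
  cat(sprintf("  k (shifts) = %d, k' (regimes) = %d, delta_k = %d\n",
              x$k, x$k_prime, x$delta_k))
  cat(sprintf("  c = %d, k'_conv = %d, k'_nonconv = %d\n",
              x$c, x$k_conv, x$k_nonconv))
  cat(sprintf("  AICc: OUc %.4f | OUnc %.4f | OU1 %.4f | BM %.4f\n",
              x$aicc_ouc, x$aicc_ounc, x$aicc_ou1, x$aicc_bm))
  invisible(x)
}
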