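test_that("aicc arithmetic", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(0, 2, 10), 5.7142857, tolerance = 1e-7)
  expect_identical(aicc(0, 9, 10), Inf)
})

test_that("bm_fit matches the closed-form GLS on a 2-tip tree", {
  tr <- parse_newick("(A:1,B:1);")
  y <- matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), "x"))
  fit <- bm_fit(tr, y)
  expect_equal(fit$z0, 1)
  expect_equal(fit$sigma_sq, 1)
  expect_equal(fit$n_params, 2L)
  # constant trait: floored sigma with a warning
  yc <- matrix(c(1, 1), 2, 1, dimnames = list(c("A", "B"), "x"))
  expect_warning(fitc <- bm_fit(tr, yc), "degenerate")
  expect_equal(fitc$sigma_sq, 1e-12)
})

test_that("bm loglik equals direct multivariate-normal density on random trees", {
  set.seed(31)
  for (i in 1:5) {
    tr <- simulate_yule_tree(5, depth = 2)
    y <- simulate_bm(tr, rates = 0.5)
    fit <- bm_fit(tr, y)
    C <- shared_depth_matrix(tr)[tr$tip.label, tr$tip.label]
    V <- fit$sigma_sq * C
    r <- y[tr$tip.label, 1] - fit$z0
    ll <- -0.5 * (5 * log(2 * pi) + determinant(V)$modulus[1] +
                    drop(r %*% solve(V, r)))
    expect_equal(fit$loglik, ll, tolerance = 1e-8)
  }
})

test_that("hansen weight rows sum to 1 for any alpha and painting", {
  set.seed(32)
  for (i in 1:8) {
    tr <- simulate_yule_tree(sample(4:20, 1), depth = 5)
    nshift <- sample(0:3, 1)
    cand <- sample(tr$edge[, 2], nshift)
    painting <- paint_from_shifts(
      tr, setNames(seq_len(nshift) + 1L, as.character(cand)))
    for (a in c(1e-6, 0.1, 1, 50)) {
      W <- hansen_weights(tr, painting, a)
      expect_equal(rowSums(W), rep(1, ape::Ntip(tr)), tolerance = 1e-10)
    }
  }
})

test_that("OU covariance diagonal approaches the stationary variance", {
  tr <- parse_newick("(A:1000,B:1000);")
  V <- hansen_vcv(tr, alpha = 1, sigma_sq = 2)
  expect_equal(unname(diag(V)), c(1, 1), tolerance = 1e-12)
})

test_that("hansen loglik converges to BM loglik as alpha -> 0", {
  set.seed(33)
  tr <- simulate_yule_tree(10, depth = 3)
  y <- simulate_bm(tr, rates = 1)
  fit <- bm_fit(tr, y)
  ll_ou <- hansen_loglik(tr, y, paint_from_shifts(tr),
                         alpha = 1e-8, sigma_sq = fit$sigma_sq,
                         theta = matrix(fit$z0, 1))
  expect_lt(abs(ll_ou - fit$loglik), 1e-6)
})

test_that("hansen_fit agrees with the R reference likelihood at its optimum", {
  set.seed(34)
  tr <- simulate_yule_tree(12, depth = 4)
  pa <- paint_from_shifts(tr, setNames(2L, as.character(sample(tr$edge[, 2], 1))))
  y <- simulate_hansen(tr, pa, alpha = 1.5, sigma_sq = 0.5,
                       theta = rbind(0, 2))
  fit <- hansen_fit(tr, y, pa)
  ll_ref <- hansen_loglik(tr, y, fit$painting, fit$alpha, fit$sigma_sq,
                          fit$theta)
  expect_equal(fit$loglik, ll_ref, tolerance = 1e-6)
  expect_equal(fit$n_params, 1L * (2L + 2L))
  # profile optimum: nearby alphas are no better
  for (f in c(0.8, 1.25)) {
    ll_near <- hansen_loglik(tr, y, fit$painting, fit$alpha * f,
                             fit$sigma_sq, fit$theta)
    expect_lte(ll_near, fit$loglik + 1e-6)
  }
})

test_that("theta recovery under strong attraction", {
  set.seed(35)
  hits <- 0L
  for (i in 1:5) {
    tr <- simulate_yule_tree(20, depth = 10)
    shift_node <- sample(tr$edge[tr$edge[, 2] > ape::Ntip(tr), 2], 1)
    pa <- paint_from_shifts(tr, setNames(2L, as.character(shift_node)))
    y <- simulate_hansen(tr, pa, alpha = 2, sigma_sq = 0.1,
                         theta = rbind(0, 3))
    fit <- hansen_fit(tr, y, pa)
    # regime tip means in compacted labels
    tips2 <- which(fit$painting[seq_len(20)] == fit$painting[shift_node])
    if (length(tips2) >= 2) {
      se <- sqrt(0.1 / (2 * 2) / length(tips2)) * 3
      reg <- fit$painting[shift_node]
      if (abs(fit$theta[reg, 1] - mean(y[tips2, 1])) < 3 * sqrt(0.1 / 4))
        hits <- hits + 1L
    } else hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("paint_from_shifts and bookkeeping identities", {
  tr <- simulate_yule_tree(20, depth = 5, seed = 36)
  shifts <- setNames(c(2L, 3L, 2L), as.character(sample(tr$edge[, 2], 3)))
  p <- paint_from_shifts(tr, shifts)
  expect_equal(p[ape::Ntip(tr) + 1L], 1L)
  bk <- surface_bookkeeping(tr, shifts)
  expect_equal(bk$delta_k, bk$k - bk$k_prime)
  expect_equal(bk$k_prime, bk$k_conv + bk$k_nonconv)
  expect_equal(bk$k, 4L)  # root origin + 3 shifts
  # regime 2 has two arrivals -> convergent; both its shifts count in c
  expect_equal(bk$k_conv, 1L)
  expect_equal(bk$c, 2L)
  # single-optimum model: k = 1 (the root regime origin), nothing convergent
  bk1 <- surface_bookkeeping(tr, integer(0))
  expect_equal(bk1[c("k", "k_prime", "delta_k", "c", "k_conv", "k_nonconv")],
               list(k = 1L, k_prime = 1L, delta_k = 0L, c = 0L, k_conv = 0L,
                    k_nonconv = 1L))
})

test_that("forward search: strictly decreasing AICc and few shifts under OU1 data", {
  set.seed(37)
  near_zero <- 0L
  n_rep <- 6L
  for (i in seq_len(n_rep)) {
    tr <- simulate_yule_tree(16, depth = 5)
    y <- simulate_hansen(tr, paint_from_shifts(tr), alpha = 1,
                         sigma_sq = 0.5, theta = matrix(0, 1, 3))
    fw <- surface_forward(tr, y)
    expect_true(all(diff(fw$history$aicc) < 0))
    if (length(fw$shifts) <= 2L) near_zero <- near_zero + 1L
  }
  expect_gte(near_zero, ceiling(0.8 * n_rep) - 1L)
})

test_that("planted two-shift scenario is recovered", {
  set.seed(38)
  ok <- 0L
  n_rep <- 5L
  for (i in seq_len(n_rep)) {
    tr <- simulate_yule_tree(24, depth = 10)
    ntip <- ape::Ntip(tr)
    internals <- tr$edge[tr$edge[, 2] > ntip, 2]
    # two non-nested internal shift branches with decent clade sizes
    sizes <- vapply(internals, function(nd)
      length(ape::extract.clade(tr, nd)$tip.label), integer(1))
    cands <- internals[sizes >= 3 & sizes <= 8]
    if (length(cands) < 2) next
    picks <- sample(cands, 2)
    pa <- paint_from_shifts(tr, setNames(c(2L, 3L), as.character(picks)))
    y <- simulate_hansen(tr, pa, alpha = 3, sigma_sq = 0.05,
                         theta = rbind(0, 2, -2))
    fw <- surface_forward(tr, y)
    found <- vapply(picks, function(nd) {
      hit <- as.character(c(nd, tr$edge[tr$edge[, 2] == nd, 1],
                            tr$edge[tr$edge[, 1] == nd, 2]))
      any(hit %in% names(fw$shifts))
    }, logical(1))
    if (all(found)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("backward phase: AICc ordering invariants and bookkeeping on every run", {
  set.seed(39)
  tr <- simulate_yule_tree(16, depth = 8)
  pa <- paint_from_shifts(tr, setNames(c(2L, 3L),
                                       as.character(sample(tr$edge[, 2], 2))))
  y <- simulate_hansen(tr, pa, alpha = 2, sigma_sq = 0.1, theta = rbind(0, 2, 2))
  res <- surface_search(tr, y)
  expect_lte(res$aicc_ouc, res$aicc_ounc + 1e-9)
  expect_lte(res$aicc_ounc, res$aicc_ou1 + 1e-9)
  expect_equal(res$delta_k, res$k - res$k_prime)
  expect_equal(res$k_prime, res$k_conv + res$k_nonconv)
})

test_that("two planted lineages sharing an optimum are merged as convergent", {
  set.seed(40)
  ok <- 0L
  n_rep <- 6L
  for (i in seq_len(n_rep)) {
    tr <- simulate_yule_tree(20, depth = 10)
    ntip <- ape::Ntip(tr)
    tips_term <- tr$edge[tr$edge[, 2] <= ntip, 2]
    lens <- tr$edge.length[match(tips_term, tr$edge[, 2])]
    # independent lineages: decent time under the regime, but not a branch
    # spanning most of the tree depth
    good <- tips_term[lens > quantile(lens, 0.5) & lens < 6]
    picks <- sample(good, 2)
    pa <- paint_from_shifts(tr, setNames(c(2L, 2L), as.character(picks)))
    y <- simulate_hansen(tr, pa, alpha = 3, sigma_sq = 0.05,
                         theta = rbind(rep(0, 3), rep(2.5, 3)))
    res <- surface_search(tr, y)
    regs <- res$painting[picks]
    if (length(unique(regs)) == 1L && sum(res$shifts == regs[1]) >= 2L &&
        res$delta_k >= 1L) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})
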