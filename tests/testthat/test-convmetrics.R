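test_that("pair metrics reproduce the worked 4-tip example", {
  b4 <- balanced4()
  anc <- squared_change_parsimony(b4$tree, b4$traits)
  pm <- pair_c_metrics(b4$tree, b4$traits, anc, "A", "C")
  expect_equal(pm$dtip, 0)
  expect_equal(pm$dmax, 8 / 3, tolerance = 1e-10)
  expect_equal(pm$c1, 1)
  expect_equal(pm$c2, 8 / 3, tolerance = 1e-10)
  expect_equal(pm$c3, 0.5, tolerance = 1e-10)
  expect_equal(pm$c4, 0.25, tolerance = 1e-10)
})

test_that("pair whose tips realize Dmax has C1 = C2 = 0", {
  b4 <- balanced4()
  anc <- squared_change_parsimony(b4$tree, b4$traits)
  pm <- pair_c_metrics(b4$tree, b4$traits, anc, "B", "D")  # tips at +-4
  expect_equal(pm$dtip, pm$dmax)
  expect_equal(pm$c1, 0, tolerance = 1e-12)
  expect_equal(pm$c2, 0, tolerance = 1e-12)
})

test_that("Dmax equals the brute-force double loop over lineage node pairs", {
  set.seed(51)
  for (i in 1:5) {
    tr <- simulate_yule_tree(8, depth = 4)
    y <- simulate_bm(tr, rates = c(1, 1))
    anc <- squared_change_parsimony(tr, y)
    tips <- sample(8, 2)
    pm <- pair_c_metrics(tr, y, anc, tips[1], tips[2])
    # oracle: explicit enumeration
    mrca <- ape::getMRCA(tr, tips)
    parent <- integer(8 + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    lineage <- function(tip) {
      p <- tip
      while (tip != mrca) { tip <- parent[tip]; p <- c(p, tip) }
      p
    }
    la <- lineage(tips[1]); lb <- lineage(tips[2])
    dm <- 0
    for (u in la) for (v in lb)
      dm <- max(dm, sqrt(sum((anc[u, ] - anc[v, ])^2)))
    expect_equal(pm$dmax, dm, tolerance = 1e-12)
  }
})

test_that("degenerate identical states return zeros with a flag", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  y <- matrix(0, 4, 1, dimnames = list(c("A", "B", "C", "D"), "x"))
  anc <- squared_change_parsimony(tr, y)
  pm <- pair_c_metrics(tr, y, anc, "A", "C")
  expect_true(pm$degenerate)
  expect_equal(pm$c1, 0)
})

test_that("group metrics: two-taxon focal set equals the pair values", {
  b4 <- balanced4()
  g <- group_c_metrics(b4$tree, b4$traits, c("A", "C"))
  anc <- squared_change_parsimony(b4$tree, b4$traits)
  pm <- pair_c_metrics(b4$tree, b4$traits, anc, "A", "C")
  expect_equal(g$c1, pm$c1)
  expect_equal(g$c2, pm$c2)
  expect_equal(g$c3, pm$c3)
  expect_equal(g$c4, pm$c4)
  expect_error(group_c_metrics(b4$tree, b4$traits, c("A", "zz")), "absent")
})

test_that("metric invariants: scaling and rotation of trait space", {
  set.seed(52)
  sc <- make_convergence_scenario(n_tips = 20, n_focal = 4, seed = 52)
  g0 <- group_c_metrics(sc$tree, sc$traits, sc$focal)
  # common scaling: C1, C3, C4 unchanged; C2 scales linearly
  g2 <- group_c_metrics(sc$tree, sc$traits * 3.7, sc$focal)
  expect_equal(g2$c1, g0$c1, tolerance = 1e-9)
  expect_equal(g2$c2, 3.7 * g0$c2, tolerance = 1e-9)
  expect_equal(g2$c3, g0$c3, tolerance = 1e-9)
  expect_equal(g2$c4, g0$c4, tolerance = 1e-9)
  # rigid rotation of trait space
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- sc$traits %*% qr_
  rownames(rot) <- rownames(sc$traits)
  g3 <- group_c_metrics(sc$tree, rot, sc$focal)
  expect_equal(g3$c1, g0$c1, tolerance = 1e-9)
  expect_equal(g3$c2, g0$c2, tolerance = 1e-9)
  expect_equal(g3$c4, g0$c4, tolerance = 1e-9)
})

test_that("c_significance is deterministic and detects planted convergence", {
  sc <- make_convergence_scenario(n_tips = 30, n_focal = 4, seed = 53)
  r1 <- c_significance(sc$tree, sc$traits, sc$focal, n_sim = 99, seed = 7)
  r2 <- c_significance(sc$tree, sc$traits, sc$focal, n_sim = 99, seed = 7)
  expect_identical(r1[c("p1", "p2", "p3", "p4")], r2[c("p1", "p2", "p3", "p4")])
  expect_lte(r1$p1, 0.05)
  expect_lte(r1$p2, 0.05)
  expect_true(all(unlist(r1[c("p1", "p2", "p3", "p4")]) >= 0))
})

test_that("BM-null p-values are valid (sub-uniform)", {
  # C1 has an atom at 0 under Brownian motion (random tip pairs often realize
  # the maximal ancestral divergence themselves), so the p-value piles up
  # near 1 and exact uniformity is impossible; what the test must guarantee
  # is validity: P(p <= a) <= a (up to binomial noise) at the usual levels.
  set.seed(54)
  tr <- simulate_yule_tree(15, depth = 5)
  nrep <- 100L
  pvals <- numeric(nrep)
  for (r in seq_len(nrep)) {
    y <- simulate_bm(tr, rates = c(1, 1))
    focal <- sample(tr$tip.label, 2)
    pvals[r] <- c_significance(tr, y, focal, n_sim = 40, seed = 1000 + r)$p1
  }
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= a), a + 2 * sqrt(a * (1 - a) / nrep))
  expect_gt(mean(pvals <= 0.5), 0.1)  # not degenerate either
})

test_that("segment-hull interval matches brute-force point sampling", {
  set.seed(55)
  hull <- matrix(c(0, 0, 2, 0, 2, 2, 0, 2), ncol = 2, byrow = TRUE)
  for (i in 1:25) {
    a <- runif(2, -1, 3); b <- runif(2, -1, 3)
    iv <- ouconv:::segment_hull_interval(a, b, hull)
    ts <- seq(0, 1, by = 1e-3)
    inside <- vapply(ts, function(t) {
      p <- a + t * (b - a)
      all(p >= -1e-9) && all(p <= 2 + 1e-9)
    }, logical(1))
    if (is.null(iv)) {
      expect_lte(sum(inside), 2L)  # at most grazing contact
    } else {
      expect_lt(max(abs(range(ts[inside]) - iv)), 1.5e-3)  # grid resolution
    }
  }
})

test_that("C5 counts focal lineages and is significant under planted convergence", {
  sc <- make_convergence_scenario(n_tips = 30, n_focal = 4, seed = 56)
  anc <- squared_change_parsimony(sc$tree, sc$traits)
  r <- c5(sc$tree, sc$traits, sc$focal, anc = anc, n_sim = 99, seed = 9)
  expect_true(all(sc$focal %in% r$entering))
  expect_gte(r$c5, length(sc$focal))
  r2 <- c5(sc$tree, sc$traits, sc$focal, anc = anc, n_sim = 99, seed = 9)
  expect_identical(r[c("c5", "p")], r2[c("c5", "p")])
})

test_that("C5 with a hull containing no other lineage equals the focal count", {
  # star-like tree with one far-away focal cluster on axis 1/2
  tr <- parse_newick("((F1:1,F2:1):8,((F3:1,F4:1):7,(N1:4,(N2:2,N3:2):2):4):1);")
  y <- rbind(F1 = c(10, 10), F2 = c(10.5, 10.4), F3 = c(10.2, 9.8),
             F4 = c(9.9, 10.1), N1 = c(0, 0), N2 = c(0.3, -0.2),
             N3 = c(-0.4, 0.2))
  colnames(y) <- c("PC1", "PC2")
  r <- c5(tr, y, c("F1", "F2", "F3", "F4"), n_sim = 19, seed = 2)
  expect_equal(r$c5, 4L)
  expect_setequal(r$entering, c("F1", "F2", "F3", "F4"))
})
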