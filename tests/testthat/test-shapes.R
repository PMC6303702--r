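test_that("centroid_size matches the direct formula", {
  cfg <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1),
               matrix(0, 6, 2))
  expect_equal(centroid_size(cfg), sqrt(8))
  # scaling linearity and random recomputation
  set.seed(1)
  for (i in 1:5) {
    cfg <- random_shape()
    s <- runif(1, 0.1, 10)
    expect_equal(centroid_size(cfg * s), s * centroid_size(cfg))
    ctr <- sweep(cfg, 2, colMeans(cfg))
    expect_equal(centroid_size(cfg), sqrt(sum(ctr^2)))
  }
  expect_error(centroid_size(matrix(1, 10, 2)), "degenerate")
})

test_that("TPS round-trip and error handling", {
  set.seed(2)
  coords <- synthesize_landmarks(n_specimens = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(coords, dimnames(coords)[[3]], path)
  back <- read_tps(path)
  expect_equal(back$ids, dimnames(coords)[[3]])
  expect_equal(back$coords, coords, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=12", rep("0 0", 12), "ID=x"), bad)
  expect_error(read_tps(bad), "record 1")
  trunc <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=10", rep("0 0", 4)), trunc)
  expect_error(read_tps(trunc), "truncated")
})

test_that("SCALE= is honored multiplicatively", {
  path <- withr::local_tempfile(fileext = ".tps")
  shp <- default_head_shape()
  writeLines(c("LM=10", sprintf("%g %g", shp[, 1], shp[, 2]),
               "ID=a", "SCALE=0.5"), path)
  got <- read_tps(path)
  expect_equal(got$coords[, , 1], unname(shp) * 0.5,
               ignore_attr = TRUE)
})

test_that("GPA removes similarity transforms exactly", {
  set.seed(4)
  shp <- default_head_shape()
  arr <- array(NA_real_, c(10, 2, 2))
  arr[, , 1] <- shp
  arr[, , 2] <- similarity_transform(shp, angle = pi / 2, scale = 1,
                                     shift = c(3, -2))
  out <- gpa(arr)
  expect_lt(max(abs(out$aligned[, , 1] - out$aligned[, , 2])), 1e-10)
  expect_lt(procrustes_distance(arr[, , 1], arr[, , 2]), 1e-10)
})

test_that("GPA consensus of duplicated shape equals the centered/scaled shape", {
  shp <- default_head_shape()
  arr <- array(rep(shp, 4), c(10, 2, 4))
  out <- gpa(arr)
  ctr <- sweep(shp, 2, colMeans(shp))
  expect_equal(out$consensus, ctr / sqrt(sum(ctr^2)), tolerance = 1e-9)
})

test_that("GPA matches a brute-force alternating-Procrustes oracle", {
  # independent minimal implementation: iterate ordinary Procrustes fits
  gpa_oracle <- function(arr, iters = 200) {
    n <- dim(arr)[3]
    al <- arr
    for (j in 1:n) {
      c0 <- sweep(arr[, , j], 2, colMeans(arr[, , j]))
      al[, , j] <- c0 / sqrt(sum(c0^2))
    }
    cons <- al[, , 1]
    for (it in 1:iters) {
      for (j in 1:n) {
        sv <- svd(crossprod(al[, , j], cons))
        R <- sv$u %*% diag(c(1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$v)
        al[, , j] <- al[, , j] %*% R
      }
      cons <- apply(al, c(1, 2), mean)
      cons <- sweep(cons, 2, colMeans(cons))
      cons <- cons / sqrt(sum(cons^2))
    }
    sum(vapply(1:n, function(j) sum((al[, , j] - cons)^2), numeric(1)))
  }
  set.seed(5)
  arr <- array(NA_real_, c(10, 2, 3))
  for (j in 1:3) arr[, , j] <- random_shape()
  out <- gpa(arr)
  ss <- sum(vapply(1:3, function(j)
    sum((out$aligned[, , j] - out$consensus)^2), numeric(1)))
  expect_equal(ss, gpa_oracle(arr), tolerance = 1e-8)
})

test_that("GPA is invariant to similarity transforms of any input", {
  set.seed(6)
  arr <- synthesize_landmarks(n_specimens = 6, seed = 7)
  out1 <- gpa(arr)
  arr2 <- arr
  arr2[, , 3] <- similarity_transform(arr[, , 3])
  out2 <- gpa(arr2)
  expect_equal(out1$aligned, out2$aligned, tolerance = 1e-7)
})

test_that("procrustes_distance: zero on similarity copies, symmetric, matches rotation scan", {
  set.seed(8)
  a <- random_shape()
  expect_lt(procrustes_distance(a, similarity_transform(a)), 1e-10)
  b <- random_shape()
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-12)
  # brute-force scan over rotations at 1e-4 rad with optimal scale per angle
  za <- sweep(a, 2, colMeans(a)); za <- za / sqrt(sum(za^2))
  zb <- sweep(b, 2, colMeans(b)); zb <- zb / sqrt(sum(zb^2))
  best <- Inf
  for (th in seq(-pi, pi, by = 1e-4)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rb <- zb %*% R
    beta <- sum(rb * za)           # optimal scale given rotation
    best <- min(best, sum((za - beta * rb)^2))
  }
  expect_equal(procrustes_distance(a, b), sqrt(best), tolerance = 1e-6)
})

test_that("PCA of aligned shapes matches an SVD oracle and its invariants", {
  set.seed(9)
  arr <- synthesize_landmarks(n_specimens = 12, shape_noise_sd = 0.05, seed = 10)
  al <- gpa(arr)
  pc <- pca_shapes(al)
  expect_equal(sum(pc$proportions), 1, tolerance = 1e-9)
  expect_lte(sum(pc$eigenvalues > 1e-12 * pc$eigenvalues[1]), 16L)
  # SVD oracle on the centered flattened deviations
  flat <- t(apply(al$aligned, 3, function(m) as.numeric(m - al$consensus)))
  flat <- sweep(flat, 2, colMeans(flat))
  ev_oracle <- svd(flat)$d^2 / (nrow(flat) - 1)
  expect_equal(pc$eigenvalues, ev_oracle[seq_along(pc$eigenvalues)],
               tolerance = 1e-9)
  # total variance identity
  expect_equal(sum(pc$eigenvalues), sum(flat^2) / (nrow(flat) - 1),
               tolerance = 1e-9)
  # scores reproduce deviations through loadings
  expect_equal(pc$scores %*% t(pc$loadings), flat, tolerance = 1e-8)
})

test_that("species_mean_scores averages correctly and preserves the grand mean", {
  set.seed(11)
  arr <- synthesize_landmarks(n_specimens = 9, seed = 12)
  al <- gpa(arr)
  pc <- pca_shapes(al)
  species <- rep(c("s1", "s2", "s3"), each = 3)
  tm <- species_mean_scores(pc, species, n_components = 3)
  expect_equal(dim(tm), c(3L, 3L))
  for (sp in unique(species))
    expect_equal(tm[sp, ], colMeans(pc$scores[species == sp, 1:3]),
                 ignore_attr = TRUE)
  counts <- as.vector(table(species))
  expect_equal(colSums(tm * counts) / sum(counts),
               colMeans(pc$scores[, 1:3]), ignore_attr = TRUE)
  # one specimen per species = identity
  sp1 <- paste0("u", 1:9)
  tm1 <- species_mean_scores(pc, sp1, 2)
  expect_equal(unname(tm1[sp1, ]), unname(pc$scores[, 1:2]))
  expect_error(species_mean_scores(pc, species, 99), "exceeds")
})
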