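# Geometric morphometrics for 2-D landmark configurations (10 landmarks on
# the dorsal head view). Shapes are k x 2 matrices; sets of shapes are
# k x 2 x n arrays as in standard morphometrics packages.

N_LANDMARKS <- 10L

#' Read a TPS landmark file
#'
#' Parses records of the form `LM=10`, ten `x y` coordinate lines, an
#' optional `SCALE=` (applied multiplicatively) and an `ID=` line
#' (`IMAGE=` lines are ignored). Every record must have exactly 10
#' landmarks.
#'
#' @param path path to a TPS file.
#' @param species optional named character vector mapping specimen id to
#'   species name; unmapped specimens get species = id.
#' @return list with `coords` (10 x 2 x n array), `ids` (specimen ids) and
#'   `species`.
#' @export
read_tps <- function(path, species = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  recs <- list(); i <- 1L; rec_idx <- 0L
  while (i <= length(lines)) {
    rec_idx <- rec_idx + 1L
    m <- regmatches(lines[i], regexec("^LM\\s*=\\s*([0-9]+)$", lines[i]))[[1]]
    if (length(m) == 0L)
      stop(sprintf("TPS record %d: expected 'LM=' line, got '%s'", rec_idx, lines[i]),
           call. = FALSE)
    nlm <- as.integer(m[2])
    if (nlm != N_LANDMARKS)
      stop(sprintf("TPS record %d: LM=%d but exactly %d landmarks are required",
                   rec_idx, nlm, N_LANDMARKS), call. = FALSE)
    if (i + nlm > length(lines))
      stop(sprintf("TPS record %d: truncated (expected %d coordinate lines)",
                   rec_idx, nlm), call. = FALSE)
    coord_lines <- lines[(i + 1L):(i + nlm)]
    xy <- t(vapply(seq_along(coord_lines), function(j) {
      parts <- strsplit(coord_lines[j], "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(parts))
      if (length(v) != 2L || any(!is.finite(v)))
        stop(sprintf("TPS record %d, landmark %d: non-numeric coordinates '%s'",
                     rec_idx, j, coord_lines[j]), call. = FALSE)
      v
    }, numeric(2)))
    i <- i + nlm + 1L
    id <- sprintf("specimen_%d", rec_idx); scale <- 1
    while (i <= length(lines) && grepl("^(ID|SCALE|IMAGE)\\s*=", lines[i])) {
      kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (key == "ID") id <- val
      if (key == "SCALE") scale <- as.numeric(val)
      i <- i + 1L
    }
    recs[[rec_idx]] <- list(id = id, coords = xy * scale)
  }
  ids <- vapply(recs, `[[`, character(1), "id")
  coords <- array(NA_real_, c(N_LANDMARKS, 2L, length(recs)),
                  dimnames = list(NULL, c("x", "y"), ids))
  for (j in seq_along(recs)) coords[, , j] <- recs[[j]]$coords
  sp <- if (is.null(species)) ids else {
    out <- unname(species[ids]); out[is.na(out)] <- ids[is.na(out)]; out
  }
  list(coords = coords, ids = ids, species = sp)
}

#' Write landmark configurations to a TPS file
#'
#' @param coords 10 x 2 x n array.
#' @param ids specimen ids (one per configuration).
#' @param path output file path.
#' @export
write_tps <- function(coords, ids, path) {
  stopifnot(dim(coords)[1] == N_LANDMARKS, dim(coords)[2] == 2L,
            dim(coords)[3] == length(ids))
  con <- file(path, "w"); on.exit(close(con))
  for (j in seq_along(ids)) {
    writeLines(sprintf("LM=%d", N_LANDMARKS), con)
    writeLines(sprintf("%.10g %.10g", coords[, 1, j], coords[, 2, j]), con)
    writeLines(sprintf("ID=%s", ids[j]), con)
  }
  invisible(path)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the scale removed by Procrustes superimposition.
#'
#' @param config k x 2 coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  cfg <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(cfg^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincident",
                    call. = FALSE)
  cs
}

# internal: center a configuration and scale it to unit centroid size
center_scale <- function(config) {
  cfg <- sweep(config, 2L, colMeans(config))
  cfg / centroid_size(config)
}

# internal: proper rotation (det = +1) of b onto a, both pre-centered
optimal_rotation <- function(a, b) {
  sv <- svd(crossprod(b, a))
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes superimposition
#'
#' Full Procrustes: each configuration is centered, scaled to unit centroid
#' size and rotated (proper rotations only, no reflection) onto the running
#' consensus; the consensus is recomputed and the cycle repeats until the
#' consensus moves less than `tol`.
#'
#' @param coords 10 x 2 x n array of raw configurations (n >= 2).
#' @param tol convergence tolerance on the consensus coordinates.
#' @param max_iter iteration cap.
#' @return list with `consensus` (10 x 2, centered, unit size), `aligned`
#'   (10 x 2 x n), `centroid_sizes` and `iterations`.
#' @export
gpa <- function(coords, tol = 1e-10, max_iter = 100L) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  n <- dim(coords)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations", call. = FALSE)
  sizes <- apply(coords, 3L, centroid_size)
  aligned <- coords
  for (j in seq_len(n)) aligned[, , j] <- center_scale(coords[, , j])
  consensus <- aligned[, , 1L]
  for (it in seq_len(max_iter)) {
    for (j in seq_len(n))
      aligned[, , j] <- aligned[, , j] %*% optimal_rotation(consensus, aligned[, , j])
    new_cons <- center_scale(apply(aligned, c(1L, 2L), mean))
    delta <- max(abs(new_cons - consensus))
    consensus <- new_cons
    if (delta < tol) {
      return(list(consensus = consensus, aligned = aligned,
                  centroid_sizes = sizes, iterations = it))
    }
  }
  warning(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                  max_iter, delta))
  list(consensus = consensus, aligned = aligned, centroid_sizes = sizes,
       iterations = max_iter)
}

#' Full Procrustes distance between two configurations
#'
#' Root summed squared difference after optimal translation, unit-size
#' scaling and proper rotation with optimal rescaling of `b` onto `a`;
#' zero iff the shapes are identical up to a similarity transform.
#'
#' @param a,b k x 2 coordinate matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  za <- center_scale(a); zb <- center_scale(b)
  R <- optimal_rotation(za, zb)
  zr <- zb %*% R
  beta <- sum(zr * za)  # optimal scale of rotated b onto a
  sqrt(sum((za - beta * zr)^2))
}

#' Principal component analysis of aligned shapes
#'
#' Covariance PCA of the flattened aligned coordinates (deviations from the
#' consensus). Eigenvector signs are fixed so the largest-magnitude loading
#' of each component is positive.
#'
#' @param aligned result of [gpa()].
#' @return list with `eigenvalues`, `proportions`, `scores` (specimen x
#'   component) and `loadings` (coordinate x component).
#' @export
pca_shapes <- function(aligned) {
  n <- dim(aligned$aligned)[3]
  if (n < 3L) stop("PCA needs at least 3 specimens", call. = FALSE)
  flat <- t(apply(aligned$aligned, 3L, function(m) as.numeric(m - aligned$consensus)))
  flat <- sweep(flat, 2L, colMeans(flat))
  sv <- svd(flat)
  ev <- sv$d^2 / (n - 1)
  keep <- seq_len(min(n - 1L, ncol(flat)))
  ev <- ev[keep]
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- flat %*% loadings
  for (j in seq_along(keep)) {         # deterministic sign convention
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- dimnames(aligned$aligned)[[3]]
  colnames(scores) <- paste0("PC", seq_along(keep))
  colnames(loadings) <- colnames(scores)
  list(eigenvalues = ev, proportions = ev / sum(ev),
       scores = scores, loadings = loadings)
}

#' Species-mean PC scores
#'
#' Arithmetic mean of the first `n_components` specimen scores per species;
#' the trait table consumed by all comparative analyses.
#'
#' @param pc result of [pca_shapes()].
#' @param species character vector of species labels, one per specimen.
#' @param n_components number of leading components to retain (default 3).
#' @return species x component numeric matrix (rownames = species).
#' @export
species_mean_scores <- function(pc, species, n_components = 3L) {
  stopifnot(length(species) == nrow(pc$scores))
  if (n_components > ncol(pc$scores))
    stop("n_components exceeds available components", call. = FALSE)
  sc <- pc$scores[, seq_len(n_components), drop = FALSE]
  counts <- as.vector(table(species))  # rowsum and table share sorted order
  rowsum(sc, group = species) / counts
}
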