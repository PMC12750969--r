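#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances of all landmarks from their centroid. Invariant
#' to translation and rotation.
#'
#' @param coords landmarks x 3 numeric matrix, or a [landmark_config()].
#' @return positive scalar.
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_config")) coords <- coords$coords
  coords <- as.matrix(coords)
  cs <- sqrt(sum(scale(coords, scale = FALSE)^2))
  if (cs <= .Machine$double.eps * nrow(coords))
    stop("degenerate configuration: all landmarks coincident (size 0)")
  cs
}

center_config <- function(coords) {
  sweep(coords, 2L, colMeans(coords))
}

is_centered <- function(coords, tol = 1e-6) {
  sqrt(sum(colMeans(coords)^2)) < tol
}

#' Optimal rigid rotation of one configuration onto another
#'
#' Ordinary Procrustes rotation: finds the proper rotation (orthonormal,
#' determinant +1 — reflections are never allowed, vertebrae being chirally
#' consistent) minimizing the root summed squared coordinate difference
#' between `moving` and `target`. Both configurations must already be
#' centered; they are used at the size they are given.
#'
#' @param moving,target landmarks x 3 centered matrices.
#' @return list with `rotation` (3 x 3), `aligned` (= `moving %*% rotation`)
#'   and `residual` (root summed squared difference after rotation).
#' @export
optimal_align <- function(moving, target) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  if (!all(dim(moving) == dim(target)))
    stop("landmark count mismatch: ", nrow(moving), " vs ", nrow(target))
  if (!is_centered(moving) || !is_centered(target))
    stop("optimal_align requires centered configurations")
  s <- svd(crossprod(moving, target))
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- moving %*% rot
  list(rotation = rot, aligned = aligned,
       residual = sqrt(sum((aligned - target)^2)))
}

#' Procrustes distance between two superimposed shapes
#'
#' Root summed squared coordinate difference after optimally rotating `a`
#' onto `b`. Both inputs must be centered and of unit centroid size, so the
#' value is the (full) Procrustes shape distance: symmetric, zero iff the
#' shapes coincide up to rotation.
#'
#' @param a,b landmarks x 3 centered, unit-size matrices.
#' @param tol tolerance for the centering/size preconditions.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b, tol = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("landmark count mismatch: ", nrow(a), " vs ", nrow(b))
  for (m in list(a, b)) {
    if (!is_centered(m, tol)) stop("configurations must be centered")
    if (abs(sqrt(sum(m^2)) - 1) > tol)
      stop("configurations must have unit centroid size")
  }
  optimal_align(a, b)$residual
}

new_aligned_block <- function(aligned, consensus, centroid_sizes, position,
                              specimen_ids, species, iterations, converged) {
  dimnames(aligned) <- list(NULL, c("x", "y", "z"), specimen_ids)
  structure(
    list(aligned = aligned, consensus = consensus,
         centroid_sizes = stats::setNames(centroid_sizes, specimen_ids),
         position = position, specimen_ids = specimen_ids, species = species,
         iterations = iterations, converged = converged),
    class = "aligned_block")
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a set of equal-landmark configurations:
#' all are centered and scaled to unit centroid size, rotated to a working
#' consensus, and the consensus (mean shape, re-scaled to unit size) is
#' updated until its Frobenius-norm change falls below `tol`. Translation,
#' scale and orientation are thereby removed; original centroid sizes are
#' retained for later use (e.g. as a regression covariate). After
#' convergence every configuration is optimally rotated onto the final
#' consensus once more, and the stored consensus is the arithmetic mean of
#' those aligned configurations.
#'
#' @param x a [landmark_dataset()] at a single vertebral position, or a
#'   landmarks x 3 x specimens array.
#' @param tol convergence tolerance on the Frobenius change of the consensus
#'   between iterations.
#' @param max_iter maximum number of consensus updates; non-convergence is
#'   flagged (`converged = FALSE`), not an error.
#' @param tangent if `TRUE`, aligned shapes are additionally projected onto
#'   the tangent plane at the consensus (orthogonal projection). Off by
#'   default; downstream component analyses operate on aligned coordinates.
#' @return an object of class `aligned_block`: `aligned` (p x 3 x n, each
#'   centered at the origin with unit centroid size), `consensus` (p x 3),
#'   `centroid_sizes` (original units), `position`, `specimen_ids`,
#'   `species`, `iterations`, `converged`.
#' @export
generalized_procrustes <- function(x, tol = 1e-8, max_iter = 100L,
                                   tangent = FALSE) {
  if (inherits(x, "landmark_dataset")) {
    pos <- unique(positions(x))
    if (length(pos) > 1L)
      stop("dataset spans several positions (",
           paste(pos, collapse = ", "), "); superimpose one at a time")
    arr <- as_coord_array(x)
    ids <- specimen_ids(x)
    spp <- species_of(x)
    position <- pos
  } else {
    arr <- x
    if (length(dim(arr)) != 3L)
      stop("'x' must be a landmark_dataset or a p x 3 x n array")
    ids <- dimnames(arr)[[3]]
    if (is.null(ids)) ids <- sprintf("ind_%d", seq_len(dim(arr)[3]))
    spp <- ids
    position <- NA_character_
  }
  n <- dim(arr)[3]
  if (n < 2L) stop("need at least 2 configurations for superimposition")

  sizes <- numeric(n)
  for (i in seq_len(n)) {
    sizes[i] <- centroid_size(arr[, , i])
    arr[, , i] <- center_config(arr[, , i]) / sizes[i]
  }

  unit_mean <- function(a) {
    m <- apply(a, c(1, 2), mean)
    m <- center_config(m)
    m / sqrt(sum(m^2))
  }

  # initial reference: first specimen (result is invariant to this choice)
  consensus <- arr[, , 1]
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n))
      arr[, , i] <- optimal_align(arr[, , i], consensus)$aligned
    new_consensus <- unit_mean(arr)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    iterations <- it
    if (delta < tol) { converged <- TRUE; break }
  }

  for (i in seq_len(n))
    arr[, , i] <- optimal_align(arr[, , i], consensus)$aligned

  if (tangent) {
    cvec <- as.vector(consensus)
    cvec <- cvec / sqrt(sum(cvec^2))
    for (i in seq_len(n)) {
      v <- as.vector(arr[, , i])
      arr[, , i] <- array(cvec + (v - sum(v * cvec) * cvec), dim(consensus))
    }
  }

  consensus_out <- apply(arr, c(1, 2), mean)
  new_aligned_block(arr, consensus_out, sizes, position, ids, spp,
                    iterations, converged)
}

#' @export
print.aligned_block <- function(x, ...) {
  cat("aligned_block", if (!is.na(x$position)) paste0("[", x$position, "]"),
      ": ", dim(x$aligned)[3], " configurations x ", dim(x$aligned)[1],
      " landmarks; GPA ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Species mean shapes from an aligned block
#'
#' Averages the Procrustes-aligned coordinates of conspecific specimens so
#' downstream (especially phylogenetic) analyses see one point per species.
#' Averaging is only meaningful after superimposition; raw configurations
#' would conflate orientation with shape. Centroid sizes are averaged on the
#' same grouping. Single-specimen species pass through unchanged.
#'
#' @param block an `aligned_block`.
#' @param species_map optional named character vector mapping specimen id to
#'   species; defaults to the species recorded in the block.
#' @return an `aligned_block` with one configuration per species (species
#'   names as specimen ids).
#' @export
species_mean_shapes <- function(block, species_map = NULL) {
  stopifnot(inherits(block, "aligned_block"))
  if (is.null(species_map))
    species_map <- stats::setNames(block$species, block$specimen_ids)
  missing <- setdiff(block$specimen_ids, names(species_map))
  if (length(missing))
    stop("specimen(s) missing from species_map: ",
         paste(missing, collapse = ", "))
  spp <- unname(species_map[block$specimen_ids])
  usp <- unique(spp)
  p <- dim(block$aligned)[1]
  out <- array(NA_real_, c(p, 3L, length(usp)))
  cs <- numeric(length(usp))
  for (i in seq_along(usp)) {
    sel <- which(spp == usp[i])
    out[, , i] <- if (length(sel) == 1L) block$aligned[, , sel]
                  else apply(block$aligned[, , sel, drop = FALSE],
                             c(1, 2), mean)
    cs[i] <- mean(block$centroid_sizes[sel])
  }
  new_aligned_block(out, apply(out, c(1, 2), mean), cs, block$position,
                    usp, usp, block$iterations, block$converged)
}
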