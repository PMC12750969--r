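vectorize_block <- function(block) {
  arr <- block$aligned
  n <- dim(arr)[3]
  X <- t(vapply(seq_len(n), function(i) as.vector(arr[, , i]),
                numeric(dim(arr)[1] * 3L)))
  rownames(X) <- block$specimen_ids
  X
}

# Covariance-matrix PCA via SVD of the centered data matrix (divisor n - 1).
# Deterministic sign: each eigenvector's largest-magnitude loading is positive.
pca_core <- function(X, k = NULL) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (is.null(k)) k <- min(n - 1L, ncol(X))
  s <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(X)))
  k <- min(k, ncol(s$v))
  V <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  ev <- (s$d[seq_len(k)]^2) / (n - 1L)
  tot <- sum(Xc^2) / (n - 1L)
  list(mean = mu, vectors = V, values = ev,
       scores = Xc %*% V,
       variance_fraction = if (tot > 0) ev / tot else rep(0, k),
       total_variance = tot)
}

#' Principal component analysis of an aligned shape block
#'
#' Eigen-decomposition of the covariance matrix (divisor n - 1) of the
#' vectorized Procrustes-aligned coordinates. With p landmarks the shape
#' vectors have 3p entries; `min(n - 1, 3p)` components are retained, which
#' captures all non-zero variance.
#'
#' @param block an `aligned_block` with at least 3 specimens.
#' @return an object of class `shape_space`: `mean_vector`, `eigenvectors`
#'   (3p x k, orthonormal), `eigenvalues` (descending), `scores` (n x k),
#'   `variance_fraction` (sums to 1), plus the block `consensus` and
#'   `position` for projecting external configurations.
#' @export
fit_pca <- function(block) {
  stopifnot(inherits(block, "aligned_block"))
  n <- dim(block$aligned)[3]
  if (n < 3L) stop("PCA needs at least 3 specimens, got ", n)
  X <- vectorize_block(block)
  f <- pca_core(X)
  structure(
    list(mean_vector = f$mean, eigenvectors = f$vectors,
         eigenvalues = f$values, scores = f$scores,
         variance_fraction = f$variance_fraction,
         total_variance = f$total_variance,
         consensus = block$consensus, position = block$position,
         specimen_ids = block$specimen_ids, n_landmarks = dim(block$aligned)[1]),
    class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("shape_space", if (!is.na(x$position)) paste0("[", x$position, "]"),
      ": ", nrow(x$scores), " specimens, ", length(x$eigenvalues),
      " components\n  leading variance fractions: ",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Project an aligned configuration into a shape space
#'
#' Computes `(vec(config) - mean) %*% eigenvectors`. The configuration must
#' be superimposed consistently with the training data: centered, unit
#' centroid size and (with `align = TRUE`, the default for external
#' material) optimally rotated onto the space's consensus. With
#' `align = FALSE` an unaligned input is an error.
#'
#' @param space a `shape_space`.
#' @param config landmarks x 3 matrix or [landmark_config()].
#' @param align center, rescale and rotate onto the consensus first.
#' @param tol precondition tolerance when `align = FALSE`.
#' @return numeric score vector of length k.
#' @export
project_shape <- function(space, config, align = FALSE, tol = 1e-6) {
  if (inherits(config, "landmark_config")) config <- config$coords
  config <- as.matrix(config)
  if (nrow(config) != space$n_landmarks)
    stop("configuration has ", nrow(config), " landmarks; space expects ",
         space$n_landmarks)
  if (align) {
    config <- center_config(config) / centroid_size(config)
    config <- optimal_align(config, center_config(space$consensus))$aligned
    # restore the consensus centroid (zero for GPA output, kept for safety)
    config <- sweep(config, 2L, colMeans(space$consensus), `+`)
  } else {
    if (!is_centered(config, tol) || abs(sqrt(sum(config^2)) - 1) > tol)
      stop("configuration is not superimposed (centered, unit size); ",
           "use align = TRUE for external material")
  }
  drop((as.vector(config) - space$mean_vector) %*% space$eigenvectors)
}

#' Reconstruct coordinates from principal component scores
#'
#' Inverse of [project_shape()]: `mean + eigenvectors %*% scores`, reshaped
#' to a landmarks x 3 matrix. Exact when all components are supplied.
#'
#' @param space a `shape_space`.
#' @param scores numeric vector of length at most k.
#' @return landmarks x 3 matrix.
#' @export
reconstruct_shape <- function(space, scores) {
  k <- length(scores)
  v <- space$mean_vector +
    drop(space$eigenvectors[, seq_len(k), drop = FALSE] %*% scores)
  matrix(v, ncol = 3L)
}

#' Combine several aligned vertebral blocks into one shape space
#'
#' Multi-element ("consensus") analysis of serially homologous vertebrae:
#' each element is superimposed separately, vectorized, column-centered and
#' (by default) scaled so its total variance is 1, preventing landmark-rich
#' or high-variance elements from dominating; the scaled matrices are
#' concatenated column-wise and a single PCA is run on the concatenation.
#' Only specimens present in every block are retained.
#'
#' @param blocks list of `aligned_block` objects (>= 1; >= 2 for a true
#'   multi-element analysis).
#' @param scale_blocks scale each block to unit total variance before
#'   concatenation (default `TRUE`); with one block and `scale_blocks =
#'   FALSE` the result reproduces [fit_pca()] of that block.
#' @return an object of class `multiblock_space`: combined `eigenvectors`,
#'   `eigenvalues`, `scores`, `variance_fraction` over the concatenated
#'   matrix, plus per-block metadata (`position`, column means, scale
#'   factor, consensus) needed to project external material.
#' @export
combine_blocks <- function(blocks, scale_blocks = TRUE) {
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1), "aligned_block")))
  ids <- Reduce(intersect, lapply(blocks, `[[`, "specimen_ids"))
  if (!length(ids))
    stop("no specimen is present in every block")
  parts <- vector("list", length(blocks))
  meta <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    X <- vectorize_block(blk)[ids, , drop = FALSE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    scl <- 1
    if (scale_blocks) {
      tot <- sum(Xc^2) / (nrow(Xc) - 1L)
      if (tot <= 0) stop("block ", b, " has zero variance; cannot scale")
      scl <- 1 / sqrt(tot)
      Xc <- Xc * scl
    }
    parts[[b]] <- Xc
    meta[[b]] <- list(position = blk$position, center = mu, scale = scl,
                      consensus = blk$consensus,
                      n_landmarks = dim(blk$aligned)[1])
  }
  X <- do.call(cbind, parts)
  f <- pca_core(X)
  structure(
    list(eigenvectors = f$vectors, eigenvalues = f$values,
         scores = f$scores, variance_fraction = f$variance_fraction,
         total_variance = f$total_variance,
         specimen_ids = ids, block_meta = meta,
         scale_blocks = scale_blocks),
    class = "multiblock_space")
}

#' @export
print.multiblock_space <- function(x, ...) {
  cat("multiblock_space: ", length(x$block_meta), " blocks (",
      paste(vapply(x$block_meta, `[[`, character(1), "position"),
            collapse = ", "),
      "), ", length(x$specimen_ids), " shared specimens\n",
      "  PC1+PC2 variance fraction: ",
      sprintf("%.4f", sum(x$variance_fraction[1:min(2, length(
        x$variance_fraction))])), "\n", sep = "")
  invisible(x)
}

#' Project external configurations into a multi-block space
#'
#' Each supplied configuration is aligned to its block's consensus,
#' vectorized, centered and scaled with the training block parameters; the
#' pieces are concatenated and multiplied by the combined eigenvectors.
#' All training blocks must be represented.
#'
#' @param mbs a `multiblock_space`.
#' @param configs named list (names = block positions) of landmarks x 3
#'   matrices or [landmark_config()] objects.
#' @return combined-space score vector.
#' @export
project_blocks <- function(mbs, configs) {
  stopifnot(inherits(mbs, "multiblock_space"))
  pieces <- vector("list", length(mbs$block_meta))
  for (b in seq_along(mbs$block_meta)) {
    m <- mbs$block_meta[[b]]
    cfg <- configs[[m$position]]
    if (is.null(cfg))
      stop("no configuration supplied for block position '", m$position, "'")
    if (inherits(cfg, "landmark_config")) cfg <- cfg$coords
    cfg <- as.matrix(cfg)
    if (nrow(cfg) != m$n_landmarks)
      stop("block '", m$position, "': configuration has ", nrow(cfg),
           " landmarks, expected ", m$n_landmarks)
    cfg <- center_config(cfg) / centroid_size(cfg)
    cfg <- optimal_align(cfg, center_config(m$consensus))$aligned
    cfg <- sweep(cfg, 2L, colMeans(m$consensus), `+`)
    pieces[[b]] <- (as.vector(cfg) - m$center) * m$scale
  }
  drop(matrix(unlist(pieces), nrow = 1L) %*% mbs$eigenvectors)
}
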