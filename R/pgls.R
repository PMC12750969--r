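#' Read a Newick phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces what the downstream
#' Brownian-motion machinery needs: branch lengths on every edge and unique
#' tip labels. Polytomies are allowed.
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths; Brownian covariance is undefined")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Prune a phylogeny to a species set
#'
#' @param tree an `ape::phylo`.
#' @param species tip labels to keep.
#' @return the pruned tree.
#' @export
prune_tree <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, species)
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion the expected trait covariance of two tips equals
#' the shared branch length from the root to their most recent common
#' ancestor; the diagonal holds root-to-tip depths. Rows/columns are
#' returned in the requested species order.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param order species order for the rows/columns; defaults to the tree's
#'   tip order.
#' @return symmetric positive semi-definite matrix with dimnames.
#' @export
bm_covariance <- function(tree, order = tree$tip.label) {
  missing <- setdiff(order, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  C <- ape::vcv(tree)
  C[order, order, drop = FALSE]
}

matrix_inv_sqrt <- function(C, jitter = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  tolv <- max(e$values) * 1e-12
  if (min(e$values) < tolv) {
    # documented jitter: ridge of jitter * mean(diag) for near-singular C
    C <- C + diag(jitter * mean(diag(C)), nrow(C))
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) <= 0)
      stop("phylogenetic covariance matrix is singular beyond jitter")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Multivariate phylogenetic generalized least squares with RRPP
#'
#' Regresses a multivariate shape matrix on one predictor under a
#' Brownian-motion residual covariance. Both response and design are
#' transformed by the inverse square root of the (unit-determinant-scaled)
#' covariance matrix; effect and total sums of squares are computed in the
#' transformed space, so `r_squared = SS_effect / SS_total`. Significance
#' comes from the residual randomization permutation procedure (RRPP):
#' reduced-model (intercept-only) residuals are randomly re-assigned to
#' fitted values and the pseudo-F refitted.
#'
#' Categorical predictors are expanded to full-rank indicator contrasts and
#' tested as one overall effect. Scaling `C` to unit determinant changes
#' neither `r_squared` nor `p`; it only stabilizes the inversion.
#'
#' @param Y species x variables numeric matrix (rownames = species).
#' @param X predictor: factor/character (categorical) or numeric vector,
#'   in the row order of `Y` (or named by species).
#' @param C phylogenetic covariance matrix with dimnames covering `Y`'s
#'   species (see [bm_covariance()]).
#' @param n_perm number of RRPP permutations.
#' @param seed integer seed for the permutation stream.
#' @param predictor label stored in the result.
#' @return object of class `pgls_result`: `predictor`, `r_squared`, `F`,
#'   `p_value`, `df`, `n_permutations`, `seed`.
#' @export
pgls_fit <- function(Y, X, C, n_perm = 999L, seed = NULL,
                     predictor = deparse(substitute(X))) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(rownames(Y)))
    stop("Y must have species rownames matching C's dimnames")
  if (!all(rownames(Y) %in% rownames(C)))
    stop("species missing from C: ",
         paste(setdiff(rownames(Y), rownames(C)), collapse = ", "))
  C <- C[rownames(Y), rownames(Y)]
  if (!is.null(names(X))) X <- X[rownames(Y)]
  if (length(X) != n) stop("length(X) != nrow(Y)")

  if (is.character(X)) X <- factor(X)
  if (is.factor(X)) {
    X <- droplevels(X)
    if (nlevels(X) < 2L) stop("predictor is constant")
    design <- stats::model.matrix(~X)
  } else {
    if (stats::var(X) == 0) stop("predictor is constant")
    design <- cbind(1, as.numeric(X))
  }

  # scale to unit determinant (numerical stability; invariant for R^2, F, p)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0)
    C <- C + diag(1e-8 * mean(diag(C)), n)
  ldet <- sum(log(eigen(C, symmetric = TRUE, only.values = TRUE)$values))
  C <- C / exp(ldet / n)
  Tm <- matrix_inv_sqrt(C)

  Yt <- Tm %*% Y
  Xf <- Tm %*% design
  Xr <- Tm %*% matrix(1, n, 1)

  hat <- function(Z) {
    q <- qr(Z)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  Hf <- hat(Xf); Hr <- hat(Xr)
  rank_f <- qr(Xf)$rank; rank_r <- 1L
  df_eff <- rank_f - rank_r
  df_res <- n - rank_f
  if (df_eff < 1L || df_res < 1L) stop("degenerate design (check group sizes)")

  fitted_r <- Hr %*% Yt
  resid_r <- Yt - fitted_r
  P_eff <- Hf - Hr
  Ires <- diag(n) - Hf

  ss_stat <- function(Ym) {
    ss_eff <- sum((P_eff %*% Ym)^2)
    ss_res <- sum((Ires %*% Ym)^2)
    c(eff = ss_eff, res = ss_res)
  }
  obs <- ss_stat(Yt)
  ss_total <- obs[["eff"]] + obs[["res"]]
  f_obs <- (obs[["eff"]] / df_eff) / (obs[["res"]] / df_res)
  r2 <- obs[["eff"]] / ss_total

  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    Yp <- fitted_r + resid_r[sample.int(n), , drop = FALSE]
    s <- ss_stat(Yp)
    fp <- (s[["eff"]] / df_eff) / (s[["res"]] / df_res)
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  # n_perm = 0 requests the effect size only (no test)
  p_value <- if (n_perm > 0L) (1 + exceed) / (1 + n_perm) else NA_real_
  structure(
    list(predictor = predictor, r_squared = unname(r2), F = unname(f_obs),
         p_value = p_value,
         df = c(effect = df_eff, residual = df_res),
         n_permutations = as.integer(n_perm),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "PGLS [%s]: R^2 = %.4f, F(%d, %d) = %.4f, p = %.4g (%d permutations)\n",
    x$predictor, x$r_squared, x$df[["effect"]], x$df[["residual"]], x$F,
    x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
as.data.frame.pgls_result <- function(x, ...) {
  data.frame(predictor = x$predictor, r_squared = x$r_squared, F = x$F,
             p_value = x$p_value, n_permutations = x$n_permutations,
             seed = x$seed, stringsAsFactors = FALSE)
}
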