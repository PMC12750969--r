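#' PERMANOVA pseudo-F statistic
#'
#' Distance-based one-way pseudo-F comparing among-group to within-group
#' variation:
#' `F = (SS_between / (g - 1)) / (SS_within / (N - g))` with
#' `SS_total = (1/N) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`,
#' `SS_between = SS_total - SS_within`.
#'
#' @param dist an N x N symmetric distance matrix (or `dist` object) with
#'   zero diagonal.
#' @param groups vector of group labels, length N; at least 2 groups with at
#'   least 2 members each.
#' @return nonnegative scalar.
#' @export
pseudo_f <- function(dist, groups) {
  D2 <- as.matrix(dist)^2
  groups <- as.factor(groups)
  check_permanova_groups(D2, groups)
  ss <- permanova_ss(D2, groups)
  g <- nlevels(groups); n <- nrow(D2)
  (ss$between / (g - 1)) / (ss$within / (n - g))
}

check_permanova_groups <- function(D2, groups) {
  if (nrow(D2) != ncol(D2) || max(abs(D2 - t(D2))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(D2)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  if (length(groups) != nrow(D2))
    stop("length(groups) != nrow(dist)")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  invisible(TRUE)
}

permanova_ss <- function(D2, groups) {
  n <- nrow(D2)
  total <- sum(D2[upper.tri(D2)]) / n
  U <- stats::model.matrix(~ groups - 1)
  ng <- colSums(U)
  within <- sum(colSums((D2 %*% U) * U) / (2 * ng))
  list(total = total, within = within, between = total - within)
}

permanova_f_from_ss <- function(D2, groups) {
  ss <- permanova_ss(D2, groups)
  g <- nlevels(groups); n <- nrow(D2)
  (ss$between / (g - 1)) / (ss$within / (n - g))
}

resolve_permanova_input <- function(x, distance = c("euclidean",
                                                    "procrustes")) {
  distance <- match.arg(distance)
  if (inherits(x, "dist")) return(as.matrix(x))
  if (inherits(x, "aligned_block")) {
    if (distance == "procrustes") {
      n <- dim(x$aligned)[3]
      D <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        D[i, j] <- D[j, i] <- optimal_align(x$aligned[, , i],
                                            x$aligned[, , j])$residual
      return(D)
    }
    x <- vectorize_block(x)
  }
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-8 &&
      all(abs(diag(x)) < 1e-12))
    return(x)  # already a distance matrix
  as.matrix(stats::dist(x))
}

#' Permutational multivariate analysis of variance
#'
#' Tests group separation in a distance matrix by comparing the observed
#' [pseudo_f()] to its distribution under random relabelling of
#' observations. `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`. By default distances are
#' Euclidean on the supplied coordinates/scores (the tangent-space
#' approximation of Procrustes distance); `distance = "procrustes"` uses the
#' exact Procrustes distance on an `aligned_block` input.
#'
#' @param x an observations x variables matrix (scores or vectorized aligned
#'   shapes), a `dist`/distance matrix, or an `aligned_block`.
#' @param groups group labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed making the permutation p-value reproducible.
#' @param distance `"euclidean"` or `"procrustes"`.
#' @param comparison label stored in the result (default "global").
#' @return object of class `permanova_result` with fields `comparison`,
#'   `pseudo_f`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(x, groups, n_perm = 999L, seed = NULL,
                      distance = c("euclidean", "procrustes"),
                      comparison = "global") {
  if (n_perm < 99L)
    stop("n_perm = ", n_perm, " is below the minimum of 99")
  D <- resolve_permanova_input(x, distance)
  D2 <- D^2
  groups <- droplevels(as.factor(groups))
  check_permanova_groups(D2, groups)
  n <- nrow(D2)
  g <- nlevels(groups)
  total <- sum(D2[upper.tri(D2)]) / n
  U <- stats::model.matrix(~ groups - 1)
  ng <- colSums(U)
  f_stat <- function(U) {
    within <- sum(colSums((D2 %*% U) * U) / (2 * ng))
    ((total - within) / (g - 1)) / (within / (n - g))
  }
  f_obs <- f_stat(U)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(U[sample.int(n), , drop = FALSE]) >= f_obs)
      exceed <- exceed + 1L
  }
  structure(
    list(comparison = comparison, pseudo_f = f_obs,
         p_value = (1 + exceed) / (1 + n_perm),
         n_permutations = as.integer(n_perm),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s]: F = %.4f, p = %.4g (%d permutations)\n",
              x$comparison, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
as.data.frame.permanova_result <- function(x, ...) {
  data.frame(comparison = x$comparison, pseudo_f = x$pseudo_f,
             p_value = x$p_value, n_permutations = x$n_permutations,
             seed = x$seed, stringsAsFactors = FALSE)
}

#' Pairwise PERMANOVA over all level pairs
#'
#' Runs [permanova()] on the observation subset of every unordered pair of
#' group levels, ordered lexicographically. Each pair uses its own
#' permutation stream with seed `seed + pair index` (so results do not
#' depend on which other levels are present). Raw p-values are reported; a
#' Bonferroni-adjusted column is appended for convenience but no threshold
#' is applied.
#'
#' @inheritParams permanova
#' @return data.frame with one row per level pair: `comparison`, `pseudo_f`,
#'   `p_value`, `p_adjusted`, `n_permutations`, `seed`.
#' @export
pairwise_permanova <- function(x, groups, n_perm = 999L, seed = NULL,
                               distance = c("euclidean", "procrustes")) {
  distance <- match.arg(distance)
  D <- resolve_permanova_input(x, distance)
  groups <- droplevels(as.factor(groups))
  lv <- sort(levels(groups))
  if (length(lv) < 2L) stop("need at least 2 group levels")
  pairs <- utils::combn(lv, 2L)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    sel <- groups %in% c(a, b)
    res <- permanova(D[sel, sel, drop = FALSE], groups[sel],
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + i,
                     comparison = paste(a, "vs", b))
    rows[[i]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out[c("comparison", "pseudo_f", "p_value", "p_adjusted",
        "n_permutations", "seed")]
}
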