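#' Number of principal components to retain for classification
#'
#' Default retention rule: the smallest k whose cumulative variance fraction
#' reaches `threshold`, capped at `N - g - 1` so the pooled within-group
#' covariance stays invertible (and at the number of available components).
#'
#' @param space a `shape_space` or `multiblock_space`.
#' @param groups group labels of the training specimens.
#' @param threshold cumulative variance fraction to reach (default 0.95).
#' @return integer k >= 1.
#' @export
retain_pcs <- function(space, groups, threshold = 0.95) {
  groups <- droplevels(as.factor(groups))
  n <- nrow(space$scores)
  g <- nlevels(groups)
  cap <- max(1L, min(n - g - 1L, length(space$eigenvalues)))
  cum <- cumsum(space$variance_fraction)
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(cum)
  min(as.integer(k), cap)
}

#' Canonical variate analysis of PC scores
#'
#' Solves the between-/within-group generalized eigenproblem on the first
#' `k` principal component scores: canonical vectors `A` maximize
#' between-group relative to pooled within-group variance and are scaled so
#' that `t(A) %*% W %*% A = I` — training scores are whitened within groups,
#' making Euclidean distance in canonical space equal to Mahalanobis
#' distance in the retained-PC space (restricted to the discriminant
#' subspace). At most `min(k, g - 1)` canonical axes exist.
#'
#' @param scores observations x components numeric matrix (PC scores).
#' @param groups group labels; >= 2 groups with >= 2 members each.
#' @param k number of leading columns of `scores` to use (default: all).
#'   Must satisfy `k <= N - g` or the within-group covariance is singular.
#' @param r number of canonical axes to keep (default `min(k, g - 1)`).
#' @return object of class `cva_model`: `canonical_vectors` (k x r),
#'   `group_means_cv` (g x r), `group_labels`, `pooled_within_cov`,
#'   `grand_mean`, `cv_scores` (training canonical scores), `groups`, `k`,
#'   `r`, `eigenvalues` (canonical roots).
#' @export
fit_cva <- function(scores, groups, k = ncol(scores), r = NULL) {
  scores <- as.matrix(scores)
  groups <- droplevels(as.factor(groups))
  n <- nrow(scores)
  g <- nlevels(groups)
  tab <- table(groups)
  if (g < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  k <- as.integer(k)
  if (k < 1L || k > ncol(scores)) stop("invalid k = ", k)
  X <- scores[, seq_len(k), drop = FALSE]

  grand <- colMeans(X)
  means <- rowsum(X, groups) / as.vector(tab)
  Wss <- crossprod(X - means[groups, , drop = FALSE])
  W <- Wss / (n - g)
  dm <- sweep(means, 2L, grand)
  B <- crossprod(dm * sqrt(as.vector(tab))) / (g - 1)

  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-10 || min(ew$values) <= 0)
    stop("pooled within-group covariance is singular; ",
         "lower k (need k <= N - g = ", n - g, ")")
  Wih <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  M <- Wih %*% B %*% Wih
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  r_max <- min(k, g - 1L)
  if (is.null(r)) r <- r_max
  r <- min(as.integer(r), r_max)
  A <- Wih %*% em$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  cv <- sweep(X, 2L, grand) %*% A
  means_cv <- rowsum(cv, groups) / as.vector(tab)
  structure(
    list(canonical_vectors = A, group_means_cv = means_cv,
         group_labels = levels(groups), pooled_within_cov = W,
         grand_mean = grand, cv_scores = cv, groups = groups,
         k = k, r = r, eigenvalues = em$values[seq_len(r)]),
    class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat("cva_model: ", length(x$group_labels), " groups (",
      paste(x$group_labels, collapse = ", "), "), k = ", x$k,
      " PCs, r = ", x$r, " canonical axes\n", sep = "")
  invisible(x)
}

assign_nearest <- function(model, cv) {
  cv <- matrix(cv, ncol = ncol(model$group_means_cv))
  d2 <- vapply(seq_len(nrow(model$group_means_cv)), function(gi) {
    rowSums(sweep(cv, 2L, model$group_means_cv[gi, ])^2)
  }, numeric(nrow(cv)))
  d2 <- matrix(d2, nrow = nrow(cv))
  colnames(d2) <- model$group_labels
  list(d2 = d2,
       label = model$group_labels[apply(d2, 1L, which.min)])
}

#' Classification accuracy of a CVA model
#'
#' Assigns each specimen to the group whose canonical-space mean is nearest
#' (Euclidean in canonical space = Mahalanobis in PC space).
#' `mode = "resubstitution"` scores the training data against the fitted
#' model; `mode = "leave-one-out"` refits the model without each specimen
#' before classifying it.
#'
#' @param model a `cva_model` (its training scores/groups are used; supply
#'   `scores`/`groups` to score other data by resubstitution).
#' @param scores,groups optional replacement data.
#' @param mode `"resubstitution"` or `"leave-one-out"`.
#' @return object of class `classification_report`: `confusion` (g x g,
#'   rows = true), `accuracy`, `mode`, `predicted`.
#' @export
classify <- function(model, scores = NULL, groups = NULL,
                     mode = c("resubstitution", "leave-one-out")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "cva_model"))
  if (mode == "leave-one-out") {
    if (!is.null(scores))
      stop("leave-one-out operates on the model's training data")
    X <- model$full_scores
    if (is.null(X))
      stop("leave-one-out needs the model's full PC scores; ",
           "fit the model with cva_from_space()")
    grp <- model$groups
    n <- length(grp)
    pred <- character(n)
    g <- nlevels(model$groups)
    for (i in seq_len(n)) {
      k_i <- min(model$k, (n - 1L) - g - 1L)
      m_i <- fit_cva(X[-i, , drop = FALSE], grp[-i], k = max(1L, k_i))
      cv_i <- drop(sweep(X[i, seq_len(m_i$k), drop = FALSE], 2L,
                         m_i$grand_mean) %*% m_i$canonical_vectors)
      pred[i] <- assign_nearest(m_i, cv_i)$label
    }
    truth <- as.character(grp)
  } else {
    if (is.null(scores)) {
      cv <- model$cv_scores
      truth <- as.character(model$groups)
    } else {
      scores <- as.matrix(scores)[, seq_len(model$k), drop = FALSE]
      cv <- sweep(scores, 2L, model$grand_mean) %*% model$canonical_vectors
      truth <- as.character(groups)
    }
    pred <- assign_nearest(model, cv)$label
  }
  lev <- model$group_labels
  confusion <- table(factor(truth, lev), factor(pred, lev))
  structure(
    list(confusion = confusion,
         accuracy = sum(diag(confusion)) / sum(confusion),
         mode = mode, predicted = pred),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report (%s): accuracy %.4f (%d/%d)\n",
              x$mode, x$accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Fit a CVA on a shape space's scores
#'
#' Convenience wrapper: picks `k` with [retain_pcs()] (unless given), fits
#' [fit_cva()] on the space's PC scores and stores the full score matrix so
#' leave-one-out classification and external projection work directly.
#'
#' @param space a `shape_space` or `multiblock_space`.
#' @param groups group labels in the order of the space's specimens.
#' @param k PCs to retain; default [retain_pcs()] at `threshold`.
#' @param threshold cumulative variance threshold for the default `k`.
#' @return a `cva_model` carrying `full_scores` and the `space` reference.
#' @export
cva_from_space <- function(space, groups, k = NULL, threshold = 0.95) {
  if (is.null(k)) k <- retain_pcs(space, groups, threshold)
  model <- fit_cva(space$scores, groups, k = k)
  model$full_scores <- space$scores
  model$space <- space
  model
}

#' Project an external (e.g. fossil) configuration into a CVA space
#'
#' The configuration is centered, scaled to unit centroid size, optimally
#' rotated onto the extant consensus, projected onto the retained principal
#' components and mapped by the canonical vectors. It must not be part of
#' the training data.
#'
#' @param model a `cva_model` fitted via [cva_from_space()].
#' @param fossil landmarks x 3 matrix or [landmark_config()] (single-block
#'   spaces), or a named list of configurations by position (multi-block).
#' @param space the `shape_space`/`multiblock_space` the model was fitted
#'   on; defaults to the one stored in the model.
#' @return canonical score vector of length r.
#' @export
project_external <- function(model, fossil, space = model$space) {
  stopifnot(inherits(model, "cva_model"))
  if (is.null(space))
    stop("no shape space available; fit the model with cva_from_space()")
  pc <- if (inherits(space, "multiblock_space")) {
    if (!is.list(fossil) || inherits(fossil, "landmark_config"))
      stop("multi-block projection needs a named list of configurations")
    project_blocks(space, fossil)
  } else {
    project_shape(space, fossil, align = TRUE)
  }
  drop((pc[seq_len(model$k)] - model$grand_mean) %*% model$canonical_vectors)
}

#' Mahalanobis membership probabilities
#'
#' For a point in canonical space, the squared Euclidean distance `d2_g` to
#' each group mean is the Mahalanobis distance in the retained-PC space.
#' Membership is reported two ways: a softmax posterior over groups with
#' equal priors, `p_g = exp(-d2_g/2) / sum_h exp(-d2_h/2)` (sums to 1,
#' invariant to adding a constant to all d2), and the chi-square typicality
#' `1 - pchisq(d2_g, df = r)` of each group taken alone.
#'
#' @param model a `cva_model`.
#' @param cv_scores canonical score vector (see [project_external()]).
#' @param specimen_id,position,category_set metadata recorded in the result.
#' @return object of class `fossil_prediction`: `mahalanobis_d2`,
#'   `probability` (posterior), `typicality`, `predicted` (argmax posterior
#'   = minimal d2), `strong_support` flag at the 0.95 reporting convention.
#' @export
membership_probabilities <- function(model, cv_scores,
                                     specimen_id = NA_character_,
                                     position = NA_character_,
                                     category_set = NA_character_) {
  stopifnot(inherits(model, "cva_model"))
  nn <- assign_nearest(model, matrix(cv_scores, nrow = 1L))
  d2 <- drop(nn$d2)
  w <- exp(-(d2 - min(d2)) / 2)  # shift-invariant softmax
  post <- w / sum(w)
  typ <- 1 - stats::pchisq(d2, df = model$r)
  structure(
    list(specimen_id = specimen_id, position = position,
         category_set = category_set,
         mahalanobis_d2 = d2, probability = post, typicality = typ,
         predicted = nn$label,
         strong_support = max(post) > 0.95),
    class = "fossil_prediction")
}

#' @export
print.fossil_prediction <- function(x, ...) {
  cat(sprintf("fossil_prediction [%s %s]: %s (p = %.3f%s)\n",
              x$position, x$category_set, x$predicted, max(x$probability),
              if (x$strong_support) ", strong support" else ""))
  tab <- data.frame(group = names(x$probability),
                    mahalanobis_d2 = round(x$mahalanobis_d2, 4),
                    probability = round(x$probability, 4),
                    typicality = round(x$typicality, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fossil_prediction <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id, position = x$position,
             category_set = x$category_set,
             prediction = x$predicted,
             probability = max(x$probability),
             strong_support = x$strong_support,
             stringsAsFactors = FALSE)
}
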