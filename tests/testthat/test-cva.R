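test_that("well-separated clusters classify perfectly by resubstitution", {
  cl <- two_cluster_scores(n_per = 10, k = 3, sep = 10, seed = 81)
  model <- fit_cva(cl$scores, cl$groups)
  rep <- classify(model, mode = "resubstitution")
  expect_equal(rep$accuracy, 1.0)
  expect_equal(unname(rowSums(rep$confusion)), c(10, 10))
})

test_that("canonical scores are whitened within groups", {
  set.seed(82)
  X <- matrix(rnorm(60 * 5), 60)
  groups <- factor(rep(c("a", "b", "c"), each = 20))
  X[groups == "b", 1] <- X[groups == "b", 1] + 3
  X[groups == "c", 2] <- X[groups == "c", 2] + 3
  model <- fit_cva(X, groups)
  cv <- model$cv_scores
  n <- nrow(X); g <- 3
  means <- rowsum(cv, groups) / as.vector(table(groups))
  W_cv <- crossprod(cv - means[groups, , drop = FALSE]) / (n - g)
  expect_equal(W_cv, diag(model$r), tolerance = 1e-6)
})

test_that("canonical directions solve the generalized eigenproblem (oracle)", {
  set.seed(83)
  for (rep in 1:5) {
    n <- 18
    k <- sample(3:5, 1)
    groups <- factor(rep(c("a", "b", "c"), each = 6))
    X <- matrix(rnorm(n * k), n)
    X[groups == "b", 1] <- X[groups == "b", 1] + 2
    X[groups == "c", 2] <- X[groups == "c", 2] + 2
    model <- fit_cva(X, groups)

    # brute-force oracle: eigenvectors of solve(W) %*% B
    tab <- table(groups)
    means <- rowsum(X, groups) / as.vector(tab)
    W <- crossprod(X - means[groups, , drop = FALSE]) / (n - 3)
    grand <- colMeans(X)
    dm <- sweep(means, 2, grand)
    B <- crossprod(dm * sqrt(as.vector(tab))) / 2
    ev <- eigen(solve(W) %*% B)
    oracle <- Re(ev$vectors[, 1:2])
    expect_lt(max_subspace_angle(model$canonical_vectors, oracle), 1e-6)
  }
})

test_that("canonical subspace agrees with MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(84)
  X <- matrix(rnorm(30 * 4), 30)
  groups <- factor(rep(c("a", "b", "c"), each = 10))
  X[groups == "a", 1] <- X[groups == "a", 1] + 2.5
  X[groups == "c", 3] <- X[groups == "c", 3] - 2.5
  model <- fit_cva(X, groups)
  ld <- MASS::lda(X, groups)
  expect_lt(max_subspace_angle(model$canonical_vectors, ld$scaling), 1e-6)
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(85)
  X <- matrix(rnorm(60 * 4), 60)
  acc <- replicate(20, {
    groups <- factor(sample(rep(c("a", "b", "c"), each = 20)))
    classify(fit_cva(X, groups), mode = "resubstitution")$accuracy
  })
  # chance is 1/3; resubstitution overfits slightly upward
  expect_gt(mean(acc), 1 / 3 - 0.1)
  expect_lt(mean(acc), 1 / 3 + 0.2)
})

test_that("leave-one-out does not beat resubstitution on average", {
  set.seed(86)
  diff <- replicate(100, {
    groups <- factor(rep(c("a", "b"), each = 12))
    X <- matrix(rnorm(24 * 3), 24)
    X[groups == "b", 1] <- X[groups == "b", 1] + 1.5
    sp <- list(scores = X, eigenvalues = rep(1, 3),
               variance_fraction = rep(1 / 3, 3))
    model <- fit_cva(X, groups)
    model$full_scores <- X
    classify(model, mode = "resubstitution")$accuracy -
      classify(model, mode = "leave-one-out")$accuracy
  })
  expect_gte(mean(diff), 0)
})

test_that("external projection reproduces training canonical scores", {
  arr <- scattered_copies(base_vertebra_shape(), 12, noise = 0.03, seed = 87)
  blk <- generalized_procrustes(arr)
  sp <- fit_pca(blk)
  groups <- factor(rep(c("a", "b"), 6))
  model <- cva_from_space(sp, groups, k = 4)
  # a training specimen round-trips through the full projection path
  expect_equal(project_external(model, blk$aligned[, , 5]),
               drop(model$cv_scores[5, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the consensus projects to the zero PC vector, whose canonical image is
  # the canonical origin (PC scores are centered, so the grand mean is 0)
  pc0 <- project_shape(sp, sp$consensus, tol = 0.3)
  cv0 <- drop((pc0[seq_len(model$k)] - model$grand_mean) %*%
                model$canonical_vectors)
  expect_lt(max(abs(cv0)), 1e-9)
  expect_error(project_external(model, blk$aligned[1:10, , 3]), "landmarks")
})

test_that("membership probabilities are softmax posteriors with typicality", {
  cl <- two_cluster_scores(n_per = 8, k = 2, sep = 6, seed = 88)
  model <- fit_cva(cl$scores, cl$groups)
  # point exactly at group 'a' mean, engineered d2 = 8 to the other mean
  mean_a <- model$group_means_cv[1, ]
  mean_b <- model$group_means_cv[2, ]
  dir <- (mean_b - mean_a) / sqrt(sum((mean_b - mean_a)^2))
  model$group_means_cv[2, ] <- mean_a + dir * sqrt(8)
  pred <- membership_probabilities(model, mean_a)
  expect_equal(unname(pred$probability),
               c(1 / (1 + exp(-4)), 1 - 1 / (1 + exp(-4))), tolerance = 1e-9)
  expect_equal(unname(pred$mahalanobis_d2), c(0, 8), tolerance = 1e-9)
  expect_equal(pred$predicted, "a")
  # typicality of a point at the mean is 1
  expect_equal(unname(pred$typicality[1]), 1)

  # equidistant point: uniform posterior; probabilities always sum to 1
  mid <- (mean_a + model$group_means_cv[2, ]) / 2
  pmid <- membership_probabilities(model, mid)
  expect_equal(unname(pmid$probability), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(pred$probability), 1, tolerance = 1e-9)
})

test_that("singular within-group covariance is caught with advice", {
  X <- matrix(rnorm(12), 6, 2)
  X <- cbind(X, X[, 1] + X[, 2])  # rank-deficient
  groups <- factor(rep(c("a", "b"), 3))
  expect_error(fit_cva(X, groups), "lower k")
})
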