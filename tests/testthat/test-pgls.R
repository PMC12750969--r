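write_tree_file <- function(text) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(text, f)
  f
}

test_that("Newick reading validates what Brownian motion needs", {
  tree <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  expect_equal(ape::Ntip(tree), 3L)
  depths <- ape::node.depth.edgelength(tree)[1:3]
  expect_equal(unname(depths), c(2, 2, 2))

  expect_error(read_newick(write_tree_file("((A:1,A:1):1,C:2);")),
               "duplicate tip")
  expect_error(read_newick(write_tree_file("((A,B),C);")),
               "branch lengths")

  pruned <- prune_tree(tree, c("A", "C"))
  expect_equal(sort(pruned$tip.label), c("A", "C"))
  expect_equal(unname(ape::cophenetic.phylo(pruned)["A", "C"]), 4)
  expect_error(prune_tree(tree, c("A", "Z")), "Z")
})

test_that("Brownian covariance matches shared path lengths", {
  tree <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  C <- bm_covariance(tree, c("A", "B", "C"))
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  star <- read_newick(write_tree_file("(A:1,B:1,C:1);"))
  expect_equal(unname(bm_covariance(star)), diag(3))

  for (seed in 1:5) {
    rt <- simulate_tree(15, seed = seed)
    ev <- eigen(bm_covariance(rt), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
  }
  expect_error(bm_covariance(tree, c("A", "missing")), "missing")
})

# independent oracle: ordinary multivariate ANOVA sums of squares
ols_anova_r2 <- function(Y, groups) {
  fit <- stats::lm(Y ~ groups)
  res <- stats::residuals(fit)
  tot <- scale(Y, scale = FALSE)
  ss_res <- sum(res^2); ss_tot <- sum(tot^2)
  g <- nlevels(groups); n <- nrow(Y)
  list(r2 = 1 - ss_res / ss_tot,
       F = ((ss_tot - ss_res) / (g - 1)) / (ss_res / (n - g)))
}

test_that("PGLS with identity covariance equals ordinary multivariate ANOVA", {
  set.seed(71)
  n <- 12
  Y <- matrix(rnorm(n * 6), n)
  rownames(Y) <- paste0("s", 1:n)
  groups <- factor(rep(c("a", "b", "c"), each = 4))
  C <- diag(n); dimnames(C) <- list(rownames(Y), rownames(Y))
  fit <- pgls_fit(Y, groups, C, n_perm = 0)
  oracle <- ols_anova_r2(Y, groups)
  expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-9)
  expect_equal(fit$F, oracle$F, tolerance = 1e-9)
})

test_that("R^2 is invariant to rotations of shape space and to scaling C", {
  set.seed(72)
  n <- 15
  tree <- simulate_tree(n, seed = 72)
  C <- bm_covariance(tree)
  Y <- matrix(rnorm(n * 8), n); rownames(Y) <- tree$tip.label
  groups <- factor(rep_len(c("a", "b", "c"), n))
  f0 <- pgls_fit(Y, groups, C, n_perm = 0)
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  fQ <- pgls_fit(Y %*% Q, groups, C, n_perm = 0)
  expect_equal(fQ$r_squared, f0$r_squared, tolerance = 1e-9)
  f5 <- pgls_fit(Y, groups, 5 * C, n_perm = 0)
  expect_equal(f5$r_squared, f0$r_squared, tolerance = 1e-9)
  expect_equal(f5$F, f0$F, tolerance = 1e-9)
  expect_error(pgls_fit(Y, factor(rep("a", n)), C, n_perm = 0), "constant")
})

test_that("shrinking C toward identity converges to the ordinary fit", {
  set.seed(73)
  n <- 12
  tree <- simulate_tree(n, seed = 73)
  C <- bm_covariance(tree)
  Y <- matrix(rnorm(n * 4), n); rownames(Y) <- tree$tip.label
  groups <- factor(rep_len(c("a", "b"), n))
  oracle <- ols_anova_r2(Y, groups)
  r2 <- vapply(c(0.5, 0.1, 0.01, 1e-4, 1e-6), function(lam) {
    Cl <- lam * C + (1 - lam) * diag(n)
    dimnames(Cl) <- dimnames(C)
    pgls_fit(Y, groups, Cl, n_perm = 0)$r_squared
  }, numeric(1))
  expect_lt(abs(r2[length(r2)] - oracle$r2), 1e-4)
  # error shrinks monotonically along the grid
  expect_true(all(diff(abs(r2 - oracle$r2)) <= 1e-12))
})

test_that("R^2 grows monotonically with a known group effect", {
  n <- 20
  tree <- simulate_tree(n, seed = 74)
  C <- bm_covariance(tree)
  set.seed(74)
  L <- t(chol(C))
  noise <- L %*% matrix(rnorm(n * 10), n)  # BM-structured residuals, fixed
  groups <- factor(rep_len(c("a", "b"), n))
  direction <- matrix(rnorm(10), 1)
  effects <- seq(0, 2, by = 0.25)
  r2 <- vapply(effects, function(e) {
    Y <- noise + (as.integer(groups) - 1.5) %o% drop(direction) * e
    rownames(Y) <- tree$tip.label
    pgls_fit(Y, groups, C, n_perm = 0)$r_squared
  }, numeric(1))
  expect_gt(stats::cor(effects, r2, method = "spearman"), 0.95)
})

test_that("RRPP p-values are seed-reproducible and detect real effects", {
  n <- 16
  tree <- simulate_tree(n, seed = 75)
  C <- bm_covariance(tree)
  set.seed(75)
  groups <- factor(rep_len(c("a", "b"), n))
  Y <- t(chol(C)) %*% matrix(rnorm(n * 5), n) +
    (as.integer(groups) - 1.5) %o% rnorm(5) * 3
  rownames(Y) <- tree$tip.label
  f1 <- pgls_fit(Y, groups, C, n_perm = 199, seed = 8)
  f2 <- pgls_fit(Y, groups, C, n_perm = 199, seed = 8)
  expect_identical(f1$p_value, f2$p_value)
  expect_lte(f1$p_value, 0.01)
})
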