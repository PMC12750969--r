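make_block <- function(n = 10, noise = 0.02, seed = 41, p = 30) {
  arr <- scattered_copies(base_vertebra_shape(p), n, noise = noise,
                          seed = seed)
  generalized_procrustes(arr)
}

test_that("PCA of identical specimens is degenerate, and needs >= 3", {
  base <- base_vertebra_shape()
  arr <- array(rep(base, 4), c(30, 3, 4))
  blk <- generalized_procrustes(arr)
  sp <- fit_pca(blk)
  expect_true(all(sp$eigenvalues < 1e-18))
  expect_true(all(abs(sp$scores) < 1e-9))
  expect_error(fit_pca(generalized_procrustes(arr[, , 1:2])), "at least 3")
})

test_that("a two-group separation dominates PC1", {
  base <- base_vertebra_shape()
  delta <- vertecol:::pure_shape_projection(rnorm(90), base)
  delta <- matrix(delta / sqrt(sum(delta^2)) * 0.2, 30, 3)
  set.seed(42)
  arr <- array(NA_real_, c(30, 3, 12))
  for (i in 1:12) {
    m <- base + (if (i <= 6) delta else -delta) +
      matrix(rnorm(90, 0, 0.005), 30, 3)
    arr[, , i] <- (m %*% rot3()) * runif(1, 5, 20)
  }
  sp <- fit_pca(generalized_procrustes(arr))
  expect_gt(sp$variance_fraction[1], max(sp$variance_fraction[-1]) * 3)
  # group separation lives on PC1
  expect_gt(abs(mean(sp$scores[1:6, 1]) - mean(sp$scores[7:12, 1])),
            4 * stats::sd(sp$scores[1:6, 1]))
})

test_that("eigenvalues are complete, descending and trace-consistent", {
  blk <- make_block(seed = 43)
  sp <- fit_pca(blk)
  X <- t(sapply(1:10, function(i) as.vector(blk$aligned[, , i])))
  total_var <- sum(scale(X, scale = FALSE)^2) / 9
  expect_equal(sum(sp$eigenvalues), total_var, tolerance = 1e-9)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
  expect_true(all(sp$variance_fraction >= 0))
  expect_equal(sum(sp$variance_fraction), 1, tolerance = 1e-9)
  expect_equal(crossprod(sp$eigenvectors),
               diag(ncol(sp$eigenvectors)), tolerance = 1e-9)
})

test_that("projection is self-consistent and invertible", {
  blk <- make_block(seed = 44)
  sp <- fit_pca(blk)
  # training specimen reproduces its stored score row
  expect_equal(project_shape(sp, blk$aligned[, , 4]),
               drop(sp$scores[4, ]), tolerance = 1e-9)
  # the mean shape projects to the origin
  expect_lt(max(abs(project_shape(sp, matrix(sp$mean_vector, ncol = 3),
                                  tol = 0.2))), 1e-9)
  # full-score reconstruction is the identity
  rec <- reconstruct_shape(sp, project_shape(sp, blk$aligned[, , 7]))
  expect_equal(rec, blk$aligned[, , 7], tolerance = 1e-9,
               ignore_attr = TRUE)
  # unaligned input is rejected unless align = TRUE
  raw <- blk$aligned[, , 2] * 25 + 3
  expect_error(project_shape(sp, raw), "not superimposed")
  expect_equal(project_shape(sp, raw, align = TRUE),
               drop(sp$scores[2, ]), tolerance = 1e-8)
})

test_that("a single unscaled block reproduces its own PCA", {
  blk <- make_block(seed = 45)
  sp <- fit_pca(blk)
  mbs <- combine_blocks(list(blk), scale_blocks = FALSE)
  expect_equal(mbs$eigenvalues, sp$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(mbs$scores), abs(sp$scores), tolerance = 1e-9)
})

test_that("two identical scaled blocks double the eigenvalues", {
  blk <- make_block(seed = 46)
  # oracle: eigenvalues of one variance-scaled block, computed directly
  X <- t(sapply(1:10, function(i) as.vector(blk$aligned[, , i])))
  Xc <- scale(X, scale = FALSE)
  Xs <- Xc / sqrt(sum(Xc^2) / 9)
  lam <- svd(Xs)$d^2 / 9
  mbs <- combine_blocks(list(blk, blk), scale_blocks = TRUE)
  k <- length(mbs$eigenvalues)
  expect_equal(mbs$eigenvalues, 2 * lam[seq_len(k)], tolerance = 1e-9)
})

test_that("combined scores are invariant to block order", {
  b1 <- make_block(seed = 47)
  b2 <- make_block(seed = 48)
  b2$specimen_ids <- b1$specimen_ids
  dimnames(b2$aligned)[[3]] <- b1$specimen_ids
  names(b2$centroid_sizes) <- b1$specimen_ids
  m12 <- combine_blocks(list(b1, b2))
  m21 <- combine_blocks(list(b2, b1))
  expect_equal(m12$eigenvalues, m21$eigenvalues, tolerance = 1e-9)
  expect_equal(m12$scores, m21$scores, tolerance = 1e-9)
  b3 <- make_block(seed = 49)
  b3$specimen_ids <- paste0("other_", seq_along(b3$specimen_ids))
  expect_error(combine_blocks(list(b1, b3)), "no specimen")
})

test_that("external multi-block projection matches training scores", {
  b1 <- make_block(seed = 50)
  b2 <- make_block(seed = 51)
  b1$position <- "TF"
  b2$position <- "LM"
  b2$specimen_ids <- b1$specimen_ids
  dimnames(b2$aligned)[[3]] <- b1$specimen_ids
  mbs <- combine_blocks(list(b1, b2))
  cfgs <- list(TF = b1$aligned[, , 3], LM = b2$aligned[, , 3])
  expect_equal(project_blocks(mbs, cfgs), drop(mbs$scores[3, ]),
               tolerance = 1e-8)
})
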