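# shared fixture builders (all generated in code; no stored data)

rot3 <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

unit_shape <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# n noisy copies of a template under random rigid motion and scale
scattered_copies <- function(template, n, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(template)
  arr <- array(NA_real_, c(p, 3, n))
  for (i in seq_len(n)) {
    m <- template + matrix(rnorm(p * 3, 0, noise), p, 3)
    m <- (m %*% rot3()) * runif(1, 5, 50)
    arr[, , i] <- sweep(m, 2, runif(3, -20, 20), `+`)
  }
  arr
}

# two well-separated gaussian clusters in k dims
two_cluster_scores <- function(n_per = 10, k = 3, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * k), n_per),
             matrix(rnorm(n_per * k), n_per))
  X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + sep
  list(scores = X, groups = factor(rep(c("a", "b"), each = n_per)))
}

# brute-force PERMANOVA pseudo-F (independent oracle, explicit double loops)
pseudo_f_bruteforce <- function(D, groups) {
  D <- as.matrix(D)
  groups <- as.factor(groups)
  n <- nrow(D)
  g <- nlevels(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + D[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    s <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + D[idx[a], idx[b]]^2
    ss_within <- ss_within + s / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# largest principal angle (radians) between the column spaces of A and B
max_subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(0, min(s))))
}
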