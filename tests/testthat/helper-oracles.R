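# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately re-derive quantities from their definitions
# (pair loops, concordance counts, primal-form solves) rather than calling
# the implementation under test.

# Tiny labeled dataset from an explicit matrix (rows = samples).
make_dataset <- function(values, labels, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(values)))
  fingerprint_dataset(values, sample_id = ids, label = labels)
}

# Two well-separated Gaussian clouds, cold around 0 and hot around `shift`.
separable_clouds <- function(n_per_class = 10, d = 6, shift = 8, sd = 0.5,
                             seed = 1) {
  set.seed(seed)
  vals <- rbind(
    matrix(abs(rnorm(n_per_class * d, mean = 2, sd = sd)), n_per_class, d),
    matrix(abs(rnorm(n_per_class * d, mean = 2 + shift, sd = sd)),
           n_per_class, d)
  )
  make_dataset(vals, rep(c("cold", "hot"), each = n_per_class))
}

# Brute-force pair-loop class scatter: sum_S outer - lambda * sum_D outer.
scatter_bruteforce <- function(X, labels, lambda_) {
  d <- nrow(X)
  n <- ncol(X)
  P <- matrix(0, d, d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- X[, i] - X[, j]
      P <- P + (if (labels[i] == labels[j]) 1 else -lambda_) * tcrossprod(v)
    }
  }
  P
}

# Primal-form patch alignment oracle: Li = H - H Xi'(Xi H Xi' + mu I_d)^-1 Xi H,
# accumulated over patches with the same neighbor rule (Euclidean, stable ties).
patch_alignment_primal <- function(X, k_patch, mu) {
  n <- ncol(X)
  d <- nrow(X)
  k1 <- k_patch + 1
  H <- diag(k1) - matrix(1 / k1, k1, k1)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- colSums((X - X[, i])^2)
    d2[i] <- Inf
    members <- c(i, order(d2)[seq_len(k_patch)])
    Xi <- X[, members, drop = FALSE]
    XiH <- Xi %*% H
    Li <- H - t(XiH) %*% solve(XiH %*% t(Xi) + mu * diag(d), XiH)
    L[members, members] <- L[members, members] + Li
  }
  (L + t(L)) / 2
}

# mu -> infinity limit of the global alignment matrix: each patch contributes
# its centering matrix H.
patch_alignment_centering_limit <- function(X, k_patch) {
  n <- ncol(X)
  k1 <- k_patch + 1
  H <- diag(k1) - matrix(1 / k1, k1, k1)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- colSums((X - X[, i])^2)
    d2[i] <- Inf
    members <- c(i, order(d2)[seq_len(k_patch)])
    L[members, members] <- L[members, members] + H
  }
  L
}

# Tie-corrected pairwise-concordance AUC: P(score_cold > score_hot) + ties/2.
auc_concordance <- function(scores, truth) {
  sc <- scores[truth == "cold"]
  sh <- scores[truth == "hot"]
  tot <- 0
  for (a in sc) tot <- tot + sum(a > sh) + 0.5 * sum(a == sh)
  tot / (length(sc) * length(sh))
}

# Random d x u matrix with orthonormal columns.
random_orthonormal <- function(d, u) {
  qr.Q(qr(matrix(rnorm(d * u), d, u)))[, seq_len(u), drop = FALSE]
}
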