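test_that("constraint sets enumerate every unordered pair exactly once", {
  cs <- build_constraints(c("cold", "cold", "hot", "hot"))
  expect_equal(nrow(cs$S), 2)
  expect_equal(nrow(cs$D), 4)

  # panel-sized class counts: C(30,2) + C(31,2) same-label, 30*31 cross
  labs <- rep(c("cold", "hot"), c(30, 31))
  cs2 <- build_constraints(labs)
  expect_equal(nrow(cs2$S), choose(30, 2) + choose(31, 2))
  expect_equal(nrow(cs2$D), 30 * 31)
  expect_equal(nrow(cs2$S) + nrow(cs2$D), choose(61, 2))
  # disjoint, no self-pairs, i < j
  expect_true(all(cs2$S[, 1] < cs2$S[, 2]))
  expect_true(all(cs2$D[, 1] < cs2$D[, 2]))

  # single class: D empty but the scatter still works with lambda > 0
  cs3 <- build_constraints(c("cold", "cold", "cold"))
  expect_equal(nrow(cs3$D), 0)
  X <- matrix(rnorm(6), 2, 3)
  expect_silent(semantic_scatter(X, cs3, lambda_ = 5))

  expect_error(build_constraints(c("cold", "unknown")), "known cold/hot")
  expect_error(build_constraints("cold"), "at least 2")
})

test_that("semantic scatter matches the brute-force pair loop (n <= 8)", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    d <- sample(2:5, 1)
    labels <- sample(c("cold", "hot"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- setdiff(c("cold", "hot"),
                                                         labels[2])
    lambda_ <- sample(c(0, 0.5, 1, 10), 1)
    X <- matrix(rnorm(d * n), d, n)
    P <- semantic_scatter(X, build_constraints(labels), lambda_)
    expect_equal(P, scatter_bruteforce(X, labels, lambda_), tolerance = 1e-10)
    expect_equal(P, t(P))
  }
})

test_that("semantic scatter special cases: single pair and lambda = 0 PSD", {
  x1 <- c(1, 2, 3); x2 <- c(0, 1, 5)
  P <- semantic_scatter(cbind(x1, x2), build_constraints(c("cold", "cold")),
                        lambda_ = 7)
  expect_equal(P, tcrossprod(x1 - x2), ignore_attr = TRUE)

  set.seed(2)
  X <- matrix(rnorm(18), 3, 6)
  P0 <- semantic_scatter(X, build_constraints(rep(c("cold", "hot"), 3)), 0)
  expect_gte(min(eigen(P0, symmetric = TRUE)$values), -1e-10)
})

test_that("patch alignment agrees with the primal-form oracle", {
  set.seed(21)
  for (trial in 1:50) {
    n <- sample(4:8, 1)
    d <- sample(2:6, 1)
    k_patch <- sample(seq_len(n - 1), 1)
    mu <- sample(c(1e-3, 1, 1e3), 1)
    X <- matrix(rnorm(d * n), d, n)
    L <- build_patch_alignment(X, k_patch, mu)
    expect_equal(L, patch_alignment_primal(X, k_patch, mu),
                 tolerance = 1e-8)
  }
})

test_that("patch alignment is PSD with zero row sums; huge mu gives the centering limit", {
  set.seed(22)
  X <- matrix(rnorm(4 * 6), 4, 6)
  L <- build_patch_alignment(X, k_patch = 2, mu = 10)
  expect_lt(max(abs(L %*% rep(1, 6))), 1e-10)
  expect_gte(min(eigen(L, symmetric = TRUE)$values), -1e-10)

  # mu far above ||Ki|| forces the ridge weights to zero: Li -> H
  L_inf <- build_patch_alignment(X, k_patch = 2, mu = 1e12)
  expect_equal(L_inf, patch_alignment_centering_limit(X, 2),
               tolerance = 1e-6)
  expect_lt(max(abs(L_inf %*% rep(1, 6))), 1e-8)

  expect_error(build_patch_alignment(X, k_patch = 0, mu = 1), "k_patch")
  expect_error(build_patch_alignment(X, k_patch = 6, mu = 1), "k_patch")
})

test_that("combined objective adds the terms and symmetrizes", {
  set.seed(3)
  d <- 4; n <- 5
  X <- matrix(rnorm(d * n), d, n)
  P <- crossprod(matrix(rnorm(d * d), d, d))
  L <- build_patch_alignment(X, 2, 1)
  Q <- combined_objective(P, X, L)
  expect_lt(max(abs(Q - t(Q))), 1e-10)
  expect_equal(Q, (P + X %*% L %*% t(X) + t(P + X %*% L %*% t(X))) / 2)
  # L = 0 reduces to P; P = 0 leaves a PSD congruence of L
  expect_equal(combined_objective(P, X, matrix(0, n, n)), (P + t(P)) / 2)
  Q0 <- combined_objective(matrix(0, d, d), X, L)
  expect_gte(min(eigen(Q0, symmetric = TRUE)$values), -1e-8)
})

test_that("projection solver picks the smallest-eigenvalue directions", {
  s1 <- solve_projection(diag(c(3, 1, 2)), u = 1)
  expect_equal(abs(s1$A), matrix(c(0, 1, 0), 3, 1), tolerance = 1e-12)
  expect_equal(s1$spectrum, 1)
  expect_gt(s1$A[2, 1], 0)  # deterministic sign

  s2 <- solve_projection(diag(c(3, 1, 2)), u = 2)
  expect_equal(s2$spectrum, c(1, 2))
  # columns span {e2, e3}
  expect_lt(max(abs(s2$A[1, ])), 1e-12)
  expect_equal(crossprod(s2$A), diag(2), tolerance = 1e-12)

  expect_error(solve_projection(diag(3), u = 4), "u must lie")
  M <- matrix(rnorm(9), 3, 3)
  expect_error(solve_projection(M, 1), "not symmetric")
})

test_that("eigensolution beats random orthonormal competitors and attains the eigenvalue sum", {
  set.seed(31)
  for (trial in 1:10) {
    Q <- crossprod(matrix(rnorm(36), 6, 6))
    Q <- Q - 2 * diag(6)  # mix of signs
    u <- sample(1:3, 1)
    sol <- solve_projection(Q, u)
    obj <- sum(diag(crossprod(sol$A, Q %*% sol$A)))
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(obj, sum(rev(ev)[seq_len(u)]), tolerance = 1e-10)
    for (k in 1:200) {
      R <- random_orthonormal(6, u)
      expect_lte(obj, sum(diag(crossprod(R, Q %*% R))) + 1e-10)
    }
  }
})

test_that("span-restricted projection stays in the span and matches the restricted solution", {
  set.seed(32)
  d <- 10
  Q <- crossprod(matrix(rnorm(d * d), d, d)) - diag(d)
  B <- random_orthonormal(d, 4)
  sol <- solve_projection(Q, u = 2, span_basis = B)
  # columns lie in span(B) and are orthonormal
  expect_lt(max(abs(sol$A - B %*% crossprod(B, sol$A))), 1e-10)
  expect_equal(crossprod(sol$A), diag(2), tolerance = 1e-10)
  # objective equals the reduced eigenproblem optimum
  ev_red <- eigen(crossprod(B, Q %*% B), symmetric = TRUE,
                  only.values = TRUE)$values
  expect_equal(sum(diag(crossprod(sol$A, Q %*% sol$A))),
               sum(rev(ev_red)[1:2]), tolerance = 1e-10)
})

test_that("learned distance is a pseudo-metric with the documented special cases", {
  set.seed(41)
  ds <- separable_clouds(8, d = 12)
  model <- fit_metric(ds, metric_hyperparams(k_patch = 3, u = 4))
  expect_equal(crossprod(model$A), diag(4), tolerance = 1e-8)

  x <- rnorm(12); y <- rnorm(12); z <- rnorm(12)
  expect_equal(mahalanobis_distance(model, x, x), 0)
  dxy <- mahalanobis_distance(model, x, y)
  expect_equal(dxy, mahalanobis_distance(model, y, x))
  expect_gte(dxy, 0)
  # triangle inequality on random triples
  for (k in 1:20) {
    a <- rnorm(12); b <- rnorm(12); cc <- rnorm(12)
    expect_lte(mahalanobis_distance(model, a, cc),
               mahalanobis_distance(model, a, b) +
                 mahalanobis_distance(model, b, cc) + 1e-12)
  }
  # identity transformation gives plain Euclidean distance
  id <- identity_metric(12)
  expect_equal(mahalanobis_distance(id, x, y), sqrt(sum((x - y)^2)))
  # coordinate projection: A = e1, x - y = (3, 4)
  m1 <- identity_metric(2)
  m1$A <- matrix(c(1, 0), 2, 1)
  expect_equal(mahalanobis_distance(m1, c(3, 4), c(0, 0)), 3)
  expect_error(mahalanobis_distance(model, rnorm(5), rnorm(12)), "length")
})

test_that("fitted metric shrinks within-class distances relative to between-class", {
  ds <- separable_clouds(10, d = 10, shift = 6, sd = 1, seed = 7)
  model <- fit_metric(ds, metric_hyperparams(k_patch = 5, u = 3))
  lab <- as.character(ds$label)
  D <- as.matrix(stats::dist(ds$values %*% model$A))
  same <- outer(lab, lab, "==") & upper.tri(D)
  diff <- outer(lab, lab, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("refitting identical inputs reproduces the model bit for bit", {
  ds <- separable_clouds(6, d = 9, seed = 5)
  hp <- metric_hyperparams(k_patch = 3, u = 4)
  m1 <- fit_metric(ds, hp)
  m2 <- fit_metric(ds, hp)
  expect_identical(m1$A, m2$A)
  expect_identical(m1$spectrum, m2$spectrum)
})

test_that("full-rank projection reproduces Euclidean geometry exactly", {
  # u equal to the centered-span rank makes A an orthonormal basis of the
  # whole search space, so learned distances coincide with Euclidean ones.
  ds <- separable_clouds(5, d = 20, seed = 9)
  model <- fit_metric(ds, metric_hyperparams(k_patch = 3, u = 9))
  D_learn <- as.matrix(stats::dist(ds$values %*% model$A))
  D_eucl <- as.matrix(stats::dist(ds$values))
  expect_equal(D_learn, D_eucl, tolerance = 1e-8)
})

test_that("metric model serialization round-trips exactly", {
  ds <- separable_clouds(6, d = 8, seed = 3)
  model <- fit_metric(ds, metric_hyperparams(lambda_ = 0.5, mu = 10,
                                             k_patch = 2, u = 3))
  p <- withr::local_tempfile(fileext = ".json")
  write_metric_model(model, p)
  back <- read_metric_model(p)
  expect_identical(back$A, model$A)
  expect_identical(back$spectrum, model$spectrum)
  expect_identical(back$training_ids, model$training_ids)
  expect_equal(back$hyperparams, model$hyperparams)
})

test_that("fit_metric validates labels, class balance and dimensions", {
  ds <- separable_clouds(4, d = 6)
  ds_un <- ds
  ds_un$label[1] <- factor("unknown", levels = levels(ds$label))
  expect_error(fit_metric(ds_un), "fully labeled")
  one_class <- make_dataset(matrix(runif(12), 4, 3), rep("cold", 4))
  expect_error(fit_metric(one_class), "both cold and hot")
  expect_error(fit_metric(ds, metric_hyperparams(k_patch = 20)), "k_patch")
  expect_error(fit_metric(ds, metric_hyperparams(u = 50)), "exceeds")
})
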