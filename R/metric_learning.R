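#' Pairwise label constraints
#'
#' Enumerates every unordered sample pair and splits it into the equivalence
#' set `S` (same nature label) and the inequivalence set `D` (different
#' labels). These sets drive the class-scatter term of the learned metric.
#'
#' @param labels character or factor vector of `"cold"`/`"hot"` labels,
#'   length `n >= 2`; `"unknown"` labels are an error.
#' @return An object of class `constraint_sets`: list with integer matrices
#'   `S` and `D` (two columns `i < j`, one row per unordered pair) and `n`.
#' @export
#' @examples
#' cs <- build_constraints(c("cold", "cold", "hot", "hot"))
#' nrow(cs$S)  # 2 same-label pairs
#' nrow(cs$D)  # 4 cross-label pairs
build_constraints <- function(labels) {
  labels <- normalize_labels(labels)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 labeled samples", call. = FALSE)
  if (any(labels == "unknown")) {
    stop("constraints require known cold/hot labels", call. = FALSE)
  }
  pairs <- t(utils::combn(n, 2L))
  same <- labels[pairs[, 1L]] == labels[pairs[, 2L]]
  structure(
    list(S = pairs[same, , drop = FALSE], D = pairs[!same, , drop = FALSE],
         n = n),
    class = "constraint_sets"
  )
}

#' @export
print.constraint_sets <- function(x, ...) {
  cat(sprintf("<constraint_sets> n=%d, |S|=%d same-label, |D|=%d cross-label\n",
              x$n, nrow(x$S), nrow(x$D)))
  invisible(x)
}

#' Semantic class-scatter matrix
#'
#' Computes the pairwise-constraint scatter
#' \deqn{P = \sum_{(i,j)\in S}(x_i-x_j)(x_i-x_j)^\top
#'         - \lambda \sum_{(i,j)\in D}(x_i-x_j)(x_i-x_j)^\top,}
#' the matrix whose trace form \eqn{tr(A^\top P A)} is small when same-label
#' fingerprints project close together and different-label fingerprints
#' project far apart. Each unordered pair is counted once. Internally the sum
#' is evaluated as \eqn{X L_w X^\top} with \eqn{L_w} the signed graph
#' Laplacian of the constraint weights, which is algebraically identical to
#' the pair loop.
#'
#' @param X numeric `d x n` matrix, one fingerprint per column.
#' @param constraints a [build_constraints()] result (indices into columns of
#'   `X`).
#' @param lambda_ non-negative trade-off weight on the inequivalence term.
#' @return symmetric `d x d` matrix `P`.
#' @export
semantic_scatter <- function(X, constraints, lambda_ = 1) {
  stopifnot(is.matrix(X), inherits(constraints, "constraint_sets"),
            lambda_ >= 0)
  n <- ncol(X)
  idx <- rbind(constraints$S, constraints$D)
  if (nrow(idx) > 0L && max(idx) > n) {
    stop("constraint indices exceed number of samples", call. = FALSE)
  }
  W <- matrix(0, n, n)
  if (nrow(constraints$S) > 0L) {
    W[constraints$S] <- 1
  }
  if (nrow(constraints$D) > 0L) {
    W[constraints$D] <- -lambda_
  }
  W <- W + t(W)
  Lw <- diag(rowSums(W), n) - W
  P <- X %*% Lw %*% t(X)
  (P + t(P)) / 2
}

#' Patch-alignment similarity matrix
#'
#' For every sample, a local "patch" is formed from the sample and its
#' `k_patch` Euclidean nearest neighbors (ties broken by dataset index). The
#' patch-local ridge-regression reconstruction objective has the closed-form
#' residual quadratic \eqn{Y_i^\top L_i Y_i} with
#' \deqn{L_i = H - H K_i (H K_i H + \mu I)^{-1} H,}
#' where \eqn{H = I - \frac{1}{k+1}11^\top} is the centering matrix and
#' \eqn{K_i = X_i^\top X_i} the patch Gram matrix. The global alignment
#' matrix accumulates the patch matrices over their member indices:
#' \eqn{L = \sum_i S_i L_i S_i^\top}. `L` is symmetric positive semi-definite
#' with zero row sums.
#'
#' @param X numeric `d x n` matrix, one fingerprint per column.
#' @param k_patch neighbors per patch (patch size `k_patch + 1`),
#'   `1 <= k_patch <= n - 1`.
#' @param mu positive ridge penalty of the patch regression.
#' @return symmetric PSD `n x n` matrix `L`.
#' @export
build_patch_alignment <- function(X, k_patch = 7, mu = 1e3) {
  stopifnot(is.matrix(X), mu > 0)
  n <- ncol(X)
  if (k_patch < 1L || k_patch > n - 1L) {
    stop("k_patch must be between 1 and n-1 (n=", n, ")", call. = FALSE)
  }
  k1 <- k_patch + 1L
  D2 <- euclidean_dist2(X)
  H <- diag(k1) - matrix(1 / k1, k1, k1)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D2[, i]
    d2[i] <- Inf
    # order() is a stable sort, so equal distances keep dataset order
    nbrs <- order(d2)[seq_len(k_patch)]
    members <- c(i, nbrs)
    Xi <- X[, members, drop = FALSE]
    Ki <- crossprod(Xi)
    Li <- H - H %*% Ki %*% solve(H %*% Ki %*% H + mu * diag(k1), H)
    L[members, members] <- L[members, members] + Li
  }
  (L + t(L)) / 2
}

# Squared Euclidean distances between columns of X.
euclidean_dist2 <- function(X) {
  ss <- colSums(X^2)
  D2 <- outer(ss, ss, "+") - 2 * crossprod(X)
  D2[D2 < 0] <- 0
  D2
}

#' Combine class scatter and patch alignment
#'
#' Forms the objective matrix \eqn{Q = P + X L X^\top} whose `u` smallest
#' eigenvectors define the learned transformation. The result is explicitly
#' symmetrized to absorb floating-point asymmetry.
#'
#' @param P symmetric `d x d` class-scatter matrix.
#' @param X numeric `d x n` fingerprint matrix.
#' @param L symmetric `n x n` patch-alignment matrix.
#' @param alignment_weight optional scalar weight on the alignment term
#'   (default 1, the plain sum).
#' @return symmetric `d x d` matrix `Q`.
#' @export
combined_objective <- function(P, X, L, alignment_weight = 1) {
  stopifnot(is.matrix(P), is.matrix(X), is.matrix(L),
            nrow(P) == nrow(X), ncol(X) == nrow(L))
  Q <- P + alignment_weight * (X %*% L %*% t(X))
  (Q + t(Q)) / 2
}

#' Minimizing orthonormal projection of a symmetric objective
#'
#' Solves \eqn{\min_A tr(A^\top Q A)} subject to \eqn{A^\top A = I} by
#' eigendecomposition: the columns of `A` are the eigenvectors of `Q`
#' belonging to the `u` algebraically smallest eigenvalues. Eigenvector signs
#' are fixed deterministically (the largest-magnitude component of each
#' column is made positive). When `span_basis` is supplied the problem is
#' solved restricted to its column span, which is how the high-dimensional
#' fit avoids the uninformative null space of `Q` (see [fit_metric()]).
#'
#' @param Q symmetric matrix; relative asymmetry above `1e-6` is rejected.
#' @param u number of projection directions.
#' @param span_basis optional `d x m` matrix with orthonormal columns; the
#'   solution is sought within its span.
#' @return list with `A` (`d x u`, orthonormal columns) and `spectrum` (the
#'   `u` selected eigenvalues, ascending).
#' @export
solve_projection <- function(Q, u, span_basis = NULL) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  asym <- max(abs(Q - t(Q)))
  scale <- max(abs(Q), 1e-300)
  if (asym / scale > 1e-6) {
    stop("Q is not symmetric (relative asymmetry ", format(asym / scale), ")",
         call. = FALSE)
  }
  Q <- (Q + t(Q)) / 2
  if (!is.null(span_basis)) {
    B <- as.matrix(span_basis)
    stopifnot(nrow(B) == nrow(Q))
    Qr <- crossprod(B, Q %*% B)
    red <- solve_projection((Qr + t(Qr)) / 2, u)
    A <- B %*% red$A
    return(list(A = fix_signs(A), spectrum = red$spectrum))
  }
  if (u < 1L || u > nrow(Q)) {
    stop("u must lie in 1..", nrow(Q), call. = FALSE)
  }
  eg <- eigen(Q, symmetric = TRUE)  # eigenvalues descending
  sel <- rev(seq(nrow(Q) - u + 1L, nrow(Q)))
  A <- eg$vectors[, sel, drop = FALSE]
  list(A = fix_signs(A), spectrum = eg$values[sel])
}

# Deterministic eigenvector orientation: largest-|.| entry made positive.
fix_signs <- function(A) {
  for (j in seq_len(ncol(A))) {
    p <- which.max(abs(A[, j]))
    if (A[p, j] < 0) A[, j] <- -A[, j]
  }
  A
}

#' Metric hyperparameters
#'
#' Bundles the tunable parameters of the learned metric: `lambda_` trades the
#' inequivalence scatter against the equivalence scatter, `mu` is the patch
#' ridge penalty, `k_patch` the patch neighborhood size, and `u` the number
#' of projection directions (`NULL` means `min(n - 1, 30)` at fit time, capped
#' by the data rank). `alignment_weight` scales the patch-alignment term in
#' the combined objective (default 1, the plain sum).
#'
#' @param lambda_ non-negative scatter trade-off (default 1).
#' @param mu positive patch ridge penalty (default `1e3`).
#' @param k_patch neighbors per patch (default 7).
#' @param u projection dimension or `NULL` for the automatic default.
#' @param alignment_weight scalar weight on the alignment term.
#' @return object of class `metric_hyperparams`.
#' @export
metric_hyperparams <- function(lambda_ = 1, mu = 1e3, k_patch = 7, u = NULL,
                               alignment_weight = 1) {
  stopifnot(lambda_ >= 0, mu > 0, k_patch >= 1)
  if (!is.null(u)) stopifnot(u >= 1)
  structure(
    list(lambda_ = lambda_, mu = mu, k_patch = as.integer(k_patch),
         u = if (is.null(u)) NULL else as.integer(u),
         alignment_weight = alignment_weight),
    class = "metric_hyperparams"
  )
}

#' Fit the Mahalanobis metric to a labeled fingerprint dataset
#'
#' Composes the pipeline: pairwise constraints from the labels, the class
#' scatter `P`, the patch-alignment matrix `L`, the combined objective
#' `Q = P + X L X^T`, and the eigensolution for the transformation `A`. The
#' learned distance is \eqn{\|A^\top(x - y)\|_2}.
#'
#' With far more channels than samples (`d >> n`), `Q` has a huge null space
#' of exact-zero eigenvalues carrying no information about the data; a
#' literal "u smallest eigenvalues of Q" could land in it. By default the
#' eigenproblem is therefore solved restricted to the span of the centered
#' training fingerprints (rank at most `n - 1`), which contains every
#' between-sample difference and hence every direction the distance can use.
#' Set `full_space = TRUE` for the literal full-space decomposition (only
#' sensible when `d <= n` or for diagnostics).
#'
#' @param dataset labeled `fingerprint_dataset` with both classes present.
#' @param hyperparams a [metric_hyperparams()] object.
#' @param full_space solve the unrestricted `d x d` eigenproblem.
#' @return object of class `metric_model`: list with `A` (`d x u`, orthonormal
#'   columns), `spectrum` (selected eigenvalues, ascending), `hyperparams`,
#'   and `training_ids`.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_config(n_cold = 8, n_hot = 8, d = 60,
#'                                          seed = 1))
#' m <- fit_metric(ds, metric_hyperparams(k_patch = 3))
#' mahalanobis_distance(m, ds$values[1, ], ds$values[2, ])
fit_metric <- function(dataset, hyperparams = metric_hyperparams(),
                       full_space = FALSE) {
  stopifnot(inherits(dataset, "fingerprint_dataset"),
            inherits(hyperparams, "metric_hyperparams"))
  labels <- dataset$label
  if (any(labels == "unknown")) {
    stop("training dataset must be fully labeled", call. = FALSE)
  }
  if (length(unique(droplevels(labels))) < 2L) {
    stop("training dataset must contain both cold and hot samples",
         call. = FALSE)
  }
  X <- fingerprint_matrix(dataset)  # d x n
  d <- nrow(X)
  n <- ncol(X)
  hp <- hyperparams
  if (hp$k_patch > n - 1L) {
    stop("k_patch (", hp$k_patch, ") must be at most n-1 = ", n - 1L,
         call. = FALSE)
  }
  constraints <- build_constraints(labels)

  if (full_space) {
    basis <- NULL
    Z <- X
  } else {
    # Orthonormal basis of the centered data span; distances between samples
    # are preserved because every difference x_i - x_j lies in this span.
    Xc <- X - rowMeans(X)
    qrX <- qr(Xc)
    rank <- qrX$rank
    basis <- qr.Q(qrX)[, seq_len(max(rank, 1L)), drop = FALSE]
    Z <- crossprod(basis, X)  # m x n reduced coordinates
  }
  m_avail <- nrow(Z)
  u <- if (is.null(hp$u)) min(n - 1L, 30L, m_avail) else hp$u
  if (u > m_avail) {
    stop("u (", u, ") exceeds the available search-space rank (", m_avail,
         ")", call. = FALSE)
  }

  P <- semantic_scatter(Z, constraints, hp$lambda_)
  L <- build_patch_alignment(Z, hp$k_patch, hp$mu)
  Q <- combined_objective(P, Z, L, hp$alignment_weight)
  sol <- solve_projection(Q, u)
  A <- if (is.null(basis)) sol$A else fix_signs(basis %*% sol$A)
  hp$u <- as.integer(u)
  structure(
    list(A = A, spectrum = sol$spectrum, hyperparams = hp,
         training_ids = dataset$sample_id),
    class = "metric_model"
  )
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf(
    "<metric_model> d=%d -> u=%d (lambda=%g, mu=%g, k_patch=%d), n_train=%d\n",
    nrow(x$A), ncol(x$A), x$hyperparams$lambda_, x$hyperparams$mu,
    x$hyperparams$k_patch, length(x$training_ids)))
  invisible(x)
}

#' Identity metric model
#'
#' A `metric_model` whose transformation is the `d x d` identity, so the
#' learned distance reduces to the plain Euclidean distance. Used to check
#' that the retrieval machinery collapses to the unweighted baseline.
#'
#' @param d channel count.
#' @return a `metric_model`.
#' @export
identity_metric <- function(d) {
  structure(
    list(A = diag(d), spectrum = rep(NA_real_, d),
         hyperparams = metric_hyperparams(u = d), training_ids = character()),
    class = "metric_model"
  )
}

#' Learned Mahalanobis distance between two fingerprints
#'
#' @param model a `metric_model`.
#' @param x,y numeric vectors of length `d` (the model's input dimension).
#' @return non-negative scalar \eqn{\|A^\top (x - y)\|_2}.
#' @export
mahalanobis_distance <- function(model, x, y) {
  stopifnot(inherits(model, "metric_model"))
  if (length(x) != nrow(model$A) || length(y) != nrow(model$A)) {
    stop("vectors must have length d = ", nrow(model$A), call. = FALSE)
  }
  sqrt(sum(crossprod(model$A, x - y)^2))
}

# All pairwise learned distances from query rows to reference rows.
# Computed in the projected space: embed once, then Euclidean.
projected_distances <- function(model, query_values, ref_values) {
  Zq <- query_values %*% model$A   # nq x u
  Zr <- ref_values %*% model$A     # nr x u
  ssq <- rowSums(Zq^2)
  ssr <- rowSums(Zr^2)
  D2 <- outer(ssq, ssr, "+") - 2 * Zq %*% t(Zr)
  D2[D2 < 0] <- 0
  sqrt(D2)
}

#' Serialize / restore a metric model
#'
#' Writes the model as plain JSON (transformation matrix in column order at
#' full IEEE precision, hyperparameters, training ids, spectrum); the
#' write/read round trip is exact.
#'
#' @param model a `metric_model`.
#' @param path file path.
#' @return `write_metric_model` returns `path` invisibly; `read_metric_model`
#'   returns the restored `metric_model`.
#' @export
write_metric_model <- function(model, path) {
  stopifnot(inherits(model, "metric_model"))
  # doubles travel as %.17g strings: exact for IEEE doubles
  num17 <- function(x) trimws(formatC(x, digits = 17, format = "g"))
  hp <- unclass(model$hyperparams)
  hp[c("lambda_", "mu", "alignment_weight")] <-
    lapply(hp[c("lambda_", "mu", "alignment_weight")], num17)
  payload <- list(
    d = nrow(model$A), u = ncol(model$A), A = num17(as.numeric(model$A)),
    spectrum = num17(model$spectrum),
    hyperparams = hp,
    training_ids = model$training_ids
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_metric_model
#' @export
read_metric_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- metric_hyperparams(lambda_ = as.numeric(p$hyperparams$lambda_),
                           mu = as.numeric(p$hyperparams$mu),
                           k_patch = p$hyperparams$k_patch,
                           u = p$hyperparams$u,
                           alignment_weight =
                             as.numeric(p$hyperparams$alignment_weight))
  structure(
    list(A = matrix(as.numeric(p$A), nrow = p$d, ncol = p$u),
         spectrum = as.numeric(p$spectrum), hyperparams = hp,
         training_ids = as.character(p$training_ids)),
    class = "metric_model"
  )
}
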