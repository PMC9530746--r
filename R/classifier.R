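#' Inverse-distance cold-nature probability
#'
#' Converts the `r` retrieved reference herbs into the probability that the
#' query is cold-natured:
#' \deqn{P_q = \frac{\sum_{i \in cold} W_i}{\sum_{i} W_i}, \qquad
#'       W_i = 1 / \max(d_i, \epsilon).}
#' The guard \eqn{\epsilon} makes the weight finite when a retrieved
#' fingerprint is (numerically) identical to the query; such a neighbor then
#' dominates the probability, matching the intuition that an identical
#' chromatogram determines the nature. By default
#' \eqn{\epsilon = 10^{-12} \times} the median non-zero retrieved distance
#' (absolute floor `1e-300` when every distance is zero).
#'
#' @param labels character/factor vector of neighbor labels (`cold`/`hot`).
#' @param distances non-negative distances, same length.
#' @param epsilon positive guard, or `NULL` for the default rule.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' cold_probability(c("cold", "hot", "cold"), c(1, 2, 4))  # 5/7
cold_probability <- function(labels, distances, epsilon = NULL) {
  labels <- normalize_labels(labels)
  if (length(labels) == 0L) stop("empty neighbor list", call. = FALSE)
  if (length(labels) != length(distances)) {
    stop("labels and distances must have equal length", call. = FALSE)
  }
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(labels == "unknown")) {
    stop("neighbors must carry known cold/hot labels", call. = FALSE)
  }
  if (is.null(epsilon)) epsilon <- default_epsilon(distances)
  w <- 1 / pmax(distances, epsilon)
  sum(w[labels == "cold"]) / sum(w)
}

default_epsilon <- function(distances) {
  nz <- distances[distances > 0]
  if (length(nz) == 0L) 1e-300 else 1e-12 * stats::median(nz)
}

#' Threshold a cold probability into a nature call
#'
#' The decision is inclusive at the threshold: `Pq >= threshold` is called
#' cold, otherwise hot. The conventional threshold is 0.5.
#'
#' @param Pq cold probability in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`.
#' @return `"cold"` or `"hot"` (vectorized over `Pq`).
#' @export
classify_nature <- function(Pq, threshold = 0.5) {
  if (any(Pq < 0 | Pq > 1)) stop("Pq must lie in [0, 1]", call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  ifelse(Pq >= threshold, "cold", "hot")
}

#' Retrieve the most similar reference herbs under the learned metric
#'
#' Ranks all labeled references by learned Mahalanobis distance to the query,
#' keeps the `r` nearest (exact ties broken by reference order — a stable
#' sort), attaches inverse-distance weights, and computes the cold
#' probability.
#'
#' @param model a `metric_model`.
#' @param query numeric fingerprint vector of length `d`, or a one-sample
#'   `fingerprint_dataset`.
#' @param references fully labeled `fingerprint_dataset`; must not contain
#'   the query's `sample_id`.
#' @param r number of neighbors to retrieve, `1 <= r <= n` references.
#' @param query_id identifier used in the result (default `"query"` for bare
#'   vectors).
#' @param epsilon weight guard passed to [cold_probability()].
#' @return object of class `retrieval_result`: list with `query_id`,
#'   `neighbors` (data.frame: `sample_id`, `label`, `distance`, `weight`,
#'   ascending distance), `r`, and `Pq`.
#' @export
retrieve <- function(model, query, references, r = 7, query_id = NULL,
                     epsilon = NULL) {
  stopifnot(inherits(model, "metric_model"),
            inherits(references, "fingerprint_dataset"))
  if (inherits(query, "fingerprint_dataset")) {
    if (n_samples(query) != 1L) {
      stop("query dataset must contain exactly one sample", call. = FALSE)
    }
    if (is.null(query_id)) query_id <- query$sample_id
    query <- drop(query$values)
  }
  if (is.null(query_id)) query_id <- "query"
  if (query_id %in% references$sample_id) {
    stop("query sample_id '", query_id, "' present among references",
         call. = FALSE)
  }
  nref <- n_samples(references)
  if (r < 1L || r > nref) {
    stop("r must lie in 1..", nref, call. = FALSE)
  }
  if (any(references$label == "unknown")) {
    stop("references must be fully labeled", call. = FALSE)
  }
  dist <- drop(projected_distances(model, matrix(query, nrow = 1L),
                                   references$values))
  keep <- order(dist)[seq_len(r)]  # stable: ties keep dataset order
  d_r <- dist[keep]
  lab_r <- as.character(references$label[keep])
  if (is.null(epsilon)) epsilon <- default_epsilon(d_r)
  w <- 1 / pmax(d_r, epsilon)
  structure(
    list(query_id = query_id,
         neighbors = data.frame(sample_id = references$sample_id[keep],
                                label = lab_r, distance = d_r, weight = w,
                                stringsAsFactors = FALSE),
         r = as.integer(r),
         Pq = sum(w[lab_r == "cold"]) / sum(w)),
    class = "retrieval_result"
  )
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> query '%s': Pq = %.4f over r = %d neighbors\n",
              x$query_id, x$Pq, x$r))
  print(x$neighbors, row.names = FALSE)
  invisible(x)
}

#' Classify query fingerprints against a labeled reference set
#'
#' End-to-end identification: for every query sample, retrieve the `r`
#' nearest labeled references under the learned metric, compute the cold
#' probability, and call the nature at the given threshold.
#'
#' @param model a `metric_model`.
#' @param queries a `fingerprint_dataset` (labels may be unknown).
#' @param references fully labeled `fingerprint_dataset`.
#' @param r number of retrieved neighbors.
#' @param threshold decision threshold on the cold probability.
#' @return data.frame with one row per query: `sample_id`, `Pq`,
#'   `predicted`, plus comma-joined neighbor ids and distances.
#' @export
classify_dataset <- function(model, queries, references, r = 7,
                             threshold = 0.5) {
  stopifnot(inherits(queries, "fingerprint_dataset"))
  rows <- lapply(seq_len(n_samples(queries)), function(i) {
    res <- retrieve(model, drop(queries$values[i, ]), references, r = r,
                    query_id = queries$sample_id[i])
    data.frame(sample_id = res$query_id, Pq = res$Pq,
               predicted = classify_nature(res$Pq, threshold),
               neighbor_ids = paste(res$neighbors$sample_id, collapse = ";"),
               neighbor_distances = paste(
                 formatC(res$neighbors$distance, digits = 6, format = "g"),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
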