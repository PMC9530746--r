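#' Confusion matrix and derived classification metrics
#'
#' Cold is the positive class. The confusion matrix has truth in rows and
#' prediction in columns, cold first. Per-class recall, precision and
#' F-score (the harmonic mean of the two) are reported for both classes,
#' together with the overall classification accuracy.
#'
#' @param truth,predicted character/factor vectors of `cold`/`hot` labels,
#'   equal length.
#' @return list with `confusion` (2 x 2 integer matrix), `recall`,
#'   `precision`, `f_score` (named numeric, `cold` and `hot`), and
#'   `accuracy`.
#' @export
#' @examples
#' confusion_metrics(rep(c("cold", "hot"), c(30, 31)),
#'                   rep(c("cold", "hot", "cold", "hot"), c(25, 5, 7, 24)))
confusion_metrics <- function(truth, predicted) {
  truth <- normalize_labels(truth)
  predicted <- normalize_labels(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (any(truth == "unknown") || any(predicted == "unknown")) {
    stop("labels must be cold or hot", call. = FALSE)
  }
  lev <- c("cold", "hot")
  confusion <- table(factor(truth, lev), factor(predicted, lev))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(truth = lev, predicted = lev))
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  f_score <- 2 * recall * precision / (recall + precision)
  list(confusion = confusion, recall = recall, precision = precision,
       f_score = f_score, accuracy = sum(diag(confusion)) / sum(confusion))
}

#' ROC curve and AUC over cold probabilities
#'
#' Sweeps the decision threshold over every distinct score (plus sentinels
#' forcing the (0,0) and (1,1) endpoints), predicting cold when the score is
#' at or above the threshold, with cold as the positive class. The AUC is the
#' trapezoid area over the stepwise curve, which equals the tie-corrected
#' Mann-Whitney concordance statistic.
#'
#' @param scores numeric cold probabilities in `[0, 1]`.
#' @param truth cold/hot labels, same length, both classes present.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`, descending
#'   thresholds) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- normalize_labels(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth must have equal length", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  pos <- truth == "cold"
  neg <- truth == "hot"
  if (!any(pos) || !any(neg)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), 0)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[neg] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Mean retrieval accuracy over queries
#'
#' For each query, the fraction of its retrieved neighbors whose nature label
#' matches the query's true label; the mean of these fractions over all
#' queries is the retrieval form of the accuracy.
#'
#' @param results list of `retrieval_result` objects.
#' @param truth true cold/hot label per query, same length as `results`.
#' @return mean per-query matching fraction in `[0, 1]`.
#' @export
retrieval_accuracy <- function(results, truth) {
  if (length(results) == 0L) stop("no retrieval results", call. = FALSE)
  truth <- as.character(normalize_labels(truth))
  if (length(truth) != length(results)) {
    stop("one truth label per retrieval result required", call. = FALSE)
  }
  fr <- vapply(seq_along(results), function(i) {
    mean(results[[i]]$neighbors$label == truth[i])
  }, numeric(1))
  mean(fr)
}

#' Pearson similarity between two fingerprints
#'
#' The Pearson correlation coefficient, the classical chromatographic
#' fingerprint similarity. The `pcc` retrieval baseline ranks references by
#' the dissimilarity `1 - pcc_similarity(x, y)`.
#'
#' @param x,y numeric vectors of equal length `>= 2`, non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pcc_similarity <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("vectors must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson similarity undefined for a constant fingerprint",
         call. = FALSE)
  }
  stats::cor(x, y)
}

# Query-to-reference distances for one baseline.
#  chnis     : learned metric (model required)
#  euclidean : plain Euclidean in the raw channel space
#  pcc       : 1 - Pearson correlation
baseline_distances <- function(baseline, query_values, ref_values,
                               model = NULL) {
  switch(baseline,
    chnis = projected_distances(model, query_values, ref_values),
    euclidean = projected_distances(identity_metric(ncol(ref_values)),
                                    query_values, ref_values),
    pcc = {
      D <- 1 - stats::cor(t(query_values), t(ref_values))
      D[D < 0] <- 0
      D
    },
    stop("unknown baseline '", baseline, "'", call. = FALSE))
}

# Rank references for one query given a distance row; returns a
# retrieval_result (stable ties by reference order).
rank_neighbors <- function(dist, references, r, query_id) {
  keep <- order(dist)[seq_len(r)]
  d_r <- dist[keep]
  lab_r <- as.character(references$label[keep])
  w <- 1 / pmax(d_r, default_epsilon(d_r))
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

# Assemble an evaluation report from per-query rows and retrieval results.
build_report <- function(protocol, per_query, results, replicate_stats = NULL) {
  cm <- confusion_metrics(per_query$truth, per_query$predicted)
  roc <- roc_auc(per_query$Pq, per_query$truth)
  structure(
    list(protocol = protocol, per_query = per_query,
         confusion = cm$confusion, recall = cm$recall,
         precision = cm$precision, f_score = cm$f_score,
         acc_classification = cm$accuracy,
         acc_retrieval = retrieval_accuracy(results, per_query$truth),
         roc = roc$roc, auc = roc$auc, replicate_stats = replicate_stats),
    class = "chnis_report"
  )
}

#' @export
print.chnis_report <- function(x, ...) {
  cat(sprintf("<chnis_report> protocol: %s, %d queries\n", x$protocol,
              nrow(x$per_query)))
  print(x$confusion)
  cat(sprintf("accuracy %.4f | retrieval accuracy %.4f | AUC %.4f\n",
              x$acc_classification, x$acc_retrieval, x$auc))
  if (!is.null(x$replicate_stats)) {
    rs <- x$replicate_stats
    cat(sprintf("over %d repeats: AUC %.3f +/- %.3f, ACC %.3f +/- %.3f\n",
                rs$n_repeats, rs$auc["mean"], rs$auc["sd"],
                rs$acc["mean"], rs$acc["sd"]))
  }
  invisible(x)
}

#' Leave-one-out stability evaluation
#'
#' Each sample in turn is held out as the query; for the learned-metric
#' scheme the metric is refit on the remaining `n - 1` samples, the `r`
#' nearest references are retrieved, the cold probability computed, and the
#' nature called at the threshold. All metrics are aggregated over the `n`
#' held-out predictions.
#'
#' @param dataset fully labeled `fingerprint_dataset`, `n >= 3`.
#' @param hyperparams [metric_hyperparams()] used for each fold's fit
#'   (`baseline = "chnis"` only).
#' @param r retrieved neighbors per query.
#' @param baseline `"chnis"` (learned metric), `"euclidean"`, or `"pcc"`.
#' @param threshold cold-probability decision threshold.
#' @param model optional fixed `metric_model`; when supplied with
#'   `baseline = "chnis"`, per-fold refitting is skipped and this
#'   transformation is used for every query (e.g. [identity_metric()] to
#'   check the Euclidean reduction).
#' @return a `chnis_report` with one per-query row per sample.
#' @export
stability_loo <- function(dataset, hyperparams = metric_hyperparams(), r = 7,
                          baseline = c("chnis", "euclidean", "pcc"),
                          threshold = 0.5, model = NULL) {
  stopifnot(inherits(dataset, "fingerprint_dataset"))
  baseline <- match.arg(baseline)
  n <- n_samples(dataset)
  if (n < 3L) stop("leave-one-out needs n >= 3", call. = FALSE)
  if (any(dataset$label == "unknown")) {
    stop("dataset must be fully labeled", call. = FALSE)
  }
  results <- vector("list", n)
  for (i in seq_len(n)) {
    refs <- dataset[-i]
    m <- NULL
    if (baseline == "chnis") {
      m <- if (is.null(model)) fit_metric(refs, hyperparams) else model
    }
    dist <- drop(baseline_distances(
      baseline, dataset$values[i, , drop = FALSE], refs$values, m))
    results[[i]] <- rank_neighbors(dist, refs, r, dataset$sample_id[i])
  }
  Pq <- vapply(results, `[[`, numeric(1), "Pq")
  per_query <- data.frame(
    sample_id = dataset$sample_id,
    truth = as.character(dataset$label),
    Pq = Pq,
    predicted = classify_nature(Pq, threshold),
    stringsAsFactors = FALSE
  )
  build_report("stability", per_query, results)
}

#' Repeated stratified-split extrapolation evaluation
#'
#' In each repeat, `n_train` samples are drawn as the labeled reference
#' (training) set — stratified so the class proportions carry over, about
#' half cold and half hot for a balanced source — the metric is fit on them,
#' and every remaining sample is scored against the training references.
#' AUC, classification accuracy and retrieval accuracy are computed per
#' repeat and summarized as mean and sample standard deviation; the pooled
#' per-query predictions across repeats form the report's confusion matrix
#' and ROC.
#'
#' @inheritParams stability_loo
#' @param n_train training-set size per repeat (`< n`).
#' @param n_repeats number of random splits.
#' @param seed integer seed making the split sequence reproducible.
#' @return a `chnis_report`; `replicate_stats` holds per-repeat summaries.
#' @export
extrapolation_split <- function(dataset, hyperparams = metric_hyperparams(),
                                r = 7, n_train = 40, n_repeats = 10,
                                seed = 1,
                                baseline = c("chnis", "euclidean", "pcc"),
                                threshold = 0.5) {
  stopifnot(inherits(dataset, "fingerprint_dataset"))
  baseline <- match.arg(baseline)
  n <- n_samples(dataset)
  if (n_train >= n) stop("n_train must be smaller than n", call. = FALSE)
  if (any(dataset$label == "unknown")) {
    stop("dataset must be fully labeled", call. = FALSE)
  }
  lab <- as.character(dataset$label)
  idx_cold <- which(lab == "cold")
  idx_hot <- which(lab == "hot")
  n_cold_train <- round(n_train * length(idx_cold) / n)
  n_hot_train <- n_train - n_cold_train
  if (n_cold_train < 1L || n_hot_train < 1L ||
      n_cold_train >= length(idx_cold) || n_hot_train >= length(idx_hot)) {
    stop("stratified split infeasible: both classes must appear in the ",
         "training and test sets", call. = FALSE)
  }
  set.seed(seed)
  all_rows <- list()
  all_results <- list()
  rep_auc <- rep_acc <- rep_ret <- numeric(n_repeats)
  for (b in seq_len(n_repeats)) {
    train <- sort(c(sample(idx_cold, n_cold_train),
                    sample(idx_hot, n_hot_train)))
    test <- setdiff(seq_len(n), train)
    refs <- dataset[train]
    m <- if (baseline == "chnis") fit_metric(refs, hyperparams) else NULL
    dist <- baseline_distances(baseline,
                               dataset$values[test, , drop = FALSE],
                               refs$values, m)
    results <- lapply(seq_along(test), function(j) {
      rank_neighbors(dist[j, ], refs, r, dataset$sample_id[test[j]])
    })
    Pq <- vapply(results, `[[`, numeric(1), "Pq")
    rows <- data.frame(
      repeat_ = b,
      sample_id = dataset$sample_id[test],
      truth = lab[test],
      Pq = Pq,
      predicted = classify_nature(Pq, threshold),
      stringsAsFactors = FALSE
    )
    rep_auc[b] <- roc_auc(rows$Pq, rows$truth)$auc
    rep_acc[b] <- mean(rows$predicted == rows$truth)
    rep_ret[b] <- retrieval_accuracy(results, rows$truth)
    all_rows[[b]] <- rows
    all_results <- c(all_results, results)
  }
  per_query <- do.call(rbind, all_rows)
  stats_pair <- function(v) c(mean = mean(v), sd = stats::sd(v))
  build_report("extrapolation", per_query, all_results,
               replicate_stats = list(
                 n_repeats = n_repeats, n_train = n_train,
                 n_test = n - n_train,
                 auc = stats_pair(rep_auc), acc = stats_pair(rep_acc),
                 acc_retrieval = stats_pair(rep_ret),
                 per_repeat = data.frame(repeat_ = seq_len(n_repeats),
                                         auc = rep_auc, acc = rep_acc,
                                         acc_retrieval = rep_ret)))
}

#' Hyperparameter sweep
#'
#' Evaluates the scheme over the Cartesian product of grids for the scatter
#' trade-off `lambda_`, the patch ridge penalty `mu`, and the retrieval
#' count `r`, under the chosen protocol. The default grids are the standard
#' log-spaced ranges for this method; sweep one parameter at a time (scalar
#' grids for the others) to reproduce the usual AUC/ACC curves.
#'
#' @inheritParams stability_loo
#' @param lambda_grid,mu_grid,r_grid numeric grids.
#' @param protocol `"stability"` (leave-one-out) or `"extrapolation"`.
#' @param ... further arguments passed to [extrapolation_split()] (e.g.
#'   `n_train`, `n_repeats`, `seed`).
#' @return data.frame with columns `lambda_`, `mu`, `r`, `auc`,
#'   `acc_classification`, `acc_retrieval`.
#' @export
parameter_sweep <- function(dataset,
                            lambda_grid = 10^seq(-8, 8, by = 2),
                            mu_grid = 10^(-3:5),
                            r_grid = c(1, 3, 5, 7, 10, 12, 15, 20),
                            protocol = c("stability", "extrapolation"),
                            hyperparams = metric_hyperparams(),
                            threshold = 0.5, ...) {
  protocol <- match.arg(protocol)
  grid <- expand.grid(lambda_ = lambda_grid, mu = mu_grid, r = r_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    hp <- metric_hyperparams(lambda_ = grid$lambda_[g], mu = grid$mu[g],
                             k_patch = hyperparams$k_patch,
                             u = hyperparams$u,
                             alignment_weight = hyperparams$alignment_weight)
    rpt <- if (protocol == "stability") {
      stability_loo(dataset, hp, r = grid$r[g], threshold = threshold)
    } else {
      extrapolation_split(dataset, hp, r = grid$r[g], threshold = threshold,
                          ...)
    }
    data.frame(lambda_ = grid$lambda_[g], mu = grid$mu[g], r = grid$r[g],
               auc = rpt$auc, acc_classification = rpt$acc_classification,
               acc_retrieval = rpt$acc_retrieval)
  })
  do.call(rbind, rows)
}

#' Write an evaluation report to disk
#'
#' Emits the per-query table and ROC points as CSV and the full report
#' (confusion matrix, per-class metrics, AUC, replicate summaries) as JSON.
#'
#' @param report a `chnis_report`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir, prefix = report$protocol) {
  stopifnot(inherits(report, "chnis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    per_query = file.path(dir, paste0(prefix, "_per_query.csv")),
    roc = file.path(dir, paste0(prefix, "_roc.csv")),
    summary = file.path(dir, paste0(prefix, "_report.json"))
  )
  utils::write.csv(report$per_query, paths["per_query"], row.names = FALSE)
  utils::write.csv(report$roc, paths["roc"], row.names = FALSE)
  summary <- list(
    protocol = report$protocol,
    confusion = as.data.frame(as.table(report$confusion)),
    recall = as.list(report$recall), precision = as.list(report$precision),
    f_score = as.list(report$f_score),
    acc_classification = report$acc_classification,
    acc_retrieval = report$acc_retrieval, auc = report$auc,
    replicate_stats = report$replicate_stats
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
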