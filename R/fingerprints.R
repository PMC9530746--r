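#' HPLC fingerprint datasets
#'
#' A fingerprint dataset holds the detector response of `n` herb samples over
#' `d` retention-time channels at a single UV wavelength, together with
#' per-sample metadata: a unique `sample_id`, a display `name`, and a binary
#' cold/hot nature label (`"unknown"` for unlabeled queries).
#'
#' @param values numeric matrix, `n` rows (samples) by `d` columns (channels);
#'   all entries finite and non-negative.
#' @param sample_id character vector of unique sample identifiers, length `n`.
#' @param name character vector of sample names, length `n` (defaults to
#'   `sample_id`).
#' @param label character vector in `c("cold", "hot", "unknown")`, length `n`;
#'   matched case-insensitively.
#' @param channel_grid optional numeric vector of retention times, length `d`.
#'
#' @return An object of class `fingerprint_dataset`: a list with elements
#'   `values` (n x d matrix), `sample_id`, `name`, `label` (factor with levels
#'   cold/hot/unknown) and `channel_grid` (or `NULL`).
#' @export
#' @examples
#' ds <- fingerprint_dataset(matrix(runif(20), 4, 5),
#'                           sample_id = paste0("s", 1:4),
#'                           label = c("cold", "cold", "hot", "hot"))
#' n_samples(ds); n_channels(ds)
fingerprint_dataset <- function(values, sample_id, name = sample_id,
                                label = "unknown", channel_grid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (n < 1L || d < 1L) {
    stop("dataset needs at least one sample and one channel", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("fingerprint values must be finite with no missing entries",
         call. = FALSE)
  }
  if (any(values < 0)) {
    stop("fingerprint values must be non-negative detector responses",
         call. = FALSE)
  }
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n) {
    stop("sample_id length must equal the number of rows", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  name <- rep_len(as.character(name), n)
  label <- normalize_labels(rep_len(as.character(label), n))
  if (!is.null(channel_grid)) {
    channel_grid <- as.numeric(channel_grid)
    if (length(channel_grid) != d) {
      stop("channel_grid length must equal the number of channels",
           call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_id, NULL)
  structure(
    list(values = values, sample_id = sample_id, name = name, label = label,
         channel_grid = channel_grid),
    class = "fingerprint_dataset"
  )
}

# Case-insensitive mapping onto the cold/hot/unknown vocabulary.
normalize_labels <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  bad <- !(lx %in% c("cold", "hot", "unknown"))
  if (any(bad)) {
    stop("unrecognized nature label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected cold, hot or unknown)", call. = FALSE)
  }
  factor(lx, levels = c("cold", "hot", "unknown"))
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<fingerprint_dataset> %d samples x %d channels (%s)\n",
              n_samples(x), n_channels(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of samples / channels in a dataset
#' @param dataset a `fingerprint_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$values)

#' @rdname n_samples
#' @export
n_channels <- function(dataset) ncol(dataset$values)

#' Subset a fingerprint dataset by sample
#' @param x a `fingerprint_dataset`.
#' @param i integer, logical or character (sample_id) index.
#' @param ... ignored.
#' @return a `fingerprint_dataset` with the selected samples.
#' @export
`[.fingerprint_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_id)
  if (anyNA(i)) stop("unknown sample_id in subset", call. = FALSE)
  fingerprint_dataset(x$values[i, , drop = FALSE],
                      sample_id = x$sample_id[i],
                      name = x$name[i],
                      label = as.character(x$label[i]),
                      channel_grid = x$channel_grid)
}

#' Read a fingerprint dataset from CSV/TSV
#'
#' The matrix file has one row per sample: first column `sample_id`, then one
#' numeric column per retention-time channel, and optionally `name` and
#' `label` columns. Labels may instead live in a separate metadata file with
#' columns `sample_id`, `name`, `label`, keyed by `sample_id`. If the channel
#' column headers parse as numbers they are kept as the retention-time grid.
#'
#' @param matrix_path path to the fingerprint matrix CSV/TSV.
#' @param metadata_path optional path to a metadata CSV/TSV.
#' @param sep field separator; inferred from the file extension by default
#'   (`.tsv`/`.txt` means tab).
#' @return a [fingerprint_dataset()].
#' @export
read_dataset <- function(matrix_path, metadata_path = NULL, sep = NULL) {
  raw <- read_delim_auto(matrix_path, sep)
  if (!"sample_id" %in% names(raw)) {
    stop("matrix file must have a sample_id column", call. = FALSE)
  }
  sample_id <- as.character(raw$sample_id)
  label_col <- if ("label" %in% names(raw)) as.character(raw$label) else NULL
  name_col <- if ("name" %in% names(raw)) as.character(raw$name) else NULL
  chan_cols <- setdiff(names(raw), c("sample_id", "name", "label"))
  if (length(chan_cols) == 0L) {
    stop("matrix file has no channel columns", call. = FALSE)
  }
  vals <- raw[chan_cols]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        stop("non-numeric value in channel column '", chan_cols[j], "'",
             call. = FALSE)
      }
      v <- num
    }
    if (anyNA(v)) {
      stop("missing value in channel column '", chan_cols[j], "'",
           call. = FALSE)
    }
    vals[[j]] <- v
  }
  values <- as.matrix(vals)
  grid <- suppressWarnings(as.numeric(sub("^[Xt]", "", chan_cols)))
  if (anyNA(grid)) grid <- NULL

  name <- if (!is.null(name_col)) name_col else sample_id
  label <- if (!is.null(label_col)) label_col else rep("unknown", length(sample_id))
  if (!is.null(metadata_path)) {
    meta <- read_delim_auto(metadata_path, sep)
    if (!all(c("sample_id", "label") %in% names(meta))) {
      stop("metadata file must have sample_id and label columns", call. = FALSE)
    }
    idx <- match(sample_id, as.character(meta$sample_id))
    if (anyNA(idx)) {
      stop("metadata missing sample_id(s): ",
           paste(sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    label <- as.character(meta$label)[idx]
    if ("name" %in% names(meta)) name <- as.character(meta$name)[idx]
  }
  fingerprint_dataset(values, sample_id = sample_id, name = name,
                      label = label, channel_grid = grid)
}

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

#' Write a fingerprint dataset to CSV/TSV
#'
#' Values are printed with 17 significant digits so the write/read round trip
#' is exact for IEEE doubles. Channel columns are headed by the retention-time
#' grid when present (prefixed `t`), else `ch1..chd`.
#'
#' @param dataset a `fingerprint_dataset`.
#' @param matrix_path output path for the matrix file.
#' @param metadata_path optional output path for a `sample_id,name,label`
#'   metadata file; when `NULL`, name and label columns are embedded in the
#'   matrix file.
#' @param sep field separator (default inferred from extension as in
#'   [read_dataset()]).
#' @return `matrix_path`, invisibly.
#' @export
write_dataset <- function(dataset, matrix_path, metadata_path = NULL,
                          sep = NULL) {
  stopifnot(inherits(dataset, "fingerprint_dataset"))
  if (n_samples(dataset) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", matrix_path, ignore.case = TRUE)) "\t" else ","
  }
  d <- n_channels(dataset)
  headers <- if (!is.null(dataset$channel_grid)) {
    paste0("t", formatC(dataset$channel_grid, digits = 17, format = "g"))
  } else {
    paste0("ch", seq_len(d))
  }
  vals <- apply(dataset$values, 2, formatC, digits = 17, format = "g")
  vals <- matrix(trimws(vals), nrow = n_samples(dataset))
  df <- data.frame(sample_id = dataset$sample_id, vals,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("sample_id", headers)
  if (is.null(metadata_path)) {
    df$name <- dataset$name
    df$label <- as.character(dataset$label)
  } else {
    meta <- data.frame(sample_id = dataset$sample_id, name = dataset$name,
                       label = as.character(dataset$label),
                       stringsAsFactors = FALSE)
    utils::write.table(meta, metadata_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  utils::write.table(df, matrix_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(matrix_path)
}

#' Normalize chromatograms within each sample
#'
#' `"none"` returns the dataset unchanged; `"total_area"` rescales every
#' sample to unit sum (relative peak-area profile); `"max_peak"` rescales to
#' unit maximum. Labels, ids and the channel grid are untouched.
#'
#' @param dataset a `fingerprint_dataset`.
#' @param method one of `"none"`, `"total_area"`, `"max_peak"`.
#' @return a `fingerprint_dataset`.
#' @export
preprocess <- function(dataset, method = c("none", "total_area", "max_peak")) {
  stopifnot(inherits(dataset, "fingerprint_dataset"))
  method <- match.arg(method)
  if (method == "none") return(dataset)
  denom <- switch(method,
                  total_area = rowSums(dataset$values),
                  max_peak = apply(dataset$values, 1, max))
  if (any(denom <= 0)) {
    stop("cannot ", method, "-normalize all-zero sample(s): ",
         paste(dataset$sample_id[denom <= 0], collapse = ", "), call. = FALSE)
  }
  out <- dataset
  out$values <- dataset$values / denom
  rownames(out$values) <- dataset$sample_id
  out
}

# Transposed view used by the metric-learning code: d x n, columns = samples.
fingerprint_matrix <- function(dataset) t(dataset$values)
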