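#' Construct a tabular dataset
#'
#' The container every stage of the pipeline consumes: a numeric feature
#' matrix with column names and a binary 0/1 target vector. Validation
#' enforces the invariants all downstream code relies on: no missing values,
#' both classes present, unique feature names matching the matrix columns.
#'
#' @param features numeric matrix (n rows x d features).
#' @param target integer/numeric vector of 0/1 labels, length n.
#' @param feature_names optional character vector; defaults to the matrix
#'   column names.
#' @return an object of class `tabular_dataset` with elements `features`,
#'   `target`, `feature_names`.
#' @export
tabular_dataset <- function(features, target, feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) {
    feature_names <- paste0("x", seq_len(ncol(features)))
  }
  target <- as.integer(target)
  if (length(target) != nrow(features)) {
    stop("validation error: target length (", length(target),
         ") does not match row count (", nrow(features), ")")
  }
  if (anyNA(features) || anyNA(target)) {
    stop("validation error: dataset contains missing values after loading")
  }
  if (!all(target %in% c(0L, 1L))) {
    stop("validation error: target must contain only 0 and 1")
  }
  if (length(unique(target)) < 2L) {
    stop("validation error: both target classes must be present")
  }
  if (length(feature_names) != ncol(features) || anyDuplicated(feature_names)) {
    stop("validation error: feature names must be unique and match column count")
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, target = target, feature_names = feature_names),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat("tabular_dataset:", nrow(x$features), "rows x", ncol(x$features),
      "features;", sum(x$target == 1L), "positive /", sum(x$target == 0L),
      "negative\n")
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$features)

#' Define a dataset schema
#'
#' Describes how a raw delimited file maps onto a [tabular_dataset()]:
#' which column is the outcome, which raw values map to the positive (1)
#' and negative (0) class, and per-column categorical encodings such as
#' famhist "Present"/"Absent" -> 1/0 or sex "Male"/"Female" -> 1/0.
#'
#' @param target_column name of the outcome column in the file.
#' @param positive_label,negative_label raw values mapped to 1 and 0. Default
#'   1/0 (already-numeric targets).
#' @param categorical_maps named list; each element is a named numeric vector
#'   mapping raw string values to integers for one feature column.
#' @param delimiter field separator, default ",".
#' @return object of class `dataset_schema`.
#' @export
dataset_schema <- function(target_column,
                           positive_label = "1", negative_label = "0",
                           categorical_maps = list(), delimiter = ",") {
  positive_label <- as.character(positive_label)
  negative_label <- as.character(negative_label)
  if (identical(positive_label, negative_label)) {
    stop("schema error: positive_label must differ from negative_label")
  }
  for (col in names(categorical_maps)) {
    m <- categorical_maps[[col]]
    if (anyDuplicated(m)) {
      stop("schema error: categorical map for '", col, "' is not injective")
    }
  }
  structure(
    list(target_column = target_column, positive_label = positive_label,
         negative_label = negative_label, categorical_maps = categorical_maps,
         delimiter = delimiter),
    class = "dataset_schema"
  )
}

#' Bundled schema registry
#'
#' Returns the shipped registry of schemas for the five public heart-disease
#' benchmark datasets (combined UCI, Z-AlizadehSani, Framingham, South
#' African heart, Cleveland UCI), so a user who downloads any of them needs
#' no manual column mapping. The registry also records the reported
#' total-feature-count discrepancy for Z-AlizadehSani (54 vs 53) without
#' resolving it.
#'
#' @param name optional registry entry name; if omitted the full registry
#'   list is returned.
#' @return a `dataset_schema` (if `name` given) or a named list of entries.
#' @export
schema_registry <- function(name = NULL) {
  path <- system.file("extdata", "schema_registry.json", package = "woafs")
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  build <- function(e) {
    maps <- lapply(e$categorical_maps, function(m) unlist(m))
    dataset_schema(e$target_column, e$positive_label, e$negative_label,
                   maps, e$delimiter)
  }
  if (is.null(name)) {
    return(lapply(reg, function(e) {
      out <- list(schema = build(e), notes = e$notes)
      out
    }))
  }
  if (!name %in% names(reg)) {
    stop("schema error: no registry entry named '", name, "'")
  }
  build(reg[[name]])
}

#' Load a delimited dataset under a schema
#'
#' Reads a CSV (header required), applies the schema's categorical
#' encodings and target labelling, drops rows with a missing target,
#' median-imputes remaining missing feature cells, and validates the result.
#' Both clean-up counts are reported via `attr(,"n_dropped_target")` and
#' `attr(,"n_imputed_cells")` and a message.
#'
#' @param path file path to a delimited text file with a header row.
#' @param schema a [dataset_schema()].
#' @return a [tabular_dataset()]; row order of the file is preserved.
#' @export
load_dataset <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = schema$delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", "", "?"), quote = "\"",
                           comment.char = "")
  if (!schema$target_column %in% names(raw)) {
    stop("schema error: target column '", schema$target_column,
         "' not present in ", path)
  }
  y_raw <- raw[[schema$target_column]]
  keep <- !is.na(y_raw)
  n_dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  y_raw <- y_raw[keep]

  y <- ifelse(y_raw == schema$positive_label, 1L,
              ifelse(y_raw == schema$negative_label, 0L, NA_integer_))
  if (anyNA(y)) {
    bad <- unique(y_raw[is.na(y)])
    stop("encoding error: target column '", schema$target_column,
         "' contains unmapped value(s): ", paste(bad, collapse = ", "))
  }

  feat_cols <- setdiff(names(raw), schema$target_column)
  X <- matrix(NA_real_, nrow(raw), length(feat_cols),
              dimnames = list(NULL, feat_cols))
  for (col in feat_cols) {
    v <- raw[[col]]
    if (col %in% names(schema$categorical_maps)) {
      m <- schema$categorical_maps[[col]]
      idx <- match(v, names(m))
      unmapped <- !is.na(v) & is.na(idx)
      if (any(unmapped)) {
        stop("encoding error: column '", col, "' has unmapped value '",
             v[which(unmapped)[1]], "'")
      }
      X[, col] <- as.numeric(m[idx])
    } else {
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(num)
      if (any(bad)) {
        stop("encoding error: column '", col, "' is non-numeric (value '",
             v[which(bad)[1]], "') and has no categorical map")
      }
      X[, col] <- num
    }
  }

  n_imputed <- sum(is.na(X))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- stats::median(X[, j], na.rm = TRUE)
    }
  }
  if (n_dropped > 0 || n_imputed > 0) {
    message("load_dataset: dropped ", n_dropped, " rows with missing target; ",
            "median-imputed ", n_imputed, " feature cells")
  }
  ds <- tabular_dataset(X, y)
  attr(ds, "n_dropped_target") <- n_dropped
  attr(ds, "n_imputed_cells") <- n_imputed
  ds
}

#' Write a dataset back to CSV
#'
#' Canonical writer: feature columns in order, then the target column.
#' Round-trips through [load_dataset()] with a plain numeric schema.
#'
#' @param ds a [tabular_dataset()].
#' @param path output file path.
#' @param target_column name of the written target column.
#' @export
write_dataset_csv <- function(ds, path, target_column = "target") {
  df <- as.data.frame(ds$features, check.names = FALSE)
  df[[target_column]] <- ds$target
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Deterministic, class-stratified partition. The number of test rows per
#' class is `round(test_fraction * n_class)`, keeping each partition's class
#' proportion within one row of the overall proportion. Row order of the
#' original dataset is preserved within both partitions so that downstream
#' fold assignment is reproducible.
#'
#' @param ds a [tabular_dataset()].
#' @param test_fraction fraction of rows held out, in (0,1). Default 0.2.
#' @param seed integer RNG seed controlling which rows are held out.
#' @return list with elements `train` and `test` (both `tabular_dataset`)
#'   and `test_rows`, the original row indices of the test partition.
#' @export
stratified_split <- function(ds, test_fraction = 0.2, seed = 0L) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("validation error: test_fraction must be in (0,1)")
  }
  test_idx <- integer(0)
  rng <- local_rng(seed)
  for (cls in c(0L, 1L)) {
    rows <- which(ds$target == cls)
    n_test <- round(test_fraction * length(rows))
    if (n_test < 1L || n_test >= length(rows)) {
      stop("validation error: split leaves class ", cls,
           " without rows in one partition (", length(rows), " rows, ",
           n_test, " to test)")
    }
    test_idx <- c(test_idx, rng$sample(rows, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(ds$features)), test_idx)
  list(
    train = tabular_dataset(ds$features[train_idx, , drop = FALSE],
                            ds$target[train_idx], ds$feature_names),
    test = tabular_dataset(ds$features[test_idx, , drop = FALSE],
                           ds$target[test_idx], ds$feature_names),
    test_rows = test_idx
  )
}
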