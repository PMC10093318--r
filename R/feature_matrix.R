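#' Feature matrix container
#'
#' Bundles an n_samples x n_features numeric matrix with sample identifiers,
#' class labels and feature names carrying provenance tags (e.g. `lbp:f0000`,
#' `deep:filterbank:0001`). All pipeline stages exchange this container.
#'
#' @param values numeric matrix, samples in rows.
#' @param sample_ids character vector, one unique id per row.
#' @param labels character vector of class names, one per row.
#' @param feature_names character vector, one per column.
#' @return An object of class `urised_features`.
#' @export
feature_matrix <- function(values, sample_ids, labels, feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(values)) - 1L)
  }
  if (nrow(values) != length(sample_ids) || nrow(values) != length(labels)) {
    stop("row count must equal the number of sample_ids and labels")
  }
  if (ncol(values) != length(feature_names)) {
    stop("column count must equal the number of feature_names")
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature matrix contains missing or non-finite values")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         labels = as.character(labels), feature_names = as.character(feature_names)),
    class = "urised_features"
  )
}

#' @export
dim.urised_features <- function(x) dim(x$values)

#' @export
print.urised_features <- function(x, ...) {
  cat(sprintf("<urised_features> %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' @export
as.matrix.urised_features <- function(x, ...) x$values

#' Write / read a feature matrix as CSV
#'
#' Canonical on-disk form: header `sample_id,label,<feature names>`, one row
#' per sample. Reading restores an identical [feature_matrix()].
#'
#' @param fm a `urised_features` object.
#' @param path CSV file path.
#' @export
write_features <- function(fm, path) {
  dt <- data.table::data.table(sample_id = fm$sample_ids, label = fm$labels)
  dt <- cbind(dt, data.table::as.data.table(fm$values))
  data.table::setnames(dt, c("sample_id", "label", fm$feature_names))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("sample_id", "label")))
  vals <- as.matrix(dt[, -(1:2)])
  feature_matrix(vals, dt$sample_id, dt$label, colnames(vals))
}
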