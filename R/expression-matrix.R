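#' Cells-by-features expression matrix
#'
#' The container every stage of the package consumes: a numeric matrix with
#' cells as rows and features (genes, proteins, primers) as columns, plus a
#' modality tag and a flag recording whether per-feature means have been
#' removed. Units depend on modality: Ct-derived log-fold units (`qpcr`),
#' arcsinh-transformed ion counts (`cytof`), or log2 molecule counts
#' (`rnaseq`).
#'
#' @param values numeric matrix, cells x features.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames, then "cell_1", ...).
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to colnames, then "f_1", ...).
#' @param modality one of `"qpcr"`, `"cytof"`, `"rnaseq"`, `"generic"`.
#' @param centered logical; `TRUE` if every column mean is (numerically) zero.
#' @param precenter optional matrix of the same shape holding values on the
#'   pre-centering scale, kept so that expression totals remain meaningful
#'   after centering (used by [filter_low_expression()]).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                              modality = c("generic", "qpcr", "cytof", "rnaseq"),
                              centered = FALSE, precenter = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f_", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) must equal nrow(values)")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length(feature_ids) must equal ncol(values)")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at cell %s, feature %s (resolve missing data in preprocessing)",
                 cell_ids[idx[1]], feature_ids[idx[2]]))
  }
  dimnames(values) <- list(cell_ids, feature_ids)
  if (!is.null(precenter)) {
    precenter <- as.matrix(precenter)
    stopifnot(all(dim(precenter) == dim(values)))
    dimnames(precenter) <- dimnames(values)
  }
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality, centered = centered, precenter = precenter),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d features [%s%s]\n",
              nrow(x$values), ncol(x$values), x$modality,
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Coerce to ExpressionMatrix
#'
#' Plain matrices (and data frames) pass through [expression_matrix()] with
#' default ids; ExpressionMatrix objects are returned unchanged.
#' @param x matrix, data.frame or ExpressionMatrix.
#' @return An `ExpressionMatrix`.
#' @export
as_expression_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) return(x)
  expression_matrix(as.matrix(x))
}

#' Subset an ExpressionMatrix
#'
#' @param x ExpressionMatrix.
#' @param i,j cell and feature indices (any standard matrix index).
#' @param ... ignored.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE],
                    modality = x$modality, centered = x$centered,
                    precenter = if (!is.null(x$precenter)) x$precenter[i, j, drop = FALSE])
}

#' Remove per-feature means
#'
#' @param mat ExpressionMatrix (or matrix).
#' @return ExpressionMatrix with every column mean zero and `centered = TRUE`.
#'   The pre-centering values are retained in the `precenter` field unless
#'   already present.
#' @export
center_features <- function(mat) {
  mat <- as_expression_matrix(mat)
  pre <- if (is.null(mat$precenter)) mat$values else mat$precenter
  v <- sweep(mat$values, 2, colMeans(mat$values))
  expression_matrix(v, mat$cell_ids, mat$feature_ids, mat$modality,
                    centered = TRUE, precenter = pre)
}

#' Read an expression matrix from CSV
#'
#' Expects a header row of feature ids and a first column of cell ids
#' (UTF-8, "." decimal). Set `features_as_rows = TRUE` for the transposed
#' orientation.
#'
#' @param path path to a CSV file.
#' @param features_as_rows logical; if `TRUE` rows are features and columns
#'   are cells.
#' @param modality modality tag for the result.
#' @param centered logical flag recorded on the result (use when the file
#'   holds already-centered values, e.g. a processed dataset).
#' @return An `ExpressionMatrix`.
#' @export
read_matrix <- function(path, features_as_rows = FALSE,
                        modality = "generic", centered = FALSE) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        fill = FALSE, fileEncoding = "UTF-8")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric entry in %s near row %d, column %d",
                 path, bad[1, 1] + 1L, bad[1, 2] + 1L))
  }
  rownames(m) <- ids
  if (features_as_rows) m <- t(m)
  expression_matrix(m, modality = modality, centered = centered)
}

#' Write an ExpressionMatrix to CSV
#'
#' Round-trips with [read_matrix()] up to float formatting.
#'
#' @param mat ExpressionMatrix.
#' @param path output path.
#' @param features_as_rows write transposed orientation.
#' @export
write_matrix <- function(mat, path, features_as_rows = FALSE) {
  mat <- as_expression_matrix(mat)
  m <- if (features_as_rows) t(mat$values) else mat$values
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (features_as_rows) "feature" else "cell"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
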