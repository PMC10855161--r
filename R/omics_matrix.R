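#' Construct an omics matrix
#'
#' Light container for one omics block: a subjects x features numeric matrix
#' with unique subject IDs (rows) and feature names (columns), plus the name
#' of the omics type (e.g. \code{"mrna"}, \code{"methylation"}, \code{"mirna"}).
#'
#' @param values Numeric matrix, subjects in rows, features in columns.
#' @param subject_ids Character vector of unique subject identifiers; defaults
#'   to existing rownames.
#' @param feature_names Character vector of unique feature names; defaults to
#'   existing colnames.
#' @param omics_name Single string naming the omics type.
#' @return An object of class \code{omics_matrix}.
#' @export
omics_matrix <- function(values, subject_ids = rownames(values),
                         feature_names = colnames(values),
                         omics_name = "omics") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  subject_ids <- as.character(subject_ids)
  feature_names <- as.character(feature_names)
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length does not match row count")
  if (length(feature_names) != ncol(values))
    stop("feature_names length does not match column count")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  if (anyNA(values)) stop("omics matrix contains missing values")
  dimnames(values) <- list(subject_ids, feature_names)
  structure(list(values = values, omics_name = as.character(omics_name)[1]),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s': %d subjects x %d features>\n",
              x$omics_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subject IDs of an omics matrix
#' @param x An \code{omics_matrix}.
#' @return Character vector of subject IDs.
#' @export
subject_ids <- function(x) rownames(x$values)

#' Feature names of an omics matrix
#' @param x An \code{omics_matrix}.
#' @return Character vector of feature names.
#' @export
feature_names <- function(x) colnames(x$values)

# internal: subset subjects/features, keeping the class
subset_omics <- function(x, subjects = NULL, features = NULL) {
  v <- x$values
  if (!is.null(subjects)) v <- v[subjects, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  omics_matrix(v, omics_name = x$omics_name)
}

#' Read an omics matrix from delimited text
#'
#' Expects a header row of feature names and a first column of subject IDs
#' (CSV or TSV, sniffed from the extension).
#'
#' @param path Path to a CSV/TSV file.
#' @param omics_name Omics-type label; defaults to the file stem.
#' @return An \code{omics_matrix}.
#' @export
read_omics_csv <- function(path, omics_name = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(omics_name))
    omics_name <- sub("\\.[^.]*$", "", basename(path))
  omics_matrix(as.matrix(df), omics_name = omics_name)
}

#' Write an omics matrix as CSV
#' @param x An \code{omics_matrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_omics_csv <- function(x, path) {
  df <- data.frame(subject_id = subject_ids(x), x$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
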