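#' Construct a validated dataset
#'
#' Bundles a predictor table, a binary outcome and a [feature_schema()].
#' Validation is strict: missing values are rejected (the package's
#' contract is complete-case input), every categorical cell must be a
#' declared level, and the outcome must be coded 0/1.
#'
#' @param features data frame of predictors, columns matching the schema.
#' @param outcome vector coercible to 0/1, length `nrow(features)`.
#' @param schema an `rr_schema`; inferred with [infer_schema()] if `NULL`.
#' @return an object of class `rr_dataset` with elements `features`
#'   (data frame, character categorical columns), `outcome` (integer
#'   0/1) and `schema`.
#' @export
as_dataset <- function(features, outcome, schema = NULL) {
  stopifnot(is.data.frame(features))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(schema)) schema <- infer_schema(features)
  stopifnot(inherits(schema, "rr_schema"))
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(features))
  if (length(missing_cols)) {
    stop("features are missing schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  features <- features[, nms, drop = FALSE]

  out <- validate_outcome(outcome)
  if (length(out) != nrow(features)) {
    stop("outcome length (", length(out), ") != number of rows (",
         nrow(features), ")", call. = FALSE)
  }

  # reject missing values, naming the offending cells
  na_cells <- which(is.na(features), arr.ind = TRUE)
  if (nrow(na_cells)) {
    show <- utils::head(na_cells, 5L)
    stop("missing values are not allowed (complete-case contract); ",
         "first offending cells: ",
         paste(sprintf("row %d, column '%s'", show[, 1],
                       names(features)[show[, 2]]), collapse = "; "),
         call. = FALSE)
  }

  for (f in schema) {
    x <- features[[f$name]]
    if (f$kind == "continuous") {
      if (!is.numeric(x)) {
        stop("continuous feature '", f$name, "' is not numeric",
             call. = FALSE)
      }
    } else {
      x <- as.character(x)
      bad <- setdiff(unique(x), f$levels)
      if (length(bad)) {
        stop("feature '", f$name, "' contains undeclared level(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      features[[f$name]] <- x
    }
  }
  rownames(features) <- NULL
  structure(list(features = features, outcome = out, schema = schema),
            class = "rr_dataset")
}

validate_outcome <- function(outcome) {
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (is.factor(outcome)) outcome <- as.character(outcome)
  if (is.character(outcome)) {
    if (!all(outcome %in% c("0", "1"))) {
      stop("outcome is not coercible to {0, 1}", call. = FALSE)
    }
    outcome <- as.integer(outcome)
  }
  if (anyNA(outcome)) stop("outcome contains missing values", call. = FALSE)
  if (!is.numeric(outcome) || !all(outcome %in% c(0, 1))) {
    stop("outcome is not coercible to {0, 1}", call. = FALSE)
  }
  as.integer(outcome)
}

#' Read a dataset from a delimited file
#'
#' Reads a comma-delimited UTF-8 file with a header row, splits off the
#' outcome column and validates the rest against `schema` (inferred when
#' absent; the inference is reported via `message()` so it lands in the
#' run log).
#'
#' @param path CSV file path.
#' @param outcome_name name of the binary outcome column.
#' @param schema optional `rr_schema` (or path to a schema file).
#' @return an `rr_dataset`.
#' @export
read_dataset <- function(path, outcome_name, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (!outcome_name %in% names(df)) {
    stop("outcome column '", outcome_name, "' not found in ", path,
         call. = FALSE)
  }
  outcome <- df[[outcome_name]]
  feats <- df[, setdiff(names(df), outcome_name), drop = FALSE]
  if (is.character(schema)) schema <- read_schema(schema)
  if (is.null(schema)) {
    schema <- infer_schema(feats)
    kinds <- schema_kinds(schema)
    message("schema inferred from data (>10 distinct numeric values => ",
            "continuous): ", sum(kinds == "continuous"), " continuous, ",
            sum(kinds == "categorical"), " categorical")
  }
  as_dataset(feats, outcome, schema)
}

#' @export
print.rr_dataset <- function(x, ...) {
  cat("<rr_dataset> ", nrow(x$features), " rows x ", ncol(x$features),
      " predictors; outcome prevalence ",
      sprintf("%.3f", mean(x$outcome)), "\n", sep = "")
  invisible(x)
}

# Row subset of a dataset, preserving the schema (no re-validation needed:
# a subset of valid rows is valid).
dataset_slice <- function(data, idx) {
  structure(list(features = data$features[idx, , drop = FALSE],
                 outcome = data$outcome[idx],
                 schema = data$schema),
            class = "rr_dataset")
}

n_rows <- function(data) length(data$outcome)
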