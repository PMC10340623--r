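#' Dummy-code a dataset
#'
#' Builds the model matrix shared by every model family: continuous
#' columns are copied (optionally centred and scaled with sample, n-1,
#' statistics), and each categorical feature with L levels contributes
#' exactly L-1 indicator columns with the reference level dropped.
#' Column provenance is recorded in `column_map` so every encoded column
#' maps back to exactly one source feature.
#'
#' @param data an `rr_dataset`.
#' @param standardize centre/scale continuous columns (default `FALSE`).
#'   A constant continuous column under standardization is an error.
#' @return an object of class `rr_encoded`: list with `values` (numeric
#'   matrix), `column_map` (data frame: `column`, `feature`, `level`,
#'   `parent1`, `parent2`) and `standardization` (data frame of per-column
#'   `center`/`scale`, or `NULL`).
#' @export
dummy_encode <- function(data, standardize = FALSE) {
  stopifnot(inherits(data, "rr_dataset"))
  enc <- encode_features(data$features, data$schema)
  std <- NULL
  if (standardize) {
    cont <- enc$column_map$column[is.na(enc$column_map$level)]
    center <- colMeans(enc$values[, cont, drop = FALSE])
    scale <- apply(enc$values[, cont, drop = FALSE], 2, stats::sd)
    if (any(scale == 0)) {
      stop("constant column(s) under standardization: ",
           paste(cont[scale == 0], collapse = ", "), call. = FALSE)
    }
    enc$values[, cont] <- scale(enc$values[, cont, drop = FALSE],
                                center = center, scale = scale)
    std <- data.frame(column = cont, center = unname(center),
                      scale = unname(scale), stringsAsFactors = FALSE)
  }
  structure(list(values = enc$values, column_map = enc$column_map,
                 standardization = std),
            class = "rr_encoded")
}

# Core encoder used by dummy_encode() and by model predict paths:
# feature data frame + schema -> base (unstandardized) matrix + map.
encode_features <- function(features, schema) {
  cols <- list()
  map <- list()
  for (f in schema) {
    x <- features[[f$name]]
    if (f$kind == "continuous") {
      cols[[f$name]] <- as.numeric(x)
      map[[length(map) + 1L]] <- data.frame(
        column = f$name, feature = f$name, level = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      x <- as.character(x)
      keep <- setdiff(f$levels, f$reference)
      for (lv in keep) {
        cn <- paste(f$name, lv, sep = ".")
        cols[[cn]] <- as.numeric(x == lv)
        map[[length(map) + 1L]] <- data.frame(
          column = cn, feature = f$name, level = lv,
          stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  column_map <- do.call(rbind, map)
  column_map$parent1 <- NA_character_
  column_map$parent2 <- NA_character_
  rownames(column_map) <- NULL
  list(values = values, column_map = column_map)
}

#' @export
print.rr_encoded <- function(x, ...) {
  cat("<rr_encoded> ", nrow(x$values), " x ", ncol(x$values),
      " model matrix", if (!is.null(x$standardization)) " (standardized)",
      "\n", sep = "")
  invisible(x)
}

#' Append all two-way product columns
#'
#' Expands an encoded matrix with all m(m-1)/2 elementwise products of
#' distinct columns, so that penalized models can represent every two-way
#' interaction.  Product columns record both parent columns in the
#' column map.
#'
#' @param enc an `rr_encoded` (or a bare numeric matrix).
#' @param cap maximum permitted total width; exceeding it is an error
#'   advising the screening mode instead.
#' @return an `rr_encoded` with the product columns appended.
#' @export
expand_interactions <- function(enc, cap = 10000L) {
  if (is.matrix(enc)) {
    enc <- structure(list(values = enc,
                          column_map = data.frame(
                            column = colnames(enc), feature = colnames(enc),
                            level = NA_character_, parent1 = NA_character_,
                            parent2 = NA_character_, stringsAsFactors = FALSE),
                          standardization = NULL),
                     class = "rr_encoded")
  }
  m <- ncol(enc$values)
  total <- m + m * (m - 1L) / 2L
  if (total > cap) {
    stop("expanded matrix would have ", total, " columns (cap ", cap,
         "); consider the screened interaction mode instead", call. = FALSE)
  }
  if (m < 2L) return(enc)
  pairs <- utils::combn(m, 2L)
  prod_cols <- enc$values[, pairs[1L, ], drop = FALSE] *
    enc$values[, pairs[2L, ], drop = FALSE]
  p1 <- colnames(enc$values)[pairs[1L, ]]
  p2 <- colnames(enc$values)[pairs[2L, ]]
  colnames(prod_cols) <- paste(p1, p2, sep = ":")
  add_map <- data.frame(column = colnames(prod_cols),
                        feature = NA_character_, level = NA_character_,
                        parent1 = p1, parent2 = p2, stringsAsFactors = FALSE)
  structure(list(values = cbind(enc$values, prod_cols),
                 column_map = rbind(enc$column_map, add_map),
                 standardization = enc$standardization),
            class = "rr_encoded")
}
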