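#' Feature schema
#'
#' Declares, for every predictor, whether it is continuous or categorical,
#' and for categorical predictors the ordered set of levels and the
#' reference level dropped during dummy coding.
#'
#' @param features a list of per-feature records, each a list with
#'   elements `name` (string), `kind` (`"continuous"` or `"categorical"`),
#'   and for categorical features `levels` (character vector, length >= 2)
#'   and optionally `reference` (defaults to the first level in sorted
#'   order).
#' @return an object of class `rr_schema`.
#' @export
feature_schema <- function(features) {
  stopifnot(is.list(features), length(features) >= 1L)
  feats <- lapply(features, function(f) {
    if (is.null(f$name) || !nzchar(f$name)) {
      stop("every schema feature needs a non-empty name", call. = FALSE)
    }
    kind <- match.arg(f$kind, c("continuous", "categorical"))
    if (kind == "categorical") {
      lv <- as.character(f$levels)
      if (length(lv) < 2L || anyDuplicated(lv)) {
        stop("categorical feature '", f$name,
             "' needs >= 2 distinct levels", call. = FALSE)
      }
      ref <- as.character(f$reference %||% sort(lv)[1L])
      if (!ref %in% lv) {
        stop("reference level '", ref, "' of '", f$name,
             "' is not a declared level", call. = FALSE)
      }
      list(name = f$name, kind = kind, levels = lv, reference = ref)
    } else {
      if (!is.null(f$levels)) {
        stop("continuous feature '", f$name, "' must not declare levels",
             call. = FALSE)
      }
      list(name = f$name, kind = kind)
    }
  })
  nms <- vapply(feats, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate feature names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(feats) <- nms
  structure(feats, class = "rr_schema")
}

#' @export
print.rr_schema <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat("<rr_schema> ", length(x), " features (",
      sum(kinds == "continuous"), " continuous, ",
      sum(kinds == "categorical"), " categorical)\n", sep = "")
  invisible(x)
}

schema_names <- function(schema) {
  unname(vapply(schema, `[[`, character(1), "name"))
}

schema_kinds <- function(schema) {
  vapply(schema, `[[`, character(1), "kind")
}

#' Infer a schema from a data frame
#'
#' Numeric columns with more than `max_discrete` distinct values become
#' continuous; everything else becomes categorical with sorted observed
#' values as levels and the first sorted level as reference.  An explicit
#' schema always takes precedence over inference.
#'
#' @param df data frame of predictors.
#' @param max_discrete distinct-value threshold above which a numeric
#'   column is treated as continuous (default 10).
#' @return an `rr_schema`.
#' @export
infer_schema <- function(df, max_discrete = 10L) {
  feats <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > max_discrete) {
      list(name = nm, kind = "continuous")
    } else {
      lv <- sort(unique(as.character(x[!is.na(x)])))
      if (length(lv) < 2L) {
        # constant column: keep it continuous if numeric so validation can
        # still pass; a constant categorical with one level is unusable
        if (is.numeric(x)) return(list(name = nm, kind = "continuous"))
        stop("column '", nm, "' is constant and non-numeric; ",
             "cannot infer a usable kind", call. = FALSE)
      }
      list(name = nm, kind = "categorical", levels = lv, reference = lv[1L])
    }
  })
  feature_schema(feats)
}

#' Read / write a schema file
#'
#' Schemas are stored as YAML: a top-level `features` list with `name`,
#' `kind`, `levels` and `reference` entries.
#'
#' @param path file path.
#' @return `read_schema` returns an `rr_schema`.
#' @export
read_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  feature_schema(obj$features %||% obj)
}

#' @rdname read_schema
#' @param schema an `rr_schema` to serialize.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "rr_schema"))
  feats <- lapply(unname(schema), function(f) f[!vapply(f, is.null, TRUE)])
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}
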