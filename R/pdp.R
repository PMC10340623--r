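# --- partial dependence -----------------------------------------------
#
# PDPs are computed on the model's prediction scale (probabilities for
# the native families).  For native models the substitution happens in
# the encoded matrix (categorical grid values flip the whole indicator
# block); manual models are handled in raw feature space.  Both are
# equivalent because encoding is columnwise.

# Prediction from a feature data frame without schema re-validation.
predict_features <- function(model, df) {
  if (model$family == "manual") return(as.numeric(model$fit(df)))
  predict_base(model, encode_features(df, model$schema)$values)
}

#' Evaluation grid for one variable
#'
#' Continuous features get `grid_size` equally spaced sample quantiles
#' (type 7), trimmed by default to the 1st-99th percentile so outliers do
#' not stretch the grid; categorical features get all declared levels.
#'
#' @param data an `rr_dataset`.
#' @param variable feature name.
#' @param grid_size number of quantile points (continuous only).
#' @param trim lower/upper percentile trim for continuous grids.
#' @return numeric or character vector of grid values.
#' @export
variable_grid <- function(data, variable, grid_size = 20L,
                          trim = c(0.01, 0.99)) {
  f <- data$schema[[variable]]
  if (is.null(f)) stop("unknown variable: ", variable, call. = FALSE)
  if (f$kind == "categorical") return(f$levels)
  x <- data$features[[variable]]
  g <- stats::quantile(x, seq(trim[1], trim[2], length.out = grid_size),
                       type = 7, names = FALSE)
  unique(g)
}

# Substitute grid value `v` for `variable` in an encoded base matrix
# (in place on a copy): continuous -> set the column; categorical level
# -> set the indicator block.
substitute_encoded <- function(X0, schema, variable, v) {
  f <- schema[[variable]]
  if (f$kind == "continuous") {
    X0[, variable] <- as.numeric(v)
  } else {
    for (lv in setdiff(f$levels, f$reference)) {
      X0[, paste(variable, lv, sep = ".")] <- as.numeric(lv == v)
    }
  }
  X0
}

# Mean prediction at each grid value; rows_X0 / rows_df hold the
# (possibly subsampled) evaluation rows in both representations.
pdp_means <- function(model, data, variable, grid, rows_df, rows_X0) {
  n <- nrow(rows_df)
  if (model$family == "manual") {
    stacked <- rows_df[rep(seq_len(n), length(grid)), , drop = FALSE]
    stacked[[variable]] <- rep(grid, each = n)
    p <- predict_features(model, stacked)
  } else {
    blocks <- lapply(grid, function(v) {
      substitute_encoded(rows_X0, data$schema, variable, v)
    })
    p <- predict_base(model, do.call(rbind, blocks))
  }
  colMeans(matrix(p, nrow = n))
}

pdp_rows <- function(data, subsample = NULL, seed = 1L) {
  n <- n_rows(data)
  idx <- seq_len(n)
  if (!is.null(subsample) && subsample < n) {
    idx <- with_seed(derive_seed(seed, "pdp_subsample"),
                     sort(sample(n, subsample)))
  }
  idx
}

#' One-dimensional partial dependence
#'
#' For each grid value v, the variable is set to v in every evaluation
#' row and the model's predictions are averaged.
#'
#' @param model an `rr_model`.
#' @param data the `rr_dataset` providing the evaluation rows (and the
#'   quantile grid).
#' @param variable feature name.
#' @param grid optional explicit grid; otherwise equally spaced sample
#'   quantiles (continuous) or all levels (categorical).
#' @param grid_size,trim continuous-grid resolution and percentile trim.
#' @param subsample optional number of evaluation rows to subsample
#'   (seeded); default uses all rows.
#' @param seed seed for the row subsample.
#' @return data frame with columns `variable`, `value`, `yhat`.
#' @export
pdp_1d <- function(model, data, variable, grid = NULL, grid_size = 20L,
                   trim = c(0.01, 0.99), subsample = NULL, seed = 1L) {
  stopifnot(inherits(model, "rr_model"), inherits(data, "rr_dataset"))
  if (is.null(grid)) grid <- variable_grid(data, variable, grid_size, trim)
  idx <- pdp_rows(data, subsample, seed)
  rows_df <- data$features[idx, , drop = FALSE]
  rows_X0 <- if (model$family == "manual") NULL else
    encode_features(rows_df, model$schema)$values
  yhat <- pdp_means(model, data, variable, grid, rows_df, rows_X0)
  out <- data.frame(variable = variable, value = grid, yhat = yhat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-dimensional partial dependence
#'
#' Joint substitution of two variables over the product grid, averaging
#' predictions over the evaluation rows for each grid cell.
#'
#' @inheritParams pdp_1d
#' @param var_a,var_b two distinct feature names.
#' @param grid_a,grid_b optional explicit grids.
#' @return list of class `rr_pdp2`: grids, and `values`, a
#'   `length(grid_a) x length(grid_b)` matrix of mean predictions.
#' @export
pdp_2d <- function(model, data, var_a, var_b, grid_a = NULL, grid_b = NULL,
                   grid_size = 10L, trim = c(0.01, 0.99), subsample = NULL,
                   seed = 1L) {
  stopifnot(inherits(model, "rr_model"), inherits(data, "rr_dataset"))
  if (identical(var_a, var_b)) {
    stop("pdp_2d needs two distinct variables", call. = FALSE)
  }
  if (is.null(grid_a)) grid_a <- variable_grid(data, var_a, grid_size, trim)
  if (is.null(grid_b)) grid_b <- variable_grid(data, var_b, grid_size, trim)
  idx <- pdp_rows(data, subsample, seed)
  rows_df <- data$features[idx, , drop = FALSE]
  n <- nrow(rows_df)
  cells <- expand.grid(a = seq_along(grid_a), b = seq_along(grid_b))
  if (model$family == "manual") {
    stacked <- rows_df[rep(seq_len(n), nrow(cells)), , drop = FALSE]
    stacked[[var_a]] <- rep(grid_a[cells$a], each = n)
    stacked[[var_b]] <- rep(grid_b[cells$b], each = n)
    p <- predict_features(model, stacked)
  } else {
    rows_X0 <- encode_features(rows_df, model$schema)$values
    blocks <- lapply(seq_len(nrow(cells)), function(i) {
      X <- substitute_encoded(rows_X0, data$schema, var_a, grid_a[cells$a[i]])
      substitute_encoded(X, data$schema, var_b, grid_b[cells$b[i]])
    })
    p <- predict_base(model, do.call(rbind, blocks))
  }
  means <- colMeans(matrix(p, nrow = n))
  values <- matrix(means, nrow = length(grid_a), ncol = length(grid_b))
  structure(list(var_a = var_a, var_b = var_b, grid_a = grid_a,
                 grid_b = grid_b, values = values,
                 kind_a = data$schema[[var_a]]$kind,
                 kind_b = data$schema[[var_b]]$kind),
            class = "rr_pdp2")
}

#' @export
print.rr_pdp2 <- function(x, ...) {
  cat("<rr_pdp2> ", x$var_a, " x ", x$var_b, ": ",
      length(x$grid_a), " x ", length(x$grid_b), " grid\n", sep = "")
  invisible(x)
}

#' PDP-based two-way interaction strength
#'
#' From the two-dimensional partial dependence surface: for each grid
#' value of b, take the dispersion of the conditional curve over a
#' (sample sd for continuous a, (max - min)/4 for categorical a); the
#' conditional importance i(a|b) is the sample sd of those dispersions
#' over b's grid.  i(b|a) is the symmetric quantity and the reported
#' strength is their mean.  An additive surface gives exactly 0.
#'
#' @inheritParams pdp_2d
#' @param pdp optionally a precomputed `rr_pdp2` for the pair.
#' @return one-row data frame: `var_a`, `var_b`, `i_ab`, `i_ba`,
#'   `strength`.
#' @export
interaction_strength <- function(model, data, var_a, var_b,
                                 grid_size = 10L, trim = c(0.01, 0.99),
                                 subsample = NULL, seed = 1L, pdp = NULL) {
  if (is.null(pdp)) {
    pdp <- pdp_2d(model, data, var_a, var_b, grid_size = grid_size,
                  trim = trim, subsample = subsample, seed = seed)
  }
  if (length(pdp$grid_a) < 2L || length(pdp$grid_b) < 2L) {
    stop("interaction strength needs >= 2 grid points on each axis",
         call. = FALSE)
  }
  cat_a <- pdp$kind_a == "categorical"
  cat_b <- pdp$kind_b == "categorical"
  disp_a_given_b <- apply(pdp$values, 2, pd_dispersion, categorical = cat_a)
  disp_b_given_a <- apply(pdp$values, 1, pd_dispersion, categorical = cat_b)
  i_ab <- sample_sd(disp_a_given_b)
  i_ba <- sample_sd(disp_b_given_a)
  data.frame(var_a = pdp$var_a, var_b = pdp$var_b, i_ab = i_ab,
             i_ba = i_ba, strength = (i_ab + i_ba) / 2,
             stringsAsFactors = FALSE)
}

#' Screen candidate interaction pairs
#'
#' Candidate set (default `"screened"` mode): all unordered pairs of the
#' screening variables (typically the demographic variables) plus every
#' (screening variable, top-ranked variable) pair, deduplicated.  The
#' `"all_pairs"` mode takes every unordered pair of predictors.
#' Strengths are computed with [interaction_strength()] and sorted
#' descending.
#'
#' @inheritParams pdp_2d
#' @param demographics character vector of screening variables.
#' @param top_vars character vector of top-ranked variables (e.g. from
#'   [top_k()]).
#' @param mode `"screened"` or `"all_pairs"`.
#' @return data frame of pairs with `i_ab`, `i_ba`, `strength`, `rank`.
#' @export
screen_pairs <- function(model, data, demographics = NULL, top_vars = NULL,
                         mode = c("screened", "all_pairs"),
                         grid_size = 10L, trim = c(0.01, 0.99),
                         subsample = NULL, seed = 1L) {
  mode <- match.arg(mode)
  all_vars <- schema_names(data$schema)
  if (mode == "all_pairs") {
    pairs <- t(utils::combn(all_vars, 2L))
  } else {
    if (is.null(demographics) || length(demographics) < 1L) {
      stop("screened mode needs at least one screening variable",
           call. = FALSE)
    }
    bad <- setdiff(c(demographics, top_vars), all_vars)
    if (length(bad)) {
      stop("unknown variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    pairs <- NULL
    if (length(demographics) >= 2L) {
      pairs <- t(utils::combn(demographics, 2L))
    }
    for (d in demographics) {
      for (t in setdiff(top_vars, d)) {
        pairs <- rbind(pairs, c(d, t))
      }
    }
    if (is.null(pairs) || nrow(pairs) == 0L) {
      stop("empty candidate set", call. = FALSE)
    }
    # deduplicate unordered pairs
    key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    interaction_strength(model, data, pairs[i, 1], pairs[i, 2],
                         grid_size = grid_size, trim = trim,
                         subsample = subsample, seed = seed)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$strength, out$var_a, out$var_b,
                   method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
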