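# --- variable importance ----------------------------------------------

# Scale raw scores to [0, 100] against the positive maximum.  Negative
# raw scores (possible for permutation importance) are retained and
# flagged; when no positive score exists the scaled column is NA and the
# result carries the `all_nonpositive` attribute.
scale_vi <- function(df) {
  mx <- suppressWarnings(max(df$raw[df$raw > 0]))
  if (is.finite(mx) && mx > 0) {
    df$scaled <- 100 * df$raw / mx
  } else {
    df$scaled <- NA_real_
    attr(df, "all_nonpositive") <- TRUE
  }
  df$negative_raw <- df$raw < 0
  df
}

# Variable set for importance computations: source features by default,
# individual encoded (base) columns when per_column = TRUE.
vi_groups <- function(data, per_column) {
  if (!per_column) {
    return(data.frame(variable = schema_names(data$schema),
                      feature = schema_names(data$schema),
                      stringsAsFactors = FALSE))
  }
  map <- encode_features(data$features[0, , drop = FALSE], data$schema)$column_map
  data.frame(variable = map$column, feature = map$feature,
             stringsAsFactors = FALSE)
}

#' Permutation variable importance (model reliance)
#'
#' Baseline AUC minus the mean AUC after permuting one variable's values
#' (the intuition: if shuffling a variable's observations barely changes
#' the model's performance, the variable is unimportant).  A categorical
#' variable's indicator columns are permuted jointly -- independently
#' permuted indicators would create impossible rows.
#'
#' @param model an `rr_model` trained on `data`'s schema.
#' @param data the `rr_dataset` to permute (typically the training data).
#' @param n_repeats independent permutations averaged per variable.
#' @param seed seed; each (variable, repeat) permutation derives its own.
#' @param per_column score individual encoded dummy columns instead of
#'   source features (each indicator permuted alone).
#' @return data frame of class scores: `variable`, `feature`, `raw`,
#'   `scaled`, `method`, `negative_raw`.
#' @export
permutation_vi <- function(model, data, n_repeats = 5L, seed = 1L,
                           per_column = FALSE) {
  stopifnot(inherits(model, "rr_model"), inherits(data, "rr_dataset"))
  check_schema_rows(model, data$features)
  y <- data$outcome
  n <- n_rows(data)
  groups <- vi_groups(data, per_column)
  manual <- model$family == "manual"
  X0 <- if (manual) NULL else
    encode_features(data$features, model$schema)$values
  baseline <- if (manual) {
    auc(predict_features(model, data$features), y)
  } else {
    auc(predict_base(model, X0), y)
  }
  raw <- numeric(nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    v <- groups$variable[gi]
    feat <- groups$feature[gi]
    cols <- if (per_column) v else {
      f <- data$schema[[feat]]
      if (f$kind == "continuous") feat else
        paste(feat, setdiff(f$levels, f$reference), sep = ".")
    }
    perm_auc <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      perm <- with_seed(derive_seed(seed, paste0("perm_", v), r), sample(n))
      if (manual) {
        df <- data$features
        df[[feat]] <- df[[feat]][perm]
        perm_auc[r] <- auc(predict_features(model, df), y)
      } else {
        Xp <- X0
        Xp[, cols] <- X0[perm, cols, drop = FALSE]
        perm_auc[r] <- auc(predict_base(model, Xp), y)
      }
    }
    raw[gi] <- baseline - mean(perm_auc)
  }
  out <- data.frame(variable = groups$variable, feature = groups$feature,
                    raw = raw, method = "permutation",
                    stringsAsFactors = FALSE)
  scale_vi(out)
}

#' FIRM variable importance (PDP dispersion)
#'
#' Feature-importance-ranking measure: the dispersion of a variable's
#' one-dimensional partial dependence curve -- sample standard deviation
#' over the grid for continuous variables, (max - min)/4 over the levels
#' for categorical variables.  A variable the model ignores has a flat
#' curve and importance exactly 0.
#'
#' @inheritParams permutation_vi
#' @param grid_size,trim continuous-grid resolution (quantile grid).
#' @param subsample optional number of evaluation rows used for the PDP
#'   averages (seeded); default all rows.
#' @param per_column score individual encoded dummy columns over the
#'   \{0, 1\} grid instead of whole source features.
#' @return data frame of scores (see [permutation_vi()]), `method` =
#'   `"pdp_variance"`.
#' @export
firm_vi <- function(model, data, grid_size = 20L, trim = c(0.01, 0.99),
                    subsample = NULL, seed = 1L, per_column = FALSE) {
  stopifnot(inherits(model, "rr_model"), inherits(data, "rr_dataset"))
  check_schema_rows(model, data$features)
  idx <- pdp_rows(data, subsample, seed)
  rows_df <- data$features[idx, , drop = FALSE]
  n <- nrow(rows_df)
  manual <- model$family == "manual"
  rows_X0 <- if (manual) NULL else
    encode_features(rows_df, model$schema)$values
  groups <- vi_groups(data, per_column)

  # grids per scored variable
  grids <- vector("list", nrow(groups))
  cat_flag <- logical(nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    feat <- groups$feature[gi]
    f <- data$schema[[feat]]
    if (per_column && f$kind == "categorical") {
      grids[[gi]] <- c(0, 1)
      cat_flag[gi] <- TRUE
    } else if (f$kind == "categorical") {
      grids[[gi]] <- f$levels
      cat_flag[gi] <- TRUE
    } else {
      grids[[gi]] <- variable_grid(data, feat, grid_size, trim)
      cat_flag[gi] <- FALSE
    }
  }

  if (manual) {
    raw <- vapply(seq_len(nrow(groups)), function(gi) {
      means <- pdp_means(model, data, groups$feature[gi], grids[[gi]],
                         rows_df, NULL)
      pd_dispersion(means, cat_flag[gi])
    }, numeric(1))
  } else {
    # one stacked prediction call across all variables and grid values
    blocks <- vector("list", nrow(groups))
    for (gi in seq_len(nrow(groups))) {
      v <- groups$variable[gi]
      feat <- groups$feature[gi]
      blocks[[gi]] <- do.call(rbind, lapply(grids[[gi]], function(val) {
        if (per_column && cat_flag[gi]) {
          X <- rows_X0
          X[, v] <- as.numeric(val)
          X
        } else {
          substitute_encoded(rows_X0, data$schema, feat, val)
        }
      }))
    }
    p <- predict_base(model, do.call(rbind, blocks))
    offsets <- c(0, cumsum(vapply(grids, length, integer(1)) * n))
    raw <- vapply(seq_len(nrow(groups)), function(gi) {
      seg <- p[(offsets[gi] + 1):offsets[gi + 1]]
      means <- colMeans(matrix(seg, nrow = n))
      pd_dispersion(means, cat_flag[gi])
    }, numeric(1))
  }
  out <- data.frame(variable = groups$variable, feature = groups$feature,
                    raw = raw, method = "pdp_variance",
                    stringsAsFactors = FALSE)
  scale_vi(out)
}

#' Top-k ranked variables
#'
#' Ranks by scaled score, descending, with exact ties broken by variable
#' name (C-locale order).  With `aggregate = TRUE`, per-column scores are
#' first summed within each source feature.
#'
#' @param scores a score data frame from [permutation_vi()] or
#'   [firm_vi()].
#' @param k number of variables to keep (`k > p` returns all).
#' @param aggregate sum scaled scores per source feature before ranking.
#' @return the ranked sublist with a `rank` column.
#' @export
top_k <- function(scores, k = 10L, aggregate = FALSE) {
  stopifnot(is.data.frame(scores), k >= 1L)
  df <- scores
  if (aggregate) {
    agg <- stats::aggregate(cbind(raw, scaled) ~ feature, data = df, FUN = sum)
    df <- data.frame(variable = agg$feature, feature = agg$feature,
                     raw = agg$raw, scaled = agg$scaled,
                     method = df$method[1], stringsAsFactors = FALSE)
  }
  df <- df[order(-df$scaled, df$variable, method = "radix"), , drop = FALSE]
  df <- utils::head(df, k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Bootstrap percentile intervals for variable importance
#'
#' Resamples the rows with replacement B times, refits the family with
#' the fixed (NCV-selected) hyperparameters on each resample, recomputes
#' the importance scores, rescales them within each replicate, and takes
#' empirical percentile bounds.  A resample with a single outcome class
#' is redrawn (at most 10 times, then an error); a replicate whose refit
#' keeps no variable (all raw scores zero, relative importance
#' undefined) is excluded from the percentile step and counted in the
#' `"n_degenerate"` attribute.  The full-data point
#' estimate is not guaranteed to lie inside a percentile interval; rows
#' where it does not are flagged.
#'
#' @param family model family.
#' @param params fixed hyperparameters (typically `selected_params` from
#'   [nested_cv()]).
#' @param data an `rr_dataset`.
#' @param B bootstrap replicates (default 100).
#' @param level interval coverage (default 0.95).
#' @param vi_method `"pdp_variance"` (default) or `"permutation"`.
#' @param seed master seed; each replicate derives its own.
#' @param expand fit with two-way product expansion.
#' @param grid_size,subsample,n_repeats,per_column passed to the
#'   importance method.
#' @return data frame of class `rr_vi_ci`: `variable`, `point`,
#'   `ci_lower`, `ci_upper`, `B`, `level`, `method`,
#'   `point_outside_ci`; the replicate matrix is attached as the
#'   `"replicates"` attribute.
#' @export
bootstrap_vi_ci <- function(family, params, data, B = 100L, level = 0.95,
                            vi_method = c("pdp_variance", "permutation"),
                            seed = 1L, expand = FALSE, grid_size = 20L,
                            subsample = NULL, n_repeats = 5L,
                            per_column = FALSE) {
  vi_method <- match.arg(vi_method)
  stopifnot(B >= 2L, inherits(data, "rr_dataset"))
  n <- n_rows(data)
  vi_fun <- function(m, d, s) {
    if (vi_method == "pdp_variance") {
      firm_vi(m, d, grid_size = grid_size, subsample = subsample,
              seed = s, per_column = per_column)
    } else {
      permutation_vi(m, d, n_repeats = n_repeats, seed = s,
                     per_column = per_column)
    }
  }
  full <- fit_model(family, data, params = params,
                    seed = derive_seed(seed, "vi_full_fit"), expand = expand)
  point <- vi_fun(full, data, derive_seed(seed, "vi_full"))

  reps <- matrix(NA_real_, nrow = nrow(point), ncol = B,
                 dimnames = list(point$variable, NULL))
  redraws <- 0L
  for (b in seq_len(B)) {
    idx <- NULL
    for (attempt in 0:10) {
      if (attempt == 10L) {
        stop("bootstrap replicate ", b,
             ": 10 consecutive single-class resamples", call. = FALSE)
      }
      cand <- with_seed(derive_seed(seed, "boot_draw", b * 32L + attempt),
                        sample(n, n, replace = TRUE))
      if (length(unique(data$outcome[cand])) == 2L) {
        idx <- cand
        if (attempt > 0L) redraws <- redraws + attempt
        break
      }
    }
    d_b <- dataset_slice(data, idx)
    m_b <- fit_model(family, d_b, params = params,
                     seed = derive_seed(seed, "boot_fit", b),
                     expand = expand)
    vi_b <- vi_fun(m_b, d_b, derive_seed(seed, "boot_vi", b))
    reps[, b] <- vi_b$scaled[match(rownames(reps), vi_b$variable)]
  }
  # a replicate whose model keeps no variable has undefined scaled scores
  # (all raw = 0); such replicates carry no ranking information and are
  # excluded from the percentile computation, with their count recorded
  degenerate <- colSums(!is.na(reps)) == 0L
  if (sum(!degenerate) < 2L) {
    stop("fewer than 2 bootstrap replicates produced usable importance ",
         "scores (", sum(degenerate), " of ", B, " were degenerate)",
         call. = FALSE)
  }
  ci <- t(apply(reps[, !degenerate, drop = FALSE], 1, percentile_ci,
                level = level))
  out <- data.frame(variable = point$variable, feature = point$feature,
                    point = point$scaled, ci_lower = ci[, "lower"],
                    ci_upper = ci[, "upper"], B = B, level = level,
                    method = vi_method, stringsAsFactors = FALSE)
  out$point_outside_ci <- out$point < out$ci_lower | out$point > out$ci_upper
  attr(out, "replicates") <- reps
  attr(out, "redraws") <- redraws
  attr(out, "n_degenerate") <- sum(degenerate)
  class(out) <- c("rr_vi_ci", "data.frame")
  rownames(out) <- NULL
  out
}

#' Cross-model consensus variables
#'
#' Variables appearing in at least two models' top-k lists, sorted by
#' support count (descending) then best rank.
#'
#' @param per_model_top_k named list (>= 2 models) of ranked variable
#'   character vectors, or of [top_k()] data frames.
#' @return data frame: `variable`, `support`, `best_rank`, `models`.
#' @export
consensus_variables <- function(per_model_top_k) {
  stopifnot(is.list(per_model_top_k), length(per_model_top_k) >= 2L)
  lists <- lapply(per_model_top_k, function(x) {
    if (is.data.frame(x)) as.character(x$variable) else as.character(x)
  })
  if (is.null(names(lists))) names(lists) <- paste0("model", seq_along(lists))
  all_vars <- unique(unlist(lists))
  rows <- lapply(all_vars, function(v) {
    hit <- vapply(lists, function(l) v %in% l, logical(1))
    if (sum(hit) < 2L) return(NULL)
    ranks <- vapply(lists[hit], function(l) match(v, l), numeric(1))
    data.frame(variable = v, support = sum(hit), best_rank = min(ranks),
               models = paste(names(lists)[hit], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(variable = character(0), support = integer(0),
                      best_rank = numeric(0), models = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, out$best_rank, out$variable,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
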