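RR_FAMILIES <- c("lasso_logistic", "elastic_net_logistic", "random_forest",
                 "neural_net", "plain_logistic")

# Hyperparameter names per family. LASSO is the mixing = 1 special case of
# the elastic net and shares its fitting code path.
family_param_names <- function(family) {
  switch(family,
         lasso_logistic = "penalty",
         elastic_net_logistic = c("penalty", "mixing"),
         random_forest = c("mtry", "num_trees"),
         neural_net = c("size", "decay"),
         plain_logistic = character(0),
         stop("unknown model family: ", family, call. = FALSE))
}

#' Model specification
#'
#' @param family one of `"lasso_logistic"`, `"elastic_net_logistic"`,
#'   `"random_forest"`, `"neural_net"`, `"plain_logistic"`.
#' @param params named list of hyperparameters for the family
#'   (`penalty`/`mixing`, `mtry`/`num_trees`, `size`/`decay`).
#' @param seed integer seed controlling any stochastic element of the fit
#'   (forest resampling, network initialisation).
#' @return an object of class `rr_model_spec`.
#' @export
model_spec <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, RR_FAMILIES)
  allowed <- family_param_names(family)
  bad <- setdiff(names(params), allowed)
  if (length(bad)) {
    stop("unknown parameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (family %in% c("lasso_logistic", "elastic_net_logistic")) {
    if (is.null(params$penalty)) {
      stop(family, " requires a 'penalty' value", call. = FALSE)
    }
    stopifnot(params$penalty > 0)
    if (family == "elastic_net_logistic") {
      params$mixing <- params$mixing %||% 0.5
      stopifnot(params$mixing >= 0, params$mixing <= 1)
    }
  }
  if (family == "random_forest") {
    params$num_trees <- as.integer(params$num_trees %||% 500L)
    stopifnot(params$num_trees >= 1L)
    if (!is.null(params$mtry)) stopifnot(params$mtry >= 1)
  }
  if (family == "neural_net") {
    params$size <- as.integer(params$size %||% 3L)
    params$decay <- params$decay %||% 0.01
    stopifnot(params$size >= 1L, params$decay > 0)
  }
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "rr_model_spec")
}

#' Default random-search space for a family
#'
#' The tuning grids are the package's documented defaults (overridable in
#' the run configuration): elastic net draws its penalty on a log scale
#' spanning four orders of magnitude and its mixing uniformly on \[0, 1\]
#' (fixed at 1 for LASSO); the random forest tunes variables-per-split
#' over `1..p` with the tree count fixed at 500; the neural network tunes
#' the hidden-layer size over `1..20` and its weight decay on a log
#' scale; plain logistic regression has nothing to tune.
#'
#' @param family model family.
#' @param p number of encoded predictor columns (required for
#'   `random_forest`, whose `mtry` range depends on it).
#' @return an object of class `rr_space`: a list of per-parameter
#'   sampling rules (`name`, `type` in linear/log/integer/choice, and
#'   `range` or `values`).
#' @export
default_space <- function(family, p = NULL) {
  family <- match.arg(family, RR_FAMILIES)
  rules <- switch(
    family,
    lasso_logistic = list(
      list(name = "penalty", type = "log", range = c(1e-4, 1e0))),
    elastic_net_logistic = list(
      list(name = "penalty", type = "log", range = c(1e-4, 1e0)),
      list(name = "mixing", type = "linear", range = c(0, 1))),
    random_forest = {
      if (is.null(p)) {
        stop("default_space('random_forest') needs p, the number of ",
             "encoded predictor columns", call. = FALSE)
      }
      list(list(name = "mtry", type = "integer", range = c(1L, as.integer(p))),
           list(name = "num_trees", type = "choice", values = 500L))
    },
    neural_net = list(
      list(name = "size", type = "integer", range = c(1L, 20L)),
      list(name = "decay", type = "log", range = c(1e-4, 1e-1))),
    plain_logistic = list())
  for (r in rules) {
    if (r$type == "log" && any(r$range <= 0)) {
      stop("log-scale range must be strictly positive", call. = FALSE)
    }
  }
  structure(rules, class = "rr_space")
}

#' Draw hyperparameter settings from a space
#'
#' Random search: each draw samples every parameter independently on its
#' declared scale.  Deterministic given the seed.
#'
#' @param space an `rr_space`.
#' @param n_draws number of settings to draw (>= 1).
#' @param seed integer seed.
#' @return a list of `n_draws` named parameter lists (empty lists for an
#'   empty space).
#' @export
sample_params <- function(space, n_draws, seed = 1L) {
  stopifnot(n_draws >= 1L)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      draw <- lapply(space, function(r) {
        switch(r$type,
               linear = stats::runif(1, r$range[1], r$range[2]),
               log = exp(stats::runif(1, log(r$range[1]), log(r$range[2]))),
               integer = sample(seq(r$range[1], r$range[2]), 1L),
               choice = {
                 v <- r$values
                 if (length(v) == 1L) v else sample(v, 1L)
               },
               stop("unknown sampling type: ", r$type, call. = FALSE))
      })
      names(draw) <- vapply(space, `[[`, character(1), "name")
      draw
    })
  })
}

needs_standardization <- function(family) {
  family %in% c("lasso_logistic", "elastic_net_logistic", "neural_net")
}

#' Fit a probability-emitting classifier
#'
#' All families consume the shared dummy-coded model matrix; penalized
#' and network families consume it standardized (sample mean/sd recorded
#' in the fitted object), the forest unstandardized.  Refitting with
#' identical data, parameters and seed reproduces identical predictions.
#'
#' @param spec an `rr_model_spec` (or a family string, with `params` and
#'   `seed` given separately).
#' @param data an `rr_dataset` whose outcome contains both classes.
#' @param params,seed used when `spec` is a family string.
#' @param expand append all two-way product columns before fitting
#'   (penalized interaction mode).
#' @return an object of class `rr_model`.
#' @export
fit_model <- function(spec, data, params = list(), seed = 1L,
                      expand = FALSE) {
  if (is.character(spec)) spec <- model_spec(spec, params, seed)
  stopifnot(inherits(spec, "rr_model_spec"), inherits(data, "rr_dataset"))
  y <- data$outcome
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: both classes are required to fit",
         call. = FALSE)
  }
  enc <- dummy_encode(data, standardize = FALSE)
  if (expand) enc <- expand_interactions(enc)
  X <- enc$values
  std <- NULL
  if (needs_standardization(spec$family)) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1  # constant columns pass through
    X <- scale_columns(X, center, scl)
    std <- list(center = center, scale = scl)
  }

  fit <- switch(
    spec$family,
    plain_logistic = fit_plain_logistic(X, y),
    lasso_logistic = fit_glmnet(X, y, alpha = 1, lambda = spec$params$penalty),
    elastic_net_logistic = fit_glmnet(X, y, alpha = spec$params$mixing,
                                      lambda = spec$params$penalty),
    random_forest = fit_ranger(X, y, spec),
    neural_net = fit_nnet(X, y, spec))

  structure(list(family = spec$family, params = spec$params,
                 seed = spec$seed, schema = data$schema,
                 column_map = enc$column_map, expand = expand,
                 standardization = std, prevalence = mean(y),
                 n_train = length(y), fit = fit),
            class = "rr_model")
}

fit_plain_logistic <- function(X, y) {
  res <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = list(maxit = 100)),
    warning = function(w) {
      # complete separation yields 0/1 fitted probabilities; that is a
      # legitimate fit for prediction purposes
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!isTRUE(res$converged) && res$deviance > 1e-6) {
    stop("plain logistic fit did not converge (deviance ",
         format(res$deviance), " after ", res$iter, " iterations)",
         call. = FALSE)
  }
  list(coef = res$coefficients)
}

# Single-penalty elastic net: glmnet is fitted along a decreasing path
# that terminates exactly at the requested penalty, so coefficients at
# the target are exact (no path interpolation).
fit_glmnet <- function(X, y, alpha, lambda) {
  n <- length(y)
  alpha_eff <- max(alpha, 1e-3)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / (n * alpha_eff)
  lmax <- max(lmax, lambda * 1.0001, 1e-3)
  path <- exp(seq(log(lmax * 1.05), log(lambda), length.out = 20L))
  path[length(path)] <- lambda  # exact target, no near-duplicates
  path <- path[!duplicated(signif(path, 10))]
  obj <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-7, maxit = 1e5)
  list(glmnet = obj, lambda = lambda)
}

fit_ranger <- function(X, y, spec) {
  m <- ncol(X)
  mtry <- min(spec$params$mtry %||% max(1L, floor(sqrt(m))), m)
  ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                 probability = TRUE,
                 num.trees = spec$params$num_trees %||% 500L,
                 mtry = mtry, seed = spec$seed, num.threads = 1L)
}

fit_nnet <- function(X, y, spec) {
  with_seed(spec$seed, {
    nnet::nnet(x = X, y = y, size = spec$params$size,
               decay = spec$params$decay, entropy = TRUE,
               maxit = 500L, trace = FALSE, MaxNWts = 100000L)
  })
}

#' Wrap an arbitrary prediction function as a model
#'
#' Importance, partial dependence and interaction tools in this package
#' are model-agnostic: they only need a function mapping a predictor
#' table to probabilities (or any numeric prediction scale).  This
#' wrapper lets those tools run on user-supplied prediction rules.
#'
#' @param predict_fun function taking a feature data frame and returning
#'   a numeric vector of predictions.
#' @param schema the `rr_schema` the function expects.
#' @return an `rr_model` of family `"manual"`.
#' @export
manual_model <- function(predict_fun, schema) {
  stopifnot(is.function(predict_fun), inherits(schema, "rr_schema"))
  structure(list(family = "manual", params = list(), seed = NA_integer_,
                 schema = schema, column_map = NULL, expand = FALSE,
                 standardization = NULL, fit = predict_fun),
            class = "rr_model")
}

#' @export
print.rr_model <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), vapply(x$params, format, character(1)),
          sep = "=", collapse = ", ")
  } else "none"
  cat("<rr_model> family ", x$family, "; params: ", ps,
      if (isTRUE(x$expand)) "; two-way expansion", "\n", sep = "")
  invisible(x)
}

# Validate a feature table against the training schema.
check_schema_rows <- function(model, rows) {
  schema <- model$schema
  missing_cols <- setdiff(schema_names(schema), names(rows))
  if (length(missing_cols)) {
    stop("rows are missing training column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (f in schema) {
    if (f$kind == "categorical") {
      bad <- setdiff(unique(as.character(rows[[f$name]])), f$levels)
      if (length(bad)) {
        stop("unknown level(s) in '", f$name, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Predict class-1 probabilities
#'
#' @param model an `rr_model`.
#' @param rows a feature data frame (or `rr_dataset`) conforming to the
#'   training schema.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, rows) {
  stopifnot(inherits(model, "rr_model"))
  if (inherits(rows, "rr_dataset")) rows <- rows$features
  check_schema_rows(model, rows)
  if (model$family == "manual") {
    return(as.numeric(model$fit(rows)))
  }
  X0 <- encode_features(rows, model$schema)$values
  predict_base(model, X0)
}

# Fast path: predictions from a pre-encoded base (unexpanded,
# unstandardized) matrix.  Large inputs are processed in row chunks to
# bound the memory of the two-way expansion.
predict_base <- function(model, X0) {
  if (model$family == "manual") {
    stop("encoded-matrix prediction is unavailable for manual models",
         call. = FALSE)
  }
  m_out <- if (isTRUE(model$expand)) {
    ncol(X0) * (ncol(X0) + 1) / 2
  } else {
    ncol(X0)
  }
  if (nrow(X0) * m_out > 5e6) {
    chunk <- max(1L, floor(5e6 / m_out))
    starts <- seq(1L, nrow(X0), by = chunk)
    return(unlist(lapply(starts, function(s) {
      predict_base(model, X0[s:min(s + chunk - 1L, nrow(X0)), , drop = FALSE])
    }), use.names = FALSE))
  }
  X <- X0
  if (isTRUE(model$expand)) X <- expand_interactions(X)$values
  if (!is.null(model$standardization)) {
    X <- scale_columns(X, model$standardization$center,
                       model$standardization$scale)
  }
  p <- switch(
    model$family,
    plain_logistic = sigmoid(drop(cbind(1, X) %*% model$fit$coef)),
    lasso_logistic = ,
    elastic_net_logistic = drop(stats::predict(
      model$fit$glmnet, newx = X, s = model$fit$lambda, type = "response")),
    random_forest = stats::predict(
      model$fit, data = X, num.threads = 1L)$predictions[, "1"],
    neural_net = drop(stats::predict(model$fit, X)))
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' @export
predict.rr_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Save / load a fitted model
#'
#' Serializes an `rr_model` together with the package version and its
#' training schema (which doubles as the schema fingerprint checked at
#' prediction time).
#'
#' @param model an `rr_model`.
#' @param path file path for the serialized artifact.
#' @return `load_model` returns the `rr_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rr_model"))
  saveRDS(list(format = 1L,
               package_version = as.character(utils::packageVersion("riskrank")),
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format) || !inherits(obj$model, "rr_model")) {
    stop("not a riskrank model artifact: ", path, call. = FALSE)
  }
  obj$model
}

# Nonzero slope coefficients (penalized families), used by tests and by
# the penalty-monotonicity property.
nonzero_coefs <- function(model) {
  stopifnot(model$family %in% c("lasso_logistic", "elastic_net_logistic"))
  b <- stats::coef(model$fit$glmnet, s = model$fit$lambda)
  sum(abs(b[-1]) > 0)
}
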