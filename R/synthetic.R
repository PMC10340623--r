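# --- synthetic survey generator ---------------------------------------

#' Planted-effect specification
#'
#' Effects live on the logit scale.  Term references are feature names
#' for continuous variables and `"feature:level"` for indicator terms of
#' categorical variables.
#'
#' @param linear named numeric vector of linear coefficients.
#' @param quadratic named numeric vector of quadratic coefficients
#'   (continuous variables only; produces U-shaped dependence).
#' @param interactions list of `list(a =, b =, coef =)` two-way product
#'   terms; each side is a term reference as above.
#' @param intercept fixed intercept, or `NULL` to solve for
#'   `target_prevalence`.
#' @param target_prevalence desired mean outcome probability in (0, 1);
#'   the intercept is found by bisection to tolerance 1e-4.
#' @return an object of class `rr_effects`.
#' @export
effect_spec <- function(linear = numeric(0), quadratic = numeric(0),
                        interactions = list(), intercept = NULL,
                        target_prevalence = NULL) {
  if (is.null(intercept) && is.null(target_prevalence)) intercept <- 0
  if (!is.null(target_prevalence)) {
    stopifnot(target_prevalence > 0, target_prevalence < 1)
  }
  structure(list(linear = linear, quadratic = quadratic,
                 interactions = interactions, intercept = intercept,
                 target_prevalence = target_prevalence),
            class = "rr_effects")
}

#' Simulation schema
#'
#' @param continuous character vector of continuous feature names (drawn
#'   standard normal).
#' @param categorical named list: each element `list(levels =, probs =)`
#'   (probs defaults to uniform).
#' @return a list of generator specs consumed by [generate_survey()].
#' @export
make_sim_schema <- function(continuous = character(0), categorical = list()) {
  feats <- c(
    lapply(continuous, function(nm) list(name = nm, kind = "continuous")),
    lapply(names(categorical), function(nm) {
      spec <- categorical[[nm]]
      lv <- as.character(spec$levels)
      probs <- spec$probs %||% rep(1 / length(lv), length(lv))
      stopifnot(length(probs) == length(lv), all(probs > 0))
      list(name = nm, kind = "categorical", levels = lv,
           probs = probs / sum(probs))
    }))
  feats
}

# Resolve a term reference ("x" or "x:level") to a numeric column.
resolve_term <- function(ref, features, sim_schema) {
  if (grepl(":", ref, fixed = TRUE)) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (!parts[1] %in% names(features)) {
      stop("effect term references unknown variable: ", parts[1],
           call. = FALSE)
    }
    as.numeric(features[[parts[1]]] == parts[2])
  } else {
    if (!ref %in% names(features)) {
      stop("effect term references unknown variable: ", ref, call. = FALSE)
    }
    as.numeric(features[[ref]])
  }
}

#' Generate a survey-like dataset with known ground truth
#'
#' Continuous features are standard normal (optionally correlated via a
#' supplied correlation matrix); categorical features are multinomial
#' with the declared level probabilities.  The outcome is
#' Bernoulli(sigmoid(eta)) with eta built from the [effect_spec()].  When
#' a target prevalence is requested the intercept is solved by bisection
#' on the mean predicted probability (tolerance 1e-4).
#'
#' @param n number of rows (>= 10).
#' @param sim_schema generator schema from [make_sim_schema()].
#' @param effects an [effect_spec()].
#' @param seed integer seed; identical inputs give identical datasets.
#' @param correlation optional correlation matrix for the continuous
#'   block (must be positive definite).
#' @return list with `data` (an `rr_dataset`) and `truth` (ground-truth
#'   record: ranked signal variables, interacting pairs, realized
#'   prevalence, intercept, seed, effects echo).
#' @export
generate_survey <- function(n, sim_schema, effects = effect_spec(),
                            seed = 1L, correlation = NULL) {
  stopifnot(n >= 10L, inherits(effects, "rr_effects"))
  cont_names <- vapply(Filter(function(f) f$kind == "continuous", sim_schema),
                       `[[`, character(1), "name")
  features <- with_seed(seed, {
    out <- list()
    if (length(cont_names)) {
      Z <- matrix(stats::rnorm(n * length(cont_names)), nrow = n)
      if (!is.null(correlation)) {
        stopifnot(nrow(correlation) == length(cont_names))
        ch <- tryCatch(chol(correlation), error = function(e)
          stop("correlation matrix is not positive definite", call. = FALSE))
        Z <- Z %*% ch
      }
      colnames(Z) <- cont_names
      out <- c(out, as.list(as.data.frame(Z)))
    }
    for (f in sim_schema) {
      if (f$kind == "categorical") {
        out[[f$name]] <- sample(f$levels, n, replace = TRUE, prob = f$probs)
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)[
      , vapply(sim_schema, `[[`, character(1), "name"), drop = FALSE]
  })

  eta <- rep(0, n)
  for (nm in names(effects$linear)) {
    eta <- eta + effects$linear[[nm]] * resolve_term(nm, features, sim_schema)
  }
  for (nm in names(effects$quadratic)) {
    eta <- eta + effects$quadratic[[nm]] *
      resolve_term(nm, features, sim_schema)^2
  }
  for (tm in effects$interactions) {
    eta <- eta + tm$coef * resolve_term(tm$a, features, sim_schema) *
      resolve_term(tm$b, features, sim_schema)
  }

  if (!is.null(effects$target_prevalence)) {
    target <- effects$target_prevalence
    lo <- -40; hi <- 40
    if (mean(sigmoid(eta + lo)) > target || mean(sigmoid(eta + hi)) < target) {
      stop("target prevalence ", target, " is unattainable", call. = FALSE)
    }
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mean(sigmoid(eta + mid)) < target) lo <- mid else hi <- mid
      if (abs(mean(sigmoid(eta + (lo + hi) / 2)) - target) < 1e-4) break
    }
    intercept <- (lo + hi) / 2
  } else {
    intercept <- effects$intercept
  }
  prob <- sigmoid(eta + intercept)
  y <- with_seed(derive_seed(seed, "outcome"),
                 stats::rbinom(n, 1L, prob))

  schema <- feature_schema(lapply(sim_schema, function(f) {
    if (f$kind == "categorical") {
      list(name = f$name, kind = "categorical", levels = sort(f$levels))
    } else {
      list(name = f$name, kind = "continuous")
    }
  }))
  data <- as_dataset(features, y, schema)

  base_var <- function(ref) strsplit(ref, ":", fixed = TRUE)[[1]][1]
  contrib <- new.env()
  addc <- function(v, a) assign(v, (get0(v, contrib) %||% 0) + abs(a), contrib)
  for (nm in names(effects$linear)) addc(base_var(nm), effects$linear[[nm]])
  for (nm in names(effects$quadratic)) addc(base_var(nm), effects$quadratic[[nm]])
  for (tm in effects$interactions) {
    addc(base_var(tm$a), tm$coef / 2)
    addc(base_var(tm$b), tm$coef / 2)
  }
  sig <- unlist(as.list(contrib))
  signal <- if (length(sig)) names(sort(sig, decreasing = TRUE)) else character(0)
  truth <- list(
    signal_vars = signal,
    null_vars = setdiff(schema_names(schema), signal),
    interacting_pairs = lapply(effects$interactions, function(tm) {
      c(base_var(tm$a), base_var(tm$b))
    }),
    realized_prevalence = mean(y),
    intercept = intercept,
    seed = seed,
    effects = effects)
  list(data = data, truth = truth)
}

#' Survey-scale scenario with planted effects
#'
#' Emulates a survey of (by default) 1414 respondents and 70 mixed-type
#' predictors with a roughly balanced binary outcome (target prevalence
#' 0.4).  Planted structure mirrors the qualitative findings the package
#' is designed to recover: three strong categorical main effects
#' (substance-use analogues `cannabis`, `cocaine`, and one `orientation`
#' level), one U-shaped continuous effect (`ace`, an adverse-childhood-
#' experience analogue, quadratic on the logit scale), and one sign-flip
#' interaction between a continuous scale (`suicidality`) and the binary
#' `cannabis` variable: the suicidality slope is positive for non-users
#' and negative for users.  All remaining variables are null.
#'
#' @param seed integer seed.
#' @param n number of rows (default 1414).
#' @param p number of predictors (default 70; minimum 12).
#' @return list with `data` and `truth`; `truth` additionally carries
#'   `strong_main` (the three planted categorical main effects) and
#'   `screen_vars` (the demographic-analogue screening set, which
#'   includes the continuous interactor so the planted pair is
#'   screenable, mirroring how demographic-by-top-predictor pairs are
#'   screened in practice).
#' @export
paper_like_scenario <- function(seed = 1L, n = 1414L, p = 70L) {
  stopifnot(p >= 12L)
  core_cont <- c("age", "ace", "suicidality")
  core_cat <- list(
    cannabis = list(levels = c("no", "yes"), probs = c(0.6, 0.4)),
    cocaine = list(levels = c("no", "yes"), probs = c(0.75, 0.25)),
    orientation = list(levels = c("bi", "gay", "lesbian", "queer"),
                       probs = c(0.35, 0.3, 0.2, 0.15)),
    gender = list(levels = c("man", "nonbinary", "woman"),
                  probs = c(0.3, 0.25, 0.45)),
    education = list(levels = c("college", "highschool", "university"),
                     probs = c(0.3, 0.3, 0.4)))
  n_extra <- p - length(core_cont) - length(core_cat)
  extra_cont <- sprintf("scale%02d", seq_len(ceiling(n_extra / 2)))
  n_extra_cat <- n_extra - length(extra_cont)
  extra_cat <- list()
  lvl_sets <- list(c("no", "yes"), c("low", "mid", "high"),
                   c("a", "b", "c", "d"), c("q1", "q2", "q3", "q4", "q5"))
  for (i in seq_len(n_extra_cat)) {
    extra_cat[[sprintf("cat%02d", i)]] <-
      list(levels = lvl_sets[[(i - 1L) %% 4L + 1L]])
  }
  sim_schema <- make_sim_schema(
    continuous = c(core_cont, extra_cont),
    categorical = c(core_cat, extra_cat))
  effects <- effect_spec(
    linear = c("cannabis:yes" = 1.2, "cocaine:yes" = 1.0,
               "orientation:gay" = 0.9, "suicidality" = 0.8),
    quadratic = c(ace = 0.5),
    interactions = list(list(a = "suicidality", b = "cannabis:yes",
                             coef = -1.6)),
    target_prevalence = 0.4)
  res <- generate_survey(n, sim_schema, effects, seed = seed)
  res$truth$strong_main <- c("cannabis", "cocaine", "orientation")
  res$truth$screen_vars <- c("age", "gender", "education", "suicidality")
  res
}

#' Null scenario
#'
#' All coefficients zero: the outcome is an independent fair coin.  Used
#' for type-I-style calibration checks (any honest pipeline should show
#' mean outer-fold AUC near 0.5).
#'
#' @param n rows (>= 10).
#' @param p predictors (>= 1); alternating continuous and binary.
#' @param seed integer seed.
#' @return list with `data` and `truth` (every variable marked null).
#' @export
null_scenario <- function(n, p, seed = 1L) {
  stopifnot(n >= 10L, p >= 1L)
  cont <- sprintf("x%02d", seq_len(ceiling(p / 2)))
  n_cat <- p - length(cont)
  cats <- list()
  for (i in seq_len(n_cat)) {
    cats[[sprintf("c%02d", i)]] <- list(levels = c("no", "yes"))
  }
  sim_schema <- make_sim_schema(continuous = cont, categorical = cats)
  generate_survey(n, sim_schema, effect_spec(intercept = 0), seed = seed)
}
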