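# --- pipeline orchestration -------------------------------------------

# Reference defaults of the analysis framework (10 outer x 5 inner folds,
# 100 bootstrap replicates, top 10); any configured deviation is written
# to the run log.
FRAMEWORK_DEFAULTS <- list(outer_k = 10L, inner_k = 5L, B = 100L, top_k = 10L)

#' Run configuration
#'
#' Accepts a named list or a path to a YAML file with the same fields.
#'
#' @param config named list or YAML path.  Recognised fields:
#'   `input` (list: `path`, `outcome`, optional `schema`) or `scenario`
#'   (list: `name` in paper_like/null, `n`, `p`); `families` (character);
#'   `outer_k`, `inner_k`, `n_param_draws`, `stratified`; `B`, `level`,
#'   `top_k`, `vi_method` (pdp_variance/permutation);
#'   `interaction_mode` (screened/all_pairs/expansion); `demographics`;
#'   `grid_size`, `screen_grid_size`, `pdp_subsample`, `expand_cap`;
#'   `threshold`; `seed`; `selection` (best_outer/full_data).
#' @return validated list of class `rr_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    families = "elastic_net_logistic",
    outer_k = 10L, inner_k = 5L, n_param_draws = 20L, stratified = TRUE,
    B = 100L, level = 0.95, top_k = 10L,
    vi_method = "pdp_variance",
    interaction_mode = "screened", demographics = NULL,
    grid_size = 20L, screen_grid_size = 10L, pdp_subsample = NULL,
    expand_cap = 10000L, threshold = 0.5, seed = 1L,
    selection = "best_outer", n_top_pairs = 2L)
  cfg <- utils::modifyList(defaults, config)
  cfg$families <- match.arg(cfg$families, RR_FAMILIES, several.ok = TRUE)
  cfg$vi_method <- match.arg(cfg$vi_method, c("pdp_variance", "permutation"))
  cfg$interaction_mode <- match.arg(cfg$interaction_mode,
                                    c("screened", "all_pairs", "expansion"))
  cfg$selection <- match.arg(cfg$selection, c("best_outer", "full_data"))
  if (length(cfg$families) < 1L) stop("at least one model family required")
  if (is.null(cfg$input) && is.null(cfg$scenario)) {
    stop("config needs either 'input' (a CSV) or 'scenario' (synthetic)",
         call. = FALSE)
  }
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$path) || !file.exists(cfg$input$path)) {
      stop("input path not resolvable: ", cfg$input$path %||% "<missing>",
           call. = FALSE)
    }
    if (!is.null(cfg$input$schema) && !file.exists(cfg$input$schema)) {
      stop("schema path not resolvable: ", cfg$input$schema, call. = FALSE)
    }
  }
  structure(cfg, class = c("rr_config", "list"))
}

load_config_data <- function(cfg) {
  if (!is.null(cfg$input)) {
    data <- read_dataset(cfg$input$path, cfg$input$outcome,
                         schema = cfg$input$schema)
    list(data = data, truth = NULL)
  } else {
    sc <- cfg$scenario
    name <- match.arg(sc$name, c("paper_like", "null"))
    seed <- sc$seed %||% derive_seed(cfg$seed, "scenario")
    if (name == "paper_like") {
      paper_like_scenario(seed = seed, n = sc$n %||% 1414L,
                          p = sc$p %||% 70L)
    } else {
      null_scenario(n = sc$n %||% 500L, p = sc$p %||% 10L, seed = seed)
    }
  }
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

#' Run the full descriptive-ML pipeline
#'
#' Per family: nested cross-validation, performance summary, variable
#' importance on the final model, bootstrap percentile intervals for the
#' scores, top-k ranking, one-dimensional PDPs for the top variables,
#' interaction screening (or all-pairs / penalized two-way expansion),
#' and two-dimensional PDPs for the strongest pairs; then cross-model
#' consensus.  Writes `performance.json`, `vi.csv`, `vi_ci.csv`,
#' `pdp.csv`, `interactions.csv`, `consensus.csv`, `manifest.json` and
#' `run.log` into `out_dir`, plus tidy `performance.csv` (one row per
#' family) and `cv_folds.csv` (per-fold tuning records) companions.  All CSVs are free of timestamps, so a
#' rerun with an identical configuration is byte-identical.
#'
#' @param config an [run_config()] (or list / YAML path coercible to one).
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly; the in-memory results are attached as
#'   the `"results"` attribute.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "rr_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    writeLines(paste0(iso_time(), " ", sprintf(...)), log_con)
  }
  timings <- list()
  warnings_seen <- character(0)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("riskrank")))

  result <- tryCatch({
    logf("pipeline start; master seed %d", cfg$seed)
    for (fld in names(FRAMEWORK_DEFAULTS)) {
      if (!identical(as.integer(cfg[[fld]]),
                     as.integer(FRAMEWORK_DEFAULTS[[fld]]))) {
        logf("NOTE: %s = %s deviates from the framework default %s",
             fld, cfg[[fld]], FRAMEWORK_DEFAULTS[[fld]])
      }
    }
    loaded <- load_config_data(cfg)
    data <- loaded$data
    logf("data: %d rows, %d predictors, prevalence %.3f",
         n_rows(data), length(data$schema), mean(data$outcome))
    if (!is.null(loaded$truth)) {
      manifest$scenario_truth <- loaded$truth[
        c("signal_vars", "interacting_pairs", "realized_prevalence", "seed")]
    }

    demographics <- cfg$demographics %||% loaded$truth$screen_vars
    perf <- list()
    vi_rows <- list()
    vi_ci_rows <- list()
    pdp_rows_out <- list()
    inter_rows <- list()
    top_lists <- list()
    selected <- list()
    seeds_used <- list(master = cfg$seed)

    for (family in cfg$families) {
      t0 <- Sys.time()
      stage <- function(what) paste0(family, "/", what)
      logf("[%s] nested CV (%d outer x %d inner, %d draws)", family,
           cfg$outer_k, cfg$inner_k, cfg$n_param_draws)
      expand <- cfg$interaction_mode == "expansion" &&
        family %in% c("lasso_logistic", "elastic_net_logistic")
      plan <- cv_plan(outer_k = cfg$outer_k, inner_k = cfg$inner_k,
                      n_param_draws = cfg$n_param_draws,
                      stratified = cfg$stratified,
                      seed = derive_seed(cfg$seed, stage("ncv")))
      seeds_used[[stage("ncv")]] <- plan$seed
      ncv <- nested_cv(family, data, plan, expand = expand,
                       selection = cfg$selection, threshold = cfg$threshold)
      ps <- performance_summary(ncv, threshold = cfg$threshold)
      perf[[family]] <- list(
        auc_best_outer = unname(ps$summary["point"]),
        auc_fold_percentile_lower = unname(ps$summary["lower"]),
        auc_fold_percentile_upper = unname(ps$summary["upper"]),
        sensitivity = ps$report$sensitivity,
        specificity = ps$report$specificity,
        threshold = cfg$threshold,
        per_fold = ncv$fold_table[, c("fold", "params", "inner_metric",
                                      "outer_metric")],
        selected_params = ncv$selected_params,
        selected_fold = ncv$selected_fold)
      selected[[family]] <- ncv$selected_params
      logf("[%s] selected params %s (best outer AUC %.3f)", family,
           jsonlite::toJSON(ncv$selected_params, auto_unbox = TRUE),
           ps$summary["point"])

      vi_seed <- derive_seed(cfg$seed, stage("vi"))
      seeds_used[[stage("vi")]] <- vi_seed
      vi <- if (cfg$vi_method == "pdp_variance") {
        firm_vi(ncv$final_model, data, grid_size = cfg$grid_size,
                subsample = cfg$pdp_subsample, seed = vi_seed)
      } else {
        permutation_vi(ncv$final_model, data, seed = vi_seed)
      }
      tk <- top_k(vi, cfg$top_k)
      top_lists[[family]] <- tk$variable
      vi_rank <- top_k(vi, k = nrow(vi))
      vi_rank$model <- family
      vi_rows[[family]] <- vi_rank[, c("model", "method", "variable",
                                       "feature", "raw", "scaled", "rank")]

      logf("[%s] bootstrap VI intervals (B = %d)", family, cfg$B)
      ci_seed <- derive_seed(cfg$seed, stage("boot"))
      seeds_used[[stage("boot")]] <- ci_seed
      ci <- bootstrap_vi_ci(family, ncv$selected_params, data, B = cfg$B,
                            level = cfg$level, vi_method = cfg$vi_method,
                            seed = ci_seed, expand = expand,
                            grid_size = cfg$grid_size,
                            subsample = cfg$pdp_subsample)
      ci_df <- as.data.frame(ci)
      ci_df$model <- family
      vi_ci_rows[[family]] <- ci_df[, c("model", "method", "variable",
                                        "point", "ci_lower", "ci_upper",
                                        "B", "level", "point_outside_ci")]

      for (v in tk$variable) {
        pd <- pdp_1d(ncv$final_model, data, v, grid_size = cfg$grid_size,
                     subsample = cfg$pdp_subsample,
                     seed = derive_seed(cfg$seed, stage("pdp")))
        pdp_rows_out[[length(pdp_rows_out) + 1L]] <- data.frame(
          model = family, variable = v, value = as.character(pd$value),
          variable_2 = NA_character_, value_2 = NA_character_,
          yhat = pd$yhat, stringsAsFactors = FALSE)
      }

      if (cfg$interaction_mode %in% c("screened", "expansion") &&
          is.null(demographics)) {
        msg <- paste0(family, ": no screening variables configured; ",
                      "skipping interaction stage")
        warnings_seen <- c(warnings_seen, msg)
        logf("WARNING: %s", msg)
      } else {
        logf("[%s] interaction screening (%s mode)", family,
             cfg$interaction_mode)
        scr_mode <- if (cfg$interaction_mode == "all_pairs")
          "all_pairs" else "screened"
        scr <- screen_pairs(ncv$final_model, data,
                            demographics = demographics,
                            top_vars = unique(tk$feature),
                            mode = scr_mode,
                            grid_size = cfg$screen_grid_size,
                            subsample = cfg$pdp_subsample,
                            seed = derive_seed(cfg$seed, stage("screen")))
        scr$model <- family
        inter_rows[[family]] <- scr[, c("model", "var_a", "var_b", "i_ab",
                                        "i_ba", "strength", "rank")]
        for (i in seq_len(min(cfg$n_top_pairs, nrow(scr)))) {
          pd2 <- pdp_2d(ncv$final_model, data, scr$var_a[i], scr$var_b[i],
                        grid_size = cfg$screen_grid_size,
                        subsample = cfg$pdp_subsample,
                        seed = derive_seed(cfg$seed, stage("pdp2")))
          grid <- expand.grid(a = seq_along(pd2$grid_a),
                              b = seq_along(pd2$grid_b))
          pdp_rows_out[[length(pdp_rows_out) + 1L]] <- data.frame(
            model = family, variable = pd2$var_a,
            value = as.character(pd2$grid_a[grid$a]),
            variable_2 = pd2$var_b,
            value_2 = as.character(pd2$grid_b[grid$b]),
            yhat = as.vector(pd2$values), stringsAsFactors = FALSE)
        }
      }
      timings[[family]] <- as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))
      logf("[%s] done in %.1f s", family, timings[[family]])
    }

    consensus <- if (length(top_lists) >= 2L) {
      consensus_variables(top_lists)
    } else {
      data.frame(variable = character(0), support = integer(0),
                 best_rank = numeric(0), models = character(0),
                 stringsAsFactors = FALSE)
    }

    # tidy companions to performance.json: one row per family, and the
    # per-fold records (fold, params as JSON, inner/outer metric)
    perf_csv <- do.call(rbind, lapply(names(perf), function(m) {
      p <- perf[[m]]
      data.frame(model = m, auc_best_outer = p$auc_best_outer,
                 auc_fold_percentile_lower = p$auc_fold_percentile_lower,
                 auc_fold_percentile_upper = p$auc_fold_percentile_upper,
                 sensitivity = p$sensitivity, specificity = p$specificity,
                 threshold = p$threshold, stringsAsFactors = FALSE)
    }))
    write_csv_out(perf_csv, file.path(out_dir, "performance.csv"))
    folds_csv <- do.call(rbind, lapply(names(perf), function(m) {
      cbind(model = m, perf[[m]]$per_fold)
    }))
    write_csv_out(folds_csv, file.path(out_dir, "cv_folds.csv"))

    write_csv_out(do.call(rbind, unname(vi_rows)),
                  file.path(out_dir, "vi.csv"))
    write_csv_out(do.call(rbind, unname(vi_ci_rows)),
                  file.path(out_dir, "vi_ci.csv"))
    write_csv_out(do.call(rbind, pdp_rows_out),
                  file.path(out_dir, "pdp.csv"))
    inter_out <- if (length(inter_rows)) do.call(rbind, unname(inter_rows))
      else data.frame(model = character(0), var_a = character(0),
                      var_b = character(0), i_ab = numeric(0),
                      i_ba = numeric(0), strength = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    write_csv_out(inter_out, file.path(out_dir, "interactions.csv"))
    write_csv_out(consensus, file.path(out_dir, "consensus.csv"))
    perf_out <- lapply(perf, function(x) {
      x$per_fold <- NULL
      x
    })
    jsonlite::write_json(
      list(models = perf_out,
           per_fold = lapply(perf, function(x) x$per_fold)),
      file.path(out_dir, "performance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    manifest$selected_params <- selected
    manifest$derived_seeds <- seeds_used
    manifest$stage_timings_s <- timings
    manifest$warnings <- warnings_seen
    manifest$status <- "OK"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("pipeline complete")
    list(performance = perf, consensus = consensus, top = top_lists)
  }, error = function(e) {
    manifest$status <- "FAILED"
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("FAILED: %s", conditionMessage(e))
    stop(e)
  })
  out <- out_dir
  attr(out, "results") <- result
  invisible(out)
}

#' Re-render tables from an existing run directory
#'
#' Reads the canonical CSV/JSON outputs of [run_pipeline()] and prints a
#' compact report; nothing is recomputed or refitted.
#'
#' @param dir a directory written by [run_pipeline()].
#' @return invisible list of the parsed outputs.
#' @export
report_run <- function(dir) {
  need <- c("performance.json", "vi.csv", "vi_ci.csv", "consensus.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) {
    stop("run directory is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  perf <- jsonlite::read_json(file.path(dir, "performance.json"),
                              simplifyVector = TRUE)
  vi <- utils::read.csv(file.path(dir, "vi.csv"))
  vi_ci <- utils::read.csv(file.path(dir, "vi_ci.csv"))
  consensus <- utils::read.csv(file.path(dir, "consensus.csv"))
  interactions <- if (file.exists(file.path(dir, "interactions.csv")))
    utils::read.csv(file.path(dir, "interactions.csv")) else NULL
  cat("== model performance (best outer fold; percentile bounds across folds)\n")
  for (m in names(perf$models)) {
    p <- perf$models[[m]]
    cat(sprintf("  %-22s AUC %.3f (%.3f, %.3f)  sens %.2f  spec %.2f\n",
                m, p$auc_best_outer, p$auc_fold_percentile_lower,
                p$auc_fold_percentile_upper, p$sensitivity, p$specificity))
  }
  cat("== top variables per model (scaled importance)\n")
  for (m in unique(vi$model)) {
    sub <- utils::head(vi[vi$model == m, ], 5)
    cat(sprintf("  %s: %s\n", m,
                paste(sprintf("%s(%.0f)", sub$variable, sub$scaled),
                      collapse = ", ")))
  }
  if (nrow(consensus)) {
    cat("== consensus variables (selected by >= 2 models)\n")
    for (i in seq_len(nrow(consensus))) {
      cat(sprintf("  %-20s support %d, best rank %d\n",
                  consensus$variable[i], consensus$support[i],
                  as.integer(consensus$best_rank[i])))
    }
  }
  if (!is.null(interactions) && nrow(interactions)) {
    cat("== strongest screened interactions\n")
    top <- utils::head(interactions[order(-interactions$strength), ], 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s x %s (%s): strength %.4f\n", top$var_a[i],
                  top$var_b[i], top$model[i], top$strength[i]))
    }
  }
  invisible(list(performance = perf, vi = vi, vi_ci = vi_ci,
                 consensus = consensus, interactions = interactions))
}
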