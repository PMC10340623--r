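test_that("default spaces match their documented shapes", {
  en <- default_space("elastic_net_logistic")
  nm <- vapply(en, `[[`, character(1), "name")
  expect_setequal(nm, c("penalty", "mixing"))
  pen <- en[[which(nm == "penalty")]]
  expect_identical(pen$type, "log")
  expect_gte(log10(pen$range[2] / pen$range[1]), 4)  # >= 4 orders

  # LASSO has no free mixing parameter: it is the mixing = 1 special case
  la <- default_space("lasso_logistic")
  expect_setequal(vapply(la, `[[`, character(1), "name"), "penalty")

  expect_length(default_space("plain_logistic"), 0L)
  rf <- default_space("random_forest", p = 7)
  rf_nm <- vapply(rf, `[[`, character(1), "name")
  expect_identical(rf[[which(rf_nm == "mtry")]]$range, c(1L, 7L))
  expect_identical(rf[[which(rf_nm == "num_trees")]]$values, 500L)
  expect_error(default_space("random_forest"), "needs p")
  expect_error(default_space("not_a_family"))
})

test_that("random search draws respect bounds, scales and seeds", {
  sp <- default_space("elastic_net_logistic")
  d1 <- sample_params(sp, 25, seed = 9)
  d2 <- sample_params(sp, 25, seed = 9)
  expect_identical(d1, d2)
  pens <- vapply(d1, `[[`, numeric(1), "penalty")
  mixes <- vapply(d1, `[[`, numeric(1), "mixing")
  expect_true(all(pens >= 1e-4 & pens <= 1))
  expect_true(all(mixes >= 0 & mixes <= 1))
  d3 <- sample_params(sp, 25, seed = 10)
  expect_false(identical(d1, d3))

  # forced draw from a single-choice space
  one <- structure(list(list(name = "p", type = "choice", values = "a")),
                   class = "rr_space")
  expect_identical(sample_params(one, 1, seed = 1)[[1]], list(p = "a"))
})

test_that("LASSO equals elastic net at mixing = 1", {
  for (seed in c(11, 12, 13)) {
    d <- toy_signal_data(n = 100, p = 3, seed = seed)
    m1 <- fit_model("lasso_logistic", d, params = list(penalty = 0.02),
                    seed = 5)
    m2 <- fit_model("elastic_net_logistic", d,
                    params = list(penalty = 0.02, mixing = 1), seed = 5)
    expect_equal(predict_proba(m1, d), predict_proba(m2, d),
                 tolerance = 1e-12)
  }
})

test_that("an overwhelming penalty collapses to the intercept-only model", {
  d <- toy_signal_data(n = 200, p = 3, seed = 2)
  m <- fit_model("elastic_net_logistic", d,
                 params = list(penalty = 50, mixing = 1))
  p <- predict_proba(m, d)
  expect_equal(unname(p), rep(mean(d$outcome), n <- length(p)),
               tolerance = 1e-6)
})

test_that("nonzero coefficient count is non-increasing in the penalty", {
  d <- toy_signal_data(n = 150, p = 6, seed = 8)
  pens <- c(1e-4, 1e-3, 1e-2, 5e-2, 0.2, 1)
  counts <- vapply(pens, function(lam) {
    riskrank:::nonzero_coefs(
      fit_model("lasso_logistic", d, params = list(penalty = lam)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fits are deterministic given (data, params, seed)", {
  d <- toy_signal_data(n = 80, p = 3, seed = 4)
  for (fam in list(
    list("elastic_net_logistic", list(penalty = 0.01, mixing = 0.5)),
    list("random_forest", list(mtry = 2, num_trees = 100)),
    list("neural_net", list(size = 2, decay = 0.05)),
    list("plain_logistic", list()))) {
    m1 <- fit_model(fam[[1]], d, params = fam[[2]], seed = 99)
    m2 <- fit_model(fam[[1]], d, params = fam[[2]], seed = 99)
    expect_identical(predict_proba(m1, d), predict_proba(m2, d))
  }
})

test_that("prediction contract: range, pointwise, schema enforcement", {
  d <- toy_signal_data(n = 60, p = 2, seed = 3)
  m <- fit_model("neural_net", d, params = list(size = 2, decay = 0.1),
                 seed = 1)
  p <- predict_proba(m, d)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated row -> duplicated prediction
  two <- d$features[c(1, 1), , drop = FALSE]
  expect_equal(predict_proba(m, two)[1], predict_proba(m, two)[2])
  # schema mismatch
  expect_error(predict_proba(m, d$features[, "x1", drop = FALSE]),
               "missing training column")
  dm <- mixed_data()
  mm <- fit_model("plain_logistic", dm)
  bad <- dm$features
  bad$g[1] <- "unseen"
  expect_error(predict_proba(mm, bad), "unknown level")
})

test_that("plain logistic orders predictions along the separating direction", {
  df <- data.frame(x1 = c(-2, -1.5, -1, 1, 1.5, 2))
  d <- as_dataset(df, c(0, 0, 0, 1, 1, 1),
                  feature_schema(list(list(name = "x1",
                                           kind = "continuous"))))
  m <- fit_model("plain_logistic", d)
  p <- predict_proba(m, d)
  expect_true(all(diff(p) >= 0))
  expect_gt(p[6], p[1])
})

test_that("fitted models round-trip through serialization", {
  d <- toy_signal_data(n = 60, p = 2, seed = 6)
  m <- fit_model("elastic_net_logistic", d,
                 params = list(penalty = 0.05, mixing = 0.5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict_proba(back, d), predict_proba(m, d))
  expect_identical(schema_names(back$schema), schema_names(d$schema))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(load_model(bad), "not a riskrank model artifact")
})

test_that("degenerate outcomes and bad params are rejected", {
  df <- data.frame(x1 = rnorm(20))
  d <- as_dataset(df, rep(1, 20),
                  feature_schema(list(list(name = "x1",
                                           kind = "continuous"))))
  expect_error(fit_model("plain_logistic", d), "both classes")
  expect_error(model_spec("elastic_net_logistic",
                          list(penalty = 0.1, bogus = 2)), "unknown parameter")
  expect_error(model_spec("lasso_logistic", list()), "penalty")
})
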