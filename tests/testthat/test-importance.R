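test_that("permutation importance is exactly zero for constant or unused variables", {
  # model uses x1 only; x2 is ignored by construction
  m <- identity_linear(c(1.5, 0))
  set.seed(41)
  df <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  y <- as.integer(df$x1 + rnorm(60, sd = 0.3) > 0)
  d <- as_dataset(df, y, cont_schema(2))
  vi <- permutation_vi(m, d, n_repeats = 4, seed = 2)
  expect_identical(vi$raw[vi$variable == "x2"], 0)
  expect_gt(vi$raw[vi$variable == "x1"], 0)

  # constant column: permutation is the identity on values
  df2 <- data.frame(x1 = rnorm(40), x2 = rep(1.7, 40))
  y2 <- as.integer(df2$x1 > 0)
  d2 <- as_dataset(df2, y2, cont_schema(2))
  m2 <- fit_model("plain_logistic", d2)
  vi2 <- permutation_vi(m2, d2, n_repeats = 3, seed = 3)
  expect_identical(vi2$raw[vi2$variable == "x2"], 0)
})

test_that("permutation importance separates signal from noise on a linear logit", {
  sc <- make_sim_schema(continuous = c("x1", "x2"))
  gen <- generate_survey(400, sc, effect_spec(linear = c(x1 = 3)), seed = 7)
  d <- gen$data
  m <- fit_model("plain_logistic", d)
  vi <- permutation_vi(m, d, n_repeats = 50, seed = 11)
  expect_gt(vi$raw[vi$variable == "x1"], 0.1)
  expect_lt(abs(vi$raw[vi$variable == "x2"]), 0.02)
})

test_that("FIRM importance matches hand computations on identity-scale models", {
  # f = 2 x1: PDP over {-1, 0, 1} is (-2, 0, 2); sample sd = 2
  m <- identity_linear(c(2))
  d <- as_dataset(data.frame(x1 = c(-1, 0.5, 1)), c(0, 1, 1),
                  cont_schema(1))
  pd <- pdp_1d(m, d, "x1", grid = c(-1, 0, 1))
  expect_equal(pd$yhat, c(-2, 0, 2))
  vi <- firm_vi(m, d, grid_size = 3, trim = c(0, 1))
  expect_equal(vi$raw[vi$variable == "x1"], sd(pdp_1d(m, d, "x1",
    grid = variable_grid(d, "x1", 3, c(0, 1)))$yhat))

  # additive model ignoring x2 has a flat PDP for x2
  m2 <- identity_linear(c(1.2, 0))
  d2 <- as_dataset(data.frame(x1 = rnorm(30), x2 = rnorm(30)),
                   rep(c(0, 1), 15), cont_schema(2))
  vi2 <- firm_vi(m2, d2, grid_size = 5)
  expect_identical(vi2$raw[vi2$variable == "x2"], 0)
})

test_that("FIRM categorical importance is (max - min) / 4 over level PDPs", {
  schema <- feature_schema(list(
    list(name = "g", kind = "categorical", levels = c("a", "b"))))
  m <- manual_model(function(df) ifelse(df$g == "b", 0.6, 0.2), schema)
  d <- as_dataset(data.frame(g = c("a", "b", "a", "b")), c(0, 1, 0, 1),
                  schema)
  vi <- firm_vi(m, d)
  expect_equal(vi$raw[vi$variable == "g"], (0.6 - 0.2) / 4)
})

test_that("FIRM equals |beta_j| * sd(grid_j) for identity-link linear models", {
  set.seed(90)
  for (i in 1:5) {
    p <- sample(3:6, 1)
    beta <- round(runif(p, -2, 2), 2)
    m <- identity_linear(beta)
    df <- as.data.frame(matrix(rnorm(200 * p), 200,
                               dimnames = list(NULL, paste0("x", 1:p))))
    d <- as_dataset(df, rep(c(0, 1), 100), cont_schema(p))
    vi <- firm_vi(m, d, grid_size = 12)
    expected <- vapply(seq_len(p), function(j) {
      abs(beta[j]) * sd(variable_grid(d, paste0("x", j), 12))
    }, numeric(1))
    expect_equal(vi$raw[match(paste0("x", 1:p), vi$variable)], expected,
                 tolerance = 1e-10)
  }
})

test_that("scaling maps the best variable to 100 and flags degenerate cases", {
  m <- identity_linear(c(2, 1, 0))
  df <- as.data.frame(matrix(rnorm(150 * 3), 150,
                             dimnames = list(NULL, paste0("x", 1:3))))
  d <- as_dataset(df, rep(c(0, 1), 75), cont_schema(3))
  vi <- firm_vi(m, d)
  expect_equal(max(vi$scaled), 100)
  expect_identical(vi$scaled[vi$variable == "x3"], 0)

  m0 <- identity_linear(c(0, 0, 0))
  vi0 <- firm_vi(m0, d)
  expect_true(all(is.na(vi0$scaled)))
  expect_true(isTRUE(attr(vi0, "all_nonpositive")))
})

test_that("top-k ranking: order, ties, aggregation, k > p", {
  sc <- data.frame(variable = c("b", "a", "c"), feature = c("b", "a", "c"),
                   raw = c(3, 3, 1), scaled = c(100, 100, 33),
                   method = "pdp_variance", stringsAsFactors = FALSE)
  expect_identical(top_k(sc, 1)$variable, "a")        # tie -> name order
  expect_identical(top_k(sc, 10)$variable, c("a", "b", "c"))
  agg <- data.frame(variable = c("g.b", "g.c", "x"), feature = c("g", "g", "x"),
                    raw = c(0.3, 0.2, 0.4), scaled = c(30, 20, 40),
                    method = "pdp_variance", stringsAsFactors = FALSE)
  out <- top_k(agg, 2, aggregate = TRUE)
  expect_equal(out$scaled[out$variable == "g"], 50)   # sum per source feature
})

test_that("percentile machinery matches hand-computed type-7 quantiles", {
  reps <- seq(10, 100, by = 10)
  ci <- percentile_ci(reps, level = 0.90)
  expect_equal(unname(ci), c(14.5, 95.5))
  expect_equal(unname(percentile_ci(rep(7, 5), 0.95)), c(7, 7))
})

test_that("bootstrap VI intervals: structure, determinism, within-replicate scaling", {
  sc <- make_sim_schema(continuous = c("x1", "x2", "x3"))
  gen <- generate_survey(150, sc, effect_spec(linear = c(x1 = 1.5)), seed = 31)
  d <- gen$data
  ci1 <- bootstrap_vi_ci("lasso_logistic", list(penalty = 0.02), d,
                         B = 12, seed = 5, grid_size = 8)
  ci2 <- bootstrap_vi_ci("lasso_logistic", list(penalty = 0.02), d,
                         B = 12, seed = 5, grid_size = 8)
  expect_equal(as.data.frame(ci1), as.data.frame(ci2))
  expect_true(all(ci1$ci_lower <= ci1$ci_upper))
  reps <- attr(ci1, "replicates")
  expect_identical(dim(reps), c(3L, 12L))
  # scores are rescaled within each replicate: every replicate tops at 100
  expect_true(all(abs(apply(reps, 2, max, na.rm = TRUE) - 100) < 1e-9))
  # flag fires exactly when the point sits outside its interval
  expect_identical(ci1$point_outside_ci,
                   ci1$point < ci1$ci_lower | ci1$point > ci1$ci_upper)
})

test_that("consensus ranks by support then best rank", {
  lists <- list(m1 = c("a", "b", "c"), m2 = c("a", "c"), m3 = c("a", "d"),
                m4 = c("d", "b"))
  out <- consensus_variables(lists)
  expect_identical(out$variable[1], "a")     # 3 of 4 beats 2 of 4
  expect_identical(out$support[1], 3L)
  expect_setequal(out$variable, c("a", "b", "c", "d"))
  expect_identical(nrow(consensus_variables(list(c("a"), c("b")))), 0L)
  same <- consensus_variables(list(c("a", "b"), c("a", "b")))
  expect_true(all(same$support == 2L))
})
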