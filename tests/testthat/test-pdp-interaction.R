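test_that("1-D partial dependence matches direct substitution", {
  # intercept-only: flat curve
  schema <- cont_schema(2)
  m0 <- manual_model(function(df) rep(0.37, nrow(df)), schema)
  d <- as_dataset(data.frame(x1 = rnorm(25), x2 = rnorm(25)),
                  rep(c(0, 1), c(12, 13)), schema)
  pd0 <- pdp_1d(m0, d, "x1", grid = c(-1, 0, 1))
  expect_equal(pd0$yhat, rep(0.37, 3))

  # f = 3 x1: curve is 3 * grid
  m1 <- identity_linear(c(3, 0))
  pd1 <- pdp_1d(m1, d, "x1", grid = c(0, 1, 2))
  expect_equal(pd1$yhat, c(0, 3, 6))

  # f = x1 + x2 with x2 in {0, 2}: PDP(x1 = g) = g + mean(x2) = g + 1
  m2 <- identity_linear(c(1, 1))
  d2 <- as_dataset(data.frame(x1 = rnorm(10), x2 = rep(c(0, 2), 5)),
                   rep(c(0, 1), 5), schema)
  pd2 <- pdp_1d(m2, d2, "x1", grid = c(-1, 0, 2))
  expect_equal(pd2$yhat, c(-1, 0, 2) + 1)
})

test_that("PDP is invariant to row order and row duplication", {
  d <- toy_signal_data(n = 80, p = 2, seed = 51)
  m <- fit_model("elastic_net_logistic", d,
                 params = list(penalty = 0.01, mixing = 0.5))
  g <- variable_grid(d, "x1", 8)
  base <- pdp_1d(m, d, "x1", grid = g)$yhat
  shuf <- dataset_slice(d, sample(n <- 80))
  expect_equal(pdp_1d(m, shuf, "x1", grid = g)$yhat, base)
  dup <- dataset_slice(d, rep(seq_len(80), 3))
  expect_equal(pdp_1d(m, dup, "x1", grid = g)$yhat, base)
})

test_that("2-D partial dependence: separability, symmetry, constants", {
  schema <- cont_schema(2)
  d <- as_dataset(data.frame(x1 = rnorm(20), x2 = rnorm(20)),
                  rep(c(0, 1), 10), schema)
  m <- manual_model(function(df) 2 * df$x1 - 3 * df$x2, schema)
  ga <- c(-1, 0, 1); gb <- c(0, 2)
  p2 <- pdp_2d(m, d, "x1", "x2", grid_a = ga, grid_b = gb)
  expect_equal(p2$values, outer(2 * ga, -3 * gb, `+`))
  p2r <- pdp_2d(m, d, "x2", "x1", grid_a = gb, grid_b = ga)
  expect_equal(t(p2$values), p2r$values)
  mc <- manual_model(function(df) rep(0.5, nrow(df)), schema)
  expect_true(all(pdp_2d(mc, d, "x1", "x2", grid_a = ga,
                         grid_b = gb)$values == 0.5))
  expect_error(pdp_2d(m, d, "x1", "x1"), "distinct")
})

test_that("interaction strength: additive zero, product hand value, symmetry", {
  schema <- cont_schema(2)
  d <- as_dataset(data.frame(x1 = rnorm(30), x2 = rnorm(30)),
                  rep(c(0, 1), 15), schema)
  # identity-scale additive model: exactly 0
  ma <- manual_model(function(df) 1.3 * df$x1 - 0.8 * df$x2 + 0.1, schema)
  s <- interaction_strength(ma, d, "x1", "x2", grid_size = 6)
  expect_lte(s$strength, 1e-12)

  # f = x1 * x2 on {0,1}^2: conditional sds (0, sqrt(0.5)); i = 0.5 each way
  mp <- manual_model(function(df) df$x1 * df$x2, schema)
  sp <- interaction_strength(mp, d, "x1", "x2",
                             pdp = pdp_2d(mp, d, "x1", "x2",
                                          grid_a = c(0, 1), grid_b = c(0, 1)))
  expect_equal(sp$i_ab, 0.5)
  expect_equal(sp$i_ba, 0.5)
  expect_equal(sp$strength, 0.5)

  # symmetry on a fitted model
  df <- toy_signal_data(n = 100, p = 3, seed = 52)
  mf <- fit_model("elastic_net_logistic", df,
                  params = list(penalty = 0.005, mixing = 0.5), expand = TRUE)
  s_ab <- interaction_strength(mf, df, "x1", "x2", grid_size = 5)
  s_ba <- interaction_strength(mf, df, "x2", "x1", grid_size = 5)
  expect_equal(s_ab$strength, s_ba$strength, tolerance = 1e-12)

  expect_error(
    interaction_strength(mp, d, "x1", "x2",
                         pdp = pdp_2d(mp, d, "x1", "x2", grid_a = 0,
                                      grid_b = c(0, 1))),
    ">= 2 grid points")
})

test_that("pair screening enumerates the declared candidate set", {
  d <- toy_signal_data(n = 60, p = 4, seed = 53)
  m <- fit_model("plain_logistic", d)
  # 2 screening vars, 1 non-screening top var: C(2,2) + 2 = 3 pairs
  scr <- screen_pairs(m, d, demographics = c("x1", "x2"),
                      top_vars = "x3", grid_size = 4)
  expect_identical(nrow(scr), 3L)
  expect_identical(scr$rank, seq_len(3L))
  expect_true(all(diff(scr$strength) <= 0))
  # a top var that is itself a screening var is never self-paired
  scr2 <- screen_pairs(m, d, demographics = c("x1", "x2"),
                       top_vars = c("x1"), grid_size = 4)
  expect_identical(nrow(scr2), 1L)  # only (x1, x2)... dedup of both routes
  expect_false(any(scr2$var_a == scr2$var_b))
  # all-pairs override: p (p-1) / 2
  scr3 <- screen_pairs(m, d, mode = "all_pairs", grid_size = 3)
  expect_identical(nrow(scr3), 6L)
  expect_error(screen_pairs(m, d, demographics = character(0)),
               "at least one")
})

test_that("two-way expansion appends exactly the product columns", {
  d <- mixed_data()
  enc <- dummy_encode(d)           # 4 base columns
  ex <- expand_interactions(enc)
  expect_identical(ncol(ex$values), 4L + 6L)
  # no self-products: every product names two distinct parents
  prods <- ex$column_map[!is.na(ex$column_map$parent1), ]
  expect_identical(nrow(prods), 6L)
  expect_true(all(prods$parent1 != prods$parent2))
  # indicator x indicator = logical AND
  expect_equal(unname(ex$values[, "g.b:g.c"]),
               as.numeric(enc$values[, "g.b"] & enc$values[, "g.c"]))
  expect_error(expand_interactions(enc, cap = 5), "cap")
})
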