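test_that("CSV reading builds a validated dataset and infers kinds", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("y,x1,x2",
               paste(rep(c(0, 1), 6), seq(0.1, 1.2, by = 0.1),
                     rep(c("a", "b"), 6), sep = ",")),
             path)
  # explicit schema: x1 continuous even at few rows
  schema <- feature_schema(list(
    list(name = "x1", kind = "continuous"),
    list(name = "x2", kind = "categorical", levels = c("a", "b"))))
  d <- read_dataset(path, "y", schema = schema)
  expect_s3_class(d, "rr_dataset")
  expect_identical(schema_names(d$schema), c("x1", "x2"))
  expect_true(all(d$outcome %in% c(0L, 1L)))

  # inference: 12 distinct decimals > 10 => continuous; 2 strings => categorical
  expect_message(d2 <- read_dataset(path, "y"), "schema inferred")
  expect_identical(d2$schema[["x1"]]$kind, "continuous")
  expect_identical(d2$schema[["x2"]]$kind, "categorical")
  expect_identical(d2$schema[["x2"]]$reference, "a")
})

test_that("few-valued numeric columns are inferred categorical (>10 rule)", {
  df <- data.frame(a = rep(c(1, 2, 3), 5), b = seq(0.1, 1.5, by = 0.1))
  sc <- infer_schema(df)
  expect_identical(sc[["a"]]$kind, "categorical")
  expect_identical(sc[["a"]]$levels, c("1", "2", "3"))
  expect_identical(sc[["b"]]$kind, "continuous")
})

test_that("validation rejects missing cells, bad outcomes, unknown levels", {
  df <- data.frame(x1 = c(1, NA, 3, 4), g = c("a", "b", "a", "b"),
                   stringsAsFactors = FALSE)
  schema <- feature_schema(list(
    list(name = "x1", kind = "continuous"),
    list(name = "g", kind = "categorical", levels = c("a", "b"))))
  expect_error(as_dataset(df, c(0, 1, 0, 1), schema),
               "row 2, column 'x1'")
  df$x1[2] <- 2
  expect_error(as_dataset(df, c(0, 1, 2, 1), schema), "coercible")
  df$g[1] <- "zz"
  expect_error(as_dataset(df, c(0, 1, 0, 1), schema), "undeclared level")
})

test_that("schema invariants are enforced", {
  expect_error(feature_schema(list(list(name = "", kind = "continuous"))),
               "non-empty name")
  expect_error(feature_schema(list(
    list(name = "g", kind = "categorical", levels = "only"))),
    ">= 2 distinct levels")
  expect_error(feature_schema(list(
    list(name = "g", kind = "categorical", levels = c("a", "b"),
         reference = "zz"))), "not a declared level")
  expect_error(feature_schema(list(
    list(name = "x", kind = "continuous"),
    list(name = "x", kind = "continuous"))), "duplicate")
})

test_that("dummy coding follows the L-1 reference-dropped rule", {
  d <- mixed_data()
  enc <- dummy_encode(d)
  # 2 continuous + (3-level categorical -> 2 indicators)
  expect_identical(ncol(enc$values), 4L)
  expect_identical(colnames(enc$values), c("x1", "x2", "g.b", "g.c"))
  # rows (a,b,c,b), reference a: g.b indicator is (0,1,0,1)
  expect_equal(unname(enc$values[, "g.b"]), c(0, 1, 0, 1))
  expect_equal(unname(enc$values[, "g.c"]), c(0, 0, 1, 0))
  # row order preserved
  expect_equal(unname(enc$values[, "x1"]), d$features$x1)
})

test_that("binary categorical indicator matches its definition", {
  df <- data.frame(g = c("a", "b", "b"), stringsAsFactors = FALSE)
  schema <- feature_schema(list(
    list(name = "g", kind = "categorical", levels = c("a", "b"),
         reference = "a")))
  d <- as_dataset(df, c(0, 1, 1), schema)
  enc <- dummy_encode(d)
  expect_equal(unname(enc$values[, "g.b"]), c(0, 1, 1))
})

test_that("standardization uses sample (n-1) statistics", {
  df <- data.frame(x = c(1, 2, 3), stringsAsFactors = FALSE)
  d <- as_dataset(df, c(0, 1, 1),
                  feature_schema(list(list(name = "x", kind = "continuous"))))
  enc <- dummy_encode(d, standardize = TRUE)
  expect_equal(unname(enc$values[, "x"]), c(-1, 0, 1))  # sd = 1 with n-1
  expect_equal(enc$standardization$center, 2)
  expect_equal(enc$standardization$scale, 1)

  dconst <- as_dataset(data.frame(x = c(2, 2, 2)), c(0, 1, 1),
                       feature_schema(list(list(name = "x",
                                                kind = "continuous"))))
  expect_error(dummy_encode(dconst, standardize = TRUE), "constant")
})

test_that("column map reconstructs the feature partition (round trip)", {
  d <- mixed_data()
  enc <- dummy_encode(d)
  partition <- split(enc$column_map$column, enc$column_map$feature)
  expect_setequal(names(partition), schema_names(d$schema))
  expect_identical(sort(unlist(partition, use.names = FALSE)),
                   sort(colnames(enc$values)))
  # every encoded column maps to exactly one source feature
  expect_identical(anyDuplicated(enc$column_map$column), 0L)
})

test_that("encoding is deterministic", {
  d <- mixed_data()
  expect_identical(dummy_encode(d)$values, dummy_encode(d)$values)
})

test_that("schema YAML round-trips", {
  schema <- mixed_data()$schema
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(schema, path)
  back <- read_schema(path)
  expect_identical(schema_names(back), schema_names(schema))
  expect_identical(back[["g"]]$levels, schema[["g"]]$levels)
  expect_identical(back[["g"]]$reference, schema[["g"]]$reference)
})
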