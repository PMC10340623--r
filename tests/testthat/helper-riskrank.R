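# Shared fixtures and independent oracles, built in code at test time.

# Brute-force all-pairs Mann-Whitney AUC: the independent oracle the
# rank-based implementation is checked against.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Schema of purely continuous features x1..xp.
cont_schema <- function(p, prefix = "x") {
  feature_schema(lapply(paste0(prefix, seq_len(p)), function(nm) {
    list(name = nm, kind = "continuous")
  }))
}

# Identity-scale linear manual model: f(x) = intercept + sum(beta_j x_j).
identity_linear <- function(beta, intercept = 0) {
  schema <- cont_schema(length(beta))
  names(beta) <- schema_names(schema)
  manual_model(function(df) {
    intercept + as.numeric(as.matrix(df[names(beta)]) %*% beta)
  }, schema)
}

# Small informative dataset: y depends on x1 through a logistic model.
toy_signal_data <- function(n = 120, p = 3, beta1 = 2, seed = 42) {
  sc <- make_sim_schema(continuous = paste0("x", seq_len(p)))
  eff <- effect_spec(linear = stats::setNames(beta1, "x1"), intercept = 0)
  generate_survey(n, sc, eff, seed = seed)$data
}

# Tiny mixed-type dataset for encoding tests.
mixed_data <- function() {
  df <- data.frame(
    x1 = c(1.5, 2.5, 3.5, 4.5),
    x2 = c(0.1, 0.2, 0.3, 0.4),
    g = c("a", "b", "c", "b"),
    stringsAsFactors = FALSE)
  schema <- feature_schema(list(
    list(name = "x1", kind = "continuous"),
    list(name = "x2", kind = "continuous"),
    list(name = "g", kind = "categorical", levels = c("a", "b", "c"))))
  as_dataset(df, c(0, 1, 0, 1), schema)
}
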