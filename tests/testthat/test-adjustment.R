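# small preprocessed table with roles, used across adjustment tests
adj_fixture <- function(n = 120, seed = 61) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rbinom(n, 1, 0.5)
  f <- rnorm(n)
  X <- sapply(1:4, function(j) 0.7 * f + 0.4 * z1 * (j == 1) +
                0.5 * z2 + rnorm(n))
  colnames(X) <- paste0("x", 1:4)
  y <- f + 0.6 * z1 + 0.8 * z2 + rnorm(n)
  df <- data.frame(y = y, z1 = z1, z2 = z2, X)
  tab <- preprocess(data_table(df), standardize = TRUE)
  set_roles(tab, "y", paste0("x", 1:4), covariates = c("z1", "z2"))
}

test_that("the adjustment ledger is an exact orthogonal variance bookkeeping", {
  tab <- adj_fixture()
  st <- adjustment_state(tab)
  st <- adjust_univariate(st, "z1")
  st <- adjust_univariate(st, "z2")
  expect_identical(st$n_CP, 2L)
  # original SS = removed parts + residual SS, per column
  total <- colSums(st$ledger) + colSums(st$aug^2)
  expect_equal(unname(total / st$original_ss), rep(1, ncol(st$aug)),
               tolerance = 1e-8)
  # adjusted-for covariate columns are exactly zero
  expect_true(all(st$aug[, c("z1", "z2")] == 0))
  # net outcome orthogonal to every projected score
  for (pr in st$projections)
    expect_lt(abs(sum(st$aug[, "y"] * pr$score)),
              1e-8 * sqrt(sum(st$aug[, "y"]^2) * sum(pr$score^2)))
  expect_error(adjust_univariate(st, "z1"), "already adjusted")
})

test_that("adjustment residuals equal per-column regression residuals", {
  tab <- adj_fixture()
  st <- adjust_univariate(adjustment_state(tab), "z1")
  z <- tab$values[, "z1"]
  for (cl in c("y", paste0("x", 1:4))) {
    r <- residuals(lm(tab$values[, cl] ~ z - 1))
    expect_equal(unname(st$aug[, cl]), unname(r), tolerance = 1e-10)
  }
})

test_that("an orthogonal covariate removes essentially nothing", {
  set.seed(71)
  n <- 500
  df <- data.frame(y = rnorm(n), z = rnorm(n), x1 = rnorm(n))
  tab <- set_roles(preprocess(data_table(df)), "y", "x1", covariates = "z")
  st <- adjust_univariate(adjustment_state(tab), "z")
  expect_lt(max(st$ledger[1, c("y", "x1")] / st$original_ss[c("y", "x1")]), 0.02)
})

test_that("a rank-deficient covariate block compresses to a predictive score", {
  set.seed(81)
  n <- 250
  g <- rnorm(n)
  Z <- sapply(1:6, function(j) 0.8 * g + 0.6 * rnorm(n))
  Z <- cbind(Z, Z[, 1])            # exact linear dependence
  colnames(Z) <- paste0("z", 1:7)
  Z <- scale(Z)
  y <- drop(scale(g + 0.8 * rnorm(n)))
  comp <- compress_covariate_block(Z, y, fast_ctrl(n_rep = 60, A_max = 3, seed = 5))
  expect_gte(comp$selected_A, 1L)
  # duplicated columns get identical target loadings
  expect_equal(unname(comp$tp$p[7]), unname(comp$tp$p[1]), tolerance = 1e-10)
  expect_equal(var(comp$score), 1, tolerance = 1e-12)

  # a block containing y itself gives a score correlated +-1 with y
  Z2 <- cbind(scale(matrix(rnorm(n * 3), n)), y)
  colnames(Z2) <- paste0("q", 1:4)
  comp2 <- compress_covariate_block(Z2, y, fast_ctrl(n_rep = 60, A_max = 3, seed = 6))
  expect_equal(abs(cor(comp2$score, y)), 1, tolerance = 1e-6)

  # pure noise block: explicit no-signal error
  Z3 <- scale(matrix(rnorm(200 * 4), 200))
  colnames(Z3) <- paste0("n", 1:4)
  y3 <- rnorm(200); y3 <- y3 - mean(y3)
  expect_error(compress_covariate_block(Z3, y3,
                                        fast_ctrl(n_rep = 60, A_max = 3, seed = 7)),
               "no predictive association")
})

test_that("multivariate adjustment zeroes the score direction everywhere", {
  tab <- adj_fixture(n = 200, seed = 91)
  # treat x3, x4 as a mediator block for this check
  st <- adjustment_state(tab)
  Z <- tab$values[, c("x3", "x4")]
  comp <- compress_covariate_block(Z, tab$values[, "y"],
                                   fast_ctrl(n_rep = 50, A_max = 2, seed = 8))
  st <- adjust_multivariate(st, "block", comp$score)
  expect_lt(abs(cor(st$aug[, "y"], comp$score)), 1e-10)
  # re-projecting a collinear score is refused
  expect_error(adjust_multivariate(st, "block2", comp$score), "collinear")
})

test_that("net model on unadjusted state equals plain PLS + TP", {
  tab <- adj_fixture(n = 150, seed = 101)
  st <- adjustment_state(tab)
  nm <- net_model(st, A = 2)
  direct <- pls1(tab$values[, paste0("x", 1:4)], tab$values[, "y"], 2)
  expect_equal(nm$pls$b, direct$b, tolerance = 1e-12)
  tp_direct <- target_projection(direct, tab$values[, paste0("x", 1:4)])
  expect_equal(nm$tp$p, tp_direct$p, tolerance = 1e-12)
})

test_that("net model returns a null marker when associations are exhausted", {
  set.seed(111)
  n <- 300
  z <- rnorm(n)
  df <- data.frame(y = 0.9 * z + 0.3 * rnorm(n),
                   z = z,
                   x1 = 0.8 * z + 0.4 * rnorm(n),
                   x2 = 0.7 * z + 0.5 * rnorm(n))
  tab <- set_roles(preprocess(data_table(df)), "y", c("x1", "x2"),
                   covariates = "z")
  st <- adjust_univariate(adjustment_state(tab), "z")
  nm <- net_model(st, fast_ctrl(n_rep = 80, A_max = 2, seed = 9))
  expect_identical(nm$selected_A, 0L)
  expect_null(nm$tp)
})

test_that("adjusting y alone or y and X gives the same net fit quality", {
  tab <- adj_fixture(n = 250, seed = 121)
  y <- tab$values[, "y"]; X <- tab$values[, paste0("x", 1:4)]
  z <- tab$values[, "z2"]
  y_net <- drop(residuals(lm(y ~ z - 1)))
  X_net <- apply(X, 2, function(cl) residuals(lm(cl ~ z - 1)))
  f_both <- pls1(X_net, y_net, 2)
  f_yonly <- pls1(X, y_net, 2)
  ess_both <- sum(f_both$ess_y) / sum(tab$values[, "y"]^2)
  ess_yonly <- sum(f_yonly$ess_y) / sum(tab$values[, "y"]^2)
  expect_equal(ess_both, ess_yonly, tolerance = 0.05)
})
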