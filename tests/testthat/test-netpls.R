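# one moderately sized fitted cohort shared across method tests
fit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- small_cohort_spec()
    sim <- simulate_cohort(spec, seed = 33)
    cols <- cohort_columns(spec)
    fit <- netpls(reformulate(cols$explanatory, "HOMA_IR"), sim$data,
                  covariates = c("age", "sex"),
                  blocks = list(lipoproteins = cols$mediator),
                  log_columns = setdiff(colnames(sim$data), c("age", "sex")),
                  validation = fast_ctrl(n_rep = 80, A_max = 4, seed = 55),
                  stage_models = TRUE)
    cache <<- list(spec = spec, sim = sim, cols = cols, fit = fit)
    cache
  }
})

test_that("the fitted object exposes a coherent model surface", {
  fx <- fit_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "netpls")
  expect_identical(fit$state$n_CP, 3L)
  expect_named(coef(fit), fx$cols$explanatory)
  expect_length(fitted(fit), nrow(fx$sim$data))
  # total decomposition: y = y_cov + y_net_hat + e_y on the preprocessed scale
  y_pre <- fit$table$values[, "HOMA_IR"]
  y_cov <- y_pre - fit$state$aug[, "HOMA_IR"]
  expect_equal(y_cov + fitted(fit) + residuals(fit), y_pre, tolerance = 1e-10)
  # per-variable variance fractions sum to one
  expect_equal(unname(rowSums(fit$partition)), rep(1, nrow(fit$partition)),
               tolerance = 1e-6)
  # printing works
  expect_output(print(fit), "netpls")
  expect_output(print(summary(fit, blocks = list(adiposity = fx$cols$adiposity,
                                                 pa = fx$cols$pa))),
                "Remaining and explained")
})

test_that("prediction on the training data reproduces the internal fit", {
  fx <- fit_fixture()
  fit <- fx$fit
  pn <- predict(fit, newdata = fx$sim$data, type = "net")
  expect_equal(unname(pn), unname(drop(net_data(fit$state)$X_net %*% coef(fit))),
               tolerance = 1e-8)
  pr <- predict(fit, newdata = fx$sim$data, type = "response")
  # response-scale predictions positively track the observed outcome
  expect_gt(cor(pr, fx$sim$data$HOMA_IR), 0.4)
  expect_error(predict(fit, newdata = fx$sim$data[, 1:3]), "lacks column")
})

test_that("with no covariates netpls is the plain PLS + TP analysis", {
  fx <- fit_fixture()
  cols <- fx$cols
  fit0 <- netpls(reformulate(cols$explanatory, "HOMA_IR"), fx$sim$data,
                 log_columns = setdiff(colnames(fx$sim$data), c("age", "sex")),
                 validation = fast_ctrl(n_rep = 60, A_max = 3, seed = 21),
                 importance = FALSE)
  tabd <- preprocess(data_table(fx$sim$data[c("HOMA_IR", cols$explanatory)]),
                     log_columns = c("HOMA_IR", cols$explanatory))
  direct <- pls1(tabd$values[, cols$explanatory], tabd$values[, "HOMA_IR"],
                 fit0$net$selected_A)
  expect_equal(unname(coef(fit0)), unname(direct$b), tolerance = 1e-10)
  expect_identical(fit0$state$n_CP, 0L)
})

test_that("the mediated share and stagewise table behave as a nested decomposition", {
  fx <- fit_fixture()
  fit <- fx$fit
  s <- summary(fit, blocks = list(adiposity = fx$cols$adiposity, pa = fx$cols$pa))
  tab <- s$table
  expect_identical(tab$stage[1], "unadjusted")
  expect_equal(tab$remaining_outcome[1], 100)
  expect_true(all(diff(tab$remaining_outcome) <= 1e-8))
  expect_true(all(diff(tab$remaining_adiposity) <= 1e-8))
  expect_equal(fit$mediated_share,
               fit$stages[["sex"]]$explained_y - fit$stages[["lipoproteins"]]$explained_y,
               tolerance = 1e-12)
  # after adjustment the net outcome no longer associates with the mediator block
  nd <- net_data(fit$state)
  Z_net <- fit$state$aug[, fx$cols$mediator]
  val <- mc_validate(Z_net, nd$y_net, fast_ctrl(n_rep = 80, A_max = 3, seed = 13))
  expect_identical(val$selected_A, 0L)
})

test_that("run_pipeline writes deterministic artifacts", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- list(input = list(simulate = list(n = 250, seed = 17,
                                           n_lipo = 8, n_pa = 6,
                                           pa_signal = rep(0.5, 6),
                                           pa_sex = rep(0.2, 6))),
              validation = list(n_rep = 50, A_max = 3, seed = 23),
              blocks = "mediator", stage_models = FALSE,
              output_dir = dir1)
  fit <- run_pipeline(cfg)
  expect_s3_class(fit, "netpls")
  for (f in c("variance_partition.csv", "block_variance_table.csv",
              "adjustment_ledger.csv", "net_data.csv", "run_log.txt",
              "config_used.json", "preprocessing_log.json"))
    expect_true(file.exists(file.path(dir1, f)), label = f)
  cfg$output_dir <- dir2
  run_pipeline(cfg)
  for (f in c("variance_partition.csv", "block_variance_table.csv", "net_data.csv"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
})

test_that("pipeline configs round-trip through YAML and JSON", {
  cfg <- list(outcome = "y", covariates = c("age", "sex"),
              validation = list(n_rep = 100, A_max = 5, threshold = 0.5,
                                split = 0.5, cost = "RMSEP", seed = 7),
              output_dir = "out")
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  expect_equal(read_config(yml)$validation$n_rep, 100)
  expect_identical(read_config(yml)$covariates, c("age", "sex"))
  js <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), js)
  rt <- read_config(js)
  expect_identical(rt$outcome, "y")
  expect_equal(rt$validation$seed, 7)
})

test_that("models serialise to JSON with their full geometry", {
  d <- rand_xy(30, 4, seed = 3)
  fit <- pls1(d$X, d$y, 2)
  js <- model_to_json(fit)
  doc <- jsonlite::fromJSON(js)
  expect_identical(doc$criterion, "pls")
  expect_equal(doc$b, unname(fit$b), tolerance = 1e-12)
  expect_equal(dim(doc$weights), dim(fit$W))
  tp <- target_projection(fit, d$X)
  doc2 <- jsonlite::fromJSON(model_to_json(tp))
  expect_equal(doc2$loading, unname(tp$p), tolerance = 1e-12)
})
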