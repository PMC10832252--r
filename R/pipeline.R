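#' Serialize a projection model to JSON
#'
#' Writes weights, scores, loadings and the criterion-specific extras of a
#' latent-variable model (PCA, PLS, target projection) as a JSON document.
#'
#' @param model a \code{latent_model}, \code{pls_model} or \code{tp_model}.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- if (inherits(model, "tp_model")) {
    list(criterion = "tp", weights = unname(model$w), score = model$t,
         loading = unname(model$p), q = model$q,
         explained_y_fraction = model$explained_y_fraction,
         explained_X_fraction = model$explained_X_fraction,
         column_names = model$column_names)
  } else {
    out <- list(criterion = model$criterion,
                weights = model$W, scores = model$T, loadings = model$P,
                explained_ss = model$ess, column_names = model$column_names)
    if (inherits(model, "pls_model")) {
      out$q <- model$q; out$b <- unname(model$b)
      out$explained_y_fraction <- model$explained_y_fraction
    }
    out
  }
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON configuration file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Chains the stages -- data import (or synthetic-cohort simulation),
#' validation, preprocessing, covariate-block compression, stepwise
#' adjustment, net model, variance partition, importance -- and writes all
#' tables, model JSONs, figures and a run log to an output directory.
#' Deterministic given the configured seed; every table carries the
#' configuration hash and seed in the run log.
#'
#' @param config a configuration list, or a path to a YAML/JSON file with
#'   entries: \code{input} (either \code{path}/\code{format}/\code{id_column}
#'   or \code{simulate: list(n, seed)}), \code{outcome},
#'   \code{explanatory} (optional; default all remaining columns),
#'   \code{covariates}, \code{blocks} (named lists of columns, or for
#'   synthetic input the shorthand \code{"mediator"}), \code{log_columns}
#'   (vector, or \code{"all_except_covariates"}), \code{validation}
#'   (arguments to \code{\link{mc_control}}), \code{variable_blocks}
#'   (named groups for the summary table), \code{stage_models},
#'   \code{output_dir}.
#' @return the \code{\link{netpls}} fit, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$output_dir %||% stop("config$output_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(cfg_json, file.path(out_dir, "config_used.json"))
  logf("config sha: %s", substr(digest_string(cfg_json), 1, 16))

  spec <- NULL
  if (!is.null(config$input$simulate)) {
    sim_args <- config$input$simulate
    spec <- do.call(cohort_spec, sim_args[setdiff(names(sim_args), c("n", "seed"))])
    sim <- simulate_cohort(spec, n = sim_args$n %||% spec$n_subjects,
                           seed = sim_args$seed %||% 1L)
    df <- sim$data
    cols <- cohort_columns(spec)
    logf("simulated cohort: %d subjects, seed %s", nrow(df), sim_args$seed %||% 1L)
  } else {
    tab0 <- read_table(config$input$path,
                       format = config$input$format %||% "auto",
                       id_column = isTRUE(config$input$id_column))
    val <- attr(tab0, "validation")
    if (length(val$missing))
      stop("input validation: missing values in ", paste(val$missing, collapse = ", "))
    if (length(val$zero_variance))
      logf("warning: zero-variance columns: %s", paste(val$zero_variance, collapse = ", "))
    df <- as.data.frame(tab0$values)
    cols <- NULL
  }

  outcome <- config$outcome %||% if (!is.null(cols)) cols$outcome else stop("config$outcome required")
  covariates <- config$covariates %||% if (!is.null(cols)) cols$confounders else character()
  blocks <- config$blocks %||% list()
  if (identical(blocks, "mediator") && !is.null(cols))
    blocks <- list(mediator = cols$mediator)
  log_columns <- config$log_columns %||% character()
  if (identical(log_columns, "all_except_covariates"))
    log_columns <- setdiff(colnames(df), covariates)
  explanatory <- config$explanatory %||%
    setdiff(colnames(df), c(outcome, covariates, unlist(blocks)))

  ctrl <- do.call(mc_control, config$validation %||% list())
  fml <- stats::reformulate(explanatory, response = outcome)
  fit <- netpls(fml, df, covariates = covariates, blocks = blocks,
                log_columns = log_columns, validation = ctrl,
                stage_models = isTRUE(config$stage_models))
  logf("net model: %d component(s); explained %.2f%%; remaining y %.2f%%",
       fit$net$selected_A, 100 * fit$explained_net_fraction,
       100 * fit$remaining_y_fraction)

  # tables
  utils::write.csv(as.data.frame(fit$partition),
                   file.path(out_dir, "variance_partition.csv"), row.names = FALSE)
  ledger <- fit$state$ledger
  if (nrow(ledger)) {
    tidy <- data.frame(column = rep(colnames(ledger), each = nrow(ledger)),
                       projection = rep(rownames(ledger), ncol(ledger)),
                       removed_ss = as.vector(ledger),
                       removed_fraction = as.vector(
                         sweep(ledger, 2, fit$state$original_ss, "/")))
    utils::write.csv(tidy, file.path(out_dir, "adjustment_ledger.csv"),
                     row.names = FALSE)
  }
  covd <- cbind(fit$table$values[, c(outcome, covariates), drop = FALSE],
                vapply(fit$block_fits, `[[`, numeric(nrow(fit$table$values)),
                       "score"))
  if (ncol(covd) > 1)
    utils::write.csv(round(stats::cor(covd), 4),
                     file.path(out_dir, "covariate_correlations.csv"))
  vb <- config$variable_blocks
  if (is.null(vb) && !is.null(cols))
    vb <- list(adiposity = cols$adiposity, pa = cols$pa)
  s <- summary(fit, blocks = vb)
  utils::write.csv(s$table, file.path(out_dir, "block_variance_table.csv"),
                   row.names = FALSE)
  if (!is.null(fit$importance))
    utils::write.csv(as.data.frame(fit$importance),
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
  if (fit$net$selected_A > 0L) {
    model_to_json(fit$net$pls, file.path(out_dir, "net_pls_model.json"))
    model_to_json(fit$net$tp, file.path(out_dir, "net_tp_model.json"))
  }
  utils::write.csv(cbind(as.data.frame(fit$state$aug)),
                   file.path(out_dir, "net_data.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(fit$table$preprocessing_log, auto_unbox = TRUE,
                              digits = NA),
             file.path(out_dir, "preprocessing_log.json"))

  # figures
  plot_svg <- function(name, expr) {
    grDevices::svg(file.path(out_dir, name), width = 9, height = 5)
    on.exit(grDevices::dev.off())
    force(expr)
  }
  try(plot_svg("variance_plot.svg", plot(fit, "variance")), silent = TRUE)
  if (!is.null(fit$net$validation))
    try(plot_svg("validation_plot.svg", plot(fit, "validation")), silent = TRUE)
  if (!is.null(fit$importance))
    try(plot_svg("importance_plot.svg", plot(fit, "importance")), silent = TRUE)

  logf("artifacts written to %s", normalizePath(out_dir))
  invisible(fit)
}

# small stable polynomial string hash (hex) for provenance stamping
digest_string <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
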