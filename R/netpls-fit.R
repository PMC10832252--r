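#' Net predictive association pattern analysis
#'
#' Fits the full multivariate pattern analysis pipeline: preprocess the
#' data (optional log transform, centring, unit-variance scaling), adjust
#' the outcome and the explanatory variables for univariate covariates and
#' for multicollinear covariate blocks (each block first compressed to a
#' single predictive target score by Monte-Carlo-validated PLS + target
#' projection), fit the Monte-Carlo-validated net PLS model on the adjusted
#' data, post-process it by target projection, and assemble the orthogonal
#' variance partition and selectivity-fraction importance profile.
#'
#' All explained and remaining variances are reported as fractions of the
#' original (post-preprocessing, pre-adjustment) variance; net data are
#' never re-standardised between projection steps.
#'
#' @param formula model formula \code{outcome ~ explanatory terms}; use
#'   \code{outcome ~ .} for all columns not named as covariates or blocks.
#' @param data data.frame (or coercible) of raw numeric variables.
#' @param covariates character vector of univariate covariate columns, in
#'   projection order.
#' @param blocks named list of character vectors: multicollinear covariate
#'   blocks, each adjusted for via its target score.
#' @param log_columns columns to natural-log-transform before centring
#'   (must be strictly positive).
#' @param standardize scale all columns to unit sample variance.
#' @param validation an \code{\link{mc_control}}; its seed (if any) is the
#'   master seed from which each stage's resampling seed is derived.
#' @param order projection order over \code{c(covariates, names(blocks))};
#'   default: univariate covariates first (in the given order), then blocks.
#' @param compress_on fit each block's target-score model on the
#'   \code{"unadjusted"} data (default) or on the \code{"adjusted"} data as
#'   it stands when the block's turn comes.
#' @param A_net fixed component count for the net model (NULL: select by
#'   Monte Carlo validation).
#' @param importance compute Monte Carlo confidence limits for the
#'   selectivity fractions of the net model.
#' @param stage_models additionally refit the net model at every nested
#'   adjustment stage (unadjusted, then after each projection), enabling
#'   stagewise remaining/explained variance tables and the mediated-share
#'   estimate; costs one Monte Carlo validation per stage.
#' @return object of class \code{"netpls"}. Key elements: \code{table}
#'   (preprocessed data with provenance), \code{state} (adjustment state
#'   with variance ledger), \code{block_fits} (per-block compression
#'   models), \code{net} (validated net PLS + target projection),
#'   \code{partition} (per-variable variance partition),
#'   \code{importance}, \code{explained_net_fraction},
#'   \code{remaining_y_fraction}, \code{mediated_share}, \code{stages}.
#' @seealso \code{\link{summary.netpls}}, \code{\link{predict.netpls}},
#'   \code{\link{mc_validate}}, \code{\link{compress_covariate_block}}
#' @export
netpls <- function(formula, data, covariates = character(), blocks = list(),
                   log_columns = character(), standardize = TRUE,
                   validation = mc_control(), order = NULL,
                   compress_on = c("unadjusted", "adjusted"),
                   A_net = NULL, importance = TRUE, stage_models = FALSE) {
  cl <- match.call()
  compress_on <- match.arg(compress_on)
  data <- as.data.frame(data)
  tf <- stats::terms(formula, data = data)
  outcome <- as.character(attr(tf, "variables"))[-1][attr(tf, "response")]
  rhs <- attr(tf, "term.labels")
  block_cols <- unlist(blocks, use.names = FALSE)
  # block columns named on the formula RHS stay explanatory (they are
  # adjusted for via their target score AND re-enter the net model);
  # block columns absent from the RHS act as pure covariates
  explanatory <- setdiff(rhs, c(outcome, covariates))
  block_cols_cov <- setdiff(block_cols, explanatory)
  if (!length(explanatory)) stop("no explanatory variables left after removing covariates")
  used <- unique(c(outcome, covariates, block_cols_cov, explanatory))
  missing_cols <- setdiff(used, colnames(data))
  if (length(missing_cols))
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))

  tab <- data_table(data[used])
  tab <- set_roles(tab, outcome, explanatory,
                   covariates = c(covariates, block_cols_cov))
  tab <- preprocess(tab, log_columns = intersect(log_columns, used),
                    standardize = standardize)

  base_seed <- validation$seed
  stage_ctrl <- function(offset) {
    ctrl <- validation
    if (!is.null(base_seed)) ctrl$seed <- base_seed + offset
    ctrl
  }

  state <- adjustment_state(tab)
  y0 <- tab$values[, outcome]

  if (is.null(order)) order <- c(covariates, names(blocks))
  stopifnot(setequal(order, c(covariates, names(blocks))))

  block_fits <- list()
  stage_states <- list(unadjusted = state)
  for (i in seq_along(order)) {
    lab <- order[i]
    if (lab %in% covariates) {
      state <- adjust_univariate(state, lab)
    } else {
      vars <- blocks[[lab]]
      if (compress_on == "unadjusted") {
        Z <- tab$values[, vars, drop = FALSE]
        y_for <- y0
      } else {
        Z <- state$aug[, vars, drop = FALSE]
        y_for <- state$aug[, outcome]
      }
      comp <- compress_covariate_block(Z, y_for, stage_ctrl(i))
      block_fits[[lab]] <- comp
      state <- adjust_multivariate(state, lab, comp$score)
    }
    stage_states[[lab]] <- state
  }

  net <- net_model(state, stage_ctrl(100L), A = A_net)
  partition <- variance_partition(state, net)

  oss_y <- state$original_ss[outcome]
  explained_net <- if (net$selected_A > 0L)
    sum(net$tp$t^2) * net$tp$q^2 / oss_y else 0
  remaining_y <- sum(state$aug[, outcome]^2) / oss_y

  stages <- NULL
  mediated_share <- NA_real_
  if (stage_models) {
    stages <- lapply(seq_along(stage_states), function(i) {
      st <- stage_states[[i]]
      nm_i <- if (identical(st, state)) net
              else net_model(st, stage_ctrl(100L + i), A = A_net)
      vp <- variance_partition(st, nm_i)
      list(label = names(stage_states)[i], net = nm_i, partition = vp,
           explained_y = if (nm_i$selected_A > 0L)
             sum(nm_i$tp$t^2) * nm_i$tp$q^2 / oss_y else 0,
           remaining_y = sum(st$aug[, outcome]^2) / oss_y)
    })
    names(stages) <- names(stage_states)
    if (length(blocks)) {
      pre_block <- max(which(!(names(stage_states) %in% names(blocks))))
      mediated_share <- stages[[pre_block]]$explained_y -
        stages[[length(stages)]]$explained_y
    }
  }

  imp <- NULL
  if (importance && net$selected_A > 0L) {
    nd <- net_data(state)
    imp <- mc_importance(nd$X_net, nd$y_net, net$selected_A, stage_ctrl(200L))
  }

  structure(list(call = cl, table = tab, outcome = outcome,
                 explanatory = explanatory, covariates = covariates,
                 blocks = blocks, order = order, compress_on = compress_on,
                 state = state,
                 block_fits = block_fits, net = net, partition = partition,
                 importance = imp, validation = validation,
                 explained_net_fraction = explained_net,
                 remaining_y_fraction = remaining_y,
                 mediated_share = mediated_share, stages = stages),
            class = "netpls")
}

#' @export
print.netpls <- function(x, ...) {
  cat("Net predictive association model (netpls)\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  subjects: %d, explanatory: %d, covariate projections: %d\n",
              nrow(x$state$aug), length(x$explanatory), x$state$n_CP))
  for (lab in names(x$block_fits))
    cat(sprintf("  block '%s': %d PLS component(s), %.1f%% of outcome variance, score used for adjustment\n",
                lab, x$block_fits[[lab]]$selected_A,
                100 * x$block_fits[[lab]]$explained_y_fraction))
  if (x$net$selected_A == 0L) {
    cat("  net model: no predictive components (null model)\n")
  } else {
    cat(sprintf("  net model: %d component(s); explains %.1f%% of the original outcome variance\n",
                x$net$selected_A, 100 * x$explained_net_fraction))
  }
  cat(sprintf("  remaining outcome variance after adjustment: %.1f%%\n",
              100 * x$remaining_y_fraction))
  invisible(x)
}

#' Summarise a netpls fit
#'
#' @param object a \code{\link{netpls}} fit.
#' @param blocks optional named list of explanatory-variable blocks for the
#'   remaining/explained variance table (default: all explanatory variables
#'   as one block).
#' @param ... unused.
#' @return object of class \code{"summary.netpls"} with the stagewise (if
#'   fitted) or final block variance table, component counts, and the
#'   importance profile head.
#' @export
summary.netpls <- function(object, blocks = NULL, ...) {
  if (is.null(blocks))
    blocks <- list(outcome = object$outcome, explanatory = object$explanatory)
  else
    blocks <- c(list(outcome = object$outcome), blocks)
  parts <- if (!is.null(object$stages))
    lapply(object$stages, `[[`, "partition")
  else list(final = object$partition)
  tab <- block_variance_table(parts, blocks)
  structure(list(call = object$call, table = tab,
                 selected_A = object$net$selected_A,
                 block_fits = object$block_fits,
                 explained_net_fraction = object$explained_net_fraction,
                 remaining_y_fraction = object$remaining_y_fraction,
                 mediated_share = object$mediated_share,
                 importance = object$importance),
            class = "summary.netpls")
}

#' @export
print.summary.netpls <- function(x, ...) {
  cat("Net predictive association model\n")
  cat("  call: ", deparse(x$call), "\n\n", sep = "")
  cat("Remaining and explained variance (% of original) by stage and block:\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  cat(sprintf("\nNet model: %d component(s); %.1f%% of original outcome variance explained; %.1f%% remaining after adjustment\n",
              x$selected_A, 100 * x$explained_net_fraction,
              100 * x$remaining_y_fraction))
  if (!is.na(x$mediated_share))
    cat(sprintf("Mediated share (drop in explained outcome variance after block adjustment): %.1f%%\n",
                100 * x$mediated_share))
  if (!is.null(x$importance)) {
    cat("\nTop variables by |selectivity fraction|:\n")
    o <- order(-abs(x$importance$sf))
    print.data.frame(utils::head(x$importance[o, ], 8), digits = 3,
                     row.names = FALSE)
  }
  invisible(x)
}

#' Net regression coefficients
#'
#' @param object a \code{\link{netpls}} fit.
#' @param ... unused.
#' @return named vector: the net PLS regression vector \code{b_net} on the
#'   preprocessed scale (zero vector for a null net model).
#' @export
coef.netpls <- function(object, ...) {
  b <- if (object$net$selected_A > 0L) object$net$pls$b
       else numeric(length(object$explanatory))
  stats::setNames(b, object$explanatory)
}

#' Fitted net outcome values
#'
#' @param object a \code{\link{netpls}} fit.
#' @param ... unused.
#' @return vector of fitted values of the net target component,
#'   \code{t_TP q_TP}, on the preprocessed outcome scale.
#' @export
fitted.netpls <- function(object, ...) {
  if (object$net$selected_A == 0L) return(rep(0, nrow(object$state$aug)))
  object$net$tp$t * object$net$tp$q
}

#' Residuals of the total model
#'
#' @param object a \code{\link{netpls}} fit.
#' @param type \code{"net"}: net outcome minus net fitted values (the
#'   \code{e_y} of the total decomposition); \code{"covariate"}: the net
#'   outcome itself (what remains after covariate projections only).
#' @param ... unused.
#' @export
residuals.netpls <- function(object, type = c("net", "covariate"), ...) {
  type <- match.arg(type)
  y_net <- object$state$aug[, object$outcome]
  if (type == "covariate") return(y_net)
  y_net - fitted(object)
}

#' Predict from a netpls fit
#'
#' New subjects are put on the training preprocessing scale by replaying
#' the stored transform parameters, their covariate scores are reconstructed
#' (raw covariate columns residualised in the training projection order;
#' block scores via the stored target weights and scaling), the stored
#' projection loadings remove the covariate parts, and the net regression
#' vector is applied.
#'
#' @param object a \code{\link{netpls}} fit.
#' @param newdata data.frame of raw variables (default: training data
#'   reproduction).
#' @param type \code{"net"}: prediction of the net (covariate-adjusted)
#'   outcome on the preprocessed scale; \code{"response"}: prediction of
#'   the outcome itself (covariate parts added back, preprocessing
#'   inverted to the raw outcome scale).
#' @param ... unused.
#' @export
predict.netpls <- function(object, newdata = NULL,
                           type = c("net", "response"), ...) {
  type <- match.arg(type)
  outcome <- object$outcome
  if (is.null(newdata)) {
    y_hat_net <- fitted(object)
    if (type == "net") return(y_hat_net)
    y_cov <- object$table$values[, outcome] - object$state$aug[, outcome]
    return(invert_outcome_scale(object, y_cov + y_hat_net))
  }
  newdata <- as.data.frame(newdata)
  cols <- setdiff(colnames(object$table$values), outcome)
  M <- replay_preprocessing_cols(object$table, newdata, cols)
  M0 <- M                     # pre-adjustment scale, for unadjusted block scores
  y_cov <- rep(0, nrow(M))
  z_used <- list()
  for (pr in object$state$projections) {
    if (pr$type == "raw column") {
      z <- M[, pr$label]
    } else {
      comp <- object$block_fits[[pr$label]]
      src <- if (identical(object$compress_on, "unadjusted")) M0 else M
      zb <- src[, object$blocks[[pr$label]], drop = FALSE]
      z <- drop(zb %*% comp$tp$w) / stats::sd(comp$tp$t)
      # replay the training-time Gram-Schmidt step against earlier scores
      for (lab in names(pr$orth)) z <- z - pr$orth[[lab]] * z_used[[lab]]
    }
    z_used[[pr$label]] <- z
    p <- pr$loading
    keep <- intersect(names(p), colnames(M))
    M[, keep] <- M[, keep, drop = FALSE] - tcrossprod(z, p[keep])
    y_cov <- y_cov + z * p[[outcome]]
  }
  y_hat_net <- drop(M[, object$explanatory, drop = FALSE] %*% coef(object))
  if (type == "net") return(y_hat_net)
  invert_outcome_scale(object, y_cov + y_hat_net)
}

# replay preprocessing for a subset of columns of new raw data
replay_preprocessing_cols <- function(table, raw, cols) {
  raw <- as.data.frame(raw)
  miss <- setdiff(cols, colnames(raw))
  if (length(miss)) stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
  out <- as.matrix(raw[cols])
  storage.mode(out) <- "double"
  for (cl in cols)
    for (step in table$preprocessing_log[[cl]])
      out[, cl] <- switch(step$op,
        log = log(out[, cl]),
        center = out[, cl] - step$mean,
        scale = out[, cl] / step$sd)
  out
}

# invert the outcome's preprocessing chain (scale -> centre -> log)
invert_outcome_scale <- function(object, y_pre) {
  steps <- rev(object$table$preprocessing_log[[object$outcome]])
  for (step in steps)
    y_pre <- switch(step$op,
      scale = y_pre * step$sd,
      center = y_pre + step$mean,
      log = exp(y_pre))
  y_pre
}

#' Diagnostic and interpretation plots for a netpls fit
#'
#' @param x a \code{\link{netpls}} fit.
#' @param which \code{"validation"} (net-model Monte Carlo validation),
#'   \code{"variance"} (stacked per-variable variance partition), or
#'   \code{"importance"} (selectivity fraction profile with Monte Carlo
#'   limits).
#' @param ... passed to the underlying plot method.
#' @export
plot.netpls <- function(x, which = c("variance", "validation", "importance"), ...) {
  which <- match.arg(which)
  switch(which,
    validation = {
      if (is.null(x$net$validation)) stop("net model was fitted with fixed A; no validation to plot")
      plot(x$net$validation, ...)
    },
    variance = plot(x$partition, ...),
    importance = {
      if (is.null(x$importance)) stop("no importance profile in this fit")
      plot(x$importance, ...)
    })
  invisible(x)
}
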