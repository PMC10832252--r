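#' Initialise a stepwise covariate-adjustment state
#'
#' Builds the augmented matrix \code{[y | covariates | X]} from a
#' preprocessed \code{\link{data_table}} and starts the orthogonal variance
#' ledger: for every column the sum of squares at entry is recorded and
#' each subsequent covariate projection appends the sum of squares it
#' removed, so that at any stage
#' original SS = sum of removed parts + residual SS.
#'
#' @param table a preprocessed (centred) \code{\link{data_table}} whose
#'   roles have been assigned with \code{\link{set_roles}}.
#' @return object of class \code{"adjustment_state"} with elements
#'   \code{aug} (current residual matrix), \code{roles} (per augmented
#'   column), \code{original_ss}, \code{ledger} (0-row matrix growing by
#'   one row per projection), \code{projections} (list of label/type/score/
#'   loading records), and \code{n_CP}.
#' @export
adjustment_state <- function(table) {
  stopifnot(inherits(table, "data_table"))
  role <- table$column_roles
  outcome <- names(role)[role == "outcome"]
  if (length(outcome) != 1) stop("exactly one outcome column required")
  covs <- names(role)[role == "covariate"]
  expl <- names(role)[role == "explanatory"]
  if (!length(expl)) stop("no explanatory columns")
  cols <- c(outcome, covs, expl)
  M <- table$values[, cols, drop = FALSE]
  if (max(abs(colMeans(M))) > 1e-8)
    stop("columns must be centred before adjustment (run preprocess())")
  structure(list(aug = M,
                 roles = stats::setNames(
                   c("outcome", rep("covariate", length(covs)),
                     rep("explanatory", length(expl))), cols),
                 outcome = outcome, covariates = covs, explanatory = expl,
                 original_ss = colSums(M^2),
                 ledger = matrix(numeric(0), 0, length(cols),
                                 dimnames = list(NULL, cols)),
                 projections = list(), n_CP = 0L),
            class = "adjustment_state")
}

#' Adjust for a univariate covariate
#'
#' Performs one covariate projection on the augmented matrix: every column
#' is residualised on the named covariate column, the covariate's own
#' residual becomes exactly zero, and the removed sum of squares per column
#' is appended to the ledger.
#'
#' @param state an \code{\link{adjustment_state}}.
#' @param covariate name of a covariate column not yet adjusted for.
#' @return the updated state.
#' @export
adjust_univariate <- function(state, covariate) {
  stopifnot(inherits(state, "adjustment_state"))
  if (!covariate %in% colnames(state$aug)) stop("no such column: ", covariate)
  if (covariate %in% vapply(state$projections, `[[`, "", "label"))
    stop("covariate already adjusted for: ", covariate)
  cp <- covariate_project(state$aug, covariate)
  state$aug <- cp$M
  state$ledger <- rbind(state$ledger, cp$removed_ss)
  rownames(state$ledger)[nrow(state$ledger)] <- covariate
  state$projections <- c(state$projections,
                         list(list(label = covariate, type = "raw column",
                                   score = cp$score, loading = cp$p)))
  state$n_CP <- state$n_CP + 1L
  state
}

#' Compress a multivariate covariate block to a predictive target score
#'
#' For a multicollinear (possibly rank-deficient) covariate block Z, a
#' direct covariate projection per column is not meaningful. Instead the
#' block's association with the outcome is condensed into one latent
#' variable: a Monte-Carlo-validated PLS1 model of y on Z is fitted, then
#' post-processed by target projection, and the target score (scaled to
#' unit sample variance) is returned as a single covariate column.
#'
#' @param Z numeric matrix, centred covariate block (linear dependence
#'   among columns is allowed).
#' @param y centred outcome vector.
#' @param control an \code{\link{mc_control}} for component selection.
#' @param A optional fixed component count, bypassing validation.
#' @return list of class \code{"covariate_compression"}: \code{score}
#'   (unit-variance target score), \code{validation}, \code{pls}, \code{tp},
#'   \code{selected_A}, \code{explained_y_fraction},
#'   \code{explained_Z_fraction}.
#' @export
compress_covariate_block <- function(Z, y, control = mc_control(), A = NULL) {
  Z <- as.matrix(Z); y <- as.numeric(y)
  val <- NULL
  if (is.null(A)) {
    val <- mc_validate(Z, y, control)
    A <- val$selected_A
  }
  if (A == 0L)
    stop("no predictive association between the covariate block and the ",
         "outcome (0 components selected); nothing to adjust for")
  fit <- pls1(Z, y, A)
  tp <- target_projection(fit, Z, y)
  score <- tp$t / stats::sd(tp$t)
  structure(list(score = score, validation = val, pls = fit, tp = tp,
                 selected_A = fit$A,
                 explained_y_fraction = fit$explained_y_fraction,
                 explained_Z_fraction = tp$explained_X_fraction),
            class = "covariate_compression")
}

#' @export
print.covariate_compression <- function(x, ...) {
  cat(sprintf("Covariate block compressed to a target score (%d PLS component(s))\n",
              x$selected_A))
  cat(sprintf("  explained outcome variance: %.1f%%\n", 100 * x$explained_y_fraction))
  cat(sprintf("  explained block variance:   %.1f%%\n", 100 * x$explained_Z_fraction))
  invisible(x)
}

#' Adjust for a multivariate covariate via its target score
#'
#' Appends the standardised target score of a covariate block to the
#' augmented matrix and performs a covariate projection on it. The outcome,
#' the explanatory variables, and the block's own columns are all
#' residualised on the score, so the ledger records the block's variance
#' pattern alongside those of the univariate covariates.
#'
#' The incoming score is first residualised on the scores of all previous
#' projections (Gram-Schmidt): this is equivalent to the score column
#' having been part of the augmented matrix since the first projection,
#' and it is what keeps the removed variance parts of successive
#' projections mutually orthogonal. The net data are unaffected (the
#' projection span is the same); only the per-projection attribution in
#' the ledger depends on the order, as for any correlated covariates.
#'
#' @param state an \code{\link{adjustment_state}}.
#' @param label name for the projection (e.g. \code{"lipoproteins"}).
#' @param score the unit-variance target score, typically
#'   \code{compress_covariate_block(...)$score}; must be centred.
#' @return the updated state.
#' @export
adjust_multivariate <- function(state, label, score) {
  stopifnot(inherits(state, "adjustment_state"))
  score <- as.numeric(score)
  if (length(score) != nrow(state$aug))
    stop("score length must equal the number of subjects")
  score <- score - mean(score)
  ss_in <- sum(score^2)
  orth <- numeric(0)
  for (pr in state$projections) {
    cf <- sum(pr$score * score) / sum(pr$score^2)
    score <- score - cf * pr$score
    orth[pr$label] <- cf
  }
  if (sum(score^2) < 1e-10 * ss_in)
    stop("target score is collinear with the already-projected covariate scores")
  if (label %in% vapply(state$projections, `[[`, "", "label"))
    stop("projection label already used: ", label)
  M <- cbind(state$aug, score)
  colnames(M)[ncol(M)] <- label
  cp <- covariate_project(M, label)
  state$aug <- cp$M[, colnames(state$aug), drop = FALSE]
  state$ledger <- rbind(state$ledger,
                        cp$removed_ss[colnames(state$aug)])
  rownames(state$ledger)[nrow(state$ledger)] <- label
  state$projections <- c(state$projections,
                         list(list(label = label, type = "target score",
                                   score = score, orth = orth,
                                   loading = cp$p[colnames(state$aug)])))
  state$n_CP <- state$n_CP + 1L
  state
}

#' Net outcome and net explanatory matrix of an adjustment state
#'
#' @param state an \code{\link{adjustment_state}}.
#' @return list with \code{y_net} and \code{X_net} (explanatory residuals).
#' @export
net_data <- function(state) {
  stopifnot(inherits(state, "adjustment_state"))
  list(y_net = state$aug[, state$outcome],
       X_net = state$aug[, state$explanatory, drop = FALSE])
}

#' Fit the net predictive model on adjusted data
#'
#' Runs Monte-Carlo-validated PLS1 of the net outcome on the net
#' explanatory matrix and post-processes by target projection. Net data are
#' used as they stand (centred residuals, not re-standardised), so all
#' explained variances remain expressible as fractions of the original,
#' pre-adjustment variance.
#'
#' @param state an \code{\link{adjustment_state}} (possibly with zero
#'   projections, in which case this is the plain analysis of the
#'   unadjusted data).
#' @param control an \code{\link{mc_control}}.
#' @param A optional fixed component count, bypassing validation.
#' @return list of class \code{"net_model"}: \code{validation}, \code{pls},
#'   \code{tp}, \code{selected_A}; when validation selects 0 components the
#'   \code{pls}/\code{tp} slots are NULL and \code{selected_A} is 0 (a null
#'   model: no predictive net association).
#' @export
net_model <- function(state, control = mc_control(), A = NULL) {
  nd <- net_data(state)
  v <- colSums(nd$X_net^2)
  if (all(v < 1e-12)) stop("no explanatory column with nonzero residual variance")
  val <- NULL
  if (is.null(A)) {
    val <- mc_validate(nd$X_net, nd$y_net, control)
    A <- val$selected_A
  }
  if (A == 0L)
    return(structure(list(validation = val, pls = NULL, tp = NULL,
                          selected_A = 0L), class = "net_model"))
  fit <- pls1(nd$X_net, nd$y_net, A)
  tp <- target_projection(fit, nd$X_net, nd$y_net)
  structure(list(validation = val, pls = fit, tp = tp,
                 selected_A = fit$A), class = "net_model")
}

#' @export
print.net_model <- function(x, ...) {
  if (x$selected_A == 0L) {
    cat("Net model: no predictive components selected (null model)\n")
  } else {
    cat(sprintf("Net model: %d PLS component(s), target-projected\n", x$selected_A))
    cat(sprintf("  explained net outcome variance: %.1f%% (of the net SS)\n",
                100 * x$pls$explained_y_fraction))
  }
  invisible(x)
}

#' @export
print.adjustment_state <- function(x, ...) {
  cat(sprintf("Adjustment state: %d subjects, outcome '%s', %d explanatory, %d covariate column(s)\n",
              nrow(x$aug), x$outcome, length(x$explanatory), length(x$covariates)))
  if (x$n_CP == 0L) {
    cat("  no covariate projections performed\n")
  } else {
    rem <- 100 * colSums(x$aug^2)[x$outcome] / x$original_ss[x$outcome]
    cat("  projections:", paste(vapply(x$projections, `[[`, "", "label"),
                                collapse = " -> "), "\n")
    cat(sprintf("  remaining outcome variance: %.1f%% of original\n", rem))
  }
  invisible(x)
}
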