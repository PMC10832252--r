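#' General latent-variable projection: extract one component
#'
#' One pass of the four-step projection algorithm that underlies every model
#' in this package (PCA, PLS1, target projection, covariate projection):
#' given a column-centred matrix and a unit-length weight vector, compute the
#' score \code{t = X w}, the loading \code{p = X't / (t't)}, and the deflated
#' matrix \code{X - t p'}. The residual matrix is orthogonal to the score.
#'
#' @param X numeric matrix, column-centred (N subjects x V variables).
#' @param w numeric weight vector of length V with unit Euclidean norm.
#' @return list with elements \code{t} (score, length N), \code{p} (loading,
#'   length V), \code{X_next} (deflated matrix), and \code{ss} (sum of squares
#'   removed, \code{(t't)(p'p)}).
#' @export
project_component <- function(X, w) {
  X <- as.matrix(X)
  w <- as.numeric(w)
  if (length(w) != ncol(X))
    stop("weight vector length must equal ncol(X)")
  nw <- sqrt(sum(w^2))
  if (abs(nw - 1) > 1e-8)
    stop("weight vector must have unit length")
  t <- drop(X %*% w)
  tt <- sum(t^2)
  if (tt <= .Machine$double.eps * max(1, sum(X^2)))
    stop("degenerate component: score vector is numerically zero ",
         "(weight orthogonal to the column space)")
  p <- drop(crossprod(X, t)) / tt
  X_next <- X - tcrossprod(t, p)
  list(t = t, p = p, X_next = X_next, ss = tt * sum(p^2))
}

#' Principal component analysis by power iteration
#'
#' Extracts \code{A} principal components with the projection algorithm:
#' the weight vector of each component is the fixed point of iterating
#' score and loading updates until the normalised loading reproduces the
#' weight. Components coincide with the truncated singular value
#' decomposition of \code{X} up to sign; each component is oriented so that
#' its largest-magnitude loading entry is positive.
#'
#' @param X numeric matrix, column-centred.
#' @param A number of components, at most \code{min(N - 1, V)}.
#' @param tol convergence tolerance on the change in the weight vector
#'   between successive iterations.
#' @param max_iter maximum iterations per component before an error. The
#'   fixed-point iteration is run on the V x V cross-product matrix, so a
#'   generous ceiling costs little even for slowly separating eigenvalues.
#' @return object of class \code{"latent_model"}: list with \code{W}, \code{T},
#'   \code{P} (weights, scores, loadings as V x A, N x A, V x A matrices),
#'   \code{criterion = "pca"}, \code{ess} (explained sum of squares per
#'   component) and \code{degenerate} (TRUE where successive components have
#'   numerically equal explained sums of squares, i.e. the principal subspace
#'   is not uniquely oriented).
#' @export
pca_nipals <- function(X, A, tol = 1e-12, max_iter = 10000L) {
  X <- as.matrix(X)
  n <- nrow(X); v <- ncol(X)
  if (A > min(n - 1L, v))
    stop("A must be at most min(N - 1, V)")
  W <- matrix(0, v, A); Tm <- matrix(0, n, A); P <- matrix(0, v, A)
  ess <- numeric(A)
  Xa <- X
  for (a in seq_len(A)) {
    # the score/loading alternation has fixed point w = S w / ||S w|| with
    # S = X'X; iterate on S directly so many iterations stay cheap
    S <- crossprod(Xa)
    css <- diag(S)
    if (max(css) <= .Machine$double.eps * max(1, sum(diag(S))))
      stop("degenerate component ", a, ": matrix rank exhausted")
    w <- numeric(v); w[which.max(css)] <- 1   # deterministic start
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p_raw <- drop(S %*% w)
      np <- sqrt(sum(p_raw^2))
      if (np <= .Machine$double.eps)
        stop("degenerate component ", a, ": matrix rank exhausted")
      w_new <- p_raw / np
      if (sum(w_new * w) < 0) w_new <- -w_new   # compare up to sign
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; converged <- TRUE; break }
      w <- w_new
    }
    if (!converged)
      stop("power iteration did not converge for component ", a,
           " after ", max_iter, " iterations")
    # orient: largest-magnitude loading entry positive
    t <- drop(Xa %*% w)
    p <- drop(crossprod(Xa, t)) / sum(t^2)
    if (p[which.max(abs(p))] < 0) { w <- -w; t <- -t; p <- -p }
    W[, a] <- w; Tm[, a] <- t; P[, a] <- p
    ess[a] <- sum(t^2) * sum(p^2)
    Xa <- Xa - tcrossprod(t, p)
  }
  degenerate <- c(FALSE, abs(diff(ess)) < 1e-8 * pmax(ess[-A], 1e-300))
  structure(list(W = W, T = Tm, P = P, criterion = "pca", ess = ess,
                 degenerate = degenerate,
                 column_names = colnames(X)),
            class = "latent_model")
}

#' Partial least squares regression with a single outcome (PLS1)
#'
#' Fits a PLS1 model with the projection algorithm: for each component the
#' weight vector is the normalised covariance between the current (deflated)
#' predictor matrix and the outcome, \code{w_a = X_a' y / ||X_a' y||}. Only
#' the predictor matrix is deflated; the outcome is left untouched (for a
#' single outcome this is algebraically equivalent to schemes that deflate
#' both). The regression vector is recovered as \code{b = W (P'W)^{-1} q}
#' via a triangular solve: \code{P'W} is unit upper triangular in this
#' scheme.
#'
#' @param X numeric matrix, column-centred predictors.
#' @param y numeric vector, centred outcome.
#' @param A number of components to extract.
#' @return object of class \code{c("pls_model", "latent_model")}: weights
#'   \code{W}, scores \code{T}, loadings \code{P}, inner coefficients
#'   \code{q}, regression vector \code{b}, per-component explained outcome
#'   sum of squares \code{ess_y}, explained predictor sum of squares
#'   \code{ess}, \code{explained_y_fraction}, and the data dimensions.
#'   If \code{X_a' y} vanishes before \code{A} components are extracted the
#'   model is truncated with a warning.
#' @export
pls1 <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (A < 1L) stop("A must be at least 1")
  n <- nrow(X); v <- ncol(X)
  ssy <- sum(y^2)
  if (ssy == 0) stop("outcome has zero variance")
  W <- matrix(0, v, A); Tm <- matrix(0, n, A); P <- matrix(0, v, A)
  q <- numeric(A); ess <- numeric(A); ess_y <- numeric(A)
  Xa <- X
  tol <- 1e-12 * sqrt(sum(X^2) * ssy)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, y))
    nw <- sqrt(sum(w^2))
    if (nw <= tol) {
      if (a == 1L)
        stop("X'y is zero: no predictive component can be extracted")
      warning("X'y vanished after ", a - 1L,
              " components; returning a truncated model")
      break
    }
    w <- w / nw
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(Xa, t)) / tt
    q[a] <- sum(y * t) / tt
    W[, a] <- w; Tm[, a] <- t; P[, a] <- p
    ess[a] <- tt * sum(p^2)
    ess_y[a] <- q[a]^2 * tt
    Xa <- Xa - tcrossprod(t, p)
    a_used <- a
  }
  if (a_used == 0L) stop("X'y is zero: no predictive component can be extracted")
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]; q <- q[keep]; ess <- ess[keep]; ess_y <- ess_y[keep]
  # P'W is unit upper triangular; solve R r = q and map back through W
  R <- crossprod(P, W)
  b <- drop(W %*% backsolve(R, q))
  names(b) <- colnames(X)
  structure(list(W = W, T = Tm, P = P, q = q, b = b,
                 criterion = "pls", ess = ess, ess_y = ess_y,
                 explained_y_fraction = sum(ess_y) / ssy,
                 ss_y = ssy, ss_X = sum(X^2), A = a_used,
                 column_names = colnames(X), y = y),
            class = c("pls_model", "latent_model"))
}

#' Fitted values of a PLS1 model
#'
#' @param object a \code{pls_model}.
#' @param newdata optional matrix of centred predictors; defaults to
#'   reproducing the training fit via the score matrix.
#' @param ... unused.
#' @return numeric vector of fitted (centred-scale) outcome values.
#' @export
predict.pls_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) drop(object$T %*% object$q)
  else drop(as.matrix(newdata) %*% object$b)
}

#' Target projection of a PLS1 model
#'
#' Compresses a multi-component PLS1 model into a single predictive latent
#' variable by running one pass of the projection algorithm with the
#' normalised regression vector as weight, \code{w_TP = b / ||b||}. The
#' target score is collinear with the PLS fitted values, so the target
#' component carries exactly the predictive outcome variance of the full
#' model; its loading describes how that predictive variance is distributed
#' over the explanatory variables.
#'
#' @param model a \code{pls_model} from \code{\link{pls1}}.
#' @param X the centred predictor matrix the model was fitted on.
#' @param y the centred outcome (defaults to the one stored in the model).
#' @return object of class \code{"tp_model"}: \code{w} (unit weight),
#'   \code{t} (target score), \code{p} (target loading), \code{q}
#'   (regression of y on the target score), \code{explained_y_fraction},
#'   \code{explained_X_fraction}, and \code{ss_x} (per-variable sums of
#'   squares of \code{X}, kept for selectivity measures).
#' @export
target_projection <- function(model, X, y = model$y) {
  if (!inherits(model, "pls_model")) stop("model must be a pls_model")
  X <- as.matrix(X)
  b <- model$b
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero regression vector: target projection undefined")
  w <- unname(b) / nb
  cmp <- project_component(X, w)
  t <- cmp$t; p <- cmp$p
  names(w) <- names(p) <- colnames(X)
  q <- sum(y * t) / sum(t^2)
  # orient the target score with the predicted outcome
  if (q < 0) { w <- -w; t <- -t; p <- -p; q <- -q }
  ssy <- sum(y^2)
  structure(list(w = w, t = t, p = p, q = q,
                 explained_y_fraction = q^2 * sum(t^2) / ssy,
                 explained_X_fraction = sum(t^2) * sum(p^2) / sum(X^2),
                 ss_x = colSums(X^2),
                 column_names = colnames(X)),
            class = "tp_model")
}

#' Covariate projection of an augmented data matrix
#'
#' Residualises every column of a centred matrix on one of its own columns
#' (the covariate) with a single pass of the projection algorithm using an
#' indicator weight vector: each column \code{c} becomes
#' \code{c - z (z'c) / (z'z)}. The covariate's own residual column is
#' exactly zero afterwards. This equals per-column simple-regression
#' residualisation, but performed inside one joint projection model so that
#' the removed variance is available per column.
#'
#' @param M centred numeric matrix (typically the augmented matrix
#'   \code{[y | covariates | X]}).
#' @param covariate column index or name of the covariate inside \code{M}.
#' @return list with \code{M} (residual matrix), \code{removed_ss} (named
#'   vector, sum of squares removed from each column), \code{p} (the
#'   covariate-projection loading), and \code{score} (the covariate column
#'   used as score).
#' @export
covariate_project <- function(M, covariate) {
  M <- as.matrix(M)
  j <- if (is.character(covariate)) match(covariate, colnames(M)) else as.integer(covariate)
  if (is.na(j) || j < 1L || j > ncol(M)) stop("covariate column not found")
  z <- M[, j]
  ztz <- sum(z^2)
  mean_ss <- mean(colSums(M^2))
  if (ztz < 1e-12 * max(mean_ss, .Machine$double.eps))
    stop("zero-variance (or exhausted) covariate column: ",
         if (is.character(covariate)) covariate else colnames(M)[j] %||% j)
  p <- drop(crossprod(M, z)) / ztz
  removed_ss <- ztz * p^2
  names(removed_ss) <- colnames(M)
  M_next <- M - tcrossprod(z, p)
  M_next[, j] <- 0   # exact zero for the covariate's own residual
  list(M = M_next, removed_ss = removed_ss, p = p, score = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("Latent-variable projection model (criterion: %s)\n", x$criterion))
  cat(sprintf("  components: %d, variables: %d, subjects: %d\n",
              ncol(x$W), nrow(x$W), nrow(x$T)))
  cat("  explained SS per component:", format(signif(x$ess, 4)), "\n")
  invisible(x)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d component(s), %d variables, %d subjects\n",
              x$A, nrow(x$W), nrow(x$T)))
  cat(sprintf("  explained outcome variance: %.1f%%\n",
              100 * x$explained_y_fraction))
  invisible(x)
}

#' @export
print.tp_model <- function(x, ...) {
  cat("Target-projection component\n")
  cat(sprintf("  explained outcome variance: %.1f%%\n",
              100 * x$explained_y_fraction))
  cat(sprintf("  explained explanatory-block variance: %.1f%%\n",
              100 * x$explained_X_fraction))
  invisible(x)
}
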