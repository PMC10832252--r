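#' Control settings for Monte Carlo model validation
#'
#' Bundles the tunable inputs of the repeated Monte Carlo resampling
#' procedure. The defaults mirror common practice for cohort-sized data:
#' 1000 repetitions, half of the subjects as calibration set, an acceptance
#' threshold of 0.5 on the exceedance fraction, and RMSEP as cost.
#'
#' @param n_rep number of resampling repetitions.
#' @param A_max maximum number of PLS components to assess.
#' @param threshold acceptance threshold on the exceedance fraction; a
#'   candidate component count is rejected while the fraction of its errors
#'   exceeding the median error of the model with one component less is at
#'   or above this value. Lower values are more conservative.
#' @param split fraction of subjects drawn (without replacement) into the
#'   calibration set each repetition.
#' @param cost \code{"RMSEP"} (root mean squared error of prediction) or
#'   \code{"MAE"} (mean absolute error).
#' @param seed integer seed for the resampling stream (NULL: leave the RNG
#'   state untouched).
#' @return list of class \code{"mc_control"}.
#' @export
mc_control <- function(n_rep = 1000L, A_max = 6L, threshold = 0.5,
                       split = 0.5, cost = c("RMSEP", "MAE"), seed = NULL) {
  cost <- match.arg(cost)
  stopifnot(n_rep >= 1, A_max >= 1, threshold > 0, threshold <= 1,
            split > 0, split < 1)
  structure(list(n_rep = as.integer(n_rep), A_max = as.integer(A_max),
                 threshold = threshold, split = split, cost = cost,
                 seed = seed),
            class = "mc_control")
}

#' Prediction cost on held-out subjects
#'
#' @param y_true,y_pred numeric vectors of equal, positive length.
#' @param cost \code{"RMSEP"} or \code{"MAE"}.
#' @return nonnegative scalar.
#' @export
prediction_cost <- function(y_true, y_pred, cost = c("RMSEP", "MAE")) {
  cost <- match.arg(cost)
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be nonempty vectors of equal length")
  r <- y_true - y_pred
  if (cost == "RMSEP") sqrt(mean(r^2)) else mean(abs(r))
}

#' Select the number of predictive PLS components by Monte Carlo resampling
#'
#' Repeatedly splits the subjects into a calibration and a validation half,
#' fits PLS1 models with 0 to \code{A_max} components on the calibration
#' half (centred and scaled with calibration statistics only, to avoid
#' information leakage), and records the prediction error on the held-out
#' half. The 0-component reference model predicts the calibration mean.
#'
#' Selection walks down from the component count with the smallest median
#' error: a candidate \code{A} is accepted only if fewer than
#' \code{threshold} of its errors exceed the median error of the
#' \code{A - 1}-component model (strictly greater; ties do not count as
#' exceeding); otherwise \code{A} is decremented and the comparison
#' repeated, possibly down to the 0-component model.
#'
#' @param X numeric matrix of predictors (any centring/scaling; each
#'   repetition re-centres and re-scales with calibration statistics).
#' @param y numeric outcome vector.
#' @param control an \code{\link{mc_control}} object.
#' @return object of class \code{"mc_validation"}: \code{rmsep_samples}
#'   (n_rep x (A_max + 1) matrix of costs for 0..A_max components),
#'   \code{medians}, \code{exceedance_fractions} (for each a >= 1, fraction
#'   of a-component errors exceeding the median of the a-1 model),
#'   \code{selected_A}, and \code{config}.
#' @export
mc_validate <- function(X, y, control = mc_control()) {
  stopifnot(inherits(control, "mc_control"))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("nrow(X) must equal length(y)")
  n_cal <- floor(control$split * n)
  if (n_cal < 2L || n_cal >= n) stop("split leaves too few subjects in a half")
  if (control$A_max >= n_cal)
    stop("A_max must be smaller than the calibration size (", n_cal, ")")
  if (!is.null(control$seed)) set.seed(control$seed)
  A_max <- control$A_max
  costs <- matrix(NA_real_, control$n_rep, A_max + 1L)
  for (r in seq_len(control$n_rep)) {
    for (try in seq_len(11L)) {
      idx <- sample.int(n, n_cal)
      Xc <- X[idx, , drop = FALSE]
      mu <- colMeans(Xc)
      s <- sqrt(apply(Xc, 2, stats::var))
      if (all(s > 1e-12)) break
      if (try == 11L) stop("zero-variance calibration column after 10 retries")
      warning("zero-variance calibration column; resampling this repetition")
    }
    Xc <- sweep(sweep(Xc, 2, mu), 2, s, "/")
    my <- mean(y[idx]); sy <- stats::sd(y[idx])
    if (sy < 1e-12) stop("zero-variance calibration outcome")
    yc <- (y[idx] - my) / sy
    Xv <- sweep(sweep(X[-idx, , drop = FALSE], 2, mu), 2, s, "/")
    yv <- y[-idx]
    costs[r, 1L] <- prediction_cost(yv, rep(my, length(yv)), control$cost)
    fit <- suppressWarnings(pls1(Xc, yc, A_max))   # may truncate if X'y vanishes
    # nested regression vectors for 1..A components from one fit
    R <- crossprod(fit$P, fit$W)
    for (a in seq_len(A_max)) {
      if (a > fit$A) { costs[r, a + 1L] <- costs[r, fit$A + 1L]; next }
      ba <- drop(fit$W[, 1:a, drop = FALSE] %*%
                   backsolve(R[1:a, 1:a, drop = FALSE], fit$q[1:a]))
      pred <- my + sy * drop(Xv %*% ba)
      costs[r, a + 1L] <- prediction_cost(yv, pred, control$cost)
    }
  }
  medians <- apply(costs, 2, stats::median)
  exceed <- vapply(seq_len(A_max), function(a)
    mean(costs[, a + 1L] > medians[a]), numeric(1))
  # smallest component count whose median is (numerically) minimal; the
  # tolerance keeps float-level noise on an exact fit from inflating A
  eps_tie <- 1e-8 * medians[1]
  A_star <- which(medians <= min(medians) + eps_tie)[1] - 1L
  while (A_star > 0L && exceed[A_star] >= control$threshold)
    A_star <- A_star - 1L
  structure(list(rmsep_samples = costs, medians = medians,
                 exceedance_fractions = exceed,
                 selected_A = A_star, config = control),
            class = "mc_validation")
}

#' @export
print.mc_validation <- function(x, ...) {
  A_max <- length(x$medians) - 1L
  cat(sprintf("Monte Carlo validation (%d repetitions, cost = %s)\n",
              nrow(x$rmsep_samples), x$config$cost))
  cat("  median cost by components 0..", A_max, ": ",
      paste(signif(x$medians, 4), collapse = ", "), "\n", sep = "")
  cat("  exceedance fractions (a vs a-1):",
      paste(signif(x$exceedance_fractions, 3), collapse = ", "), "\n")
  cat("  selected components:", x$selected_A, "\n")
  invisible(x)
}

#' Validation plot: error distributions by component count
#'
#' Draws the median prediction error against the number of components, with
#' the resampled error distribution as points coloured by whether each
#' error exceeds the median of the model with one component less.
#'
#' @param x an \code{\link{mc_validate}} result.
#' @param ... passed to \code{matplot}-style base graphics.
#' @export
plot.mc_validation <- function(x, ...) {
  A_max <- length(x$medians) - 1L
  a_seq <- 0:A_max
  jitter_x <- rep(a_seq, each = nrow(x$rmsep_samples)) +
    stats::runif(length(x$rmsep_samples), -0.15, 0.15)
  exceeds <- x$rmsep_samples
  exceeds[] <- FALSE
  for (a in seq_len(A_max))
    exceeds[, a + 1L] <- x$rmsep_samples[, a + 1L] > x$medians[a]
  col <- ifelse(as.vector(exceeds), "#c0392b55", "#27ae6055")
  graphics::plot(jitter_x, as.vector(x$rmsep_samples), pch = 16, cex = 0.4,
                 col = col, xlab = "number of PLS components",
                 ylab = paste0(x$config$cost, " (held-out)"), ...)
  graphics::lines(a_seq, x$medians, lwd = 2)
  graphics::points(x$selected_A, x$medians[x$selected_A + 1L], pch = 8, cex = 1.6)
  invisible(x)
}
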