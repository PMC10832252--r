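#' Selectivity fraction: signed explained predictive variance per variable
#'
#' For each explanatory variable the selectivity fraction is the fraction
#' of its total variance captured by the target component,
#' \code{SF_i = ||t_TP p_i,TP||^2 / ||x_i||^2}, signed by the direction of
#' association (the sign of the target loading, with the target score
#' oriented towards the predicted outcome). SF lies in [-1, 1]: +/-1 means
#' the variable is fully captured by (collinear with) the predictive
#' component, 0 means it carries none of the predictive variance.
#'
#' @param tp a \code{\link{target_projection}} model.
#' @param X the centred matrix the target projection was computed on
#'   (defaults to reusing the per-variable sums of squares stored in
#'   \code{tp}).
#' @return named numeric vector of signed selectivity fractions.
#' @export
selectivity_fraction <- function(tp, X = NULL) {
  stopifnot(inherits(tp, "tp_model"))
  ss_x <- if (is.null(X)) tp$ss_x else colSums(as.matrix(X)^2)
  if (any(ss_x <= 0)) stop("zero-variance explanatory variable")
  tt <- sum(tp$t^2)
  sf <- sign(tp$p) * tt * tp$p^2 / ss_x
  names(sf) <- tp$column_names %||% names(ss_x)
  sf
}

#' Selectivity ratio: explained over residual predictive variance
#'
#' \code{SR_i = ||t_TP p_i,TP||^2 / ||e_i,TP||^2} with
#' \code{e_i,TP = x_i - t_TP p_i,TP}. Unbounded above; a variable fully
#' captured by the target component has infinite ratio, reported as the
#' cap \code{1e6} with attribute \code{capped}.
#'
#' @inheritParams selectivity_fraction
#' @return named nonnegative vector with logical attribute \code{capped}.
#' @export
selectivity_ratio <- function(tp, X = NULL) {
  stopifnot(inherits(tp, "tp_model"))
  ss_x <- if (is.null(X)) tp$ss_x else colSums(as.matrix(X)^2)
  if (any(ss_x <= 0)) stop("zero-variance explanatory variable")
  tt <- sum(tp$t^2)
  expl <- tt * tp$p^2
  resid <- pmax(ss_x - expl, 0)
  capped <- resid < expl / 1e6
  sr <- ifelse(capped, 1e6, expl / pmax(resid, .Machine$double.xmin))
  sr[expl == 0] <- 0
  names(sr) <- tp$column_names %||% names(ss_x)
  attr(sr, "capped") <- capped
  sr
}

#' Monte Carlo confidence limits for selectivity fractions
#'
#' Refits the PLS + target-projection model (with the component count fixed
#' in advance by \code{\link{mc_validate}}) on repeated random calibration
#' halves, computes the selectivity fraction of every variable in each
#' refit, and summarises the resulting per-variable distributions by their
#' median and empirical 2.5/97.5 percentiles (type-7 quantiles).
#'
#' @param X numeric predictor matrix (centred or raw; each resample is
#'   centred and scaled with calibration statistics).
#' @param y outcome vector.
#' @param A fixed number of PLS components (>= 1).
#' @param control an \code{\link{mc_control}}; \code{n_rep}, \code{split}
#'   and \code{seed} are used.
#' @return object of class \code{"importance_profile"}: data.frame with
#'   columns \code{variable}, \code{sf} (full-data value), \code{sr},
#'   \code{mc_median}, \code{mc_low}, \code{mc_high}.
#' @export
mc_importance <- function(X, y, A, control = mc_control()) {
  stopifnot(inherits(control, "mc_control"))
  if (A < 1L) stop("A must be at least 1 (run mc_validate first)")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  n_cal <- floor(control$split * n)
  if (!is.null(control$seed)) set.seed(control$seed)
  sf_samples <- matrix(NA_real_, control$n_rep, ncol(X))
  for (r in seq_len(control$n_rep)) {
    for (try in seq_len(11L)) {
      idx <- sample.int(n, n_cal)
      Xc <- X[idx, , drop = FALSE]
      mu <- colMeans(Xc); s <- sqrt(apply(Xc, 2, stats::var))
      if (all(s > 1e-12)) break
      if (try == 11L) stop("zero-variance calibration column after 10 retries")
    }
    Xc <- sweep(sweep(Xc, 2, mu), 2, s, "/")
    yc <- y[idx] - mean(y[idx])
    fit <- suppressWarnings(pls1(Xc, yc, A))
    tp <- target_projection(fit, Xc, yc)
    sf_samples[r, ] <- selectivity_fraction(tp)
  }
  Xf <- sweep(X, 2, colMeans(X))
  yf <- y - mean(y)
  fit <- suppressWarnings(pls1(Xf, yf, A))
  tp <- target_projection(fit, Xf, yf)
  qs <- apply(sf_samples, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              type = 7, names = FALSE)
  out <- data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                    sf = as.numeric(selectivity_fraction(tp)),
                    sr = as.numeric(selectivity_ratio(tp)),
                    mc_median = qs[2, ], mc_low = qs[1, ], mc_high = qs[3, ],
                    row.names = NULL)
  structure(out, sf_samples = sf_samples, A = A,
            class = c("importance_profile", "data.frame"))
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("Selectivity profile (%d variables, %d-component model)\n",
              nrow(x), attr(x, "A")))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Selectivity fraction bar plot with Monte Carlo limits
#'
#' Bars show the Monte Carlo median selectivity fraction per variable in
#' input column order; whiskers span the 2.5--97.5 percentile limits.
#'
#' @param x an \code{\link{mc_importance}} profile.
#' @param ... passed to \code{barplot}.
#' @export
plot.importance_profile <- function(x, ...) {
  mids <- graphics::barplot(x$mc_median, names.arg = x$variable, las = 2,
                            ylim = range(0, x$mc_low, x$mc_high) * 1.05,
                            ylab = "selectivity fraction", cex.names = 0.6,
                            col = ifelse(x$mc_median >= 0, "#2c7fb8", "#d95f0e"),
                            border = NA, ...)
  graphics::arrows(mids, x$mc_low, mids, x$mc_high, angle = 90, code = 3,
                   length = 0.02, col = "grey30")
  graphics::abline(h = 0)
  invisible(x)
}
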