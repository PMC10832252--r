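#' Specification of a synthetic cohort with known ground truth
#'
#' Defines a linear Gaussian structural model emulating a school-cohort
#' dataset: one outcome (an insulin-resistance proxy), two confounders (a
#' binary sex indicator and a narrow continuous age), a multicollinear
#' mediator block (lipoprotein-like features generated from a few latent
#' factors, optionally with exactly duplicated columns to force rank
#' deficiency), a 3-variable adiposity block with strong pairwise
#' correlation, and a 23-variable physical-activity intensity spectrum with
#' smooth factor loadings and serially correlated noise along the intensity
#' index. Every observed variable is a fixed linear combination of
#' independent unit-variance latents, so the population covariance -- and
#' hence the true net association pattern -- is available in closed form.
#'
#' @param n_subjects default cohort size for \code{\link{simulate_cohort}}.
#' @param n_lipo number of mediator (lipoprotein-like) features.
#' @param n_pa number of physical-activity intensity variables.
#' @param adiposity_loadings loadings of the three adiposity measures on
#'   the adiposity factor (pairwise correlations ~ product of loadings).
#' @param adi_pa_cor correlation between the adiposity and activity factors.
#' @param sex_skinfold loading of the third adiposity measure on sex
#'   (negative: girls higher skinfold).
#' @param pa_signal length-\code{n_pa} loadings of the activity variables on
#'   the activity factor (smooth bump over the intensity spectrum).
#' @param pa_sex length-\code{n_pa} loadings on sex (boys more time at high
#'   intensities).
#' @param pa_rho lag-1 autocorrelation of the serial noise along the
#'   activity spectrum.
#' @param mediator_gamma k x 3 matrix: loadings of the k mediator latent
#'   factors on (adiposity factor, activity factor, sex).
#' @param mediator_weights length-k weights combining the latent factors
#'   into the mediator signal that enters the outcome.
#' @param lipo_dominant,lipo_cross dominant and cross loadings of the
#'   observed mediator features on their latent factors.
#' @param beta_y named coefficients of the outcome equation on
#'   (adiposity, pa, mediator, sex, age); all on the standardised scale.
#' @param duplicate_lipo indices of mediator columns to duplicate exactly
#'   (appended as \code{<name>_dup}), forcing linear dependence.
#' @param lognormal generate strictly positive log-normal marginals for all
#'   variables except age and sex (so the standard preprocessing --
#'   log-transform, centre, scale -- returns them to the linear scale).
#' @param log_scale standard deviation multiplier on the log scale.
#' @param age_mean,age_sd observed age distribution (years).
#' @return object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects = 836L,
                        n_lipo = 26L,
                        n_pa = 23L,
                        adiposity_loadings = c(BMI = 0.92, WCH = 0.88, skinfold = 0.80),
                        adi_pa_cor = -0.45,
                        sex_skinfold = -0.33,
                        pa_signal = 0.62 * exp(-((seq_len(23) - 12) / 9)^2),
                        pa_sex = 0.29 * seq_len(23) / 23,
                        pa_rho = 0.85,
                        mediator_gamma = rbind(c(0.315, -0.14,  0.07),
                                               c(-0.245, 0.175, -0.105),
                                               c(0.175, -0.07,  0.14)),
                        mediator_weights = c(0.6, -0.5, 0.3),
                        lipo_dominant = 0.85,
                        lipo_cross = 0.20,
                        beta_y = c(adiposity = 0.35, pa = -0.20,
                                   mediator = 0.25, sex = 0.10, age = 0.03),
                        duplicate_lipo = integer(0),
                        lognormal = TRUE,
                        log_scale = 0.3,
                        age_mean = 10.22, age_sd = 0.29) {
  stopifnot(length(adiposity_loadings) == 3, length(pa_signal) == n_pa,
            length(pa_sex) == n_pa, ncol(mediator_gamma) == 3,
            length(mediator_weights) == nrow(mediator_gamma),
            all(c("adiposity", "pa", "mediator", "sex", "age") %in% names(beta_y)),
            all(duplicate_lipo %in% seq_len(n_lipo)))
  spec <- list(n_subjects = as.integer(n_subjects), n_lipo = as.integer(n_lipo),
               n_pa = as.integer(n_pa),
               adiposity_loadings = adiposity_loadings, adi_pa_cor = adi_pa_cor,
               sex_skinfold = sex_skinfold, pa_signal = pa_signal,
               pa_sex = pa_sex, pa_rho = pa_rho,
               mediator_gamma = mediator_gamma,
               mediator_weights = mediator_weights,
               lipo_dominant = lipo_dominant, lipo_cross = lipo_cross,
               beta_y = beta_y, duplicate_lipo = as.integer(duplicate_lipo),
               lognormal = lognormal, log_scale = log_scale,
               age_mean = age_mean, age_sd = age_sd)
  class(spec) <- "cohort_spec"
  # fail fast on infeasible settings
  invisible(cohort_loadings(spec))
  spec
}

# Loading matrix of every observed variable (rows, standardised scale) over
# independent unit-variance latents (columns). Row sums of squares are 1, so
# C C' is the population correlation matrix of the analysis-scale data.
cohort_loadings <- function(spec) {
  k <- nrow(spec$mediator_gamma)
  lat <- c("u_adi", "u_pa", "sex_std", "age_std",
           paste0("e_g", seq_len(k)), "e_y",
           paste0("e_lipo", seq_len(spec$n_lipo)),
           paste0("e_adi", 1:3),
           paste0("xi_pa", seq_len(spec$n_pa)))
  row0 <- function() stats::setNames(numeric(length(lat)), lat)
  f_adi <- row0(); f_adi["u_adi"] <- 1
  f_pa <- row0()
  f_pa["u_adi"] <- spec$adi_pa_cor
  f_pa["u_pa"] <- sqrt(1 - spec$adi_pa_cor^2)
  sex <- row0(); sex["sex_std"] <- 1
  age <- row0(); age["age_std"] <- 1
  unitize <- function(r, noise_name = NULL) {
    ss <- sum(r^2)
    if (is.null(noise_name)) return(r / sqrt(ss))
    if (ss >= 0.97)
      stop("infeasible cohort_spec: systematic variance ", round(ss, 3),
           " leaves no room for noise in ", noise_name)
    r[noise_name] <- sqrt(1 - ss)
    r
  }
  # mediator latent factors (unit variance, correlated through shared parents)
  G <- t(vapply(seq_len(k), function(m) {
    g <- spec$mediator_gamma[m, 1] * f_adi + spec$mediator_gamma[m, 2] * f_pa +
      spec$mediator_gamma[m, 3] * sex
    unitize(g, paste0("e_g", m))
  }, row0()))
  # mediator signal entering the outcome
  m_sig <- drop(spec$mediator_weights %*% G)
  m_sig <- m_sig / sqrt(sum(m_sig^2))
  # outcome
  y <- spec$beta_y[["adiposity"]] * f_adi + spec$beta_y[["pa"]] * f_pa +
    spec$beta_y[["mediator"]] * m_sig + spec$beta_y[["sex"]] * sex +
    spec$beta_y[["age"]] * age
  y <- unitize(y, "e_y")
  # observed mediator features: dominant factor by block of roughly equal size
  dom <- sort(rep_len(seq_len(k), spec$n_lipo))
  lipo <- t(vapply(seq_len(spec$n_lipo), function(v) {
    d <- dom[v]
    r <- spec$lipo_dominant * G[d, ] + spec$lipo_cross * G[d %% k + 1, ]
    unitize(r, paste0("e_lipo", v))
  }, row0()))
  rownames(lipo) <- paste0("lipo_", seq_len(spec$n_lipo))
  # adiposity block
  adi <- t(vapply(1:3, function(j) {
    r <- spec$adiposity_loadings[j] * f_adi
    if (j == 3) r <- r + spec$sex_skinfold * sex
    unitize(r, paste0("e_adi", j))
  }, row0()))
  rownames(adi) <- names(spec$adiposity_loadings)
  # physical-activity spectrum with AR(1) serial noise
  rho <- spec$pa_rho
  pa <- t(vapply(seq_len(spec$n_pa), function(i) {
    r <- spec$pa_signal[i] * f_pa + spec$pa_sex[i] * sex
    ss <- sum(r^2)
    if (ss >= 0.97) stop("infeasible pa loadings at index ", i)
    kappa <- sqrt(1 - ss)
    ar <- numeric(i)
    ar[1] <- rho^(i - 1)
    if (i > 1) ar[2:i] <- rho^(i - (2:i)) * sqrt(1 - rho^2)
    r[paste0("xi_pa", seq_len(i))] <- kappa * ar
    r
  }, row0()))
  rownames(pa) <- paste0("PA_", seq_len(spec$n_pa))
  C <- rbind(HOMA_IR = y, age = age, sex = sex, lipo, adi, pa)
  if (length(spec$duplicate_lipo)) {
    dup <- C[paste0("lipo_", spec$duplicate_lipo), , drop = FALSE]
    rownames(dup) <- paste0("lipo_", spec$duplicate_lipo, "_dup")
    C <- rbind(C, dup)
  }
  C
}

#' Variable-name helper for a cohort specification
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{outcome}, \code{confounders}, \code{mediator},
#'   \code{adiposity}, \code{pa}, \code{explanatory} name vectors.
#' @export
cohort_columns <- function(spec) {
  lipo <- paste0("lipo_", seq_len(spec$n_lipo))
  if (length(spec$duplicate_lipo))
    lipo <- c(lipo, paste0("lipo_", spec$duplicate_lipo, "_dup"))
  adi <- names(spec$adiposity_loadings)
  pa <- paste0("PA_", seq_len(spec$n_pa))
  list(outcome = "HOMA_IR", confounders = c("age", "sex"), mediator = lipo,
       adiposity = adi, pa = pa, explanatory = c(adi, pa))
}

#' Generate a synthetic cohort dataset
#'
#' Draws \code{n} subjects from the structural model of a
#' \code{\link{cohort_spec}}. Apart from age and sex, marginals are
#' log-normal by default, so the standard analysis preprocessing
#' (log-transform all variables except age and sex, then centre and scale)
#' recovers the linear-scale structure exactly. The output is reproducible
#' bit-identically from \code{(spec, seed)}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param n number of subjects (default \code{spec$n_subjects}).
#' @param seed integer seed.
#' @return list with \code{data} (data.frame of raw observed variables),
#'   \code{truth} (the \code{\link{population_truth}} of the spec), and
#'   \code{spec}.
#' @export
simulate_cohort <- function(spec, n = spec$n_subjects, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  C <- cohort_loadings(spec)
  set.seed(seed)
  L <- ncol(C)
  E <- matrix(stats::rnorm(n * L), n, L, dimnames = list(NULL, colnames(C)))
  E[, "sex_std"] <- (stats::rbinom(n, 1L, 0.5) - 0.5) / 0.5
  S <- E %*% t(C)   # standardised-scale observations
  out <- as.data.frame(S)
  out$age <- spec$age_mean + spec$age_sd * S[, "age"]
  out$sex <- (S[, "sex"] + 1) / 2           # back to 0/1
  pos <- setdiff(colnames(S), c("age", "sex"))
  if (spec$lognormal) out[pos] <- exp(1 + spec$log_scale * S[, pos])
  list(data = out, truth = population_truth(spec), spec = spec)
}

# Moore-Penrose pseudoinverse via SVD (tolerance relative to largest
# singular value); used only for population-level truth computations where
# duplicated mediator columns make covariance blocks singular.
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Closed-form population ground truth of a cohort specification
#'
#' Computes, from the exact population correlation matrix implied by the
#' structural model, the quantities the analysis pipeline estimates: the
#' mediator target-score direction (the population best linear predictor of
#' the outcome from the mediator block), the net association pattern of the
#' explanatory variables with the outcome after removing age, sex and the
#' mediator score (proportional to the net covariance
#' \code{Cov(x_net, y_net)}, which is what the net target-projection
#' loading estimates), and the explained outcome-variance fractions before
#' adjustment, after confounder adjustment, and after full adjustment --
#' all as fractions of the original outcome variance.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list of class \code{"cohort_truth"}: \code{Sigma} (population
#'   correlation matrix), \code{net_pattern} (named, over explanatory
#'   variables), \code{score_outcome_cor}, \code{r2_unadjusted},
#'   \code{r2_confounders}, \code{r2_net}, \code{mediated_share}
#'   (\code{r2_confounders - r2_net}), and \code{remaining_y} (fraction of
#'   outcome variance left after all covariate projections).
#' @export
population_truth <- function(spec) {
  C <- cohort_loadings(spec)
  cols <- cohort_columns(spec)
  proj_out <- function(rows, dirs) {
    # residualise row vectors against the span of direction rows
    # (Euclidean geometry in latent space = population covariance geometry)
    d <- dirs %*% t(dirs)
    coef <- rows %*% t(dirs) %*% pinv(d)
    rows - coef %*% dirs
  }
  y <- C["HOMA_IR", , drop = FALSE]
  Z <- C[cols$mediator, , drop = FALSE]
  X <- C[cols$explanatory, , drop = FALSE]
  conf <- C[cols$confounders, , drop = FALSE]
  # mediator score: population best linear predictor of y from Z
  v <- pinv(Z %*% t(Z)) %*% (Z %*% t(y))
  s <- t(v) %*% Z
  no_signal <- sum(s^2) < 1e-14
  if (!no_signal) s <- s / sqrt(sum(s^2))
  r2_of <- function(Xr, yr) {
    sxy <- Xr %*% t(yr)
    drop(t(sxy) %*% pinv(Xr %*% t(Xr)) %*% sxy)
  }
  y_c <- proj_out(y, conf); X_c <- proj_out(X, conf)
  dirs_all <- if (no_signal) conf else rbind(conf, s)
  y_n <- proj_out(y, dirs_all); X_n <- proj_out(X, dirs_all)
  net_pattern <- drop(X_n %*% t(y_n))
  names(net_pattern) <- cols$explanatory
  structure(list(Sigma = C %*% t(C),
                 score_direction = drop(v),
                 net_pattern = net_pattern,
                 score_outcome_cor = if (no_signal) 0 else drop(s %*% t(y)),
                 r2_unadjusted = r2_of(X, y),
                 r2_confounders = r2_of(X_c, y_c),
                 r2_net = r2_of(X_n, y_n),
                 mediated_share = r2_of(X_c, y_c) - r2_of(X_n, y_n),
                 remaining_y = sum(y_n^2)),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Population ground truth\n")
  cat(sprintf("  corr(mediator score, outcome): %.3f\n", x$score_outcome_cor))
  cat(sprintf("  explained outcome variance: unadjusted %.1f%%, after confounders %.1f%%, net %.1f%%\n",
              100 * x$r2_unadjusted, 100 * x$r2_confounders, 100 * x$r2_net))
  cat(sprintf("  mediated share: %.1f%% of original outcome variance\n",
              100 * x$mediated_share))
  invisible(x)
}

#' Compare a fitted net model against the simulation ground truth
#'
#' @param fit a \code{\link{netpls}} fit on data from
#'   \code{\link{simulate_cohort}}.
#' @param truth the matching \code{\link{population_truth}}.
#' @return list with \code{pattern_correlation} (Pearson correlation of the
#'   estimated net target loading with the true net pattern),
#'   \code{explained_net_bias} (estimated minus true net explained fraction
#'   of original outcome variance), and \code{mediated_share_estimate}.
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(inherits(fit, "netpls"), inherits(truth, "cohort_truth"))
  if (fit$net$selected_A == 0L)
    return(list(pattern_correlation = 0,
                explained_net_bias = -truth$r2_net,
                mediated_share_estimate = NA_real_))
  p_hat <- fit$net$tp$p
  names(p_hat) <- fit$net$tp$column_names
  vars <- intersect(names(truth$net_pattern), names(p_hat))
  list(pattern_correlation = stats::cor(p_hat[vars], truth$net_pattern[vars]),
       explained_net_bias = fit$explained_net_fraction - truth$r2_net,
       mediated_share_estimate = fit$mediated_share)
}
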