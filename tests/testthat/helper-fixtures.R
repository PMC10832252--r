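# Shared fixture builders. Everything is generated in code under fixed seeds.

# centred random matrix
rand_centred <- function(n, v, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * v), n, v, dimnames = list(NULL, paste0("x", seq_len(v))))
  sweep(X, 2, colMeans(X))
}

# centred outcome linearly related to X plus noise
rand_xy <- function(n, v, seed = 1, noise = 0.5) {
  set.seed(seed)
  X <- rand_centred(n, v)
  beta <- rnorm(v)
  y <- drop(X %*% beta) + noise * rnorm(n)
  list(X = X, y = y - mean(y), beta = beta)
}

# small default synthetic cohort for pipeline-level tests
small_cohort_spec <- function(...) {
  cohort_spec(n_subjects = 400L, n_lipo = 12L, n_pa = 10L,
              pa_signal = 0.62 * exp(-((seq_len(10) - 5) / 4)^2),
              pa_sex = 0.29 * seq_len(10) / 10, ...)
}

fast_ctrl <- function(n_rep = 80L, A_max = 4L, seed = 11L, ...) {
  mc_control(n_rep = n_rep, A_max = A_max, seed = seed, ...)
}
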