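# Fixtures built in code: a small logistic design, a desk-size scenario, and
# a fast algorithm roster for pipeline-level tests.

# design with a known logistic relationship y ~ plogis(b0 + b1 x1 + b2 x2)
make_logistic_design <- function(n = 200, beta = c(-0.5, 2, -1), seed = 42,
                                 balanced_weights = FALSE) {
  set.seed(seed)
  X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  eta <- beta[1] + beta[2] * X$x1 + beta[3] * X$x2
  y <- rbinom(n, 1, plogis(eta))
  w <- rep(1, n)
  if (balanced_weights && any(y == 0) && any(y == 1))
    w[y == 0] <- sum(y == 1) / sum(y == 0)
  structure(list(X = X, y = y, w = w,
                 coords = data.frame(x = seq_len(n), y = seq_len(n)),
                 region = rep(NA_integer_, n),
                 variables = names(X),
                 n_dropped = c(presence = 0L, background = 0L)),
            class = "sdm_design")
}

manual_design <- function(X, y, w = rep(1, length(y))) {
  structure(list(X = X, y = y, w = w,
                 coords = data.frame(x = seq_along(y), y = seq_along(y)),
                 region = rep(NA_integer_, length(y)),
                 variables = names(X),
                 n_dropped = c(presence = 0L, background = 0L)),
            class = "sdm_design")
}

# small landscape for pipeline tests (full study size is exercised in the
# acceptance suite)
small_scenario <- function(n_presences = 150L, ...) {
  scenario_config(nrows = 60L, ncols = 90L, smooth_k = 4L,
                  n_presences = n_presences, ...)
}

fast_algorithms <- function() {
  default_algorithms(gbm_n_trees = 40L, cta_max_depth = 3L)
}

small_config <- function(seed = 1L, ...) {
  run_config(scenario = small_scenario(), n_background = 1500L,
             algorithms = fast_algorithms(), seed = seed, ...)
}
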