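#' Repeated stratified random calibration/evaluation splits
#'
#' Generates `runs` independent seeded splits, each placing (close to)
#' `train_fraction` of every class in the calibration set. Repeated random
#' splits, not a partition: the stated 80/20 ratio with three runs forces
#' this reading of "threefold random cross-validation".
#'
#' @param design an `sdm_design`.
#' @param runs number of splits (default 3).
#' @param train_fraction fraction of each class used for calibration
#'   (default 0.8).
#' @param seed integer seed.
#' @return list of splits, each a list with `run`, `train`, `test` (integer
#'   row indices into the design).
#' @export
split_cv <- function(design, runs = 3L, train_fraction = 0.8, seed = 1L) {
  idx1 <- which(design$y == 1L)
  idx0 <- which(design$y == 0L)
  if (length(idx1) < 5L || length(idx0) < 5L)
    stop("each class needs at least 5 rows for cross-validation")
  with_seed(seed, lapply(seq_len(runs), function(r) {
    tr1 <- sample(idx1, round(train_fraction * length(idx1)))
    tr0 <- sample(idx0, round(train_fraction * length(idx0)))
    train <- sort(c(tr1, tr0))
    list(run = r, train = train,
         test = sort(setdiff(c(idx1, idx0), train)))
  }))
}

#' Area under the ROC curve for presence vs background scores
#'
#' The probability that a random presence outscores a random background
#' point, ties counted one half:
#' `AUC = (#(s_p > s_b) + 0.5 #(s_p = s_b)) / (n_p n_b)`.
#' Computed from midranks, which equals the pairwise definition exactly.
#'
#' @param presence_scores,background_scores numeric score vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Presence is classified at `score >= tau` (inclusive, so a threshold equal
#' to the maximum presence score still classifies that presence correctly).
#' `tss = sensitivity + specificity - 1` by construction.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @param tau threshold in `[0, 1]`.
#' @return named list: `sensitivity`, `specificity`, `tss`.
#' @export
confusion_metrics <- function(presence_scores, background_scores, tau) {
  sens <- mean(presence_scores >= tau)
  spec <- mean(background_scores < tau)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Threshold maximizing sensitivity + specificity
#'
#' Scans every unique pooled score as a candidate threshold and returns the
#' maximizer of sensitivity + specificity (ties broken toward the smallest
#' threshold), together with the metrics achieved there and the AUC.
#'
#' @inheritParams confusion_metrics
#' @return named list: `threshold`, `sensitivity`, `specificity`, `tss`,
#'   `auc`.
#' @export
optimize_threshold <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  sp <- sort(presence_scores); sb <- sort(background_scores)
  sens <- (np - findInterval(cand, sp, left.open = TRUE)) / np
  spec <- findInterval(cand, sb, left.open = TRUE) / nb
  i <- which.max(sens + spec)  # first max = smallest threshold
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i],
       tss = sens[i] + spec[i] - 1,
       auc = auc(presence_scores, background_scores))
}

#' Permutation importance of one covariate
#'
#' For each repetition the covariate's column is randomly permuted (seeded)
#' and the model re-predicted; importance is the mean over repetitions of
#' `1 - cor(original, permuted predictions)`, clamped at 0. A covariate the
#' model ignores scores 0; constant original predictions are defined as 0.
#'
#' @param model a fitted model with a `predict` method returning scores.
#' @param design an `sdm_design` (or any list with an `X` data.frame).
#' @param variable column name to permute.
#' @param reps number of permutations (default 5).
#' @param seed integer seed.
#' @return importance score >= 0.
#' @export
permutation_importance <- function(model, design, variable, reps = 5L,
                                   seed = 1L) {
  X <- design$X
  if (!variable %in% names(X)) stop("unknown variable: ", variable)
  orig <- predict(model, X)
  if (stats::sd(orig) == 0) return(0)
  vals <- with_seed(seed, vapply(seq_len(reps), function(r) {
    Xp <- X
    Xp[[variable]] <- X[[variable]][sample.int(nrow(X))]
    perm <- predict(model, Xp)
    if (stats::sd(perm) == 0) 1 else 1 - stats::cor(orig, perm)
  }, numeric(1L)))
  max(0, mean(vals))
}

#' Importance table across models and variables
#'
#' @param models named list of fitted models.
#' @param design an `sdm_design`.
#' @param variables variables to score (default: design variables).
#' @param reps,seed passed to [permutation_importance()].
#' @return data.frame, one row per variable, one column per model plus
#'   `mean`.
#' @export
importance_table <- function(models, design, variables = design$variables,
                             reps = 5L, seed = 1L) {
  m <- vapply(models, function(mod) {
    vapply(variables, function(v)
      permutation_importance(mod, design, v, reps = reps, seed = seed),
      numeric(1L))
  }, numeric(length(variables)))
  m <- matrix(m, nrow = length(variables),
              dimnames = list(variables, names(models)))
  out <- data.frame(variable = variables, m, row.names = NULL,
                    check.names = FALSE)
  out$mean <- rowMeans(m)
  out
}

#' Marginal response curve of a model along one covariate
#'
#' Varies the focal covariate over its observed calibration range in
#' `n_steps` equal steps while holding every other covariate at its
#' calibration median (robust to the skewed distance covariates), and
#' records the model prediction at each step.
#'
#' @param model a fitted model with a `predict` method.
#' @param design an `sdm_design`.
#' @param variable focal covariate name.
#' @param n_steps number of evaluation points (>= 2, default 25).
#' @return data.frame with columns `value`, `prediction`.
#' @export
response_curve <- function(model, design, variable, n_steps = 25L) {
  if (n_steps < 2L) stop("`n_steps` must be >= 2")
  X <- design$X
  if (!variable %in% names(X)) stop("unknown variable: ", variable)
  vals <- seq(min(X[[variable]]), max(X[[variable]]), length.out = n_steps)
  med <- vapply(X, stats::median, numeric(1L))
  newX <- as.data.frame(lapply(med, rep, times = n_steps))
  names(newX) <- names(X)
  newX[[variable]] <- vals
  data.frame(value = vals, prediction = predict(model, newX))
}
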