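# Term expansion for the logistic model: linear, or linear + quadratic per
# covariate. Zero-variance columns (after expansion) are excluded.
expand_terms <- function(X, variables, terms) {
  m <- design_matrix(X, variables)
  if (terms == "quadratic") {
    q <- m^2
    colnames(q) <- paste0(variables, "_sq")
    m <- cbind(m, q)
  }
  m
}

#' Fit a weighted logistic regression (GLM)
#'
#' Maximum weighted-likelihood logistic regression by iteratively reweighted
#' least squares. Default terms are linear plus quadratic per covariate;
#' zero-variance columns are excluded and get no coefficient. Perfect or
#' quasi-perfect separation is detected from diverging linear predictors and
#' reported via the `separation` flag (the fit is still returned, with a
#' warning).
#'
#' @param design an `sdm_design`.
#' @param terms `"linear"` or `"quadratic"` (default) per-covariate terms.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return an object of class `sdm_glm` with `coefficients` (named, intercept
#'   first), `deviance`, `converged`, `separation`.
#' @export
fit_glm <- function(design, terms = c("quadratic", "linear"),
                    max_iter = 50L, tol = 1e-10) {
  terms <- match.arg(terms)
  Xt <- expand_terms(design$X, design$variables, terms)
  keep <- apply(Xt, 2L, function(col) stats::sd(col) > 0)
  Xt <- Xt[, keep, drop = FALSE]
  Xd <- cbind(`(Intercept)` = 1, Xt)
  # drop aliased columns once, via pivoted QR
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    used <- qrd$pivot[seq_len(qrd$rank)]
    used <- sort(used)
    if (!1L %in% used) used <- c(1L, used[-length(used)])
    Xd <- Xd[, used, drop = FALSE]
  }
  y <- as.numeric(design$y); w <- design$w
  beta <- numeric(ncol(Xd))
  eta <- drop(Xd %*% beta)
  dev_old <- bernoulli_deviance(y, stats::plogis(eta), w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / v
    ww <- w * v
    fit <- stats::lm.wfit(Xd, z, ww)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    eta_new <- drop(Xd %*% beta_new)
    dev_new <- bernoulli_deviance(y, stats::plogis(eta_new), w)
    # step-halve if deviance worsens (guards quasi-separation oscillation)
    step <- 1
    while (dev_new > dev_old + 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      eta_new <- drop(Xd %*% beta_new)
      dev_new <- bernoulli_deviance(y, stats::plogis(eta_new), w)
    }
    done <- abs(dev_old - dev_new) / (abs(dev_old) + 0.1) < tol
    beta <- beta_new; eta <- eta_new; dev_old <- dev_new
    if (done) { converged <- TRUE; break }
  }
  separation <- max(abs(eta)) > 25
  if (separation)
    warning("possible (quasi-)separation: linear predictor diverging")
  names(beta) <- colnames(Xd)
  structure(list(algorithm = "GLM", variables = design$variables,
                 terms = terms, coefficients = beta, deviance = dev_old,
                 converged = converged, separation = separation),
            class = c("sdm_glm", "sdm_model"))
}

#' @export
predict.sdm_glm <- function(object, newdata, ...) {
  Xt <- expand_terms(newdata, object$variables, object$terms)
  Xd <- cbind(`(Intercept)` = 1, Xt)
  cols <- names(object$coefficients)
  stats::plogis(drop(Xd[, cols, drop = FALSE] %*% object$coefficients))
}

#' Fit a surface range envelope (SRE / BIOCLIM)
#'
#' Per-variable envelopes are the `[alpha, 1 - alpha]` empirical quantiles of
#' the presence values only (linear-interpolation quantiles, R type 7, fixed
#' for reproducibility). A point is predicted 1 iff every variable lies
#' inside its envelope (inclusive), else 0.
#'
#' @param design an `sdm_design`.
#' @param alpha tail fraction clipped per side, in `[0, 0.5)` (default
#'   0.025).
#' @return an object of class `sdm_sre` with an `envelope` matrix (rows
#'   `lower`/`upper`).
#' @export
fit_sre <- function(design, alpha = 0.025) {
  if (alpha < 0 || alpha >= 0.5) stop("`alpha` must be in [0, 0.5)")
  Xp <- design$X[design$y == 1L, design$variables, drop = FALSE]
  if (!nrow(Xp)) stop("no presence rows")
  env <- vapply(Xp, function(x)
    unname(stats::quantile(x, c(alpha, 1 - alpha), type = 7)),
    numeric(2L))
  rownames(env) <- c("lower", "upper")
  structure(list(algorithm = "SRE", variables = design$variables,
                 alpha = alpha, envelope = env),
            class = c("sdm_sre", "sdm_model"))
}

#' @export
predict.sdm_sre <- function(object, newdata, ...) {
  Xm <- design_matrix(newdata, object$variables)
  inside <- rep(TRUE, nrow(Xm))
  for (j in seq_along(object$variables)) {
    inside <- inside & Xm[, j] >= object$envelope["lower", j] &
      Xm[, j] <= object$envelope["upper", j]
  }
  as.numeric(inside)
}

#' Wrap an external algorithm in the uniform fit/predict contract
#'
#' Adapters let further algorithms (random forest, GAM, MaxEnt, flexible
#' discriminant analysis, ...) join the ensemble without the package
#' implementing their internals: `fit_fun(design)` returns any object, and
#' `predict_fun(object, X)` must return scores in `[0, 1]` for a covariate
#' data.frame `X`.
#'
#' @param name algorithm id used in reports.
#' @param fit_fun function of an `sdm_design` returning an opaque model.
#' @param predict_fun function `(model, X) -> numeric in [0, 1]`.
#' @return a fit function compatible with the native algorithms: calling it
#'   on a design yields an object of class `sdm_adapter_model`.
#' @export
sdm_adapter <- function(name, fit_fun, predict_fun) {
  force(name); force(fit_fun); force(predict_fun)
  function(design, ...) {
    inner <- fit_fun(design, ...)
    structure(list(algorithm = name, variables = design$variables,
                   inner = inner, predict_fun = predict_fun),
              class = c("sdm_adapter_model", "sdm_model"))
  }
}

#' @export
predict.sdm_adapter_model <- function(object, newdata, ...) {
  p <- object$predict_fun(object$inner, newdata[object$variables])
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("adapter '", object$algorithm, "' returned scores outside [0, 1]")
  pmin(pmax(p, 0), 1)
}

#' Predict a fitted model over a covariate stack
#'
#' Cellwise model predictions as a suitability grid; a cell is nodata iff any
#' model variable is nodata there.
#'
#' @param model a fitted model (`sdm_model` or ensemble).
#' @param stack an [sdm_stack()] containing all model variables.
#' @return an [sdm_grid()] of scores in `[0, 1]`.
#' @export
predict_map <- function(model, stack) {
  vars <- model$variables
  if (!all(vars %in% names(stack)))
    stop("stack lacks model variables: ",
         paste(setdiff(vars, names(stack)), collapse = ", "))
  ref <- stack[[vars[1L]]]
  ok <- do.call(joint_valid, unname(as.list(stack[vars])))
  X <- as.data.frame(lapply(stack[vars], function(g) g$values[ok]))
  names(X) <- vars
  out <- matrix(NA_real_, grid_nrows(ref), grid_ncols(ref))
  out[ok] <- predict(model, X)
  sdm_grid(out, ref$cell_size, ref$origin)
}
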