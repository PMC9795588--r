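#' Default penalty grid for the nuisance models
#'
#' Log-spaced over `[1e-4, 1e2]`, returned in decreasing order as expected
#' by the coordinate-descent path.
#'
#' @param length_out number of grid points.
#' @return numeric vector of penalty strengths.
#' @export
default_penalty_grid <- function(length_out = 16L) {
  exp(seq(log(1e2), log(1e-4), length.out = length_out))
}

#' Fit the exposure (propensity) model
#'
#' Ridge-penalized logistic regression of treatment on all covariates, with
#' the penalty chosen by k-fold cross-validation maximizing held-out
#' log-likelihood (minimum binomial deviance). Covariates are standardized
#' internally for penalization; coefficients are reported on the original
#' scale. Predictions are clipped to `[1e-6, 1 - 1e-6]` before any odds
#' computation.
#'
#' @param X covariate matrix.
#' @param t binary treatment vector; both classes must be present.
#' @param n_cv_folds number of cross-validation folds (default 5).
#' @param penalty_grid candidate penalty strengths
#'   (default [default_penalty_grid()]).
#' @param seed optional RNG seed controlling the fold assignment.
#' @return an object of class `eca_exposure_model` with `coefficients`,
#'   `intercept`, and the selected `penalty`.
#' @export
fit_exposure_model <- function(X, t, n_cv_folds = 5L,
                               penalty_grid = default_penalty_grid(),
                               seed = NULL) {
  t <- as.integer(t)
  if (length(unique(t)) < 2L)
    stop("both arms must be present to fit the exposure model ",
         "(positivity failure)")
  stopifnot(n_cv_folds >= 3L) # coordinate-descent CV needs >= 3 folds
  local_seed_if(seed)
  d <- ncol(X)
  Xf <- pad_single_column(X)
  foldid <- balanced_folds(t, n_cv_folds)
  cv <- glmnet::cv.glmnet(Xf, t, family = "binomial", alpha = 0,
                          lambda = penalty_grid, foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  co <- stats::coef(cv, s = "lambda.min")
  structure(
    list(coefficients = as.numeric(co)[1L + seq_len(d)],
         intercept = as.numeric(co)[1L],
         penalty = cv$lambda.min),
    class = "eca_exposure_model"
  )
}

#' Predict propensity scores from an exposure model
#'
#' @param object an `eca_exposure_model`.
#' @param newdata covariate matrix.
#' @param ... unused.
#' @return propensities, clipped to the open unit interval.
#' @export
predict.eca_exposure_model <- function(object, newdata, ...) {
  eta <- object$intercept + drop(as.matrix(newdata) %*% object$coefficients)
  clip_probability(stats::plogis(eta))
}

#' Fit the control-outcome model
#'
#' Lasso-penalized linear regression of the outcome on all covariates,
#' trained on control-arm units only (`T = 0`), with the penalty chosen by
#' k-fold cross-validation minimizing held-out squared error. Covariates
#' are standardized internally; coefficients are reported on the original
#' scale.
#'
#' @param X covariate matrix (all units).
#' @param t binary treatment vector.
#' @param y outcome vector.
#' @param n_cv_folds number of cross-validation folds (default 5).
#' @param penalty_grid candidate penalty strengths.
#' @param seed optional RNG seed controlling the fold assignment.
#' @return an object of class `eca_outcome_model` with `coefficients`,
#'   `intercept`, and the selected `penalty`.
#' @export
fit_outcome_model <- function(X, t, y, n_cv_folds = 5L,
                              penalty_grid = default_penalty_grid(),
                              seed = NULL) {
  ctrl <- which(as.integer(t) == 0L)
  if (length(ctrl) < n_cv_folds)
    stop("need at least ", n_cv_folds, " control units to cross-validate")
  stopifnot(n_cv_folds >= 3L)
  local_seed_if(seed)
  d <- ncol(X)
  yc <- y[ctrl]
  if (stats::sd(yc) == 0) {
    # constant control outcome: intercept-only fit
    return(structure(
      list(coefficients = rep(0, d), intercept = yc[1L],
           penalty = max(penalty_grid)),
      class = "eca_outcome_model"))
  }
  Xf <- pad_single_column(X[ctrl, , drop = FALSE])
  foldid <- sample(rep_len(seq_len(n_cv_folds), length(ctrl)))
  cv <- glmnet::cv.glmnet(Xf, yc, alpha = 1,
                          lambda = penalty_grid, foldid = foldid,
                          type.measure = "mse", standardize = TRUE)
  co <- stats::coef(cv, s = "lambda.min")
  structure(
    list(coefficients = as.numeric(co)[1L + seq_len(d)],
         intercept = as.numeric(co)[1L],
         penalty = cv$lambda.min),
    class = "eca_outcome_model"
  )
}

#' Predict expected control outcomes from an outcome model
#'
#' @param object an `eca_outcome_model`.
#' @param newdata covariate matrix.
#' @param ... unused.
#' @return expected control-arm outcomes.
#' @export
predict.eca_outcome_model <- function(object, newdata, ...) {
  object$intercept + drop(as.matrix(newdata) %*% object$coefficients)
}

# glmnet needs >= 2 columns; a zero-variance pad column draws coefficient 0
# and is dropped when coefficients are read back.
pad_single_column <- function(X) {
  if (ncol(X) >= 2L) X else cbind(X, 0)
}

# Fold labels balanced within each treatment class, so every fold keeps
# both arms whenever class sizes allow it.
balanced_folds <- function(t, k) {
  foldid <- integer(length(t))
  for (cls in unique(t)) {
    idx <- which(t == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Serialize a nuisance model to JSON
#'
#' @param model an `eca_exposure_model` or `eca_outcome_model`.
#' @return a JSON string with class, coefficients, intercept and penalty.
#' @export
nuisance_model_to_json <- function(model) {
  stopifnot(inherits(model, c("eca_exposure_model", "eca_outcome_model")))
  jsonlite::toJSON(
    list(class = class(model)[1L], coefficients = model$coefficients,
         intercept = model$intercept, penalty = model$penalty),
    digits = NA, auto_unbox = TRUE
  )
}

#' Restore a nuisance model from JSON
#'
#' @param json a string produced by [nuisance_model_to_json()].
#' @return the reconstructed model object.
#' @export
nuisance_model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(
    list(coefficients = as.numeric(obj$coefficients),
         intercept = as.numeric(obj$intercept),
         penalty = as.numeric(obj$penalty)),
    class = obj$class
  )
}
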