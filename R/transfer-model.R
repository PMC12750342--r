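# Log10-scale soil-to-grain transfer models: predictor screening, VIF
# collinearity control, OLS fitting, prediction, importance, validation.

# Transform convention shared by screening, VIF and fitting: concentrations
# and oxide fractions enter as log10, pH and SOM raw.
predictor_transform <- function(predictor) {
  ifelse(predictor %in% c("pH", "SOM"), "raw", "log10")
}

# Build the transformed design table for a set of predictors.
transformed_predictors <- function(data, predictors) {
  out <- lapply(predictors, function(p) {
    if (!p %in% names(data)) stop("predictor not found in data: ", p)
    x <- data[[p]]
    if (predictor_transform(p) == "log10") {
      if (any(x <= 0)) stop("non-positive values in predictor ", p)
      x <- log10(x)
    }
    x
  })
  names(out) <- predictors
  as.data.frame(out, optional = TRUE)
}

#' Screen candidate soil predictors by correlation with grain concentration
#'
#' Retains soil factors whose Pearson correlation with log10 grain
#' concentration is significant at `alpha`. Concentrations and oxide
#' fractions are correlated on the log10 scale; pH and SOM on their raw
#' scale. Constant columns are dropped with a warning.
#'
#' @param data A paired soil-rice data.frame.
#' @param element `"Cd"` or `"As"`.
#' @param alpha Significance level for the correlation test (default 0.05).
#' @param candidates Candidate predictor columns; defaults to pH, SOM, the
#'   element's soil total and available fraction, and all oxide fractions.
#' @return Character vector of retained predictor names, ordered as in
#'   `candidates`.
#' @export
screen_predictors <- function(data, element = c("Cd", "As"), alpha = 0.05,
                              candidates = NULL) {
  element <- match.arg(element)
  if (nrow(data) < 10L) stop("need at least 10 samples to screen predictors")
  if (is.null(candidates)) {
    candidates <- c("pH", "SOM", soil_total_column(element),
                    available_column(element), oxide_columns())
    candidates <- intersect(candidates, names(data))
  }
  y <- log10(data[[rice_column(element)]])
  keep <- vapply(candidates, function(p) {
    x <- transformed_predictors(data, p)[[1L]]
    if (stats::sd(x) == 0) {
      warning("predictor ", p, " is constant; excluded")
      return(FALSE)
    }
    stats::cor.test(x, y)$p.value < alpha
  }, logical(1L))
  candidates[keep]
}

#' Variance inflation factors of a predictor set
#'
#' For each predictor j, VIF_j = 1 / (1 - R^2_j) where R^2_j comes from the
#' ordinary least-squares regression of predictor j on the remaining
#' predictors (on the package's transform scale). Perfect collinearity is
#' reported as `Inf` rather than an error.
#'
#' @param data A paired soil-rice data.frame (or an already-transformed
#'   numeric data.frame if `transform = FALSE`).
#' @param predictors Predictor column names (at least two).
#' @param transform Apply the standard log10/raw transforms first.
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(data, predictors, transform = TRUE) {
  if (length(predictors) < 2L) stop("VIF needs at least two predictors")
  X <- if (transform) transformed_predictors(data, predictors)
       else data[predictors]
  if (nrow(X) <= length(predictors)) stop("need n > number of predictors")
  vif <- vapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", setdiff(predictors, p)),
                                        response = sprintf("`%s`", p)),
                     data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(vif) <- predictors
  vif
}

#' Resolve collinearity among screened predictors
#'
#' Iteratively drops predictors while any VIF exceeds `vif_threshold`:
#' among the most correlated remaining pair with |r| > `corr_threshold`,
#' the available-form member (column prefixed `A_`) is dropped in favour of
#' the soil total; with no such pair, the predictor with the highest VIF is
#' dropped. Deterministic given the input order.
#'
#' @param data A paired soil-rice data.frame.
#' @param predictors Predictor names (screened).
#' @param vif_threshold Severe-collinearity cutoff (default 5).
#' @param corr_threshold Pairwise |r| cutoff for the paired-drop rule
#'   (default 0.7).
#' @return Character vector of retained predictors.
#' @export
resolve_collinearity <- function(data, predictors, vif_threshold = 5,
                                 corr_threshold = 0.7) {
  keep <- predictors
  repeat {
    if (length(keep) < 2L) break
    vif <- compute_vif(data, keep)
    if (all(vif <= vif_threshold)) break
    X <- transformed_predictors(data, keep)
    cors <- stats::cor(X)
    diag(cors) <- 0
    top <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
    pair <- keep[top]
    drop <- if (max(abs(cors)) > corr_threshold) {
      avail <- pair[startsWith(pair, "A_")]
      if (length(avail) >= 1L) avail[1L] else pair[which.max(vif[pair])]
    } else {
      names(which.max(vif))
    }
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Fit a log10 soil-to-grain transfer model
#'
#' Ordinary least squares of log10 grain concentration on soil predictors
#' (concentrations log10, pH and SOM raw):
#' `lg(C_rice) = c + sum_j beta_j * t_j(x_j)`.
#' By default predictors are screened by correlation and pruned for
#' collinearity before fitting. If the data carry a `split` column only the
#' `modeling` rows are used.
#'
#' @param data A paired soil-rice data.frame.
#' @param element `"Cd"` or `"As"`.
#' @param predictors Predictor names; `NULL` (default) screens and resolves
#'   collinearity automatically.
#' @param alpha,vif_threshold,corr_threshold Passed to [screen_predictors()]
#'   and [resolve_collinearity()].
#' @return An object of class `transfer_model` with the intercept, a terms
#'   table (predictor, coefficient, transform), fit diagnostics (R, R^2,
#'   adjusted R^2, overall F-test p-value), per-predictor VIFs, and the
#'   underlying `lm` fit.
#' @seealso [predict.transfer_model()], [invert_for_st()],
#'   [validate_transfer_model()]
#' @export
transfer_model <- function(data, element = c("Cd", "As"), predictors = NULL,
                           alpha = 0.05, vif_threshold = 5,
                           corr_threshold = 0.7) {
  element <- match.arg(element)
  if ("split" %in% names(data)) data <- data[data$split == "modeling", , drop = FALSE]
  if (is.null(predictors)) {
    predictors <- screen_predictors(data, element, alpha = alpha)
    predictors <- resolve_collinearity(data, predictors,
                                       vif_threshold = vif_threshold,
                                       corr_threshold = corr_threshold)
  }
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1L) stop("need n > number of predictors + 1")
  X <- transformed_predictors(data, predictors)
  X$.y <- log10(data[[rice_column(element)]])
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", predictors),
                                      response = ".y"), data = X)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design; dependent column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  cf <- stats::coef(fit)
  structure(list(
    element = element,
    intercept = unname(cf[1L]),
    terms = data.frame(predictor = predictors,
                       coefficient = unname(cf[-1L]),
                       transform = predictor_transform(predictors),
                       stringsAsFactors = FALSE),
    n_fit = n,
    r = sqrt(r2),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    p_value = unname(pval),
    vif = if (p >= 2L) compute_vif(data, predictors) else
      stats::setNames(1, predictors),
    lm_fit = fit
  ), class = "transfer_model")
}

#' Construct a transfer model from known coefficients
#'
#' Builds a `transfer_model` object directly from an intercept and named
#' coefficients, e.g. a published regional model or a generating truth for
#' simulation. Fit diagnostics are `NA`.
#'
#' @param element `"Cd"` or `"As"`.
#' @param intercept Intercept on the log10 mg/kg scale.
#' @param coefficients Named numeric vector of per-predictor coefficients.
#' @return A `transfer_model` object.
#' @export
as_transfer_model <- function(element, intercept, coefficients) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(
    element = element,
    intercept = intercept,
    terms = data.frame(predictor = names(coefficients),
                       coefficient = unname(coefficients),
                       transform = predictor_transform(names(coefficients)),
                       stringsAsFactors = FALSE),
    n_fit = NA_integer_, r = NA_real_, r2 = NA_real_, adj_r2 = NA_real_,
    p_value = NA_real_, vif = NULL, lm_fit = NULL
  ), class = "transfer_model")
}

#' Reference transfer models for the Gejiu-Mengzi karst paddy region
#'
#' The published regional log10 regression models of milled-rice Cd and As
#' on soil properties (116 modeling sites). These serve as the generating
#' truth of the synthetic-data module and as the default models for
#' threshold derivation when no survey data are supplied.
#'
#' @return Named list of two `transfer_model` objects (`Cd`, `As`).
#' @export
reference_models <- function() {
  list(
    Cd = as_transfer_model("Cd", 1.481, c(
      pH = -0.096, SOM = -0.003, S_T_Cd = 0.852,
      C_Fe = -0.25, F_Fe = -0.32, Am_Fe = 0.217,
      C_Mn = 0.238, Am_Mn = -0.381)),
    As = as_transfer_model("As", -2.077, c(
      pH = -0.006, SOM = -0.000125, S_T_As = 0.975, A_As = -0.003,
      C_Fe = -0.001, F_Fe = -0.017, Am_Fe = -0.006, C_Mn = -0.002))
  )
}

#' @export
coef.transfer_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$terms$coefficient),
                  c("(Intercept)", object$terms$predictor))
}

#' @export
print.transfer_model <- function(x, digits = 4, ...) {
  lhs <- sprintf("lg(Rice-%s)", x$element)
  rhs <- paste0(format(x$intercept, digits = digits),
                paste0(sprintf(" %+g*", round(x$terms$coefficient, 6)),
                       ifelse(x$terms$transform == "log10",
                              sprintf("lg(%s)", x$terms$predictor),
                              x$terms$predictor),
                       collapse = ""))
  cat("Soil-to-grain transfer model (", x$element, ")\n", sep = "")
  cat(" ", lhs, " = ", rhs, "\n", sep = "")
  if (!is.na(x$r2)) {
    cat(sprintf("  n = %d, R = %.3f, R2 = %.3f, adj. R2 = %.3f, p = %.3g\n",
                x$n_fit, x$r, x$r2, x$adj_r2, x$p_value))
  }
  invisible(x)
}

#' @export
summary.transfer_model <- function(object, ...) {
  out <- list(model = object,
              lm_summary = if (!is.null(object$lm_fit)) summary(object$lm_fit),
              vif = object$vif)
  class(out) <- "summary.transfer_model"
  out
}

#' @export
print.summary.transfer_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$lm_summary)) {
    cat("\nCoefficient tests (log10 response scale):\n")
    stats::printCoefmat(x$lm_summary$coefficients)
  }
  if (!is.null(x$vif)) {
    cat("\nVariance inflation factors:\n")
    print(round(x$vif, 3))
  }
  invisible(x)
}

#' @export
residuals.transfer_model <- function(object, ...) {
  if (is.null(object$lm_fit)) stop("no residuals: model was not fitted to data")
  stats::residuals(object$lm_fit)
}

#' Predict grain concentration from soil properties
#'
#' Evaluates the model's linear predictor on the log10 scale and, by
#' default, back-transforms to mg/kg. `newdata` must carry every predictor
#' the model names, on the linear (untransformed) scale.
#'
#' @param object A `transfer_model`.
#' @param newdata A data.frame (or coercible named list) of covariates.
#' @param type `"response"` for mg/kg, `"log10"` for the linear predictor.
#' @param ... Unused.
#' @return Numeric vector of predicted grain concentrations.
#' @export
predict.transfer_model <- function(object, newdata,
                                   type = c("response", "log10"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$terms$predictor, names(newdata))
  if (length(missing) > 0L) {
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "))
  }
  lp <- rep(object$intercept, nrow(newdata))
  for (i in seq_len(nrow(object$terms))) {
    x <- newdata[[object$terms$predictor[i]]]
    if (object$terms$transform[i] == "log10") {
      if (any(x <= 0)) stop("non-positive value for log10 predictor ",
                            object$terms$predictor[i])
      x <- log10(x)
    }
    lp <- lp + object$terms$coefficient[i] * x
  }
  if (type == "log10") lp else 10^lp
}

#' Relative importance of model predictors
#'
#' A surrogate importance measure: the absolute standardized coefficient of
#' each predictor (|beta_j| * sd(t_j(x_j)) / sd(y)), rescaled so the
#' largest equals 100 percent. This is a transparent stand-in for
#' normalized-importance outputs of black-box statistical suites, whose
#' algorithm is not public; ranks are comparable, exact percentages are
#' not.
#'
#' @param model A `transfer_model`.
#' @param data The data used to standardize (modeling split if present).
#' @return Named numeric vector of percentages with maximum 100.
#' @export
relative_importance <- function(model, data) {
  if ("split" %in% names(data)) data <- data[data$split == "modeling", , drop = FALSE]
  X <- transformed_predictors(data, model$terms$predictor)
  y <- log10(data[[rice_column(model$element)]])
  std <- abs(model$terms$coefficient) *
    vapply(X, stats::sd, numeric(1L)) / stats::sd(y)
  100 * std / max(std)
}

#' Validate a transfer model on held-out sites
#'
#' Computes hold-out R^2 and RMSE on the log10 scale between predicted and
#' measured grain concentrations. R^2 is relative to the mean model
#' (1 - SS_res/SS_tot) and can be negative.
#'
#' @param model A `transfer_model`.
#' @param data A paired data.frame; if it has a `split` column only the
#'   `validation` rows are used.
#' @return A list with `n_validation`, `r2`, `rmse`, and a `pairs`
#'   data.frame of (predicted, measured) log10 values.
#' @export
validate_transfer_model <- function(model, data) {
  if ("split" %in% names(data)) data <- data[data$split == "validation", , drop = FALSE]
  if (nrow(data) == 0L) stop("validation split is empty")
  pred <- predict(model, data, type = "log10")
  meas <- log10(data[[rice_column(model$element)]])
  ss_res <- sum((meas - pred)^2)
  ss_tot <- sum((meas - mean(meas))^2)
  list(n_validation = nrow(data),
       r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((meas - pred)^2)),
       pairs = data.frame(predicted = pred, measured = meas))
}
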