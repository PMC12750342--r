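# Safety thresholds (ST): invert a fitted transfer model at the grain
# limit, with covariates fixed at regional means and pH at the bin's
# representative value.

#' Regional covariate means used when inverting a transfer model
#'
#' One study-wide set of means for SOM and the six Fe/Mn oxide fractions.
#' With `data` supplied, arithmetic means are computed from the table;
#' otherwise the published regional survey means are returned (SOM 34.55
#' g/kg; C-Fe 390, C-Mn 80, F-Fe 34450, F-Mn 1080, Am-Fe 4190, Am-Mn 970
#' mg/kg).
#'
#' @param data Optional paired soil-rice data.frame.
#' @return Named numeric vector of covariate means.
#' @export
covariate_means <- function(data = NULL) {
  if (is.null(data)) {
    return(c(SOM = 34.55, C_Fe = 390, F_Fe = 34450, Am_Fe = 4190,
             C_Mn = 80, F_Mn = 1080, Am_Mn = 970))
  }
  cols <- c("SOM", oxide_columns())
  vapply(cols, function(c) mean(data[[c]]), numeric(1L))
}

#' Linear relation tying an available fraction to the soil total
#'
#' Some transfer models use an available metal fraction as a predictor;
#' during inversion the available fraction must be expressed as a function
#' of the soil total being solved for. The relation is linear on the
#' concentration scale: `available = slope * total + intercept`. Defaults
#' are the regional regression of available As on total As
#' (y = 0.721 x - 0.263, R^2 = 0.55).
#'
#' @param slope,intercept Relation parameters (mg/kg scale).
#' @param r2 Fit diagnostic carried for reporting.
#' @param response,predictor Column names related.
#' @return A list of class `aux_relation`.
#' @export
aux_relation <- function(slope = 0.721, intercept = -0.263, r2 = 0.55,
                         response = "A_As", predictor = "S_T_As") {
  if (slope == 0) stop("slope must be nonzero")
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 response = response, predictor = predictor),
            class = "aux_relation")
}

#' Fit the available-vs-total auxiliary relation from data
#'
#' @param data A paired soil-rice data.frame.
#' @param response,predictor Columns to relate (default A_As on S_T_As).
#' @return An `aux_relation`.
#' @export
fit_aux_relation <- function(data, response = "A_As", predictor = "S_T_As") {
  fit <- stats::lm(data[[response]] ~ data[[predictor]])
  aux_relation(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r2 = summary(fit)$r.squared,
               response = response, predictor = predictor)
}

# Linear predictor at soil total x (mg/kg) with other covariates fixed.
# Returns the log10 grain prediction; aux substitutes the available
# fraction as a function of x on the linear scale before its log10.
lp_at_soil_total <- function(model, x, pH, means, aux = NULL) {
  covs <- as.list(means)
  covs$pH <- pH
  covs[[soil_total_column(model$element)]] <- x
  if (!is.null(aux) && aux$response %in% model$terms$predictor) {
    a <- aux$slope * x + aux$intercept
    if (any(a <= 0)) {
      stop("auxiliary relation yields non-positive ", aux$response,
           " at soil total ", paste(signif(x[a <= 0], 4), collapse = ", "))
    }
    covs[[aux$response]] <- a
  }
  predict(model, as.data.frame(covs), type = "log10")
}

#' Invert a transfer model at the grain limit to derive a safety threshold
#'
#' Solves for the soil total concentration x* at which the model predicts
#' the grain concentration equal to `mac`, holding pH at the bin's
#' representative value and all other covariates at regional means. When
#' the soil total enters exactly one model term the solution is the exact
#' algebraic rearrangement `lg(x*) = (lg(mac) - other terms) / beta`;
#' otherwise (e.g. an auxiliary relation ties a second predictor to the
#' soil total) a bracketed root search on lg(x) is used.
#'
#' @param model A `transfer_model` whose soil-total coefficient is
#'   positive over the bracket.
#' @param mac Grain limit, mg/kg.
#' @param pH Representative pH of the bin.
#' @param means Covariate means ([covariate_means()]).
#' @param aux Optional [aux_relation()] substituting an available-fraction
#'   predictor; required if the model uses one.
#' @param bracket Search interval for lg(x) (default [-2, 4], i.e.
#'   0.01-10000 mg/kg).
#' @param method `"auto"` picks closed form when available;
#'   `"closed_form"` or `"root"` force one path.
#' @return Soil threshold in mg/kg.
#' @export
invert_for_st <- function(model, mac, pH, means = covariate_means(),
                          aux = NULL, bracket = c(-2, 4),
                          method = c("auto", "closed_form", "root")) {
  method <- match.arg(method)
  stc <- soil_total_column(model$element)
  if (!stc %in% model$terms$predictor) {
    stop("model has no soil-total term ", stc)
  }
  uses_aux <- !is.null(aux) && aux$response %in% model$terms$predictor
  if (is.null(aux) && any(startsWith(model$terms$predictor, "A_"))) {
    stop("model uses an available-fraction predictor; supply aux")
  }
  if (method == "auto") {
    method <- if (uses_aux) "root" else "closed_form"
  }
  if (method == "closed_form") {
    if (uses_aux) stop("closed form unavailable when aux ties a second term")
    beta <- model$terms$coefficient[model$terms$predictor == stc]
    other <- lp_at_soil_total(model, 1, pH, means, aux = NULL)  # lg(1) term = 0
    lgx <- (log10(mac) - other) / beta
    return(10^lgx)
  }
  f <- function(lgx) lp_at_soil_total(model, 10^lgx, pH, means, aux) - log10(mac)
  lo <- bracket[1L]; hi <- bracket[2L]
  if (uses_aux) {
    # keep the bracket where the aux relation stays positive
    min_x <- (1e-9 - aux$intercept) / aux$slope
    if (aux$slope > 0 && min_x > 10^lo) lo <- log10(min_x)
  }
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    grid <- seq(lo, hi, length.out = 25L)
    stop("no sign change in bracket [", lo, ", ", hi, "]; f at grid: ",
         paste(signif(vapply(grid, f, numeric(1L)), 3), collapse = ", "))
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  10^root
}

#' Derive the safety-threshold table
#'
#' One safety threshold per element and pH bin, obtained by inverting each
#' element's transfer model at its MAC with covariates at regional means.
#'
#' @param models Named list of `transfer_model` objects per element.
#' @param limits Regulatory limits table ([regulatory_limits()]).
#' @param means Covariate means.
#' @param aux Optional `aux_relation` (applied to the model that names its
#'   response as a predictor).
#' @param bins pH bin table (default [ph_bins()]).
#' @return Data.frame with `element`, `ph_bin`, `representative_pH`, `st`,
#'   `rsv`, `mac`.
#' @export
safety_thresholds <- function(models, limits = regulatory_limits(),
                              means = covariate_means(), aux = NULL,
                              bins = ph_bins()) {
  rows <- list()
  for (el in names(models)) {
    for (i in seq_len(nrow(bins))) {
      lim <- limits_row(limits, el, bins$label[i])
      st <- invert_for_st(models[[el]], mac = lim$mac,
                          pH = bins$representative_pH[i],
                          means = means, aux = aux)
      rows[[length(rows) + 1L]] <- data.frame(
        element = el, ph_bin = bins$label[i],
        representative_pH = bins$representative_pH[i],
        st = st, rsv = lim$rsv, mac = lim$mac, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$ph_bin <- factor(out$ph_bin, levels = c("neutral", "alkaline"))
  out
}
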