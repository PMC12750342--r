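# Logistic species-sensitivity distribution over reciprocal
# bioconcentration factors, its exact inverse, and hazard thresholds.

#' Bioconcentration factors of a paired dataset
#'
#' BCF is the dimensionless ratio of grain to soil total concentration;
#' its reciprocal (soil/grain) is the working variable of the sensitivity
#' distribution. (Reporting conventions sometimes express BCF as a
#' percentage; all computations here use the plain ratio.)
#'
#' @param data A paired soil-rice data.frame.
#' @param element `"Cd"` or `"As"`.
#' @return Data.frame with `site_id`, `element`, `bcf`, `inv_bcf`.
#' @export
compute_bcf <- function(data, element = c("Cd", "As")) {
  element <- match.arg(element)
  soil <- data[[soil_total_column(element)]]
  rice <- data[[rice_column(element)]]
  if (any(soil <= 0)) {
    stop("non-positive soil total for site(s): ",
         paste(data$site_id[soil <= 0], collapse = ", "))
  }
  if (any(rice <= 0)) {
    stop("non-positive grain concentration for site(s): ",
         paste(data$site_id[rice <= 0], collapse = ", "))
  }
  data.frame(site_id = data$site_id, element = element,
             bcf = rice / soil, inv_bcf = soil / rice,
             stringsAsFactors = FALSE)
}

#' Empirical cumulative probabilities by plotting position
#'
#' Ranks the values ascending (average ranks on ties) and assigns
#' cumulative percentages by the Hazen rule `100 (r - 0.5) / n` (default)
#' or the Weibull rule `100 r / (n + 1)`. Both keep every probability
#' strictly inside (0, 100).
#'
#' @param x Numeric vector (at least 3 values).
#' @param plotting_position `"hazen"` or `"weibull"`.
#' @return Data.frame with ascending `x` and `y` (percent).
#' @export
empirical_cumulative <- function(x, plotting_position = c("hazen", "weibull")) {
  plotting_position <- match.arg(plotting_position)
  if (length(x) < 3L) stop("need at least 3 values")
  ord <- order(x)
  r <- rank(x, ties.method = "average")[ord]
  n <- length(x)
  y <- switch(plotting_position,
              hazen = 100 * (r - 0.5) / n,
              weibull = 100 * r / (n + 1))
  data.frame(x = x[ord], y = y)
}

ssd_forward <- function(x, a, b, x0) a / (1 + (x / x0)^b)

#' Fit a logistic sensitivity distribution to cumulative 1/BCF data
#'
#' Nonlinear least squares of the three-parameter logistic curve
#' `y = a / (1 + (x/x0)^b)` to cumulative-probability points over positive
#' x (here 1/BCF). Because y rises with x, the fitted shape `b` is
#' negative. Initialization: a = 100, b = -2, x0 = median(x). The
#' asymptote can be fixed at 100 (`fix_a = TRUE`), appropriate when the
#' points are an empirical CDF whose population limit is 100 percent.
#'
#' @param x Positive values of 1/BCF, or a 2-column data.frame/list with
#'   `x` and `y` as produced by [empirical_cumulative()].
#' @param y Cumulative percentages; if missing, computed from `x` with
#'   `plotting_position`.
#' @param plotting_position Passed to [empirical_cumulative()].
#' @param fix_a Fix the asymptote at 100 percent.
#' @param start Optional named start values overriding the defaults.
#' @return An object of class `ssd_logistic` with elements `a`, `b`, `x0`,
#'   `residual_sse`, `n_points`, `converged`, and the fitted point table.
#' @export
ssd_logistic <- function(x, y = NULL,
                         plotting_position = c("hazen", "weibull"),
                         fix_a = FALSE, start = NULL) {
  if (is.data.frame(x) || (is.list(x) && all(c("x", "y") %in% names(x)))) {
    y <- x$y; x <- x$x
  } else if (is.null(y)) {
    pts <- empirical_cumulative(x, match.arg(plotting_position))
    x <- pts$x; y <- pts$y
  }
  if (length(x) < 4L) stop("need at least 4 points to fit the logistic SSD")
  if (any(x <= 0)) stop("x (1/BCF) values must be positive")
  s <- list(a = 100, b = -2, x0 = stats::median(x))
  if (!is.null(start)) s[names(start)] <- start
  dat <- data.frame(x = x, y = y)
  fit <- if (fix_a) {
    minpack.lm::nlsLM(y ~ 100 / (1 + (x / x0)^b), data = dat,
                      start = s[c("b", "x0")],
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(y ~ a / (1 + (x / x0)^b), data = dat,
                      start = s,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- as.list(stats::coef(fit))
  if (fix_a) cf$a <- 100
  conv <- fit$convInfo$isConv
  if (!isTRUE(conv)) {
    stop("logistic SSD fit did not converge; last iterate a=", cf$a,
         " b=", cf$b, " x0=", cf$x0,
         ", SSE=", sum(stats::residuals(fit)^2))
  }
  structure(list(a = cf$a, b = cf$b, x0 = cf$x0,
                 residual_sse = sum(stats::residuals(fit)^2),
                 n_points = length(x), converged = conv,
                 points = dat, fix_a = fix_a),
            class = "ssd_logistic")
}

#' @export
coef.ssd_logistic <- function(object, ...) {
  c(a = object$a, b = object$b, x0 = object$x0)
}

#' @export
print.ssd_logistic <- function(x, ...) {
  cat("Logistic sensitivity distribution over 1/BCF\n")
  cat(sprintf("  y = %.4g / (1 + (x/%.6g)^%.6g)%s\n", x$a, x$x0, x$b,
              if (x$fix_a) "   [asymptote fixed]" else ""))
  cat(sprintf("  n = %d points, residual SSE = %.4g\n",
              x$n_points, x$residual_sse))
  invisible(x)
}

#' Evaluate the fitted logistic curve
#'
#' @param object An `ssd_logistic`.
#' @param newdata Positive 1/BCF values (numeric vector or data.frame with
#'   column `x`); defaults to the fitted points.
#' @param ... Unused.
#' @return Cumulative percentages.
#' @export
predict.ssd_logistic <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  ssd_forward(x, object$a, object$b, object$x0)
}

#' Invert the logistic sensitivity distribution at a cumulative percentage
#'
#' The exact algebraic inverse of the fitted curve:
#' `x = 10^(lg(a/y - 1)/b + lg(x0))`. Forward-evaluating the result
#' returns `y` to numerical precision.
#'
#' @param fit An `ssd_logistic` (or list with `a`, `b`, `x0`).
#' @param y Cumulative percentage, 0 < y < a.
#' @return The 1/BCF value at which the curve reaches `y`.
#' @export
inverse_ssd <- function(fit, y) {
  if (any(y <= 0) || any(y >= fit$a)) {
    stop("y must lie strictly between 0 and the asymptote a = ", fit$a)
  }
  10^(log10(fit$a / y - 1) / fit$b + log10(fit$x0))
}

#' Hazard threshold from a protection percentile of 1/BCF
#'
#' The hazard threshold is the grain limit multiplied by the reciprocal
#' bioconcentration factor at the protection percentile of the fitted
#' cumulative distribution: `HT = MAC * HC_p` with `HC_p =
#' inverse_ssd(fit, p)`. At the default 95 percent level, HT is the soil
#' concentration above which 95 percent of rice is predicted to exceed
#' the grain limit.
#'
#' @param fit An `ssd_logistic`, or `NULL` when `hc` is supplied directly.
#' @param mac Grain limit, mg/kg.
#' @param protection Protection percentile (default 95).
#' @param hc Optional known reciprocal-BCF percentile value, bypassing the
#'   curve inversion.
#' @return List with `hc` (the 1/BCF percentile) and `ht` (mg/kg).
#' @export
derive_ht <- function(fit = NULL, mac, protection = 95, hc = NULL) {
  if (is.null(hc)) {
    if (is.null(fit)) stop("supply a fitted curve or an hc value")
    if (protection >= fit$a) {
      stop("protection percentile ", protection, " exceeds the fitted ",
           "asymptote a = ", signif(fit$a, 5),
           "; widen the data or refit with fix_a = TRUE")
    }
    hc <- inverse_ssd(fit, protection)
  }
  list(hc = hc, ht = mac * hc)
}

#' Derive the hazard-threshold table from survey data
#'
#' Per element and pH bin: compute 1/BCF, rank into an empirical CDF, fit
#' the logistic sensitivity distribution, invert at the protection level
#' and multiply by the element's MAC (four fits in total).
#'
#' @param data A paired soil-rice data.frame.
#' @param limits Regulatory limits table.
#' @param protection Protection percentile (default 95).
#' @param plotting_position Passed to [empirical_cumulative()].
#' @param fix_a Fix the logistic asymptote at 100 percent (default `TRUE`,
#'   the empirical-CDF reading of the curve).
#' @param bins pH bin table.
#' @return Data.frame with `element`, `ph_bin`, `n`, `hc95`, `ht`, `riv`,
#'   `mac`, plus the fitted curves as an attribute `fits`.
#' @export
hazard_thresholds <- function(data, limits = regulatory_limits(),
                              protection = 95,
                              plotting_position = "hazen", fix_a = TRUE,
                              bins = ph_bins()) {
  bin_of <- ph_bin(data$pH)
  rows <- list(); fits <- list()
  for (el in c("Cd", "As")) {
    bcf <- compute_bcf(data, el)
    for (lab in bins$label) {
      sel <- !is.na(bin_of) & bin_of == lab
      lim <- limits_row(limits, el, lab)
      fit <- ssd_logistic(bcf$inv_bcf[sel],
                          plotting_position = plotting_position,
                          fix_a = fix_a)
      ht <- derive_ht(fit, mac = lim$mac, protection = protection)
      fits[[paste(el, lab, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        element = el, ph_bin = lab, n = sum(sel),
        hc95 = ht$hc, ht = ht$ht, riv = lim$riv, mac = lim$mac,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$ph_bin <- factor(out$ph_bin, levels = c("neutral", "alkaline"))
  attr(out, "fits") <- fits
  out
}

#' Plot a fitted sensitivity distribution
#'
#' Points and fitted curve with 1/BCF on a log-scaled x axis.
#'
#' @param x An `ssd_logistic`.
#' @param ... Passed to [plot()].
#' @export
plot.ssd_logistic <- function(x, ...) {
  pts <- x$points
  xs <- 10^seq(log10(min(pts$x)), log10(max(pts$x)), length.out = 200L)
  graphics::plot(pts$x, pts$y, log = "x", xlab = "1/BCF",
                 ylab = "cumulative probability (%)", ...)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}
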