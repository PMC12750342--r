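# Four-quadrant applicability analysis, misclassification rates, and
# three-class soil-quality assignment for any threshold system.

# Round half away from zero, matching conventional reporting of rates.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Resolve a per-bin threshold specification to one value per sample.
# `threshold` may be a scalar or a named vector c(neutral=, alkaline=).
resolve_threshold <- function(threshold, bin_of) {
  if (length(threshold) == 1L && is.null(names(threshold))) {
    return(rep(unname(threshold), length(bin_of)))
  }
  unname(threshold[as.character(bin_of)])
}

#' Classify samples into the four soil-vs-grain quadrants
#'
#' Each sample is cross-classified by the signs of `ln(soil/threshold)`
#' and `ln(rice/limit)`: quadrant I (both exceed; true positive), II (soil
#' compliant, rice exceeds; false negative), III (both compliant; true
#' negative), IV (soil exceeds, rice compliant; false positive). Values
#' exactly on a boundary count as compliant. Samples whose pH falls
#' outside the supported bins are skipped with a warning.
#'
#' @param data A paired soil-rice data.frame.
#' @param element `"Cd"` or `"As"`.
#' @param soil_threshold Soil criterion in mg/kg: a scalar, a named
#'   per-bin vector `c(neutral=, alkaline=)`, or a per-sample vector.
#' @param grain_limit Grain limit (MAC) in mg/kg.
#' @return Object of class `quadrant_result`: quadrant `counts`, per-site
#'   `labels`, number skipped, and the criteria used.
#' @export
quadrant_classify <- function(data, element = c("Cd", "As"),
                              soil_threshold, grain_limit) {
  element <- match.arg(element)
  soil <- data[[soil_total_column(element)]]
  rice <- data[[rice_column(element)]]
  thr <- if (length(soil_threshold) == nrow(data) &&
             is.null(names(soil_threshold))) {
    soil_threshold
  } else {
    resolve_threshold(soil_threshold, ph_bin(data$pH))
  }
  ok <- !is.na(thr)
  soil_exceeds <- log(soil / thr) > 0
  rice_exceeds <- log(rice / grain_limit) > 0
  quadrant <- ifelse(soil_exceeds & rice_exceeds, "I",
              ifelse(!soil_exceeds & rice_exceeds, "II",
              ifelse(!soil_exceeds & !rice_exceeds, "III", "IV")))
  quadrant[!ok] <- NA
  counts <- table(factor(quadrant[ok], levels = c("I", "II", "III", "IV")))
  structure(list(element = element,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 labels = stats::setNames(quadrant, data$site_id),
                 n_skipped = sum(!ok),
                 soil_threshold_used = soil_threshold,
                 grain_limit_used = grain_limit),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat("Quadrant classification (", x$element, "), n = ",
      sum(x$counts), "\n", sep = "")
  print(x$counts)
  r <- misclassification_rates(x)
  cat(sprintf("  accuracy %.1f%%, false positives %.1f%%, false negatives %.1f%%\n",
              r["accuracy"], r["false_positive_rate"],
              r["false_negative_rate"]))
  invisible(x)
}

#' Misclassification rates of a quadrant classification
#'
#' Rates over all classified samples: accuracy = (I + III)/n, false
#' positive rate = IV/n, false negative rate = II/n, each times 100; the
#' three always sum to 100 percent before rounding.
#'
#' @param result A `quadrant_result` (or a named count vector I/II/III/IV).
#' @param digits Decimal places for reporting (round half up; default 1).
#' @return Named vector `accuracy`, `false_positive_rate`,
#'   `false_negative_rate` in percent.
#' @export
misclassification_rates <- function(result, digits = 1) {
  counts <- if (inherits(result, "quadrant_result")) result$counts else result
  n <- sum(counts)
  if (n == 0L) stop("no classified samples")
  c(accuracy = round_half_up(100 * (counts[["I"]] + counts[["III"]]) / n, digits),
    false_positive_rate = round_half_up(100 * counts[["IV"]] / n, digits),
    false_negative_rate = round_half_up(100 * counts[["II"]] / n, digits))
}

#' Score soil criteria against observed grain exceedance, per pH bin
#'
#' For each pH bin and each criterion (RSV, ST, RIV, HT), classifies the
#' bin's samples into quadrants using that criterion's soil value and the
#' element's grain limit, and reports accuracy and false positive/negative
#' rates.
#'
#' @param data A paired soil-rice data.frame.
#' @param element `"Cd"` or `"As"`.
#' @param limits Regulatory limits table (provides RSV, RIV, MAC).
#' @param st Per-bin safety thresholds `c(neutral=, alkaline=)` (mg/kg).
#' @param ht Per-bin hazard thresholds `c(neutral=, alkaline=)` (mg/kg).
#' @return Data.frame with one row per bin x criterion: `element`,
#'   `ph_bin`, `criterion`, `value`, `n`, `accuracy`,
#'   `false_positive_rate`, `false_negative_rate`.
#' @export
score_criteria <- function(data, element = c("Cd", "As"),
                           limits = regulatory_limits(), st, ht) {
  element <- match.arg(element)
  bin_of <- ph_bin(data$pH)
  rows <- list()
  for (lab in c("neutral", "alkaline")) {
    sub <- data[!is.na(bin_of) & bin_of == lab, , drop = FALSE]
    lim <- limits_row(limits, element, lab)
    crit <- c(RSV = lim$rsv, ST = unname(st[[lab]]),
              RIV = lim$riv, HT = unname(ht[[lab]]))
    for (cn in names(crit)) {
      row <- data.frame(element = element, ph_bin = lab, criterion = cn,
                        value = crit[[cn]], n = nrow(sub),
                        accuracy = NA_real_, false_positive_rate = NA_real_,
                        false_negative_rate = NA_real_,
                        stringsAsFactors = FALSE)
      if (nrow(sub) > 0L) {
        q <- quadrant_classify(sub, element, soil_threshold = crit[[cn]],
                               grain_limit = lim$mac)
        r <- misclassification_rates(q)
        row$accuracy <- r[["accuracy"]]
        row$false_positive_rate <- r[["false_positive_rate"]]
        row$false_negative_rate <- r[["false_negative_rate"]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$ph_bin <- factor(out$ph_bin, levels = c("neutral", "alkaline"))
  out$criterion <- factor(out$criterion, levels = c("RSV", "ST", "RIV", "HT"))
  out
}

#' Three-class soil-quality assignment under a lower/upper threshold pair
#'
#' Per element: class I (priority protection) when the soil concentration
#' is strictly below the lower threshold, class II (controllable risk)
#' when between lower (exclusive) and upper (inclusive), class III
#' (strict control) above the upper threshold. The composite class is the
#' worst per-element class. The threshold pair is (RSV, RIV) for the
#' national system or (ST, HT) for the regional one, resolved per sample
#' pH bin. Optionally, class III sites whose measured grain concentration
#' is below the grain limit are demoted to class II
#' (`demote_by_grain = TRUE`), reflecting co-monitoring of the crop.
#'
#' @param data A paired soil-rice data.frame.
#' @param thresholds Named list per element, each a list with per-bin
#'   vectors `lower` and `upper`, e.g.
#'   `list(Cd = list(lower = c(neutral = 0.6, alkaline = 0.8), upper = ...))`.
#' @param limits Regulatory limits (used only with `demote_by_grain`).
#' @param demote_by_grain Demote class III to II when grain is compliant.
#' @return Data.frame with `site_id`, one class column per element, and
#'   `composite` (factor I < II < III).
#' @export
classify_quality <- function(data, thresholds, limits = regulatory_limits(),
                             demote_by_grain = FALSE) {
  bin_of <- ph_bin(data$pH)
  lv <- c("I", "II", "III")
  out <- data.frame(site_id = data$site_id, stringsAsFactors = FALSE)
  worst <- rep(1L, nrow(data))
  for (el in names(thresholds)) {
    lower <- resolve_threshold(thresholds[[el]]$lower, bin_of)
    upper <- resolve_threshold(thresholds[[el]]$upper, bin_of)
    x <- data[[soil_total_column(el)]]
    cl <- ifelse(x < lower, 1L, ifelse(x <= upper, 2L, 3L))
    if (demote_by_grain) {
      mac <- resolve_threshold(
        stats::setNames(limits$mac[limits$element == el],
                        as.character(limits$ph_bin[limits$element == el])),
        bin_of)
      demote <- cl == 3L & data[[rice_column(el)]] < mac
      cl[demote] <- 2L
    }
    out[[paste0("class_", el)]] <- factor(lv[cl], levels = lv)
    worst <- pmax(worst, cl)
  }
  out$composite <- factor(lv[worst], levels = lv)
  out
}
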