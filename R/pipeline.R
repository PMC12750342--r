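# End-to-end orchestration: simulate (or load) -> split -> fit -> derive
# ST -> derive HT -> evaluate, reproducible from one root seed.

#' Run the full threshold-derivation pipeline
#'
#' Sequences every stage on one dataset: generate (or accept) paired
#' soil-rice samples, split into modeling/validation sets, fit per-element
#' transfer models, validate them on the hold-out, derive safety
#' thresholds by model inversion at the MAC, derive hazard thresholds by
#' logistic SSD fitting per pH bin, and score RSV/ST/RIV/HT criteria by
#' quadrant analysis. All randomness descends from `seed` through named
#' per-stage substreams, so a rerun with the same arguments is identical.
#'
#' @param data Optional paired data.frame; by default a synthetic dataset
#'   is generated from `config`.
#' @param config A [generator_config()] (used when `data` is `NULL`).
#' @param seed Integer root seed.
#' @param n_validation Hold-out size for model validation (default 9).
#' @param limits Regulatory limits table.
#' @param means `"from_data"` (covariate means computed from the dataset)
#'   or `"fixed"` (published regional means).
#' @param plotting_position,fix_a SSD options, see [hazard_thresholds()].
#' @param output_dir Optional directory; when given, the dataset (CSV),
#'   models, thresholds and evaluation report (JSON) are written there.
#' @return A list of class `paddythresh_run` with elements `data`,
#'   `models`, `validation`, `st_table`, `ht_table`, `scores`, `quality`,
#'   and `params`.
#' @export
run_pipeline <- function(data = NULL, config = generator_config(), seed = 1,
                         n_validation = 9, limits = regulatory_limits(),
                         means = c("from_data", "fixed"),
                         plotting_position = "hazen", fix_a = TRUE,
                         output_dir = NULL) {
  means <- match.arg(means)
  if (is.null(data)) data <- simulate_paired(config, seed = seed)
  validate_paired_data(data)
  data <- split_dataset(data, n_validation = n_validation,
                        seed = stage_seed(seed, "split"))

  models <- list(Cd = transfer_model(data, "Cd"),
                 As = transfer_model(data, "As"))
  validation <- lapply(models, validate_transfer_model, data = data)

  mns <- if (means == "from_data") covariate_means(data) else covariate_means()
  aux <- if (available_column("As") %in% names(data)) {
    fit_aux_relation(data)
  } else {
    aux_relation()
  }
  st_table <- safety_thresholds(models, limits = limits, means = mns, aux = aux)
  ht_table <- hazard_thresholds(data, limits = limits,
                                plotting_position = plotting_position,
                                fix_a = fix_a)

  st_of <- function(el) stats::setNames(
    st_table$st[st_table$element == el],
    as.character(st_table$ph_bin[st_table$element == el]))
  ht_of <- function(el) stats::setNames(
    ht_table$ht[ht_table$element == el],
    as.character(ht_table$ph_bin[ht_table$element == el]))
  scores <- rbind(
    score_criteria(data, "Cd", limits, st = st_of("Cd"), ht = ht_of("Cd")),
    score_criteria(data, "As", limits, st = st_of("As"), ht = ht_of("As")))

  rsv_riv <- lapply(stats::setNames(c("Cd", "As"), c("Cd", "As")), function(el) {
    sub <- limits[limits$element == el, ]
    list(lower = stats::setNames(sub$rsv, as.character(sub$ph_bin)),
         upper = stats::setNames(sub$riv, as.character(sub$ph_bin)))
  })
  st_ht <- lapply(stats::setNames(c("Cd", "As"), c("Cd", "As")), function(el) {
    list(lower = st_of(el), upper = ht_of(el))
  })
  quality <- list(national = classify_quality(data, rsv_riv, limits),
                  regional = classify_quality(data, st_ht, limits))

  out <- structure(list(
    data = data, models = models, validation = validation,
    st_table = st_table, ht_table = ht_table, scores = scores,
    quality = quality,
    params = list(seed = seed, n = nrow(data), n_validation = n_validation,
                  means = means, plotting_position = plotting_position,
                  fix_a = fix_a, schema_version = "1.0",
                  package_version = as.character(utils::packageVersion("paddythresh")))
  ), class = "paddythresh_run")
  if (!is.null(output_dir)) write_run(out, output_dir)
  out
}

# Persist run artifacts as CSV/JSON under output_dir.
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_paired_table(run$data[setdiff(names(run$data), "split")],
                     file.path(output_dir, "dataset.csv"))
  model_json <- lapply(run$models, function(m) {
    list(element = m$element, intercept = m$intercept,
         terms = m$terms, n_fit = m$n_fit, r = m$r, r2 = m$r2,
         adj_r2 = m$adj_r2, p_value = m$p_value)
  })
  jsonlite::write_json(
    list(schema_version = run$params$schema_version, models = model_json),
    file.path(output_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(schema_version = run$params$schema_version,
         safety_thresholds = run$st_table,
         hazard_thresholds = as.data.frame(run$ht_table)),
    file.path(output_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(schema_version = run$params$schema_version,
         params = run$params, scores = run$scores,
         quality_national = as.list(table(run$quality$national$composite)),
         quality_regional = as.list(table(run$quality$regional$composite))),
    file.path(output_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.paddythresh_run <- function(x, ...) {
  cat("paddythresh pipeline run (seed ", x$params$seed, ", n = ",
      x$params$n, ")\n\n", sep = "")
  cat("Safety thresholds (model inversion at MAC):\n")
  print(x$st_table, row.names = FALSE)
  cat("\nHazard thresholds (logistic SSD at 95% of 1/BCF):\n")
  print(as.data.frame(x$ht_table), row.names = FALSE)
  cat("\nCriterion scores (per pH bin, % of bin samples):\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Recompute the benchmark arithmetic identities of the threshold system
#'
#' Re-derives, from the package's own functions and the regional
#' benchmark constants, the arithmetic that links the published hazard
#' thresholds, their ratios to the national intervention values, and the
#' national-standard misclassification rates: HT = MAC x HC95 for all
#' four element/bin combinations, HT/RIV ratios for Cd, and the
#' false-positive and quadrant-I rates implied by the regional
#' four-quadrant counts.
#'
#' @return Data.frame with columns `quantity`, `computed`, `expected`,
#'   `pass`, printed with a pass/fail mark per row.
#' @export
worked_examples <- function() {
  hc <- c(Cd.neutral = 48.29, Cd.alkaline = 50.6,
          As.neutral = 194.3, As.alkaline = 193.8)
  mac <- c(Cd = 0.2, As = 0.5)
  ht <- vapply(names(hc), function(k) {
    el <- sub("\\..*", "", k)
    derive_ht(mac = mac[[el]], hc = hc[[k]])$ht
  }, numeric(1L))
  cd_counts <- c(I = 18L, II = 0L, III = 24L, IV = 83L)
  as_counts <- c(I = 22L, II = 0L, III = 38L, IV = 65L)
  rows <- data.frame(
    quantity = c("HT-Cd neutral", "HT-Cd alkaline", "HT-As neutral",
                 "HT-As alkaline", "HT/RIV Cd neutral", "HT/RIV Cd alkaline",
                 "RSV false-positive rate Cd", "RSV false-positive rate As",
                 "quadrant-I share Cd", "quadrant-I share As"),
    computed = c(round_half_up(ht[["Cd.neutral"]], 2),
                 round_half_up(ht[["Cd.alkaline"]], 2),
                 round_half_up(ht[["As.neutral"]], 2),
                 round_half_up(ht[["As.alkaline"]], 2),
                 round_half_up(ht[["Cd.neutral"]] / 3.0, 1),
                 round_half_up(ht[["Cd.alkaline"]] / 4.0, 1),
                 misclassification_rates(cd_counts)[["false_positive_rate"]],
                 misclassification_rates(as_counts)[["false_positive_rate"]],
                 round_half_up(100 * cd_counts[["I"]] / sum(cd_counts), 1),
                 round_half_up(100 * as_counts[["I"]] / sum(as_counts), 1)),
    expected = c(9.66, 10.12, 97.15, 96.9, 3.2, 2.5,
                 66.4, 52.0, 14.4, 17.6),
    stringsAsFactors = FALSE)
  rows$pass <- abs(rows$computed - rows$expected) < 0.005 +
    1e-9  # printed precision
  class(rows) <- c("worked_examples", "data.frame")
  rows
}

#' @export
print.worked_examples <- function(x, ...) {
  df <- as.data.frame(x)
  df$mark <- ifelse(df$pass, "PASS", "FAIL")
  print(df[c("quantity", "computed", "expected", "mark")], row.names = FALSE)
  invisible(x)
}
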