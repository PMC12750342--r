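# Paired soil-rice observations: column schema, validation, I/O, transforms.

#' Canonical column names for paired soil-rice tables
#'
#' One row per sampling site. `pH` is dimensionless, `SOM` is soil organic
#' matter in g/kg, and every other column is a concentration in mg/kg:
#' soil totals (`S_T_Cd`, `S_T_As`), available fractions (`A_Cd`, `A_As`),
#' six Fe/Mn oxide fractions (complex `C_`, free `F_`, amorphous `Am_`),
#' and milled-rice grain concentrations (`Rice_Cd`, `Rice_As`).
#'
#' @return Character vector of canonical column names.
#' @export
paired_columns <- function() {
  c("site_id", "pH", "SOM",
    "S_T_Cd", "A_Cd", "S_T_As", "A_As",
    "C_Fe", "F_Fe", "Am_Fe", "C_Mn", "F_Mn", "Am_Mn",
    "Rice_Cd", "Rice_As")
}

# concentration columns: strictly positive, log10-transformable
conc_columns <- function() {
  setdiff(paired_columns(), c("site_id", "pH", "SOM"))
}

oxide_columns <- function() c("C_Fe", "F_Fe", "Am_Fe", "C_Mn", "F_Mn", "Am_Mn")

soil_total_column <- function(element) paste0("S_T_", element)
available_column <- function(element) paste0("A_", element)
rice_column <- function(element) paste0("Rice_", element)

#' Validate a paired soil-rice table
#'
#' Checks the invariants every downstream stage relies on: unique site
#' identifiers, pH strictly inside (0, 14), positive SOM, and strictly
#' positive concentrations in every concentration column that is present.
#' Columns `A_Cd` and `A_As` may be absent; all other canonical columns are
#' required.
#'
#' @param data A data.frame with the columns of [paired_columns()]
#'   (available fractions optional).
#' @return The validated data.frame, invisibly classed as before.
#' @export
validate_paired_data <- function(data) {
  stopifnot(is.data.frame(data))
  required <- setdiff(paired_columns(), c("A_Cd", "A_As"))
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(data$site_id)) {
    stop("duplicate site_id values: ",
         paste(unique(data$site_id[duplicated(data$site_id)]), collapse = ", "))
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop("invalid ", what, " for site(s): ",
           paste(data$site_id[!ok], collapse = ", "))
    }
  }
  bad_row(is.finite(data$pH) & data$pH > 0 & data$pH < 14, "pH (must be in (0, 14))")
  bad_row(is.finite(data$SOM) & data$SOM > 0, "SOM (must be > 0)")
  for (col in intersect(conc_columns(), names(data))) {
    bad_row(is.finite(data[[col]]) & data[[col]] > 0,
            paste0(col, " (concentration must be > 0)"))
  }
  invisible(data)
}

#' Read a paired soil-rice table from a delimited file
#'
#' Reads a comma-separated file with a header row, optionally renames
#' columns to the canonical schema, and validates every row.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping canonical
#'   column names (names) to the column names used in the file (values),
#'   e.g. `c(S_T_Cd = "soil_total_cd")`.
#' @return A validated data.frame with canonical column names.
#' @export
read_paired_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(df))
    if (length(missing) > 0L) {
      stop("column_map refers to absent column(s): ",
           paste(missing, collapse = ", "))
    }
    idx <- match(unname(column_map), names(df))
    names(df)[idx] <- names(column_map)
  }
  validate_paired_data(df)
  df
}

#' Write a paired soil-rice table to CSV
#'
#' @param data A validated paired soil-rice data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_table <- function(data, path) {
  validate_paired_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log10-transform the concentration columns of a paired table
#'
#' Concentrations and oxide fractions are replaced by their base-10
#' logarithms; pH and SOM are left on their original scale unless
#' explicitly requested. Values are stored linear-scale throughout the
#' package and transformed on demand, never persisted transformed.
#'
#' @param data A paired soil-rice data.frame.
#' @param include_pH,include_som Also transform pH / SOM (default `FALSE`).
#' @return The data.frame with transformed columns.
#' @export
log10_columns <- function(data, include_pH = FALSE, include_som = FALSE) {
  cols <- intersect(conc_columns(), names(data))
  if (include_pH) cols <- c(cols, "pH")
  if (include_som) cols <- c(cols, "SOM")
  for (col in cols) {
    if (any(data[[col]] <= 0)) {
      stop("non-positive value in column ", col, "; log10 undefined")
    }
    data[[col]] <- log10(data[[col]])
  }
  data
}

#' Split a dataset into modeling and validation subsets
#'
#' Draws a seeded random hold-out of `n_validation` sites and records the
#' assignment in a `split` column with levels `modeling` and `validation`.
#'
#' @param data A paired soil-rice data.frame.
#' @param n_validation Number of validation sites (default 9 of 125).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return The data.frame with a `split` factor column.
#' @export
split_dataset <- function(data, n_validation = 9, seed = 1) {
  n <- nrow(data)
  if (n_validation <= 0 || n_validation >= n) {
    stop("n_validation must be strictly between 0 and nrow(data)")
  }
  idx <- local_seed(seed, sample.int(n, n_validation))
  data$split <- factor(ifelse(seq_len(n) %in% idx, "validation", "modeling"),
                       levels = c("modeling", "validation"))
  data
}

# Run expr under a temporary RNG state so package functions never disturb
# the caller's random stream.
local_seed <- function(seed, expr) {
  force(seed)  # the seed may be drawn from the caller's stream
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Named per-stage seeds derived from one root seed, so each pipeline stage
# is independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(soils = 11L, rice = 23L, split = 37L, aux = 41L, noise = 53L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2011L + stages[[stage]]
}

#' pH bin definitions for threshold derivation
#'
#' Two bins follow the national soil environmental quality standard for
#' paddy fields: neutral (6.5 < pH <= 7.5, evaluated at a representative
#' pH of 7) and alkaline (pH > 7.5, evaluated at pH 8). The neutral bin is
#' closed on the right.
#'
#' @return A data.frame with columns `label`, `lower`, `upper`,
#'   `representative_pH`.
#' @export
ph_bins <- function() {
  data.frame(label = c("neutral", "alkaline"),
             lower = c(6.5, 7.5),
             upper = c(7.5, Inf),
             representative_pH = c(7, 8),
             stringsAsFactors = FALSE)
}

#' Assign samples to pH bins
#'
#' Samples with pH <= 6.5 fall outside both bins (the survey range is
#' 6.56-8.25) and are returned as `NA` with a warning; threshold
#' workflows skip them.
#'
#' @param pH Numeric vector of soil pH values.
#' @return Factor with levels `neutral`, `alkaline` (`NA` outside bins).
#' @export
ph_bin <- function(pH) {
  out <- ifelse(pH > 7.5, "alkaline", ifelse(pH > 6.5, "neutral", NA))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " sample(s) with pH <= 6.5 fall outside the ",
            "supported bins and are excluded from threshold workflows")
  }
  factor(out, levels = c("neutral", "alkaline"))
}

#' Regulatory limits for Cd and As in paddy systems
#'
#' National limits per element and pH bin: the maximum allowable
#' concentration in milled rice (MAC, GB 2762), the soil risk screening
#' value (RSV, GB 15618) and the soil risk intervention value (RIV,
#' GB 15618), all in mg/kg. Read from the constants file bundled with the
#' package unless another YAML file is supplied.
#'
#' @param path Path to a YAML constants file; defaults to the bundled one.
#' @return A data.frame with columns `element`, `ph_bin`, `mac`, `rsv`,
#'   `riv`.
#' @export
regulatory_limits <- function(path = system.file("extdata", "regulatory_limits.yaml",
                                                 package = "paddythresh")) {
  raw <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(raw, function(r) {
    data.frame(element = r$element, ph_bin = r$ph_bin,
               mac = r$mac, rsv = r$rsv, riv = r$riv,
               stringsAsFactors = FALSE)
  }))
  bad <- with(rows, !(mac > 0 & mac < rsv & rsv < riv))
  if (any(bad)) stop("limits must satisfy 0 < MAC < RSV < RIV")
  rows$ph_bin <- factor(rows$ph_bin, levels = c("neutral", "alkaline"))
  rows
}

# Look up one limits row.
limits_row <- function(limits, element, bin) {
  row <- limits[limits$element == element & limits$ph_bin == bin, , drop = FALSE]
  if (nrow(row) != 1L) stop("no unique limits row for ", element, "/", bin)
  row
}
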