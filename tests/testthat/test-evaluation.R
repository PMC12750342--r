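test_that("quadrants follow the sign pair of the log ratios", {
  df <- hand_table(4)
  df$pH <- 7
  df$S_T_Cd <- c(2, 0.5, 0.5, 2)
  df$Rice_Cd <- c(2, 2, 0.5, 0.5)
  q <- quadrant_classify(df, "Cd", soil_threshold = 1, grain_limit = 1)
  expect_equal(unname(q$labels), c("I", "II", "III", "IV"))
  expect_equal(q$counts, c(I = 1L, II = 1L, III = 1L, IV = 1L))
  # exact boundary counts as compliant
  df$S_T_Cd <- c(1, 1, 1, 1); df$Rice_Cd <- c(1, 1, 1, 1)
  q <- quadrant_classify(df, "Cd", soil_threshold = 1, grain_limit = 1)
  expect_equal(unname(q$counts[["III"]]), 4L)
})

test_that("classification is invariant to joint rescaling", {
  df <- hand_table(10)
  df$pH <- 7
  set.seed(3)
  df$S_T_Cd <- 10^runif(10, -1, 1)
  df$Rice_Cd <- 10^runif(10, -1, 1)
  q1 <- quadrant_classify(df, "Cd", soil_threshold = 0.7, grain_limit = 0.2)
  df2 <- df; df2$S_T_Cd <- df$S_T_Cd * 37
  q2 <- quadrant_classify(df2, "Cd", soil_threshold = 0.7 * 37,
                          grain_limit = 0.2)
  expect_identical(q1$labels, q2$labels)
})

test_that("rates partition to 100 percent and match the definitions", {
  r <- misclassification_rates(c(I = 18L, II = 0L, III = 24L, IV = 83L))
  expect_equal(r[["false_positive_rate"]], 66.4)
  expect_equal(r[["accuracy"]], 33.6)
  r2 <- misclassification_rates(c(I = 22L, II = 0L, III = 38L, IV = 65L))
  expect_equal(r2[["false_positive_rate"]], 52.0)
  set.seed(8)
  for (i in 1:20) {
    cts <- setNames(as.integer(rmultinom(1, 125, runif(4))),
                    c("I", "II", "III", "IV"))
    raw <- misclassification_rates(cts, digits = 10)
    expect_equal(sum(raw), 100, tolerance = 1e-9)
  }
  expect_equal(misclassification_rates(
    c(I = 10L, II = 0L, III = 10L, IV = 0L))[["accuracy"]], 100)
  expect_error(misclassification_rates(c(I = 0L, II = 0L, III = 0L, IV = 0L)),
               "no classified")
})

test_that("criterion scoring sweeps bins and criteria consistently", {
  d <- make_fixture("study_like", seed = 14)
  lim <- regulatory_limits()
  st <- c(neutral = 5, alkaline = 6.5)
  ht <- c(neutral = 9.7, alkaline = 10.1)
  sc <- score_criteria(d, "Cd", lim, st = st, ht = ht)
  expect_equal(nrow(sc), 8)
  expect_equal(sum(sc$n[sc$criterion == "RSV"]), 125)
  ok <- !is.na(sc$accuracy)
  expect_true(all(abs(sc$accuracy[ok] + sc$false_positive_rate[ok] +
                      sc$false_negative_rate[ok] - 100) <= 0.1))
  # with ST set equal to RSV the two rows coincide
  st_eq <- setNames(lim$rsv[lim$element == "Cd"],
                    as.character(lim$ph_bin[lim$element == "Cd"]))
  sc_eq <- score_criteria(d, "Cd", lim, st = st_eq, ht = ht)
  rsv_rows <- sc_eq[sc_eq$criterion == "RSV",
                    c("accuracy", "false_positive_rate", "false_negative_rate")]
  st_rows <- sc_eq[sc_eq$criterion == "ST",
                   c("accuracy", "false_positive_rate", "false_negative_rate")]
  expect_equal(unname(as.matrix(st_rows)), unname(as.matrix(rsv_rows)))
})

test_that("false positives never increase when the threshold is raised", {
  d <- make_fixture("study_like", seed = 15)
  fp <- vapply(c(0.5, 1, 2, 4, 8, 16), function(thr) {
    misclassification_rates(
      quadrant_classify(d, "Cd", thr, 0.2), digits = 10
    )[["false_positive_rate"]]
  }, numeric(1))
  expect_true(all(diff(fp) <= 0))
})

test_that("an exact inversion separates perfectly when noise vanishes", {
  d <- simulate_paired(degenerate_config(2000), seed = 77)
  st <- safety_thresholds(reference_models(), aux = aux_relation())
  st_cd <- setNames(st$st[st$element == "Cd"],
                    as.character(st$ph_bin[st$element == "Cd"]))
  q <- quadrant_classify(d, "Cd", soil_threshold = st_cd, grain_limit = 0.2)
  r <- misclassification_rates(q, digits = 10)
  expect_equal(r[["false_positive_rate"]], 0)
  expect_equal(r[["false_negative_rate"]], 0)
  expect_equal(r[["accuracy"]], 100)
})

test_that("quality classes apply the worst-case rule with printed boundaries", {
  df <- hand_table(4)
  df$pH <- 7
  thr <- list(Cd = list(lower = 0.6, upper = 3.0),
              As = list(lower = 25, upper = 120))
  df$S_T_Cd <- c(0.5, 1.0, 4.0, 3.0)   # I, II, III, II (boundary <= upper)
  df$S_T_As <- c(20, 20, 20, 20)       # all I
  out <- classify_quality(df, thr)
  expect_equal(as.character(out$class_Cd), c("I", "II", "III", "II"))
  expect_equal(as.character(out$composite), c("I", "II", "III", "II"))
  # As drives the composite when worse
  df$S_T_As <- c(130, 20, 20, 20)
  out <- classify_quality(df, thr)
  expect_equal(as.character(out$composite), c("III", "II", "III", "II"))
  # optional demotion by compliant grain
  df$Rice_Cd <- rep(0.05, 4)
  df$Rice_As <- rep(0.05, 4)
  out <- classify_quality(df, thr, demote_by_grain = TRUE)
  expect_equal(as.character(out$class_Cd), c("I", "II", "II", "II"))
})
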