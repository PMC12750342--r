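test_that("screening keeps strong signals and respects the alpha level", {
  set.seed(42)
  n <- 100
  df <- hand_table(n)
  df$site_id <- paste0("R", seq_len(n))
  df$C_Fe <- 10^rnorm(n, 2.5, 0.3)
  df$Rice_Cd <- 10^(0.9 * log10(df$C_Fe) + rnorm(n, 0, 0.13))  # r ~ 0.9
  expect_true("C_Fe" %in% screen_predictors(df, "Cd", candidates = "C_Fe"))

  # pure-noise predictor retained at ~alpha over replicates
  kept <- vapply(seq_len(1000), function(i) {
    df$C_Fe <- 10^rnorm(n, 2.5, 0.3)
    df$Rice_Cd <- 10^rnorm(n, -1, 0.3)
    length(screen_predictors(df, "Cd", candidates = "C_Fe")) == 1L
  }, logical(1L))
  expect_lt(abs(mean(kept) - 0.05), 0.02)
})

test_that("screening detects the soil total on generated data", {
  d <- simulate_paired(generator_config(n = 116), seed = 8)
  expect_true("S_T_Cd" %in% screen_predictors(d, "Cd"))
  expect_true("S_T_As" %in% screen_predictors(d, "As"))
})

test_that("constant predictors are excluded with a warning", {
  df <- hand_table(20)
  df$site_id <- paste0("C", 1:20)
  df$Rice_Cd <- 10^rnorm(20)
  expect_warning(out <- screen_predictors(df, "Cd", candidates = "F_Mn"),
                 "constant")
  expect_length(out, 0)
})

test_that("VIF matches the defining regression formula", {
  set.seed(7)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- 0.8 * x1 + sqrt(1 - 0.8^2) * rnorm(n)
  X <- data.frame(a = x1, b = x2, c = x3)
  vif <- compute_vif(X, c("a", "b", "c"), transform = FALSE)
  # brute-force oracle straight from the definition
  oracle <- vapply(names(X), function(p) {
    r2 <- summary(lm(X[[p]] ~ ., data = X[setdiff(names(X), p)]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(vif, oracle, tolerance = 1e-9)
  # orthogonal standardized predictors have VIF 1
  Xo <- data.frame(a = rep(c(1, -1), n / 2),
                   b = rep(c(1, 1, -1, -1), n / 4))
  expect_equal(unname(compute_vif(Xo, c("a", "b"), transform = FALSE)),
               c(1, 1), tolerance = 1e-9)
  # duplicated predictor flags infinite VIF
  Xd <- data.frame(a = x1, b = x1)
  expect_true(all(is.infinite(compute_vif(Xd, c("a", "b"), transform = FALSE))))
})

test_that("VIF agrees with the standard implementation", {
  skip_if_not_installed("car")
  d <- simulate_paired(generator_config(n = 116), seed = 13)
  preds <- c("pH", "SOM", "S_T_Cd", "C_Fe", "F_Fe")
  m <- transfer_model(d, "Cd", predictors = preds)
  ours <- compute_vif(d, preds)
  theirs <- car::vif(m$lm_fit)
  names(theirs) <- gsub("`", "", names(theirs))
  expect_equal(ours, theirs[names(ours)], tolerance = 1e-8)
})

test_that("collinearity resolution drops the available form of a tight pair", {
  d <- simulate_paired(generator_config(n = 116), seed = 17)
  # A_Cd tracks S_T_Cd multiplicatively, so the pair is near-collinear
  out <- resolve_collinearity(d, c("S_T_Cd", "A_Cd", "pH", "C_Fe"))
  expect_true("S_T_Cd" %in% out)
  expect_false("A_Cd" %in% out)
  # untouched when all VIF are small
  ok <- c("pH", "SOM", "C_Fe")
  expect_identical(resolve_collinearity(d, ok), ok)
})

test_that("collinearity resolution always ends below the threshold", {
  set.seed(99)
  n <- 80
  base <- rnorm(n)
  df <- data.frame(site_id = paste0("Z", 1:n), pH = rnorm(n, 7.6, 0.2),
                   SOM = abs(rnorm(n, 30, 5)))
  df$S_T_Cd <- 10^(base + rnorm(n, 0, 0.05))
  df$A_Cd <- 10^(base + rnorm(n, 0, 0.05))
  df$C_Fe <- 10^(base + rnorm(n, 0, 0.05))
  preds <- c("S_T_Cd", "A_Cd", "C_Fe")
  out <- resolve_collinearity(df, preds)
  expect_true(length(out) == 1L || all(compute_vif(df, out) <= 5))
  # matches exhaustive search for the largest admissible subset that
  # keeps the soil total under the same priority rule
  subsets <- unlist(lapply(seq_along(preds), function(k) {
    utils::combn(preds, k, simplify = FALSE)
  }), recursive = FALSE)
  ok <- Filter(function(s) {
    length(s) == 1L || all(compute_vif(df, s) <= 5)
  }, subsets)
  best_size <- max(lengths(ok))
  best <- Filter(function(s) length(s) == best_size &&
                   ("S_T_Cd" %in% s || !"A_Cd" %in% s), ok)
  expect_true(any(vapply(best, setequal, logical(1), out)))
})

test_that("OLS fit reports exact diagnostics", {
  d <- simulate_paired(generator_config(n = 116), seed = 23)
  m <- transfer_model(d, "Cd",
                      predictors = c("pH", "S_T_Cd", "C_Fe", "F_Fe"))
  # adjusted R^2 closed form
  expect_equal(m$adj_r2,
               1 - (1 - m$r2) * (m$n_fit - 1) / (m$n_fit - 4 - 1),
               tolerance = 1e-12)
  expect_equal(m$r, sqrt(m$r2), tolerance = 1e-12)
  expect_lte(m$adj_r2, m$r2)
  # residuals orthogonal to every (standardized) predictor column
  X <- scale(paddythresh:::transformed_predictors(d, m$terms$predictor))
  res <- residuals(m)
  expect_lt(max(abs(crossprod(X, res))) / length(res), 1e-8)
})

test_that("a response copying one predictor fits perfectly", {
  d <- simulate_paired(generator_config(n = 50), seed = 29)
  d$Rice_Cd <- d$S_T_Cd
  m <- transfer_model(d, "Cd", predictors = "S_T_Cd")
  expect_equal(unname(coef(m)), c(0, 1), tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
})

test_that("prediction applies the log-linear form", {
  ident <- as_transfer_model("Cd", 0, c(S_T_Cd = 1))
  expect_equal(predict(ident, data.frame(S_T_Cd = 0.2)), 0.2)
  # doubling the As soil total scales the prediction by ~2^0.975
  m <- reference_models()$As
  covs <- as.data.frame(c(as.list(covariate_means()), pH = 7.5,
                          S_T_As = 50, A_As = 30))
  covs2 <- covs; covs2$S_T_As <- 100
  expect_equal(predict(m, covs2) / predict(m, covs), 2^0.975,
               tolerance = 1e-9)
  expect_error(predict(m, covs[setdiff(names(covs), "A_As")]),
               "lacks predictor")
})

test_that("relative importance ranks dominant predictors first", {
  single <- as_transfer_model("Cd", 0, c(S_T_Cd = 1))
  d <- simulate_paired(generator_config(n = 100), seed = 37)
  expect_equal(unname(relative_importance(single, d)), 100)
  m <- transfer_model(d, "Cd",
                      predictors = reference_models()$Cd$terms$predictor)
  imp <- relative_importance(m, d)
  expect_equal(max(imp), 100)
  expect_equal(names(which.max(imp)), "S_T_Cd")
})

test_that("hold-out validation measures log-scale fit quality", {
  d <- split_dataset(simulate_paired(generator_config(n = 125), seed = 41),
                     n_validation = 9, seed = 41)
  m <- transfer_model(d, "Cd",
                      predictors = reference_models()$Cd$terms$predictor)
  rep <- validate_transfer_model(m, d)
  expect_equal(rep$n_validation, 9)
  expect_gte(rep$rmse, 0)
  # perfect predictions
  dv <- d[d$split == "validation", ]
  perfect <- as_transfer_model("Cd", 0, c(S_T_Cd = 1))
  dv$Rice_Cd <- dv$S_T_Cd
  out <- validate_transfer_model(perfect, dv)
  expect_equal(out$r2, 1)
  expect_equal(out$rmse, 0, tolerance = 1e-12)
  # constant predictions never beat the mean model
  dv$Rice_Cd <- 10^rnorm(9)
  const <- as_transfer_model("Cd", log10(0.2), c(S_T_Cd = 0))
  expect_lte(validate_transfer_model(const, dv)$r2, 0)
})
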