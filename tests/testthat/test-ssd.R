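test_that("BCF is the grain/soil ratio and 1/BCF its exact reciprocal", {
  df <- hand_table(3)
  df$S_T_Cd <- c(10, 1, 5)
  df$Rice_Cd <- c(0.2, 1, 0.1)
  b <- compute_bcf(df, "Cd")
  expect_equal(b$bcf, c(0.02, 1, 0.02))
  expect_equal(b$inv_bcf, c(50, 1, 50))
  expect_equal(b$inv_bcf, 1 / b$bcf)
})

test_that("plotting positions follow the Hazen and Weibull formulas", {
  h <- empirical_cumulative(c(2, 1, 3), "hazen")
  expect_equal(h$x, c(1, 2, 3))
  expect_equal(h$y, 100 * (1:3 - 0.5) / 3)
  w <- empirical_cumulative(c(2, 1, 3), "weibull")
  expect_equal(w$y, c(25, 50, 75))
  # ties share the average rank
  t <- empirical_cumulative(c(2, 2, 1, 3), "hazen")
  expect_equal(t$y[t$x == 2], rep(100 * (2.5 - 0.5) / 4, 2))
  # cumulative probabilities stay strictly inside (0, 100)
  for (pp in c("hazen", "weibull")) {
    y <- empirical_cumulative(rexp(50), pp)$y
    expect_true(all(y > 0 & y < 100))
  }
  expect_error(empirical_cumulative(c(1, 2)), "at least 3")
})

test_that("noiseless logistic curves are recovered exactly", {
  x <- 10^seq(0, 2, length.out = 20)
  y <- 100 / (1 + (x / 30)^(-2))
  fit <- ssd_logistic(x, y)
  expect_equal(coef(fit), c(a = 100, b = -2, x0 = 30), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_error(ssd_logistic(x[1:3], y[1:3]), "at least 4")
  expect_error(ssd_logistic(c(-1, x[-1]), y), "positive")
})

test_that("forward curve and algebraic inverse are exact inverses", {
  set.seed(5)
  for (i in 1:25) {
    a <- runif(1, 80, 120); b <- runif(1, 0.5, 4) * sample(c(-1, 1), 1)
    x0 <- 10^runif(1, -1, 2)
    fit <- list(a = a, b = b, x0 = x0)
    x <- 10^runif(100, -2, 3)
    y <- a / (1 + (x / x0)^b)
    keep <- y > 0.5 & y < a - 0.5  # keep the inverse well conditioned
    expect_equal(inverse_ssd(fit, y[keep]), x[keep], tolerance = 1e-9)
  }
  # midpoint identity and a worked closed form
  expect_equal(inverse_ssd(list(a = 100, b = -2, x0 = 30), 50), 30)
  expect_equal(inverse_ssd(list(a = 100, b = 2, x0 = 10), 20),
               10 * (100 / 20 - 1)^(1 / 2))
  expect_error(inverse_ssd(list(a = 90, b = -2, x0 = 30), 95),
               "between 0 and the asymptote")
})

test_that("fitted curve round-trips through predict and inverse_ssd", {
  x <- 10^seq(0, 2, length.out = 30)
  y <- 100 / (1 + (x / 25)^(-1.7))
  fit <- ssd_logistic(x, y)
  xs <- 10^runif(100, 0, 2)
  expect_equal(inverse_ssd(fit, predict(fit, xs)), xs, tolerance = 1e-9)
})

test_that("least-squares fit beats a coarse grid-search oracle", {
  set.seed(11)
  x <- 10^seq(0.5, 2.5, length.out = 60)
  y <- 100 / (1 + (x / 40)^(-2)) + rnorm(60, 0, 2)
  fit <- ssd_logistic(x, y)
  grid <- expand.grid(a = seq(90, 110, length.out = 9),
                      b = seq(-4, -0.5, length.out = 36),
                      x0 = 10^seq(1, 2.2, length.out = 36))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((y - grid$a[i] / (1 + (x / grid$x0[i])^grid$b[i]))^2)
  }, numeric(1))
  expect_lte(fit$residual_sse, min(sse))
})

test_that("hazard thresholds multiply the MAC by the 1/BCF percentile", {
  expect_equal(derive_ht(mac = 0.2, hc = 48.29)$ht, 9.658)
  expect_equal(derive_ht(mac = 1, hc = 1)$ht, 1)
  # via a fitted curve: HC95 solves the curve at y = 95 exactly
  x <- 10^seq(0, 2, length.out = 30)
  fit <- ssd_logistic(x, 100 / (1 + (x / 20)^(-2.2)))
  out <- derive_ht(fit, mac = 0.2)
  expect_equal(predict(fit, out$hc), 95, tolerance = 1e-9)
  expect_equal(out$ht, 0.2 * out$hc)
  # unattainable protection level under a low asymptote
  low <- list(a = 90, b = -2, x0 = 20)
  class(low) <- "ssd_logistic"
  expect_error(derive_ht(low, mac = 0.2), "asymptote")
})

test_that("per-bin hazard thresholds cover the study-like dataset", {
  d <- make_fixture("study_like", seed = 6)
  ht <- hazard_thresholds(d)
  expect_equal(nrow(ht), 4)
  expect_equal(sum(ht$n[ht$element == "Cd"]), 125)
  expect_true(all(ht$ht == ht$mac * ht$hc95))
  fits <- attr(ht, "fits")
  expect_length(fits, 4)
  # 95th percentile of Cd 1/BCF is in the plausible regional range
  inv <- compute_bcf(d, "Cd")$inv_bcf
  q95 <- unname(quantile(inv, 0.95))
  expect_gt(q95, 20); expect_lt(q95, 100)
  # the fitted-curve percentile agrees with the empirical one in order
  hc_cd <- ht$hc95[ht$element == "Cd"]
  expect_true(all(hc_cd > 20 & hc_cd < 100))
})
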