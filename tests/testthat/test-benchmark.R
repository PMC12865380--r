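test_that("predictors have uniform margins with lag-decaying correlation", {
  set.seed(1)
  cfg <- scenario_config("A", n = 4000)
  X <- gen_predictors(4000, cfg)
  expect_equal(dim(X), c(4000, 20))
  expect_lt(max(abs(colMeans(X) - 0.5)), 0.03)
  expect_lt(max(abs(apply(X, 2, var) - 1 / 12)), 0.01)
  # latent lag correlations ordered lag1 > lag2 > lag3 and near d^2
  Z <- qnorm(X)
  lag_cor <- function(l) mean(vapply(1:5, function(p)
    cor(Z[, paste0("x", p, ".1")], Z[, paste0("x", p, ".", 1 + l)]), 0))
  r <- vapply(1:3, lag_cor, 0)
  expect_true(r[1] > r[2] && r[2] > r[3])
  expect_equal(r, cfg$d_lag^2, tolerance = 0.12)
  # different predictors are uncorrelated
  expect_lt(abs(cor(X[, "x1.1"], X[, "x2.1"])), 3.5 / sqrt(4000))
  expect_lt(abs(cor(X[, "x3.2"], X[, "x5.4"])), 3.5 / sqrt(4000))
  # the non-squared covariance switch changes the latent correlation
  cfg2 <- scenario_config("A", n = 4000, copula_square = FALSE)
  set.seed(1)
  X2 <- gen_predictors(4000, cfg2)
  Z2 <- qnorm(X2)
  expect_equal(cor(Z2[, "x1.1"], Z2[, "x1.2"]), 0.4, tolerance = 0.1)
})

test_that("the Friedman mean evaluates as written", {
  cfg1 <- scenario_config("A", T = 1, c_weights = 1, h = numeric(0),
                          n = 1)
  X <- matrix(0.5, 1, 5, dimnames = list(NULL, paste0("x", 1:5, ".1")))
  expect_equal(friedman_mean(X, 1), 10 * sin(pi / 4) + 5 + 2.5,
               tolerance = 1e-12)
  expect_equal(friedman_mean(X, 0), 0)
  # scenario B depends only on the final wave
  set.seed(2)
  cfgB <- scenario_config("B", n = 50)
  XB <- gen_predictors(50, cfgB)
  f1 <- friedman_mean(XB, cfgB$c_weights)
  XB2 <- XB
  XB2[, 1:15] <- XB[sample(50), 1:15]  # scramble waves 1..3
  expect_equal(friedman_mean(XB2, cfgB$c_weights), f1)
})

test_that("outcome noise has the configured scale and reproduces", {
  set.seed(3)
  f <- rep(10, 5000)
  expect_equal(gen_outcome(f, 0), f)
  y <- gen_outcome(f, 10)
  expect_equal(sd(y - f), 10, tolerance = 0.35)
  set.seed(9); a <- gen_outcome(f, 10)
  set.seed(9); b <- gen_outcome(f, 10)
  expect_identical(a, b)
})

test_that("dropout is monotone with the printed retention probability", {
  cfg <- scenario_config("A", n = 20000)
  # all predictors at 0.5: wave-2 retention = expit(0.75 * 2.5) = 0.8670
  X05 <- matrix(0.5, 20000, 20,
                dimnames = list(NULL, colnames(gen_predictors(1, cfg))))
  set.seed(4)
  R <- gen_dropout(X05, cfg$h)
  expect_equal(mean(R[, 2]), plogis(0.75 * 2.5), tolerance = 0.01)
  expect_equal(plogis(0.75 * 2.5), 0.8670, tolerance = 5e-4)
  # monotone: no re-entry
  set.seed(5)
  Xr <- gen_predictors(2000, cfg)
  Rr <- gen_dropout(Xr, cfg$h)
  expect_true(all(diff(t(Rr)) <= 0))
  expect_true(all(Rr[, 1] == 1))
  # huge coefficients: nobody drops out
  R1 <- gen_dropout(Xr, c(50, 50, 50))
  expect_true(all(R1 == 1))
})

test_that("the truth oracle matches independent quadrature", {
  cfg0 <- scenario_config("C", n = 10, c_weights = rep(0, 4))
  expect_equal(as.numeric(truth_oracle(cfg0, 1000, seed = 6)), 0)
  # scenario B truth = single-wave Friedman expectation:
  # 10 E[sin(pi u v)] + 20/12 + 5 + 2.5 with the double integral by
  # nested quadrature
  i_sin <- stats::integrate(function(u) vapply(u, function(ui)
    stats::integrate(function(v) sin(pi * ui * v), 0, 1)$value, 0),
    0, 1)$value
  quad <- 10 * i_sin + 20 / 12 + 5 + 2.5
  cfgB <- scenario_config("B", n = 10)
  tr <- truth_oracle(cfgB, 2e5, seed = 7)
  expect_equal(as.numeric(tr), quad, tolerance = 4 * attr(tr, "se") + 1e-3)
})

test_that("benchmark replicates are deterministic and well-formed", {
  cfg <- scenario_config("A", n = 60)
  c1 <- gen_benchmark_data(cfg, seed = 8)
  c2 <- gen_benchmark_data(cfg, seed = 8)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
  expect_silent(validate_cohort(c1))
  # outcome observed exactly for final-wave responders
  last <- c1[c1$t == 4, ]
  expect_equal(is.na(last$Y), last$R == 0)
  expect_error(benchmark_model_map("SBART-l2"), "unknown")
})
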