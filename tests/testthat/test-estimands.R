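test_that("PCIE is the survivor-mean difference", {
  expect_equal(pcie(10, 10), 0)
  expect_equal(pcie(12.5, 10.0), 2.5)
  expect_true(is.na(pcie(NA, 10)))
})

test_that("conditional survival follows the stochastic-monotonicity form", {
  # lambda = 0: independence, returns psi*
  expect_equal(conditional_survival(0.7, 0.9, 0), 0.7)
  # lambda = 1 with psi* >= psi0: deterministic monotonicity, U = 1
  expect_equal(conditional_survival(0.9, 0.8, 1), 1)
  # intermediate case: 0.9 + 0.5 (1 - 0.9)
  expect_equal(conditional_survival(0.9, 0.8, 0.5), 0.95)
  expect_error(conditional_survival(0.9, 0, 0.5), "positive")
  # monotone nondecreasing in lambda and always a probability
  set.seed(1)
  for (i in 1:50) {
    ps <- runif(1); p0 <- runif(1, 0.05, 1)
    lam <- sort(runif(2))
    v <- conditional_survival(ps, p0, lam)
    expect_true(all(v >= 0 & v <= 1))
    if (min(1, ps / p0) >= ps) expect_lte(v[1], v[2] + 1e-12)
  }
})

test_that("the SAIE formula reduces and evaluates as printed", {
  expect_equal(saie(1.2, 0.7, 0.9, 0.8, 0), 1.2)          # Delta = 0
  expect_equal(saie(1.2, 0.9, 0.8, 0.8, 3), 1.2)          # U = 1
  # worked case: U = 8/9, adjustment 4 * 0.86667 * (1 - 9/8)
  expect_equal(saie(1.0, 0.8, 0.9, 0.75, 4), 0.56667, tolerance = 1e-4)
  expect_equal(saie(1.0, 0.8, 0.9, 0.75, 4, flip_sign = TRUE), 1.43333,
               tolerance = 1e-4)
  expect_error(saie(1, 0.8, 0, 0.5, 1), "positive")
  # SAIE = PCIE whenever psi* >= psi0, draw by draw
  set.seed(2)
  ps <- runif(100, 0.5, 1)
  p0 <- ps * runif(100)  # p0 <= ps
  out <- saie(0.3, ps, p0, runif(100), runif(100, 0, 5))
  expect_equal(out, rep(0.3, 100))
})

test_that("estimand draws pair regimes and sensitivity parameters", {
  g0 <- structure(data.frame(draw = 1:200, survivor_mean = rnorm(200, 50),
                             psi = runif(200, 0.7, 0.9), n_surv = 100),
                  class = c("gcomp_draws", "data.frame"))
  gs <- g0
  gs$survivor_mean <- g0$survivor_mean + 1
  gs$psi <- pmin(g0$psi + 0.02, 1)
  ed <- estimand_draws(g0, gs, sensitivity_spec(u_delta = 4.6), seed = 3)
  expect_equal(ed$pcie, rep(1, 200))
  expect_true(all(ed$lambda_draw >= 0.5 & ed$lambda_draw <= 1))
  expect_true(all(ed$delta_draw >= 0 & ed$delta_draw <= 4.6))
  # psi* > psi0 here, so SAIE equals PCIE draw by draw
  expect_equal(ed$saie, ed$pcie)
  bad <- gs; bad$draw <- bad$draw + 1
  expect_error(estimand_draws(g0, bad), "same posterior draw")
})

test_that("posterior summaries use mean and equal-tailed quantiles", {
  d <- data.frame(draw = 1:5, pcie = rep(2, 5))
  s <- summarize_draws(d)
  expect_equal(unlist(s[s$estimand == "pcie", c("mean", "lower", "upper")]),
               c(mean = 2, lower = 2, upper = 2))
  d2 <- data.frame(draw = 1:100, v = 1:100)
  s2 <- summarize_draws(d2)
  expect_equal(s2$lower, 3.475)   # type-7 empirical quantile
  expect_equal(s2$upper, 97.525)
  expect_equal(s2$mean, 50.5)     # symmetric draws: mean at the center
  expect_error(summarize_draws(d2[0, ]), "at least 2")
})
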