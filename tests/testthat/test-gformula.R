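test_that("the intervention rule shifts only above the threshold", {
  expect_equal(apply_intervention(120, 130, -10), 120)
  expect_equal(apply_intervention(150, 140, 0), 150)
  expect_equal(apply_intervention(150, 140, -20), 130)
  expect_equal(apply_intervention(c(120, 150), 130, -5), c(120, 145))
  expect_error(apply_intervention(150, 140, 5))
})

test_that("the fitted set mirrors the factorization structure", {
  # benchmark data: no deaths -> response, covariate and outcome models only
  cfg <- scenario_config("A", n = 80)
  co <- gen_benchmark_data(cfg, seed = 21)
  fits <- fit_sequential(co, prior_mode = "dart",
                         control = quick_ctl(20, 10), n_trees = 5)
  nm <- names(fits$models)
  expect_false(any(grepl("^survival", nm)))
  expect_true(all(paste0("response.", 2:4) %in% nm))
  expect_true(all(paste0("covariate.x", 1:5, ".2") %in% nm))
  expect_true("outcome.4" %in% nm)
  expect_false(any(grepl("treatment", nm)))

  # single-wave cohort: the factorization collapses to the outcome model
  df1 <- data.frame(id = 1:30, t = 1, S = 1L, R = 1L,
                    x1 = runif(30), Y = rnorm(30))
  co1 <- cohort_table(df1, covariates = "x1", outcome = "Y")
  f1 <- fit_sequential(co1, prior_mode = "uniform",
                       control = quick_ctl(20, 10), n_trees = 5)
  expect_equal(names(f1$models), "outcome.1")
})

test_that("a deathless, dropout-free cohort yields psi = 1", {
  set.seed(22)
  n <- 40
  df <- data.frame(id = rep(1:n, each = 3), t = rep(1:3, n), S = 1L, R = 1L,
                   x1 = runif(3 * n), Y = rnorm(3 * n, 10))
  co <- cohort_table(df, covariates = "x1", outcome = "Y")
  fits <- fit_sequential(co, prior_mode = "uniform",
                         control = quick_ctl(30, 10), n_trees = 5)
  gc <- gcomp_estimates(fits, regime_spec("natural_course"), nstar = 200,
                        draws = 1:5, seed = 2)
  expect_equal(gc$psi, rep(1, 5))
  expect_true(all(gc$n_surv == 200))
})

test_that("a null intervention with shared seeds reproduces g0 exactly", {
  co <- generate_cohort(fixture_config(n = 100), seed = 31)
  fits <- fit_sequential(co, prior_mode = "ldart",
                         control = quick_ctl(40, 20, seed = 31), n_trees = 20)
  g0 <- gcomp_estimates(fits, regime_spec("natural_course"), nstar = 200,
                        draws = 1:6, seed = 5)
  gs <- gcomp_estimates(fits, test_regime(tau = Inf), nstar = 200,
                        draws = 1:6, seed = 5)
  expect_identical(pcie(gs$survivor_mean, g0$survivor_mean), rep(0, 6))
  expect_identical(gs$psi, g0$psi)
})

test_that("pseudo-trajectories respect monotone death and dominance", {
  co <- generate_cohort(fixture_config(n = 120), seed = 41)
  fits <- fit_sequential(co, prior_mode = "ldart",
                         control = quick_ctl(40, 20, seed = 41), n_trees = 20)
  reg <- test_regime(tau = 130)
  a0_mean <- as_mean <- matrix(NA, 3, 4)
  for (d in 1:3) {
    p0 <- simulate_regime(fits, regime_spec("natural_course"), 400, d,
                          seed = 100 + d)
    ps <- simulate_regime(fits, reg, 400, d, seed = 100 + d)
    for (pc in list(p0, ps)) {
      expect_true(all(diff(t(pc$S)) <= 0))      # monotone death
      expect_true(all(pc$psurv >= 0 & pc$psurv <= 1))
      expect_true(all(pc$w >= 0 & pc$w <= 1))
    }
    a0_mean[d, ] <- colMeans(p0$A)
    as_mean[d, ] <- colMeans(ps$A)
    # the intervened value never exceeds the natural value
    expect_true(all(ps$A <= ps$Astar + 1e-12))
  }
  expect_true(all(as_mean <= a0_mean + 1e-12))
})

test_that("oracle G-computation recovers the generator truth", {
  set.seed(51)
  cfg <- scenario_config("A", n = 250)
  om <- benchmark_oracle_models(cfg, pool_n = 20000)
  gc <- gcomp_estimates(om, regime_spec("natural_course"), nstar = 4000,
                        draws = rep(1, 4), seed = 61)
  tr <- truth_oracle(cfg, 2e5, seed = 71)
  se <- sd(gc$survivor_mean) / 2 + attr(tr, "se")
  expect_lt(abs(mean(gc$survivor_mean) - as.numeric(tr)), 4 * se + 0.1)
})

test_that("Monte-Carlo error shrinks like one over root N*", {
  set.seed(81)
  cfg <- scenario_config("B", n = 100)
  om <- benchmark_oracle_models(cfg, pool_n = 5000)
  g0 <- regime_spec("natural_course")
  est <- function(nstar, seeds) vapply(seeds, function(s)
    gcomp_estimates(om, g0, nstar = nstar, draws = 1, seed = s)$survivor_mean,
    0)
  s_small <- sd(est(150, 1:40))
  s_large <- sd(est(600, 101:140))
  # fourfold N* should halve the SE, up to sampling noise of the SDs
  expect_gt(s_small / s_large, 1.2)
  expect_lt(s_small / s_large, 3.5)
})

test_that("gcomp flags draws without survivors", {
  # hand-built model set with a near-lethal survival transition
  sc <- list(covariates = "x1", baseline = character(), treatment = NULL,
             outcome = "Y", outcome_waves = 2L, T = 2L)
  models <- list(
    "survival.2" = oracle_model(prob = function(sim) rep(0.005, nrow(sim))),
    "covariate.x1.2" = oracle_model(mean = function(sim) sim[["x1.1"]],
                                    sd = 0.1),
    "outcome.2" = oracle_model(mean = function(sim) rep(5, nrow(sim)),
                               sd = 1))
  mob <- structure(list(models = models, schema = sc, T = 2L, n_draws = 1L,
                        prior_mode = "oracle", soft = NA,
                        baseline_pool = data.frame(x1.1 = runif(50)),
                        has_deaths = TRUE, has_dropout = FALSE),
                   class = "sequential_models")
  expect_warning(
    gc <- gcomp_estimates(mob, regime_spec("natural_course"), nstar = 30,
                          draws = rep(1, 5), seed = 7),
    "no surviving")
  expect_true(anyNA(gc$survivor_mean))
  expect_true(all(gc$psi < 0.05))
})
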