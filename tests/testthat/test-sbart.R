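test_that("leaf weights are a soft partition of unity", {
  # single leaf: all weight on it
  leaf <- matrix(c(0, 0, 0, 0, 0, 1), 1, 6)
  X <- matrix(runif(10), 10, 1)
  expect_equal(as.numeric(leaf_weights(leaf, X)), rep(1, 10))

  # one split at c = 0.5 with bandwidth 0.2: symmetric gating at the cut
  tr <- rbind(c(1, 0.5, 0.2, 2, 3, 0),
              c(0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0, 0))
  w <- leaf_weights(tr, matrix(0.5, 1, 1))
  expect_equal(as.numeric(w), c(0.5, 0.5))

  # weights sum to one for prior-drawn trees at random inputs
  set.seed(1)
  for (i in 1:5) {
    pd <- sbart_prior_draw(rep(0, 3), rep(1, 3), n_trees = 1)
    tr <- pd$forest$draws[[1]]$trees[[1]]
    W <- leaf_weights(tr, matrix(runif(60), 20, 3))
    expect_equal(rowSums(W), rep(1, 20), tolerance = 1e-12)
    expect_true(all(W >= 0))
  }
})

test_that("shrinking the bandwidth recovers the hard partition", {
  set.seed(2)
  X <- matrix(runif(300), 100, 3)
  cut <- 0.4
  hard_oracle <- cbind(X[, 2] <= cut, X[, 2] > cut) * 1
  for (b in c(0.05, 0.005, 0)) {
    tr <- rbind(c(2, cut, b, 2, 3, 0), c(0, 0, 0, 0, 0, 0),
                c(0, 0, 0, 0, 0, 0))
    W <- leaf_weights(tr, X)
    if (b == 0) expect_equal(W, hard_oracle, ignore_attr = TRUE)
  }
  W1 <- leaf_weights(rbind(c(2, cut, 0.05, 2, 3, 0), c(0, 0, 0, 0, 0, 0),
                           c(0, 0, 0, 0, 0, 0)), X)
  W2 <- leaf_weights(rbind(c(2, cut, 0.005, 2, 3, 0), c(0, 0, 0, 0, 0, 0),
                           c(0, 0, 0, 0, 0, 0)), X)
  expect_lt(mean(abs(W2 - hard_oracle)), mean(abs(W1 - hard_oracle)))
  # pointwise convergence away from the cut (gating stays smooth at it)
  far <- abs(X[, 2] - cut) > 0.05
  expect_lt(max(abs(W2[far, ] - hard_oracle[far, ])), 1e-3)
})

test_that("forest prediction is additive and continuous", {
  # one single-leaf tree with value 3 plus intercept 1 predicts 4
  leaf3 <- matrix(c(0, 0, 0, 0, 0, 3), 1, 6,
                  dimnames = list(NULL, c("var", "cut", "band", "left",
                                          "right", "leaf")))
  dump <- list(forest = list(P = 1L, draws = list(list(mu0 = 1,
                                                       trees = list(leaf3)))),
               vars = "V1", type = "gaussian", ymin = -0.5, ymax = 0.5,
               mu0 = 1, n_draws = 1L, soft = TRUE, n_trees = 1L,
               sigma = NA_real_)
  fit <- sbart_restore(dump)
  expect_equal(predict(fit, matrix(0.7, 1, 1, dimnames = list(NULL, "V1"))),
               4)
  # continuity under small perturbations for a soft prior forest
  set.seed(3)
  pd <- sbart_restore(sbart_prior_draw(rep(0, 2), rep(1, 2), n_trees = 10))
  x <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("V1", "V2")))
  eps <- 1e-6
  d <- abs(predict(pd, x + eps) - predict(pd, x))
  expect_lt(max(d), 1e-3)
})

test_that("the Gaussian sampler recovers a smooth signal", {
  set.seed(4)
  n <- 400
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- friedman1(X) + rnorm(n)
  fit <- sbart(X, y, control = quick_ctl(seed = 4))
  Xt <- matrix(runif(1000 * 5), 1000, 5,
               dimnames = list(NULL, paste0("x", 1:5)))
  r2 <- 1 - mean((predict(fit, Xt) - friedman1(Xt))^2) / var(friedman1(Xt))
  expect_gt(r2, 0.7)
  # residual scale lands near the generating value
  expect_lt(abs(mean(fit$sigma) - 1), 0.5)
})

test_that("identical seeds reproduce the fit exactly", {
  set.seed(5)
  X <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- 3 * X[, 1] + rnorm(100)
  f1 <- sbart(X, y, control = quick_ctl(50, 50, seed = 9))
  f2 <- sbart(X, y, control = quick_ctl(50, 50, seed = 9))
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("degenerate targets give constant fits with a warning", {
  X <- matrix(runif(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(f <- sbart(X, rep(2, 50), control = quick_ctl(10, 10)),
                 "degenerate")
  expect_true(f$constant)
  expect_equal(predict(f, X), rep(2, 50))
  expect_warning(fp <- sbart(X, rep(1, 50), type = "probit",
                             control = quick_ctl(10, 10)), "degenerate")
  expect_true(all(predict(fp, X) < 1 & predict(fp, X) > 0.9))
})

test_that("an intercept-only forest reduces to the sample mean", {
  set.seed(6)
  y <- rnorm(60, mean = 7, sd = 0.5)
  X <- matrix(runif(60), 60, 1, dimnames = list(NULL, "x"))
  fit <- sbart(X, y, n_trees = 1, base = 0, control = quick_ctl(100, 200))
  expect_equal(unname(predict(fit, X)[1]), mean(y), tolerance = 0.1)
})

test_that("probit fits separate a sharp threshold and track a null", {
  set.seed(7)
  n <- 400
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  z <- as.integer(X[, 1] > 0.5)
  fit <- sbart(X, z, type = "probit", control = quick_ctl(seed = 7))
  p <- predict(fit, X)
  expect_true(all(p > 0 & p < 1))
  expect_gt(mean(p[X[, 1] > 0.6]), 0.8)
  expect_lt(mean(p[X[, 1] < 0.4]), 0.2)
  # agreement with a logistic-regression oracle on held-out points
  or <- suppressWarnings(stats::glm(z ~ X[, 1], family = stats::binomial()))
  expect_gt(cor(p, stats::fitted(or)), 0.85)
  # independent outcome: predicted probabilities near the base rate
  set.seed(8)
  z0 <- rbinom(n, 1, 0.3)
  f0 <- sbart(X, z0, type = "probit", control = quick_ctl(100, 100, seed = 8))
  expect_lt(abs(mean(predict(f0, X)) - mean(z0)), 0.06)
})

test_that("split counts are conserved and match the stored forests", {
  set.seed(9)
  X <- matrix(runif(300), 100, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- 5 * X[, 1] + rnorm(100)
  fit <- sbart(X, y, control = quick_ctl(50, 20, seed = 10), n_trees = 10)
  cm <- split_counts(fit)
  expect_equal(dim(cm), c(20, 3))
  dump <- forest_dump(fit)
  for (d in c(1, 10, 20)) {
    trees <- dump$forest$draws[[d]]$trees
    n_internal <- sum(vapply(trees, function(m) sum(m[, 1] > 0), 0))
    expect_equal(sum(cm[d, ]), n_internal)
  }
})

test_that("forests survive a serialization round trip (including JSON)", {
  set.seed(10)
  X <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- 4 * X[, 2] + rnorm(100)
  fit <- sbart(X, y, control = quick_ctl(50, 30, seed = 11), n_trees = 10)
  dump <- forest_dump(fit)
  back <- sbart_restore(dump)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
  js <- jsonlite::toJSON(dump, digits = NA)
  dump2 <- jsonlite::fromJSON(js, simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE)
  back2 <- sbart_restore(dump2)
  expect_equal(predict(back2, X), predict(fit, X), tolerance = 1e-8)
})
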