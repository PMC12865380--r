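test_that("the hyperprior schedule follows the linear-in-time formula", {
  expect_equal(c_schedule(4), c(0.5, 2 / 3, 5 / 6))
  expect_equal(c_schedule(2), 0.5)
  expect_length(c_schedule(1), 0)
  for (t in 2:8) {
    cs <- c_schedule(t)
    expect_equal(cs[1], 0.5)          # first time point always 0.5
    expect_true(all(diff(cs) > 0))    # strictly increasing
    expect_lt(cs[t - 1], 1)
  }
})

test_that("selection probabilities compose the two-level hierarchy", {
  # symmetric state: uniform q
  gr <- list(current = 1:3, past = list(4:6, 7:9))
  q <- selection_prob(1 / 3, rep(1 / 3, 3), c(0.5, 0.5),
                      list(rep(1 / 3, 3), rep(1 / 3, 3)), gr)
  expect_equal(q, rep(1 / 9, 9))
  # w = 1: no mass on past predictors
  q1 <- selection_prob(1, rep(1 / 3, 3), c(0.5, 0.5),
                       list(rep(1 / 3, 3), rep(1 / 3, 3)), gr)
  expect_equal(q1[4:9], rep(0, 6))
  # the printed product rule: t = 4, w = 0.6, u = (0.1, 0.3, 0.6),
  # v^2 uniform over 5 predictors -> each wave-2 predictor gets 0.024
  gr2 <- list(current = 1:2, past = list(3:4, 5:9, 10:11))
  q2 <- selection_prob(0.6, c(0.5, 0.5), c(0.1, 0.3, 0.6),
                       list(rep(0.5, 2), rep(0.2, 5), rep(0.5, 2)), gr2)
  expect_equal(unname(q2[5:9]), rep(0.4 * 0.3 / 5, 5))
  expect_equal(sum(q2), 1)
  # normalization holds for random states
  set.seed(1)
  for (i in 1:20) {
    sizes <- sample(1:4, 3, replace = TRUE)
    idx <- split(seq_len(sum(sizes)), rep(1:3, sizes))
    gr3 <- list(current = idx[[1]], past = idx[2:3])
    rs <- function(k) { v <- rexp(k); v / sum(v) }
    q3 <- selection_prob(runif(1), rs(sizes[1]), rs(2),
                         list(rs(sizes[2]), rs(sizes[3])), gr3)
    expect_equal(sum(q3), 1, tolerance = 1e-12)
  }
  expect_error(selection_prob(0.5, c(1), c(1), list(c(1)),
                              list(current = 1:2, past = list(3))),
               "v_t size")
})

test_that("the grouped prior update matches conjugate closed forms", {
  set.seed(2)
  pr <- split_prior("ldart", wave = c(NA, 3, 3, 2, 1, 1), t = 3)
  counts <- c(5, 3, 0, 2, 0, 1)
  up <- update_split_prior(counts, pr, n_sweeps = 3000)
  # w | counts ~ Beta(a + current, b + past): current = 8, past = 3
  expect_equal(mean(up$w), 9 / 13, tolerance = 0.02)
  v <- stats::var(up$w)
  expect_equal(v, 9 * 4 / (13^2 * 14), tolerance = 0.15)
  expect_equal(rowSums(up$q), rep(1, 3000), tolerance = 1e-12)
  # zero counts: the update draws from the prior (E[w] = 1/2 under
  # Beta(1,1))
  up0 <- update_split_prior(rep(0, 6), pr, n_sweeps = 3000)
  expect_equal(mean(up0$w), 0.5, tolerance = 0.03)
})

test_that("within-group exchangeability: permuted counts permute the draws", {
  set.seed(3)
  pr <- split_prior("ldart", wave = c(2, 2, 1, 1, 1), t = 2)
  counts <- c(4, 4, 2, 2, 2)  # symmetric within both groups
  up <- update_split_prior(counts, pr, n_sweeps = 4000)
  qm <- colMeans(up$q)
  expect_equal(qm[1], qm[2], tolerance = 0.02)
  expect_equal(qm[3], qm[5], tolerance = 0.02)
})

test_that("the alpha hyperpriors are stochastically ordered in time", {
  set.seed(4)
  pr <- split_prior("ldart", wave = c(4, 4, 3, 3, 2, 2, 1, 1), t = 4)
  up <- update_split_prior(rep(0, 8), pr, n_sweeps = 4000)
  # the implied priors have heavy right tails (infinite mean), so the
  # ordering is checked on medians
  am <- apply(up$alpha_g, 2, stats::median)  # groups by wave 1, 2, 3
  expect_lt(am[1], am[3])          # earlier waves: smaller concentration
  # and the implied prior mass on u follows the same ordering
  um <- colMeans(up$u)
  expect_lt(um[1], um[3])
})

test_that("heavy use of one current predictor concentrates its mass", {
  set.seed(5)
  pr <- split_prior("ldart", wave = c(2, 2, 1, 1), t = 2)
  up <- update_split_prior(c(60, 0, 0, 0), pr, n_sweeps = 3000)
  expect_gt(mean(up$q[, 1]), 0.85)
})

test_that("DART updates follow the Dirichlet-multinomial posterior", {
  set.seed(6)
  pr <- split_prior("dart")
  counts <- c(4, 1, 0)
  up <- update_split_prior(counts, pr, n_sweeps = 6000)
  keep <- 1001:6000
  # grid oracle for p(alpha | counts) with rho = P = 3, Beta(0.5, 1)
  P <- 3; rho <- 3
  al <- seq(0.001, 60, length.out = 6000)
  s <- al / (al + rho)
  lp <- stats::dbeta(s, 0.5, 1, log = TRUE) + log(rho) - 2 * log(al + rho) +
    lgamma(al) - lgamma(al + sum(counts)) +
    rowSums(outer(al / P, counts, function(a, m) lgamma(a + m)) -
              lgamma(matrix(al / P, length(al), P)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  # the posterior inherits the hyperprior's heavy right tail, so the
  # check uses the median and a tail probability rather than the mean
  med_grid <- al[which(cumsum(w) >= 0.5)[1]]
  med_mcmc <- stats::median(up$alpha[keep])
  expect_equal(med_mcmc, med_grid, tolerance = 0.15)
  p_grid <- sum(w[al < 3])
  p_mcmc <- mean(up$alpha[keep] < 3)
  expect_equal(p_mcmc, p_grid, tolerance = 0.12)
  # posterior mean of q matches Dirichlet conjugacy given the alpha draws
  e_q1 <- mean((up$alpha[keep] / P + counts[1]) /
                 (up$alpha[keep] + sum(counts)))
  expect_equal(mean(up$q[keep, 1]), e_q1, tolerance = 0.02)
})

test_that("single-predictor and single-group cases degenerate cleanly", {
  set.seed(7)
  up <- update_split_prior(5, split_prior("dart"), n_sweeps = 50)
  expect_equal(as.numeric(up$q), rep(1, 50))
  # t = 1: no past groups, LDART reduces to its current-group Dirichlet
  pr <- split_prior("ldart", wave = c(1, 1, 1), t = 1)
  up1 <- update_split_prior(c(3, 0, 0), pr, n_sweeps = 100)
  expect_equal(rowSums(up1$q), rep(1, 100), tolerance = 1e-12)
  expect_equal(as.numeric(up1$w), rep(1, 100))
})

test_that("negative counts are rejected", {
  expect_error(update_split_prior(c(-1, 2), split_prior("dart")), "negative")
})
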