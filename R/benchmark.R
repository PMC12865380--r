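#' Longitudinal Friedman benchmark configuration
#'
#' Study conditions for the simulation benchmark: five time-varying
#' predictors observed over T = 4 waves as correlated uniforms (Gaussian
#' copula with lag-decaying latent correlations), a final-wave outcome
#' from a wave-weighted Friedman function with Gaussian noise (sd 10),
#' and monotone dropout of roughly 13--15\% per follow-up wave.
#'
#' Scenario weights (in wave order c_1..c_T): A = (0.25, 0.5, 0.75, 1), a
#' decreasing association looking back in time; B = (0, 0, 0, 1), only
#' the final wave matters; C = (0.25, 0.25, 0.25, 0.25), a weak stable
#' association.
#'
#' @param scenario "A", "B" or "C" (ignored when \code{c_weights} given).
#' @param n Subjects per replicate.
#' @param T Number of waves.
#' @param sigma_T Outcome noise SD.
#' @param c_weights Optional explicit wave weights c_1..c_T.
#' @param h Dropout coefficients for waves 2..T.
#' @param d_lag Latent copula correlations at lags 1..3.
#' @param copula_square Use the squared lag parameters as covariance
#'   entries (as printed); \code{FALSE} uses them directly.
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(scenario = c("A", "B", "C"), n = 250, T = 4,
                            sigma_T = 10, c_weights = NULL,
                            h = c(0.75, 0.4, 0.25),
                            d_lag = c(0.4, 0.2, 0.1), copula_square = TRUE) {
  scenario <- match.arg(scenario)
  if (is.null(c_weights)) {
    c_weights <- switch(scenario,
                        A = c(0.25, 0.5, 0.75, 1),
                        B = c(0, 0, 0, 1),
                        C = rep(0.25, 4))
    if (T != 4) stop("named scenarios are defined for T = 4")
  }
  stopifnot(length(c_weights) == T, length(h) == T - 1)
  structure(list(scenario = scenario, n = n, T = T, sigma_T = sigma_T,
                 c_weights = c_weights, h = h, d_lag = d_lag,
                 copula_square = copula_square, n_pred = 5L),
            class = "scenario_config")
}

copula_sigma <- function(cfg) {
  Tn <- cfg$T
  Sig <- diag(Tn)
  for (t in seq_len(Tn)) for (k in seq_len(Tn)) {
    l <- abs(t - k)
    if (l >= 1 && l <= length(cfg$d_lag))
      Sig[t, k] <- if (cfg$copula_square) cfg$d_lag[l]^2 else cfg$d_lag[l]
  }
  Sig
}

#' Generate correlated-uniform longitudinal predictors
#'
#' For each of the five predictors independently, a T-variate Gaussian
#' with unit variances and lag-decaying covariances is drawn and mapped
#' through the standard normal CDF, giving Uniform(0,1) margins that are
#' correlated within predictor across waves and independent across
#' predictors.
#'
#' @param n Number of subjects.
#' @param cfg A \code{\link{scenario_config}}.
#' @return Matrix n x (5 T) with columns \code{xp.t}.
#' @export
gen_predictors <- function(n, cfg) {
  Sig <- copula_sigma(cfg)
  ch <- tryCatch(chol(Sig),
                 error = function(e) stop("copula covariance not positive definite"))
  Tn <- cfg$T
  out <- matrix(NA_real_, n, cfg$n_pred * Tn)
  cn <- character(cfg$n_pred * Tn)
  for (p in seq_len(cfg$n_pred)) {
    Z <- matrix(rnorm(n * Tn), n, Tn) %*% ch
    U <- pnorm(Z)
    for (t in seq_len(Tn)) {
      j <- (t - 1) * cfg$n_pred + p
      out[, j] <- U[, t]
      cn[j] <- wcol(paste0("x", p), t)
    }
  }
  colnames(out) <- cn
  out
}

friedman_wave <- function(x1, x2, x3, x4, x5)
  10 * sin(pi * x1 * x2) + 20 * (x3 - 0.5)^2 + 10 * x4 + 5 * x5

#' Wave-weighted Friedman mean function
#'
#' \deqn{f(x) = \sum_t c_t [10 \sin(\pi x_{1t} x_{2t}) + 20 (x_{3t} -
#' 0.5)^2 + 10 x_{4t} + 5 x_{5t}]}
#'
#' @param X Predictor matrix with columns \code{xp.t} (as produced by
#'   \code{\link{gen_predictors}}).
#' @param c_weights Wave weights c_1..c_T.
#' @return Numeric vector of conditional means.
#' @export
friedman_mean <- function(X, c_weights) {
  Tn <- length(c_weights)
  out <- numeric(nrow(X))
  for (t in seq_len(Tn)) {
    if (c_weights[t] == 0) next
    g <- function(p) as.numeric(X[, wcol(paste0("x", p), t), drop = TRUE])
    out <- out + c_weights[t] * friedman_wave(g(1), g(2), g(3), g(4), g(5))
  }
  out
}

#' @rdname friedman_mean
#' @param f_vals Conditional means.
#' @param sigma_T Noise SD.
#' @return \code{gen_outcome}: \code{f_vals} plus independent Gaussian
#'   noise.
#' @export
gen_outcome <- function(f_vals, sigma_T) {
  stopifnot(sigma_T >= 0)
  f_vals + sigma_T * rnorm(length(f_vals))
}

#' Generate monotone dropout indicators
#'
#' Retention at wave j has probability
#' \eqn{\pi_j = expit[h_j \sum_{t<j} (x_{1t} + ... + x_{5t})]}; everyone
#' is observed at wave 1 and dropout is permanent.
#'
#' @param X Predictor matrix from \code{\link{gen_predictors}}.
#' @param h Coefficients h_2..h_T.
#' @return Matrix n x T of response indicators.
#' @export
gen_dropout <- function(X, h) {
  Tn <- length(h) + 1
  n <- nrow(X)
  n_pred <- 5L
  R <- matrix(1L, n, Tn)
  csum <- numeric(n)
  for (j in 2:Tn) {
    prev <- (j - 2) * n_pred + seq_len(n_pred)
    csum <- csum + rowSums(X[, prev, drop = FALSE])
    pi_j <- stats::plogis(h[j - 1] * csum)
    R[, j] <- R[, j - 1] * rbinom(n, 1, pi_j)
  }
  R
}

#' Generate one benchmark replicate as a cohort table
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param seed Optional seed.
#' @return A \code{\link{cohort_table}} with covariates x1..x5, no
#'   treatment, no deaths, and the outcome measured at the final wave
#'   only (missing after dropout).
#' @export
gen_benchmark_data <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  Tn <- cfg$T
  X <- gen_predictors(n, cfg)
  f <- friedman_mean(X, cfg$c_weights)
  y <- gen_outcome(f, cfg$sigma_T)
  R <- gen_dropout(X, cfg$h)
  covs <- paste0("x", seq_len(cfg$n_pred))
  long <- data.frame(id = rep(seq_len(n), each = Tn),
                     t = rep(seq_len(Tn), n), S = 1L,
                     R = as.integer(t(R)))
  for (v in covs) long[[v]] <- NA_real_
  long$Y <- NA_real_
  for (t in seq_len(Tn)) {
    sel <- long$t == t
    obs <- R[, t] == 1
    for (p in seq_len(cfg$n_pred)) {
      val <- X[, wcol(paste0("x", p), t)]
      val[!obs] <- NA
      long[[covs[p]]][sel] <- val
    }
    if (t == Tn) {
      yv <- y
      yv[!obs] <- NA
      long$Y[sel] <- yv
    }
  }
  cohort_table(long, covariates = covs, outcome = "Y", outcome_waves = Tn)
}

#' Monte-Carlo truth for the benchmark estimand
#'
#' The benchmark estimand is the marginal mean of the final-wave outcome
#' under the natural course, which (with mean-zero noise) equals the
#' expectation of the weighted Friedman function over the predictor
#' law.  Evaluated by plain Monte Carlo over fresh predictor draws.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param N_mc Monte-Carlo size.
#' @param seed Optional seed.
#' @return The truth, with the Monte-Carlo standard error in attribute
#'   \code{"se"}.
#' @export
truth_oracle <- function(cfg, N_mc = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chunk <- 1e5
  tot <- 0
  tot2 <- 0
  done <- 0
  while (done < N_mc) {
    m <- min(chunk, N_mc - done)
    f <- friedman_mean(gen_predictors(m, cfg), cfg$c_weights)
    tot <- tot + sum(f)
    tot2 <- tot2 + sum(f^2)
    done <- done + m
  }
  mu <- tot / N_mc
  se <- sqrt((tot2 / N_mc - mu^2) / N_mc)
  structure(mu, se = se)
}

#' Oracle sequential models for the benchmark generator
#'
#' Wraps the generator's true conditionals (copula-conditional covariate
#' laws, logistic retention, Friedman outcome mean) in the
#' \code{sequential_models} interface so G-computation can be run with
#' the truth plugged in, isolating the Monte-Carlo standardization from
#' model fit.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param pool_n Size of the wave-1 baseline pool (fresh uniforms).
#' @return A \code{"sequential_models"} object with a single "draw".
#' @export
benchmark_oracle_models <- function(cfg, pool_n = 50000) {
  Tn <- cfg$T
  Sig <- copula_sigma(cfg)
  covs <- paste0("x", seq_len(cfg$n_pred))
  models <- list()
  for (k in 2:Tn) {
    h_k <- cfg$h[k - 1]
    past <- unlist(lapply(seq_len(k - 1), function(t) wcol(covs, t)))
    models[[paste0("response.", k)]] <- local({
      past <- past; h_k <- h_k
      oracle_model(prob = function(sim)
        stats::plogis(h_k * rowSums(as.matrix(sim[, past, drop = FALSE]))))
    })
    # conditional of the latent Gaussian given waves 1..k-1, same for all
    # five predictors
    Spp <- Sig[seq_len(k - 1), seq_len(k - 1), drop = FALSE]
    stp <- Sig[k, seq_len(k - 1)]
    wts <- solve(Spp, stp)
    csd <- sqrt(Sig[k, k] - sum(stp * wts))
    for (v in covs) {
      models[[paste0("covariate.", v, ".", k)]] <- local({
        v <- v; k <- k; wts <- wts; csd <- csd
        oracle_model(sample = function(sim, n) {
          zp <- qnorm(as.matrix(sim[, wcol(v, seq_len(k - 1)), drop = FALSE]))
          pnorm(as.numeric(zp %*% wts) + csd * rnorm(n))
        }, mean = function(sim) stop("oracle covariate has no mean slot"))
      })
    }
  }
  models[[paste0("outcome.", Tn)]] <- local({
    cw <- cfg$c_weights
    oracle_model(mean = function(sim) friedman_mean(as.matrix(sim), cw),
                 sd = cfg$sigma_T)
  })
  pool <- as.data.frame(matrix(runif(pool_n * cfg$n_pred), pool_n,
                               dimnames = list(NULL, wcol(covs, 1))))
  sc <- list(covariates = covs, baseline = character(), treatment = NULL,
             outcome = "Y", outcome_waves = Tn, T = Tn)
  structure(list(models = models, schema = sc, T = Tn, n_draws = 1L,
                 prior_mode = "oracle", soft = NA, baseline_pool = pool,
                 has_deaths = FALSE, has_dropout = TRUE),
            class = "sequential_models")
}

benchmark_model_map <- function(label) {
  switch(label,
         "LDART" = list(prior_mode = "ldart", soft = TRUE),
         "SBART" = list(prior_mode = "dart", soft = TRUE),
         "SBART-l1" = list(prior_mode = "lastwave", soft = TRUE),
         "HDART" = list(prior_mode = "dart", soft = FALSE),
         "HBART" = list(prior_mode = "uniform", soft = FALSE),
         stop("unknown benchmark model label: ", label))
}

#' Run the benchmark model comparison
#'
#' For each replicate: generate a dataset, fit each requested model's
#' sequential set, G-compute the natural-course mean of the final-wave
#' outcome, and record the posterior mean and equal-tailed 95\% credible
#' interval.  Metrics per model: relative absolute bias x 100 of the
#' mean estimate across replicates, root-mean-squared error, and the
#' coverage probability of the credible intervals.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param models Character vector among "LDART", "SBART", "SBART-l1",
#'   "HDART", "HBART".
#' @param reps Number of replicates (>= 2).
#' @param control \code{\link{mcmc_control}} for every fit.
#' @param nstar Pseudo-cohort size for G-computation.
#' @param n_trees Trees per model (default 50).
#' @param seed Base seed.
#' @param truth Generator truth; computed by \code{\link{truth_oracle}}
#'   when NULL.
#' @param truth_N Monte-Carlo size for the truth when computed here.
#' @return List with per-replicate \code{results}, the \code{metrics}
#'   table, and \code{truth}.
#' @export
run_benchmark <- function(cfg, models = c("LDART", "SBART", "SBART-l1",
                                          "HDART", "HBART"),
                          reps = 200, control = mcmc_control(),
                          nstar = 1000, n_trees = 50, seed = 1,
                          truth = NULL, truth_N = 2e5) {
  for (m in models) benchmark_model_map(m)  # validate labels up front
  stopifnot(reps >= 2)
  if (is.null(truth)) truth <- truth_oracle(cfg, truth_N, seed = seed + 990000L)
  g0 <- regime_spec("natural_course")
  rows <- list()
  for (r in seq_len(reps)) {
    cohort <- gen_benchmark_data(cfg, seed = seed + 7L * r)
    for (m in models) {
      mm <- benchmark_model_map(m)
      ctl <- control
      ctl$seed <- seed + 7L * r + 1L + match(m, models)
      fits <- fit_sequential(cohort, prior_mode = mm$prior_mode,
                             control = ctl, soft = mm$soft,
                             n_trees = n_trees)
      gc <- gcomp_estimates(fits, g0, nstar = nstar,
                            seed = seed + 13L * r)
      qs <- quantile(gc$survivor_mean, c(0.025, 0.975), names = FALSE,
                     na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, model = m,
                   estimate = mean(gc$survivor_mean, na.rm = TRUE),
                   lower = qs[1], upper = qs[2])
    }
  }
  results <- do.call(rbind, rows)
  metrics <- do.call(rbind, lapply(models, function(m) {
    e <- results[results$model == m, ]
    data.frame(model = m,
               bias = 100 * abs(mean(e$estimate) - truth) / abs(truth),
               rmse = sqrt(mean((e$estimate - truth)^2)),
               cp = 100 * mean(e$lower <= truth & truth <= e$upper))
  }))
  list(results = results, metrics = metrics, truth = truth)
}
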