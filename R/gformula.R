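#' @importFrom stats rexp qchisq
NULL

wcol <- function(var, k) paste0(var, ".", k)

# one row per subject; survival/response as matrices, everything else as
# wave-suffixed columns
wide_cohort <- function(cohort) {
  sc <- cohort_schema(cohort)
  Tn <- sc$T
  cohort <- cohort[order(cohort$id, cohort$t), , drop = FALSE]
  ids <- unique(cohort$id)
  n <- length(ids)
  S <- t(matrix(cohort$S, nrow = Tn))
  R <- t(matrix(cohort$R, nrow = Tn))
  first <- cohort$t == 1
  wide <- data.frame(row.names = seq_len(n))
  for (v in sc$baseline) wide[[v]] <- cohort[[v]][first]
  vars <- c(sc$covariates, sc$treatment, sc$outcome)
  for (v in vars) {
    m <- t(matrix(cohort[[v]], nrow = Tn))
    for (k in seq_len(Tn)) wide[[wcol(v, k)]] <- m[, k]
  }
  for (k in seq_len(Tn)) wide[[wcol("R", k)]] <- R[, k]
  list(wide = wide, S = S, R = R, ids = ids, n = n)
}

# predictor columns for a model whose target sits at wave k;
# through_x / through_a: latest wave of covariates / treatment included
hist_cols <- function(sc, through_x, through_a, through_y, through_r,
                      extra = character()) {
  cols <- character(0)
  wave <- numeric(0)
  add <- function(v, k) {
    cols <<- c(cols, wcol(v, k))
    wave <<- c(wave, k)
  }
  for (k in seq_len(max(through_x, 0)))
    for (v in sc$covariates) add(v, k)
  if (!is.null(sc$treatment))
    for (k in seq_len(max(through_a, 0))) add(sc$treatment, k)
  if (!is.null(sc$outcome))
    for (k in intersect(seq_len(max(through_y, 0)), sc$outcome_waves))
      add(sc$outcome, k)
  for (k in seq(2, length.out = max(through_r - 1, 0))) add("R", k)
  cols <- c(sc$baseline, cols, extra)
  wave <- c(rep(NA_real_, length(sc$baseline)), wave,
            rep(NA_real_, length(extra)))
  list(cols = cols, wave = wave)
}

model_prior <- function(prior_mode, hc, extra_wave = NULL) {
  wave <- hc$wave
  if (length(extra_wave))
    wave[seq(length(wave) - length(extra_wave) + 1, length(wave))] <- extra_wave
  t_model <- suppressWarnings(max(wave, na.rm = TRUE))
  if (!is.finite(t_model)) t_model <- 1
  switch(prior_mode,
         ldart = list(prior = split_prior("ldart", wave = wave, t = t_model),
                      keep = seq_along(hc$cols)),
         dart = list(prior = split_prior("dart"),
                     keep = seq_along(hc$cols)),
         uniform = list(prior = split_prior("uniform"),
                        keep = seq_along(hc$cols)),
         lastwave = list(prior = split_prior("dart"),
                         keep = which(is.na(wave) | wave == t_model)))
}

fit_one <- function(label, wide, rows, target, hc, type, prior_mode,
                    control, soft, n_trees, extra_wave = NULL, ...) {
  if (!any(rows))
    stop("empty risk set for model '", label, "'")
  mp <- model_prior(prior_mode, hc, extra_wave)
  cols <- hc$cols[mp$keep]
  X <- as.matrix(wide[rows, cols, drop = FALSE])
  y <- target[rows]
  fit <- sbart(X, y, type = type, prior = mp$prior, control = control,
               soft = soft, n_trees = n_trees, ...)
  list(fit = fit, label = label, cols = cols, type = type,
       n_rows = sum(rows))
}

#' Fit the sequential models of the G-formula
#'
#' One model per factor of the sequential factorization of the joint law
#' of (survival, response, confounders, treatment, outcome) given the
#' past: a probit survival model and a probit response model per
#' transition, a Gaussian model per covariate component and wave
#' (conditioning on earlier-in-schema components of the same wave), a
#' Gaussian treatment model (the natural-value-of-treatment model under
#' an intervention), and a Gaussian outcome model per measured wave.
#' Each model is fitted on its risk set: subjects alive (and, where the
#' factor requires it, responding) at the wave with fully observed
#' history.
#'
#' Survival models are only fitted when the cohort contains deaths, and
#' response models only when it contains non-response; otherwise those
#' transitions are deterministic.
#'
#' @param cohort A \code{\link{cohort_table}}.
#' @param prior_mode \code{"ldart"} (longitudinal grouped prior, each
#'   history variable assigned to its wave), \code{"dart"},
#'   \code{"uniform"}, or \code{"lastwave"} (only the most recent wave's
#'   predictors plus baseline, with the DART prior).
#' @param control An \code{\link{mcmc_control}} shared by all models; if
#'   it carries a seed, model i uses \code{seed + i}.
#' @param soft Soft (probabilistic) or hard trees.
#' @param n_trees Trees per model.
#' @param ... Passed to \code{\link{sbart}}.
#' @return An object of class \code{"sequential_models"}.
#' @export
fit_sequential <- function(cohort,
                           prior_mode = c("ldart", "dart", "uniform",
                                          "lastwave"),
                           control = mcmc_control(), soft = TRUE,
                           n_trees = 50, ...) {
  prior_mode <- match.arg(prior_mode)
  sc <- cohort_schema(cohort)
  Tn <- sc$T
  wc <- wide_cohort(cohort)
  wide <- wc$wide
  S <- wc$S
  R <- wc$R
  has_deaths <- any(S == 0)
  has_dropout <- any(R == 0 & S == 1)
  # complete observed history through wave j (alive and responding)
  histok <- matrix(TRUE, wc$n, Tn)
  for (j in seq_len(Tn))
    histok[, j] <- (if (j > 1) histok[, j - 1] else TRUE) &
      S[, j] == 1 & R[, j] == 1
  hist0 <- function(j) if (j >= 1) histok[, j] else rep(TRUE, wc$n)

  models <- list()
  im <- 0L
  ctl <- function() {
    im <<- im + 1L
    if (is.null(control$seed)) return(control)
    out <- control
    out$seed <- control$seed + im
    out
  }

  for (k in seq_len(Tn)) {
    if (k >= 2 && has_deaths) {
      hc <- hist_cols(sc, k - 1, k - 1, k - 1, k - 1)
      rows <- S[, k - 1] == 1 & hist0(k - 1)
      models[[paste0("survival.", k)]] <-
        fit_one(paste0("survival.", k), wide, rows, S[, k], hc, "probit",
                prior_mode, ctl(), soft, n_trees, ...)
    }
    if (k >= 2 && has_dropout) {
      hc <- hist_cols(sc, k - 1, k - 1, k - 1, k - 1)
      rows <- S[, k] == 1 & hist0(k - 1)
      models[[paste0("response.", k)]] <-
        fit_one(paste0("response.", k), wide, rows, R[, k], hc, "probit",
                prior_mode, ctl(), soft, n_trees, ...)
    }
    if (k >= 2) {
      prev <- character(0)
      for (v in sc$covariates) {
        hc <- hist_cols(sc, k - 1, k - 1, k - 1, k,
                        extra = if (length(prev)) wcol(prev, k) else character())
        rows <- S[, k] == 1 & R[, k] == 1 & hist0(k - 1)
        models[[paste0("covariate.", v, ".", k)]] <-
          fit_one(paste0("covariate.", v, ".", k), wide, rows,
                  wide[[wcol(v, k)]], hc, "gaussian", prior_mode, ctl(),
                  soft, n_trees,
                  extra_wave = rep(k, length(prev)), ...)
        prev <- c(prev, v)
      }
    }
    if (!is.null(sc$treatment)) {
      hc <- hist_cols(sc, k, k - 1, k - 1, k)
      rows <- S[, k] == 1 & R[, k] == 1 & hist0(k - 1)
      models[[paste0("treatment.", k)]] <-
        fit_one(paste0("treatment.", k), wide, rows,
                wide[[wcol(sc$treatment, k)]], hc, "gaussian", prior_mode,
                ctl(), soft, n_trees, ...)
    }
    if (!is.null(sc$outcome) && k %in% sc$outcome_waves) {
      hc <- hist_cols(sc, k, k, k - 1, k)
      rows <- S[, k] == 1 & R[, k] == 1 & hist0(k - 1)
      models[[paste0("outcome.", k)]] <-
        fit_one(paste0("outcome.", k), wide, rows,
                wide[[wcol(sc$outcome, k)]], hc, "gaussian", prior_mode,
                ctl(), soft, n_trees, ...)
    }
  }

  pool_rows <- S[, 1] == 1 & R[, 1] == 1
  pool_cols <- c(sc$baseline, wcol(sc$covariates, 1))
  baseline_pool <- wide[pool_rows, pool_cols, drop = FALSE]

  structure(list(models = models, schema = sc, T = Tn,
                 n_draws = control$n_save * control$n_chains,
                 prior_mode = prior_mode, soft = soft,
                 baseline_pool = baseline_pool,
                 has_deaths = has_deaths, has_dropout = has_dropout),
            class = "sequential_models")
}

#' @export
print.sequential_models <- function(x, ...) {
  cat(sprintf("sequential_models: %d models over %d waves (%s, %s trees)\n",
              length(x$models), x$T, x$prior_mode,
              if (x$soft) "soft" else "hard"))
  cat(" ", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

# ---- per-model prediction dispatch --------------------------------------

model_mean <- function(m, sim, draw) {
  f <- m$fit
  if (inherits(f, "oracle_model")) return(f$mean(sim))
  if (isTRUE(f$constant)) return(rep(f$value, nrow(sim)))
  as.numeric(predict(f, sim, draws = draw, type = "draws"))
}

model_sigma <- function(m, draw) {
  f <- m$fit
  if (inherits(f, "oracle_model")) return(f$sd)
  if (isTRUE(f$constant)) return(0)
  f$sigma[draw]
}

model_prob <- function(m, sim, draw) {
  f <- m$fit
  if (inherits(f, "oracle_model")) return(f$prob(sim))
  if (isTRUE(f$constant)) return(rep(f$value, nrow(sim)))
  as.numeric(predict(f, sim, draws = draw, type = "draws"))
}

model_sample <- function(m, sim, draw) {
  f <- m$fit
  n <- nrow(sim)
  if (inherits(f, "oracle_model")) return(f$sample(sim, n))
  model_mean(m, sim, draw) + model_sigma(m, draw) * rnorm(n)
}

#' An oracle stand-in for a fitted sequential model
#'
#' Wraps known generator conditionals so that G-computation can be run
#' with the true distributions plugged in, isolating the Monte-Carlo
#' standardization from model fit.
#'
#' @param mean Function(sim) giving the conditional mean (Gaussian
#'   factors).
#' @param sd Conditional SD, or 0.
#' @param prob Function(sim) giving the event probability (probit
#'   factors).
#' @param sample Function(sim, n) drawing from the conditional; defaults
#'   to \code{mean + sd * rnorm(n)}.
#' @return A model-slot list usable inside a \code{sequential_models}.
#' @export
oracle_model <- function(mean = NULL, sd = 0, prob = NULL, sample = NULL) {
  if (is.null(sample) && !is.null(mean)) {
    force(mean); force(sd)
    sample <- function(sim, n) mean(sim) + sd * rnorm(n)
  }
  f <- structure(list(mean = mean, sd = sd, prob = prob, sample = sample),
                 class = "oracle_model")
  list(fit = f, type = if (is.null(prob)) "gaussian" else "probit")
}

#' Incremental threshold intervention rule
#'
#' Returns the intervened treatment value: the natural value a* is left
#' alone when it does not exceed the threshold, and shifted downward by
#' |delta| (delta <= 0 is added) when it does.
#'
#' @param a_star Natural value of treatment.
#' @param tau Threshold.
#' @param delta Shift, delta <= 0 (drawn from the regime's shift prior).
#' @return Intervened treatment values.
#' @export
apply_intervention <- function(a_star, tau, delta) {
  stopifnot(all(delta <= 0))
  ifelse(a_star > tau, a_star + delta, a_star)
}

#' Simulate pseudo-trajectories under a regime
#'
#' Monte-Carlo forward simulation of the sequential factorization for one
#' posterior draw: baseline covariates are resampled from the observed
#' baseline rows; each wave draws survival and response indicators,
#' covariate components in schema order, the natural value of treatment,
#' the intervened treatment (under an incremental threshold regime), and
#' the outcome.  Deaths are monotone; substantive variables are generated
#' for all pseudo-subjects alive at the wave regardless of the simulated
#' response indicator, whose history enters downstream models as a
#' predictor where it varied in the fit.
#'
#' The per-wave random draws have a fixed count, so two regimes simulated
#' with the same \code{seed} consume identical random-number streams; a
#' null intervention (\code{tau = Inf} or a point-mass shift prior at 0)
#' then reproduces the natural course exactly.
#'
#' @param models A \code{"sequential_models"}.
#' @param regime A \code{\link{regime_spec}}.
#' @param nstar Number of pseudo-subjects N*.
#' @param draw Posterior draw index used for every model.
#' @param seed Seed for the trajectory stream.
#' @param deltas Per-wave shifts (length T, all <= 0); if \code{NULL}
#'   under a threshold regime they are drawn from the shift prior using a
#'   seed offset from \code{seed}, keeping the trajectory stream aligned
#'   with the natural course.
#' @return A list of class \code{"pseudo_cohort"} with matrices (nstar x
#'   T) \code{S}, \code{R}, \code{psurv}, \code{A}, \code{Astar},
#'   \code{Y}, \code{Ymean}, per-covariate matrices in \code{X}, and the
#'   per-subject cumulative survival probability \code{w}.
#' @export
simulate_regime <- function(models, regime, nstar, draw, seed = NULL,
                            deltas = NULL) {
  stopifnot(inherits(models, "sequential_models"), nstar >= 1)
  sc <- models$schema
  Tn <- models$T
  threshold <- regime$kind == "incremental_threshold"
  if (threshold && is.null(deltas)) {
    if (!is.null(seed)) set.seed(seed + 499979L)
    deltas <- rtriangular(Tn, regime$shift_prior)
  }
  if (!is.null(seed)) set.seed(seed)

  pool <- models$baseline_pool
  sim <- pool[sample.int(nrow(pool), nstar, replace = TRUE), , drop = FALSE]
  rownames(sim) <- NULL

  S <- matrix(1, nstar, Tn)
  R <- matrix(1, nstar, Tn)
  psurv <- matrix(1, nstar, Tn)
  A <- Astar <- Y <- Ymean <- matrix(NA_real_, nstar, Tn)
  M <- models$models

  for (k in seq_len(Tn)) {
    if (k >= 2) {
      ms <- M[[paste0("survival.", k)]]
      if (!is.null(ms)) {
        p <- model_prob(ms, sim, draw)
        u <- runif(nstar)
        S[, k] <- S[, k - 1] * (u < p)
        psurv[, k] <- p
      } else S[, k] <- S[, k - 1]
      mr <- M[[paste0("response.", k)]]
      if (!is.null(mr)) {
        p <- model_prob(mr, sim, draw)
        u <- runif(nstar)
        R[, k] <- R[, k - 1] * (u < p)
      } else R[, k] <- R[, k - 1]
      sim[[wcol("R", k)]] <- R[, k]
      for (v in sc$covariates)
        sim[[wcol(v, k)]] <- model_sample(M[[paste0("covariate.", v, ".", k)]],
                                          sim, draw)
    } else {
      sim[[wcol("R", 1)]] <- R[, 1]
    }
    if (!is.null(sc$treatment)) {
      mt <- M[[paste0("treatment.", k)]]
      astar <- model_sample(mt, sim, draw)
      Astar[, k] <- astar
      A[, k] <- if (threshold)
        apply_intervention(astar, regime$tau, deltas[k]) else astar
      sim[[wcol(sc$treatment, k)]] <- A[, k]
    }
    if (!is.null(sc$outcome) && k %in% sc$outcome_waves) {
      mo <- M[[paste0("outcome.", k)]]
      mu <- model_mean(mo, sim, draw)
      eps <- rnorm(nstar)
      Ymean[, k] <- mu
      Y[, k] <- mu + model_sigma(mo, draw) * eps
      sim[[wcol(sc$outcome, k)]] <- Y[, k]
    }
  }
  X <- lapply(sc$covariates, function(v)
    as.matrix(sim[, wcol(v, seq_len(Tn)), drop = FALSE]))
  names(X) <- sc$covariates
  w <- apply(psurv, 1, prod)
  structure(list(S = S, R = R, psurv = psurv, w = w, A = A, Astar = Astar,
                 Y = Y, Ymean = Ymean, X = X, nstar = nstar, T = Tn,
                 regime = regime, deltas = deltas),
            class = "pseudo_cohort")
}

#' G-computation estimates over posterior draws
#'
#' For each posterior draw, simulates a pseudo-cohort under the regime
#' and computes the survivor mean E[Y_T | S_T = 1] and the marginal
#' survival probability psi at the final wave.  The survivor mean is the
#' cumulative-survival-probability-weighted average of the per-subject
#' conditional outcome means; psi is the average cumulative survival
#' probability (both Monte-Carlo standardizations over the simulated
#' histories, which are generated conditional on survival at every step).
#'
#' @param models A \code{"sequential_models"}.
#' @param regime A \code{\link{regime_spec}}.
#' @param nstar Pseudo-cohort size per draw.
#' @param draws Posterior draw indices (default: all stored draws).
#' @param seed Base seed; the i-th requested draw uses trajectory seed
#'   \code{seed + i}, so two regimes evaluated with the same \code{seed}
#'   and draw vector share trajectory randomness draw by draw (and
#'   repeated draw indices still get fresh trajectories).
#' @return A data frame of class \code{"gcomp_draws"} with columns
#'   \code{draw}, \code{survivor_mean}, \code{psi}, \code{n_surv}.
#' @export
gcomp_estimates <- function(models, regime, nstar = 10000, draws = NULL,
                            seed = 1) {
  if (is.null(draws)) draws <- seq_len(models$n_draws)
  out <- data.frame(draw = draws, survivor_mean = NA_real_, psi = NA_real_,
                    n_surv = NA_integer_)
  n_excluded <- 0L
  for (i in seq_along(draws)) {
    d <- draws[i]
    pc <- simulate_regime(models, regime, nstar, d, seed = seed + i)
    Tn <- pc$T
    ylast <- pc$Ymean[, Tn]
    sw <- sum(pc$w)
    if (sw <= 0 || all(pc$S[, Tn] == 0)) {
      n_excluded <- n_excluded + 1L
    } else {
      out$survivor_mean[i] <- sum(pc$w * ylast) / sw
    }
    out$psi[i] <- mean(pc$w)
    out$n_surv[i] <- sum(pc$S[, Tn] == 1)
  }
  if (n_excluded > 0L)
    warning(n_excluded, " draw(s) had no surviving pseudo-subjects; ",
            "survivor_mean set to NA")
  attr(out, "regime") <- regime
  attr(out, "nstar") <- nstar
  class(out) <- c("gcomp_draws", "data.frame")
  out
}
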