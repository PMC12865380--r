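# short MCMC settings for unit tests; deeper runs live in the
# acceptance suite
quick_ctl <- function(n_warmup = 150, n_save = 150, thin = 1, seed = 1)
  mcmc_control(n_warmup, n_save, thin, seed = seed)

# a tiny hand-built long-format data frame: s_mat / r_mat are
# subjects x waves; values filled deterministically where observed
toy_long <- function(s_mat, r_mat) {
  n <- nrow(s_mat); Tn <- ncol(s_mat)
  df <- data.frame(id = rep(seq_len(n), each = Tn),
                   t = rep(seq_len(Tn), n),
                   S = as.integer(t(s_mat)), R = as.integer(t(r_mat)))
  df$x1 <- ifelse(df$R == 1, df$id + 0.1 * df$t, NA)
  df$A <- ifelse(df$R == 1, 120 + df$id + df$t, NA)
  df$Y <- ifelse(df$R == 1, 50 - df$id - df$t, NA)
  df
}

# single-wave Friedman test function
friedman1 <- function(X)
  10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 +
  10 * X[, 4] + 5 * X[, 5]

# standard fixture regime used across tests
test_regime <- function(tau = 130)
  regime_spec("incremental_threshold", tau = tau,
              shift_prior = triangular(-44, -44, 0))
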