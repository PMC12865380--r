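#' MCMC settings
#'
#' @param n_warmup Burn-in iterations discarded before saving.
#' @param n_save Saved posterior draws (after thinning), per chain.
#' @param thin Thinning interval.
#' @param n_chains Independent chains; chain \code{i} is seeded with
#'   \code{seed + i - 1} and draws are pooled after warm-up.
#' @param seed Optional integer seed.
#' @return A list of class \code{"mcmc_control"}.
#' @export
mcmc_control <- function(n_warmup = 1200, n_save = 2000, thin = 4,
                         n_chains = 1, seed = NULL) {
  stopifnot(n_warmup >= 0, n_save >= 1, thin >= 1, n_chains >= 1)
  structure(list(n_warmup = as.integer(n_warmup), n_save = as.integer(n_save),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = seed),
            class = "mcmc_control")
}

#' Split-selection priors for the tree sampler
#'
#' The probability vector q over predictors used when proposing a split
#' variable.  \code{"uniform"} fixes q at 1/P.  \code{"dart"} places a
#' Dirichlet(\eqn{\alpha/P}) prior on q with
#' \eqn{\alpha/(\alpha+\rho) \sim Beta(a, b)} (defaults a = 0.5, b = 1,
#' \eqn{\rho = P}).  \code{"ldart"} is the longitudinal grouped prior: a
#' Beta-distributed weight w splits mass between predictors measured at
#' the current wave (plus baseline predictors) and predictors from past
#' waves; within groups Dirichlet priors apply, and the concentration
#' \eqn{\alpha_j} for past wave j follows the increasing hyperprior
#' schedule \code{\link{c_schedule}}, so that temporally distant
#' predictors face more sparsity.
#'
#' @param type One of \code{"uniform"}, \code{"dart"}, \code{"ldart"}.
#' @param wave For \code{"ldart"}: integer wave of measurement for each
#'   predictor column (\code{NA} for baseline predictors, which join the
#'   current group).
#' @param t Current wave; defaults to \code{max(wave)}.
#' @param a,b Beta hyperprior shape for the DART concentration.
#' @param rho DART scale, defaults to P at fit time.
#' @param a_w,b_w Beta prior on the current-vs-past weight w (default
#'   uniform).
#' @return A list of class \code{"split_prior"}.
#' @export
split_prior <- function(type = c("uniform", "dart", "ldart"), wave = NULL,
                        t = NULL, a = 0.5, b = 1, rho = NULL,
                        a_w = 1, b_w = 1) {
  type <- match.arg(type)
  if (type == "ldart") {
    if (is.null(wave)) stop("ldart needs a wave index per predictor")
    if (is.null(t)) t <- max(wave, na.rm = TRUE)
  }
  structure(list(type = type, wave = wave, t = t, a = a, b = b, rho = rho,
                 a_w = a_w, b_w = b_w),
            class = "split_prior")
}

#' Hyperprior schedule for the longitudinal grouped prior
#'
#' For a model whose most recent predictors are measured at wave t, the
#' concentration of the group of predictors measured at past wave j
#' (j = 1, ..., t-1) gets a Beta(c_j, 1) hyperprior on
#' \eqn{\alpha_j/(\alpha_j + \rho_j)} with
#' \deqn{c_j = 1 - 0.5 (t - j) / (t - 1),}
#' an increasing schedule with c_1 = 0.5: earlier waves face more
#' sparsity.
#'
#' @param t Current wave count (t >= 2 for a non-empty schedule).
#' @return Numeric vector c_1, ..., c_{t-1} (empty for t < 2).
#' @examples
#' c_schedule(4)  # 0.5, 2/3, 5/6
#' @export
c_schedule <- function(t) {
  if (t < 2) return(numeric(0))
  j <- seq_len(t - 1)
  1 - 0.5 * (t - j) / (t - 1)
}

# build the C++ prior spec from a split_prior and the kept columns
build_prior_spec <- function(prior, P, keep_idx = seq_len(P)) {
  if (prior$type == "uniform")
    return(list(type = "uniform"))
  if (prior$type == "dart") {
    rho <- if (is.null(prior$rho)) P else prior$rho
    return(list(type = "dart", a = prior$a, b = prior$b, rho = rho))
  }
  wave <- prior$wave[keep_idx]
  t <- prior$t
  # current group: wave t and baseline (NA); past groups: earlier waves
  # with at least one predictor, compacted but keeping their wave's c_j
  grp <- integer(length(wave))
  past_waves <- sort(unique(wave[!is.na(wave) & wave < t]))
  cs <- c_schedule(t)
  c_alpha <- numeric(0)
  g <- 0L
  for (k in past_waves) {
    g <- g + 1L
    grp[!is.na(wave) & wave == k] <- g
    c_alpha <- c(c_alpha, cs[k])
  }
  list(type = "ldart", group = grp, n_past = length(past_waves),
       a_w = prior$a_w, b_w = prior$b_w, c_alpha = c_alpha,
       rho_alpha = as.numeric(t))
}

#' Split-selection probabilities implied by a longitudinal prior state
#'
#' Composes the per-predictor selection probabilities from the hierarchy:
#' q_j = w v^t_j for current predictors and q_j = (1 - w) u_k v^k_j for a
#' predictor in past group k.
#'
#' @param w Current-vs-past probability.
#' @param v_t Probability vector over the current group.
#' @param u Probability vector over past groups.
#' @param v_k List of probability vectors, one per past group.
#' @param grouping List with elements \code{current} (indices of current
#'   predictors) and \code{past} (list of index vectors per past group);
#'   the groups must partition 1..P.
#' @return Numeric vector q of length P summing to 1.
#' @export
selection_prob <- function(w, v_t, u, v_k, grouping) {
  idx <- c(grouping$current, unlist(grouping$past))
  P <- length(idx)
  if (!setequal(idx, seq_len(P)) || length(idx) != P)
    stop("grouping must partition predictors 1..P")
  if (length(v_t) != length(grouping$current))
    stop("v_t size does not match the current group")
  if (length(u) != length(grouping$past) ||
      length(v_k) != length(grouping$past))
    stop("u / v_k size does not match the past groups")
  q <- numeric(P)
  if (length(grouping$past) == 0L) w <- 1
  q[grouping$current] <- w * v_t
  for (k in seq_along(grouping$past)) {
    if (length(v_k[[k]]) != length(grouping$past[[k]]))
      stop("v_k[[", k, "]] size does not match its group")
    q[grouping$past[[k]]] <- (1 - w) * u[k] * v_k[[k]]
  }
  q
}

#' Posterior update of a split-selection prior given split counts
#'
#' Runs Gibbs/Metropolis sweeps of the prior hierarchy holding the
#' per-predictor split counts fixed, exactly as inside the sampler:
#' Dirichlet/Beta full conditionals for the simplexes and w, and
#' random-walk Metropolis on the transformed concentrations.
#'
#' @param counts Nonnegative per-predictor split counts.
#' @param prior A \code{\link{split_prior}}.
#' @param n_sweeps Number of sweeps; draws for every sweep are returned.
#' @return List with per-sweep draws (\code{q}, and for LDART also
#'   \code{w}, \code{u}, \code{alpha_g}; for DART \code{alpha}).
#' @export
update_split_prior <- function(counts, prior, n_sweeps = 1) {
  if (any(counts < 0)) stop("negative split counts")
  spec <- build_prior_spec(prior, length(counts))
  out <- split_prior_update_cpp(as.numeric(counts), spec,
                                as.integer(n_sweeps))
  out$w <- as.numeric(out$w)
  out$alpha <- as.numeric(out$alpha)
  out
}

scaled_inv_chisq_lambda <- function(sigma_hat, nu, sigquant) {
  # lambda such that P(sigma < sigma_hat) = sigquant under nu*lambda/chisq_nu
  sigma_hat^2 * stats::qchisq(1 - sigquant, nu) / nu
}

#' Fit a soft (or hard) BART model
#'
#' Sum-of-trees regression \eqn{\mu(d) = \mu_0 + \sum_b g(d; T_b, M_b)}
#' with probabilistic ("soft") decision paths: an observation is routed
#' left at a split on predictor j at cut c with probability
#' \eqn{\psi((c - d_j)/b)} where \eqn{\psi} is the logistic function and
#' b > 0 a bandwidth; \code{soft = FALSE} uses hard indicator splits.
#' Continuous outcomes use a Gaussian likelihood; binary outcomes a
#' probit link via latent-variable augmentation.
#'
#' @param X Numeric predictor matrix (columns named).  Constant columns
#'   are dropped.
#' @param y Numeric response; for \code{type = "probit"} coded 0/1.
#' @param type \code{"gaussian"} or \code{"probit"}.
#' @param prior A \code{\link{split_prior}}.
#' @param control An \code{\link{mcmc_control}}.
#' @param soft Probabilistic gating (\code{TRUE}) or hard splits.
#' @param n_trees Number of trees B (default 50).
#' @param k Leaf-prior regularization: leaf sd is 0.5/(k sqrt(B)) on the
#'   scaled outcome (3/(k sqrt(B)) for probit).
#' @param base,power Depth prior: split probability at depth d is
#'   \code{base * (1 + d)^(-power)}.
#' @param band_mean Prior mean of the per-tree bandwidth, as a fraction
#'   of each predictor's range.
#' @param nu,sigquant Residual-scale prior: scaled inverse chi-squared
#'   with \code{nu} degrees of freedom anchored so that the prior puts
#'   probability \code{sigquant} below the sample SD.
#' @param scale Internally rescale a Gaussian outcome to [-0.5, 0.5]
#'   (the usual BART convention).  \code{FALSE} fits on the raw scale,
#'   which keeps the prior free of the data (used by calibration
#'   checks).
#' @param lambda Optional explicit scale for the residual prior,
#'   overriding the \code{sigquant} anchor.
#' @return An object of class \code{"sbart_fit"}.
#' @export
sbart <- function(X, y, type = c("gaussian", "probit"),
                  prior = split_prior("dart"), control = mcmc_control(),
                  soft = TRUE, n_trees = 50, k = 2, base = 0.95, power = 2,
                  band_mean = 0.1, nu = 3, sigquant = 0.9, scale = TRUE,
                  lambda = NULL) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed in X or y")

  keep <- which(apply(X, 2, function(v) diff(range(v)) > 0))
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  Xk <- X[, keep, drop = FALSE]
  P <- ncol(Xk)

  if (type == "probit" && !all(y %in% c(0, 1)))
    stop("probit outcome must be coded 0/1")

  # degenerate targets: constant forest
  if ((type == "gaussian" && var(y) == 0) ||
      (type == "probit" && length(unique(y)) == 1L) || P == 0L) {
    warning("degenerate fit: constant target or no varying predictors")
    val <- if (type == "gaussian") mean(y) else {
      # shrink a single-class probability toward the prior (Jeffreys)
      (sum(y) + 0.5) / (length(y) + 1)
    }
    return(structure(list(constant = TRUE, value = val, type = type,
                          vars = colnames(Xk), n_draws = control$n_save,
                          sigma = rep(0, control$n_save)),
                     class = "sbart_fit"))
  }

  if (type == "gaussian") {
    if (scale) {
      ymin <- min(y); ymax <- max(y)
      ys <- (y - ymin) / (ymax - ymin) - 0.5
    } else {
      ymin <- -0.5; ymax <- 0.5  # identity unscaling
      ys <- y
    }
    mu0 <- 0
    sigma_mu <- 0.5 / (k * sqrt(n_trees))
    if (is.null(lambda))
      lambda <- scaled_inv_chisq_lambda(sd(ys), nu, sigquant)
  } else {
    ys <- y
    ymin <- 0; ymax <- 1
    mu0 <- qnorm(mean(y))
    sigma_mu <- 3 / (k * sqrt(n_trees))
    if (is.null(lambda)) lambda <- 1
  }

  spec <- build_prior_spec(prior, P, keep)

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    if (!is.null(control$seed)) set.seed(control$seed + ch - 1L)
    chains[[ch]] <- sbart_mcmc(Xk, ys, as.integer(type == "probit"), spec,
                               as.integer(n_trees), control$n_warmup,
                               control$n_save, control$thin,
                               base, power, sigma_mu, band_mean, nu, lambda,
                               as.integer(soft), mu0)
  }
  res <- chains[[1L]]
  if (control$n_chains > 1L) {
    dumps <- lapply(chains, function(cc) forest_dump_cpp(cc$ptr))
    merged <- dumps[[1L]]
    for (i in 2L:length(dumps))
      merged$draws <- c(merged$draws, dumps[[i]]$draws)
    res$ptr <- forest_load_cpp(merged)
    res$sigma <- do.call(c, lapply(chains, `[[`, "sigma"))
    res$q <- do.call(rbind, lapply(chains, `[[`, "q"))
    res$counts <- do.call(rbind, lapply(chains, `[[`, "counts"))
    res$w <- do.call(c, lapply(chains, `[[`, "w"))
    res$alpha <- do.call(rbind, lapply(chains, `[[`, "alpha"))
  }

  yscale <- ymax - ymin
  structure(list(constant = FALSE, ptr = res$ptr,
                 n_draws = control$n_save * control$n_chains,
                 sigma = as.numeric(res$sigma) *
                   (if (type == "gaussian") yscale else 1),
                 q = res$q, counts = res$counts, w = as.numeric(res$w),
                 alpha = res$alpha, type = type, soft = soft,
                 n_trees = n_trees, vars = colnames(Xk), dropped = dropped,
                 ymin = ymin, ymax = ymax, mu0 = mu0,
                 grow_rate = res$grow_rate, band_rate = res$band_rate,
                 prior = prior),
            class = "sbart_fit")
}

#' @export
print.sbart_fit <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat(sprintf("sbart_fit (degenerate constant %s fit, value %.4g)\n",
                x$type, x$value))
    return(invisible(x))
  }
  cat(sprintf("sbart_fit: %s %s BART, %d trees, %d predictors, %d draws\n",
              if (x$soft) "soft" else "hard", x$type, x$n_trees,
              length(x$vars), x$n_draws))
  invisible(x)
}

unscale <- function(fit, v) (v + 0.5) * (fit$ymax - fit$ymin) + fit$ymin

#' Predict from a fitted BART model
#'
#' @param object An \code{"sbart_fit"}.
#' @param newdata Matrix or data frame containing the fit's predictor
#'   columns.
#' @param draws Posterior draw indices; \code{NULL} uses all draws.
#' @param type \code{"mean"} (posterior mean), \code{"draws"} (matrix of
#'   per-draw predictions).  For probit fits, predictions are event
#'   probabilities unless \code{latent = TRUE}.
#' @param latent Return the latent (probit) scale?
#' @param ... Unused.
#' @export
predict.sbart_fit <- function(object, newdata, draws = NULL,
                              type = c("mean", "draws"), latent = FALSE, ...) {
  type <- match.arg(type)
  if (isTRUE(object$constant)) {
    n <- nrow(as.matrix(newdata))
    v <- rep(object$value, n)
    if (type == "mean") return(v)
    nd <- if (is.null(draws)) object$n_draws else length(draws)
    return(matrix(v, n, nd))
  }
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$vars, colnames(newdata))
  if (length(miss))
    stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "))
  Xn <- newdata[, object$vars, drop = FALSE]
  storage.mode(Xn) <- "double"
  if (is.null(draws)) draws <- seq_len(object$n_draws)
  M <- forest_predict_draws_cpp(object$ptr, Xn, as.integer(draws))
  if (object$type == "gaussian") {
    M <- unscale(object, M)
  } else if (!latent) {
    M <- pnorm(M)
  }
  if (type == "mean") rowMeans(M) else M
}

#' Per-predictor split counts of a fitted forest
#'
#' Number of internal nodes splitting on each predictor, per posterior
#' draw (rows) or averaged.
#'
#' @param fit An \code{"sbart_fit"}.
#' @param average Return the per-predictor posterior mean counts?
#' @return Matrix (draws x predictors) or named numeric vector.
#' @export
split_counts <- function(fit, average = FALSE) {
  if (isTRUE(fit$constant)) {
    out <- matrix(0, fit$n_draws, length(fit$vars),
                  dimnames = list(NULL, fit$vars))
  } else {
    out <- fit$counts
    colnames(out) <- fit$vars
  }
  if (average) colMeans(out) else out
}

#' Leaf weights of a single soft tree
#'
#' Soft gating assigns every observation a weight for every leaf: the
#' product over the root-to-leaf path of the logistic routing
#' probabilities.  Weights are nonnegative and sum to one across leaves;
#' a zero bandwidth recovers the hard indicator partition.
#'
#' @param nodes Tree node matrix with columns \code{var} (1-based, 0 for
#'   a leaf), \code{cut}, \code{band} (absolute bandwidth, 0 = hard),
#'   \code{left}, \code{right} (1-based row indices, 0 = none),
#'   \code{leaf}.
#' @param X Predictor matrix.
#' @return Matrix of weights (rows = observations, columns = leaves in
#'   node-matrix order).
#' @export
leaf_weights <- function(nodes, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  tree_leaf_weights_cpp(as.matrix(nodes), X)
}

#' Serialize / restore the posterior forests of a fit
#'
#' \code{forest_dump} returns a plain-list representation (per draw, per
#' tree, a node matrix) suitable for JSON export; \code{sbart_restore}
#' rebuilds a predictable \code{"sbart_fit"} from it.
#'
#' @param fit An \code{"sbart_fit"}.
#' @return \code{forest_dump}: a list with the forests and the scaling
#'   metadata.  \code{sbart_restore}: an \code{"sbart_fit"} usable with
#'   \code{predict}.
#' @export
forest_dump <- function(fit) {
  stopifnot(inherits(fit, "sbart_fit"), !isTRUE(fit$constant))
  d <- forest_dump_cpp(fit$ptr)
  list(forest = d, vars = fit$vars, type = fit$type, ymin = fit$ymin,
       ymax = fit$ymax, mu0 = fit$mu0, n_draws = fit$n_draws,
       soft = fit$soft, n_trees = fit$n_trees, sigma = fit$sigma)
}

#' @rdname forest_dump
#' @param dump A list produced by \code{forest_dump} (possibly after a
#'   JSON round trip).
#' @export
sbart_restore <- function(dump) {
  fd <- dump$forest
  fd$P <- as.integer(fd$P)
  fd$draws <- lapply(fd$draws, function(d) {
    d$trees <- lapply(d$trees, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      m
    })
    d
  })
  ptr <- forest_load_cpp(fd)
  structure(list(constant = FALSE, ptr = ptr, n_draws = dump$n_draws,
                 sigma = dump$sigma, type = dump$type, soft = dump$soft,
                 n_trees = dump$n_trees, vars = dump$vars,
                 ymin = dump$ymin, ymax = dump$ymax, mu0 = dump$mu0),
            class = "sbart_fit")
}

#' Draw a forest from the tree prior
#'
#' Grows each tree by the depth prior (split probability
#' \code{base*(1+d)^(-power)}), draws split variables uniformly, cut
#' points uniformly on the predictor ranges, bandwidths from the
#' exponential bandwidth prior, and leaf values from N(0, sigma_mu^2).
#' Used for prior-predictive and calibration checks.
#'
#' @param xmin,xmax Per-predictor ranges.
#' @param n_trees Number of trees.
#' @param sigma_mu Leaf prior SD.
#' @param base,power Depth prior parameters.
#' @param band_mean Bandwidth prior mean (fraction of range); 0 gives
#'   hard trees.
#' @param mu0 Global intercept.
#' @return A dump-format list accepted by \code{\link{sbart_restore}}
#'   (with \code{ymin = -0.5}, \code{ymax = 0.5}, i.e. predictions on the
#'   working scale).
#' @export
sbart_prior_draw <- function(xmin, xmax, n_trees = 50, sigma_mu = NULL,
                             base = 0.95, power = 2, band_mean = 0.1,
                             mu0 = 0) {
  P <- length(xmin)
  if (is.null(sigma_mu)) sigma_mu <- 0.5 / (2 * sqrt(n_trees))
  offset_children <- function(m, k) {
    int <- m[, 1] > 0
    m[int, 4] <- m[int, 4] + k
    m[int, 5] <- m[int, 5] + k
    m
  }
  tree_b <- NA_real_  # one bandwidth per tree, as in the sampler
  grow <- function(depth) {
    if (depth < 10 && runif(1) < base * (1 + depth)^(-power)) {
      j <- sample.int(P, 1)
      bw <- if (band_mean > 0) tree_b * (xmax[j] - xmin[j]) else 0
      left <- grow(depth + 1)
      right <- grow(depth + 1)
      nl <- nrow(left)
      node <- matrix(c(j, runif(1, xmin[j], xmax[j]), bw, 2, 2 + nl, 0), 1, 6)
      rbind(node, offset_children(left, 1), offset_children(right, 1 + nl))
    } else {
      matrix(c(0, 0, 0, 0, 0, rnorm(1, 0, sigma_mu)), 1, 6)
    }
  }
  trees <- lapply(seq_len(n_trees), function(b) {
    tree_b <<- stats::rexp(1, 1 / max(band_mean, 1e-12))
    m <- grow(0)
    colnames(m) <- c("var", "cut", "band", "left", "right", "leaf")
    rownames(m) <- NULL
    m
  })
  list(forest = list(P = P, draws = list(list(mu0 = mu0, trees = trees))),
       vars = paste0("V", seq_len(P)), type = "gaussian", ymin = -0.5,
       ymax = 0.5, mu0 = mu0, n_draws = 1L, soft = band_mean > 0,
       n_trees = n_trees, sigma = NA_real_)
}
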