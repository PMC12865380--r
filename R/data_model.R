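#' Longitudinal cohort tables
#'
#' A \code{cohort_table} is a long-format data frame with one row per
#' subject and wave, carrying survival (\code{S}) and response (\code{R})
#' flags, time-varying confounders, an optional continuous treatment, and
#' an optional continuous outcome.  Within a wave the variables respect the
#' temporal ordering S, R, X, A, Y.  Survival is observed at every wave;
#' after death (truncation by death) or non-response the substantive
#' variables are missing.
#'
#' @param data A data frame with columns \code{id}, \code{t}, \code{S},
#'   \code{R}, the covariates, and optionally the treatment and outcome.
#' @param covariates Character vector of time-varying confounder columns.
#' @param baseline Character vector of baseline covariate columns
#'   (constant within subject, e.g. age at entry).
#' @param treatment Name of the continuous treatment column, or
#'   \code{NULL} when the design has none.
#' @param outcome Name of the continuous outcome column, or \code{NULL}.
#' @param outcome_waves Waves at which the outcome is measured (defaults
#'   to all waves).  Benchmarks that only measure the response at the final
#'   wave set this to \code{T}.
#' @param validate Check the invariants (monotone death, truncation,
#'   response-implies-observed)?
#' @return A data frame of class \code{"cohort_table"} with the schema in
#'   its attributes.
#' @export
cohort_table <- function(data, covariates, baseline = character(),
                         treatment = NULL, outcome = NULL,
                         outcome_waves = NULL, validate = TRUE) {
  data <- as.data.frame(data)
  need <- c("id", "t", "S", "R", covariates, baseline, treatment, outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("unknown column(s) in schema: ", paste(miss, collapse = ", "))
  data <- data[order(data$id, data$t), , drop = FALSE]
  waves <- sort(unique(as.integer(data$t)))
  if (!identical(waves, seq_len(max(waves))))
    stop("waves must be 1..T")
  if (is.null(outcome_waves)) outcome_waves <- if (is.null(outcome)) integer() else waves
  schema <- list(covariates = covariates, baseline = baseline,
                 treatment = treatment, outcome = outcome,
                 outcome_waves = outcome_waves, T = max(waves))
  out <- structure(data, schema = schema,
                   class = c("cohort_table", "data.frame"))
  if (validate) validate_cohort(out)
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  sc <- attr(x, "schema")
  cat(sprintf("cohort_table: %d subjects x %d waves\n",
              length(unique(x$id)), sc$T))
  cat("  covariates:", paste(sc$covariates, collapse = ", "), "\n")
  if (length(sc$baseline))
    cat("  baseline:  ", paste(sc$baseline, collapse = ", "), "\n")
  if (!is.null(sc$treatment)) cat("  treatment: ", sc$treatment, "\n")
  if (!is.null(sc$outcome))
    cat("  outcome:   ", sc$outcome, "at wave(s)",
        paste(sc$outcome_waves, collapse = ", "), "\n")
  NextMethod()
}

cohort_schema <- function(cohort) attr(cohort, "schema")

#' Validate the invariants of a cohort table
#'
#' Checks monotone death, survival observed at every wave, the truncation
#' rule (no data after death or non-response) and that responders carry
#' complete records.
#'
#' @param cohort A \code{cohort_table}.
#' @return Invisibly, the cohort; errors describe the first violation.
#' @export
validate_cohort <- function(cohort) {
  sc <- cohort_schema(cohort)
  Tn <- sc$T
  ids <- unique(cohort$id)
  tab <- table(cohort$id)
  if (any(tab != Tn))
    stop("every subject needs a survival record at every wave 1..", Tn)
  if (any(!cohort$S %in% c(0, 1)) || any(!cohort$R %in% c(0, 1)))
    stop("S and R must be coded 0/1")
  svals <- matrix(cohort$S, nrow = Tn)  # ordered by id, t
  if (Tn > 1 && any(diff(svals) > 0))
    stop("non-monotone death: a subject has S = 0 followed by S = 1")
  if (any(cohort$R == 1 & cohort$S == 0))
    stop("response flagged for a dead subject")
  vars <- c(sc$covariates, sc$treatment)
  for (v in vars) {
    bad <- cohort$R == 0 & !is.na(cohort[[v]])
    if (any(bad))
      stop("variable '", v, "' present at a wave with R = 0")
    bad <- cohort$R == 1 & is.na(cohort[[v]])
    if (any(bad))
      stop("variable '", v, "' missing at a wave with R = 1")
  }
  if (!is.null(sc$outcome)) {
    y <- cohort[[sc$outcome]]
    bad <- cohort$R == 0 & !is.na(y)
    if (any(bad)) stop("outcome present at a wave with R = 0")
    inw <- cohort$t %in% sc$outcome_waves
    bad <- cohort$R == 1 & inw & is.na(y)
    if (any(bad)) stop("outcome missing at an outcome wave with R = 1")
  }
  invisible(cohort)
}

#' Read / write a cohort table as long-format CSV
#'
#' The CSV has one row per subject-wave with columns \code{id}, \code{t},
#' \code{S}, \code{R}, the covariates, and optional treatment/outcome.
#' Missing values are empty cells.
#'
#' @inheritParams cohort_table
#' @param path File path.
#' @return \code{read_cohort} returns a validated \code{cohort_table};
#'   \code{write_cohort} invisibly returns \code{path}.
#' @export
read_cohort <- function(path, covariates, baseline = character(),
                        treatment = NULL, outcome = NULL,
                        outcome_waves = NULL) {
  data <- read.csv(path)
  cohort_table(data, covariates, baseline, treatment, outcome, outcome_waves)
}

#' @rdname read_cohort
#' @param cohort A \code{cohort_table}.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Regime specifications
#'
#' A regime is either the natural course \eqn{g_0} or an incremental
#' threshold intervention \eqn{g_*}: whenever the natural value of
#' treatment exceeds the researcher-set threshold \eqn{\tau}, it is
#' shifted downward by a random amount \eqn{\delta_t \le 0} drawn from a
#' triangular shift prior with support \eqn{[L_\tau, 0]}.
#'
#' @param kind \code{"natural_course"} or \code{"incremental_threshold"}.
#' @param tau Threshold in treatment units (e.g. 130, 140 or 150 mm Hg).
#' @param shift_prior A \code{\link{triangular}} prior on the shift
#'   \eqn{\delta_t}; its support must lie in \eqn{(-\infty, 0]}.
#' @return An object of class \code{"regime_spec"}.
#' @export
regime_spec <- function(kind = c("natural_course", "incremental_threshold"),
                        tau = NULL, shift_prior = NULL) {
  kind <- match.arg(kind)
  if (kind == "incremental_threshold") {
    if (is.null(tau)) stop("an incremental threshold regime needs tau")
    if (is.null(shift_prior)) shift_prior <- triangular(0, 0, 0)
    shift_prior <- as_triangular(shift_prior)
    if (shift_prior$upper > 0)
      stop("the shift prior must have support in (-Inf, 0] (downward shift)")
  } else {
    tau <- NULL
    shift_prior <- NULL
  }
  structure(list(kind = kind, tau = tau, shift_prior = shift_prior),
            class = "regime_spec")
}

#' Sensitivity-parameter specification for the SAIE
#'
#' Priors for the stochastic-monotonicity parameter \eqn{\lambda \in
#' [0,1]} (\eqn{\lambda = 1}: deterministic monotonicity, \eqn{\lambda =
#' 0}: independent survival under the two regimes) and the
#' between-stratum outcome difference \eqn{\Delta} (outcome units).
#'
#' @param lambda_prior Triangular prior on \eqn{\lambda}; support must lie
#'   in \eqn{[0, 1]}.  Default \code{triangular(0.5, 1, 1)}.
#' @param delta_prior Triangular prior on \eqn{\Delta}.  Default
#'   \code{triangular(0, u_delta, u_delta)}.
#' @param u_delta Upper bound for the default \eqn{\Delta} prior, in
#'   outcome units.
#' @return An object of class \code{"sensitivity_spec"}.
#' @export
sensitivity_spec <- function(lambda_prior = triangular(0.5, 1, 1),
                             delta_prior = NULL, u_delta = 1) {
  lambda_prior <- as_triangular(lambda_prior)
  if (lambda_prior$lower < 0 || lambda_prior$upper > 1)
    stop("lambda prior support must lie in [0, 1]")
  if (is.null(delta_prior)) delta_prior <- triangular(0, u_delta, u_delta)
  delta_prior <- as_triangular(delta_prior)
  structure(list(lambda_prior = lambda_prior, delta_prior = delta_prior),
            class = "sensitivity_spec")
}
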