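#' Triangular prior distributions
#'
#' Triangular distributions are used as priors for the incremental shift
#' \eqn{\delta_t} and the sensitivity parameters \eqn{\lambda} and
#' \eqn{\Delta}: they have bounded support, a single mode, and are easy to
#' elicit from subject-matter bounds.
#'
#' @param lower,mode,upper Support and mode, with
#'   \code{lower <= mode <= upper}.
#' @return An object of class \code{"triangular"}.
#' @examples
#' p <- triangular(0, 1, 1)
#' dtriangular(1, p)  # 2: triangle of base 1 with apex at the upper bound
#' @export
triangular <- function(lower, mode, upper) {
  stopifnot(is.numeric(lower), is.numeric(mode), is.numeric(upper),
            length(lower) == 1L, length(mode) == 1L, length(upper) == 1L)
  if (!(lower <= mode && mode <= upper))
    stop("triangular prior requires lower <= mode <= upper")
  structure(list(lower = lower, mode = mode, upper = upper),
            class = "triangular")
}

#' @export
print.triangular <- function(x, ...) {
  cat(sprintf("Triangular(%g, %g, %g)\n", x$lower, x$mode, x$upper))
  invisible(x)
}

as_triangular <- function(p) {
  if (inherits(p, "triangular")) return(p)
  if (is.numeric(p) && length(p) == 3L) return(triangular(p[1], p[2], p[3]))
  stop("expected a 'triangular' object or a numeric vector (lower, mode, upper)")
}

#' @rdname triangular
#' @param x,q Quantiles.
#' @param p A \code{"triangular"} object (or a length-3 numeric vector).
#' @export
dtriangular <- function(x, p) {
  p <- as_triangular(p)
  a <- p$lower; c <- p$mode; b <- p$upper
  if (a == b) stop("density undefined for a degenerate triangular prior")
  out <- numeric(length(x))
  up <- x >= a & x <= c & c > a
  out[up] <- 2 * (x[up] - a) / ((b - a) * (c - a))
  dn <- x > c & x <= b & b > c
  out[dn] <- 2 * (b - x[dn]) / ((b - a) * (b - c))
  if (c == a) out[x == a] <- 2 / (b - a)
  if (c == b) out[x == b] <- 2 / (b - a)
  # the mode itself when both sides exist
  at <- x == c & c > a & c < b
  out[at] <- 2 / (b - a)
  out
}

#' @rdname triangular
#' @export
ptriangular <- function(q, p) {
  p <- as_triangular(p)
  a <- p$lower; c <- p$mode; b <- p$upper
  if (a == b) return(as.numeric(q >= a))
  out <- numeric(length(q))
  out[q >= b] <- 1
  lo <- q > a & q <= c
  if (c > a) out[lo] <- (q[lo] - a)^2 / ((b - a) * (c - a))
  hi <- q > c & q < b
  if (b > c) out[hi] <- 1 - (b - q[hi])^2 / ((b - a) * (b - c))
  if (c == a) {
    mid <- q > a & q < b
    out[mid] <- 1 - (b - q[mid])^2 / ((b - a)^2)
  }
  out
}

#' @rdname triangular
#' @param prob Probabilities.
#' @export
qtriangular <- function(prob, p) {
  p <- as_triangular(p)
  a <- p$lower; c <- p$mode; b <- p$upper
  stopifnot(all(prob >= 0 & prob <= 1))
  if (a == b) return(rep(a, length(prob)))
  fc <- if (b > a) (c - a) / (b - a) else 0
  out <- numeric(length(prob))
  lo <- prob <= fc & fc > 0
  out[lo] <- a + sqrt(prob[lo] * (b - a) * (c - a))
  hi <- !lo
  out[hi] <- b - sqrt((1 - prob[hi]) * (b - a) * (b - c))
  out
}

#' @rdname triangular
#' @param n Number of draws.
#' @details Sampling is by inversion, so draws are reproducible under
#'   \code{set.seed()}.
#' @export
rtriangular <- function(n, p) {
  qtriangular(runif(n), as_triangular(p))
}
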