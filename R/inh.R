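#' The inverted Nadarajah-Haghighi distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the two-parameter inverted Nadarajah-Haghighi (INH) distribution, the
#' distribution of \eqn{1/Y} when \eqn{Y} is Nadarajah-Haghighi.  The CDF is
#' \deqn{G(x) = \exp\{1 - (1 + \delta/x)^\theta\}, \quad x > 0,}
#' with scale-like parameter \eqn{\delta > 0} and shape \eqn{\theta > 0}.
#' The density is decreasing or unimodal right-skewed and the hazard is
#' decreasing or upside-down bathtub shaped.
#'
#' @param x,q vector of strictly positive quantiles (`pinh` also accepts the
#'   limits 0 and `Inf`).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param delta scale-like parameter, \eqn{\delta > 0}.
#' @param theta shape parameter, \eqn{\theta > 0}.
#' @param log,log.p logical; if `TRUE` probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   before sampling so that draws are reproducible.
#'
#' @return `dinh` the density, `pinh` the distribution function, `qinh` the
#'   quantile function and `rinh` a vector of random draws.
#'
#' @examples
#' dinh(1, delta = 1, theta = 1)    # exp(-1)
#' pinh(qinh(0.5, 2, 1.5), 2, 1.5)  # 0.5
#' @name inh
NULL

#' @rdname inh
#' @export
dinh <- function(x, delta, theta, log = FALSE) {
  check_inh_params(delta, theta)
  if (any(!is.finite(x) | x <= 0))
    stop("'x' must be strictly positive and finite", call. = FALSE)
  l1 <- log1p(delta / x)
  lpdf <- log(delta) + log(theta) - 2 * log(x) + (theta - 1) * l1 +
    (1 - exp(theta * l1))
  if (log) lpdf else exp(lpdf)
}

#' @rdname inh
#' @export
pinh <- function(q, delta, theta, lower.tail = TRUE, log.p = FALSE) {
  check_inh_params(delta, theta)
  if (any(is.nan(q)) || any(q < 0))
    stop("'q' must be non-negative", call. = FALSE)
  lt <- 1 - exp(theta * log1p(delta / q))  # 1 - (1+delta/q)^theta, in [-Inf, 0]
  lt[q == 0] <- -Inf
  lt[is.infinite(q)] <- 0
  if (lower.tail) {
    if (log.p) lt else exp(lt)
  } else {
    # 1 - e^{lt} without cancellation
    if (log.p) log(-expm1(lt)) else -expm1(lt)
  }
}

#' @rdname inh
#' @export
qinh <- function(p, delta, theta) {
  check_inh_params(delta, theta)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  # invert exp(1 - (1+delta/x)^theta) = p:  x = delta / ((1 - log p)^(1/theta) - 1)
  delta / expm1(log1p(-log(p)) / theta)
}

#' @rdname inh
#' @export
rinh <- function(n, delta, theta, seed = NULL) {
  check_inh_params(delta, theta)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  qinh(stats::runif(n), delta, theta)
}
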