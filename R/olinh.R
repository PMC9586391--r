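# Core evaluation of the OLINH distribution.
#
# All functions work through the shared intermediate quantities
#   l1   = log(1 + delta/x)
#   lt   = 1 - T,            T = (1 + delta/x)^theta  (so lt <= 0)
#   logD = log(1 - G)        computed as log(-expm1(lt)), never log(1 - exp(.))
#   logR = log(G/(1-G))      the odds of the baseline CDF G = e^{lt}
#   logC = log(beta + G/(1-G))  via log-sum-exp
# which keeps both tails free of cancellation: the survival function is
# evaluated directly from the odd Lomax survival form, not as 1 - CDF.

olinh_terms <- function(x, delta, theta) {
  l1 <- log1p(delta / x)
  lt <- 1 - exp(theta * l1)
  logD <- log(-expm1(lt))
  list(l1 = l1, lt = lt, logD = logD, logR = lt - logD)
}

#' The odd Lomax inverted Nadarajah-Haghighi (OLINH) distribution
#'
#' Density, distribution function, quantile function, random generation,
#' hazard rate and odds of failure for the four-parameter OLINH
#' distribution.  The OLINH law is obtained by passing the inverted
#' Nadarajah-Haghighi baseline CDF \eqn{G(x) = \exp\{1-(1+\delta/x)^\theta\}}
#' through the odd Lomax transform, giving
#' \deqn{F(x) = 1 - \beta^\alpha\left[\beta +
#'   \frac{G(x)}{1-G(x)}\right]^{-\alpha}, \quad x > 0,}
#' with shape parameters \eqn{\alpha, \beta > 0} inherited from the Lomax
#' kernel and \eqn{\delta, \theta > 0} from the baseline.  At
#' \eqn{\alpha = \beta = 1} the family reduces exactly to the INH baseline.
#' The right tail is power-law of index \eqn{\alpha}:
#' \eqn{S(x)\, x^\alpha \to \beta^\alpha (\theta\delta)^\alpha}, so moments
#' of order \eqn{r} exist iff \eqn{r < \alpha}.
#'
#' @param x,q vector of strictly positive quantiles (`polinh` also accepts
#'   the limits 0 and `Inf`).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param alpha,beta odd Lomax shape parameters, both \eqn{> 0}.
#' @param delta,theta baseline INH parameters, both \eqn{> 0}.
#' @param log,log.p logical; return values on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}.  The upper tail is computed directly from the odd
#'   Lomax survival form, without cancellation.
#' @param seed optional integer for reproducible draws.
#'
#' @return `dolinh` the density, `polinh` the distribution function,
#'   `qolinh` the quantile function, `rolinh` random draws, `holinh` the
#'   hazard rate \eqn{f/(1-F)} and `orf_olinh` the odds of failure
#'   \eqn{F/(1-F)}.
#'
#' @examples
#' # reduction to the baseline at alpha = beta = 1
#' all.equal(polinh(2, 1, 1, 1.5, 1.5), pinh(2, 1.5, 1.5))
#' # quantile/CDF round trip
#' polinh(qolinh(0.9, 1.25, 1.5, 1.5, 1.5), 1.25, 1.5, 1.5, 1.5)
#' @name olinh
NULL

#' @rdname olinh
#' @export
dolinh <- function(x, alpha, beta, delta, theta, log = FALSE) {
  check_olinh_params(alpha, beta, delta, theta)
  if (any(!is.finite(x) | x <= 0))
    stop("'x' must be strictly positive and finite", call. = FALSE)
  tm <- olinh_terms(x, delta, theta)
  logC <- logaddexp(log(beta), tm$logR)
  lpdf <- log(alpha) + log(theta) + alpha * log(beta) + log(delta) -
    2 * log(x) + (theta - 1) * tm$l1 + tm$lt - 2 * tm$logD -
    (alpha + 1) * logC
  if (log) lpdf else exp(lpdf)
}

#' @rdname olinh
#' @export
polinh <- function(q, alpha, beta, delta, theta,
                   lower.tail = TRUE, log.p = FALSE) {
  check_olinh_params(alpha, beta, delta, theta)
  if (any(is.nan(q)) || any(q < 0))
    stop("'q' must be non-negative", call. = FALSE)
  qi <- q
  qi[q == 0] <- NA  # handled as limits below
  qi[is.infinite(q)] <- NA
  tm <- olinh_terms(ifelse(is.na(qi), 1, qi), delta, theta)
  # log survival = alpha * (log beta - log(beta + odds))
  logsf <- alpha * (log(beta) - logaddexp(log(beta), tm$logR))
  logsf[q == 0] <- 0
  logsf[is.infinite(q)] <- -Inf
  if (lower.tail) {
    if (log.p) log(-expm1(logsf)) else -expm1(logsf)
  } else {
    if (log.p) logsf else exp(logsf)
  }
}

#' @rdname olinh
#' @export
qolinh <- function(p, alpha, beta, delta, theta) {
  check_olinh_params(alpha, beta, delta, theta)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  # Invert F: with u = beta * ((1-p)^{-1/alpha} - 1) the baseline CDF at the
  # quantile is G_p = u/(1+u), and the INH inverse gives
  #   x = delta / ((1 - log G_p)^{1/theta} - 1).
  # -log G_p = log1p(1/u); both expm1/log1p forms keep the extreme tails exact.
  u <- beta * expm1(-log1p(-p) / alpha)
  delta / expm1(log1p(log1p(1 / u)) / theta)
}

#' @rdname olinh
#' @export
rolinh <- function(n, alpha, beta, delta, theta, seed = NULL) {
  check_olinh_params(alpha, beta, delta, theta)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  qolinh(stats::runif(n), alpha, beta, delta, theta)
}

#' @rdname olinh
#' @export
holinh <- function(x, alpha, beta, delta, theta, log = FALSE) {
  check_olinh_params(alpha, beta, delta, theta)
  if (any(!is.finite(x) | x <= 0))
    stop("'x' must be strictly positive and finite", call. = FALSE)
  tm <- olinh_terms(x, delta, theta)
  # closed form: alpha delta theta x^{-2} (1+d/x)^{theta-1} / [(1-G) (beta(1-G)+G)/G]
  # log(beta(1-G) + G) = logaddexp(log beta + log(1-G), log G)
  logh <- log(alpha) + log(delta) + log(theta) - 2 * log(x) +
    (theta - 1) * tm$l1 + tm$lt - tm$logD -
    logaddexp(log(beta) + tm$logD, tm$lt)
  if (log) logh else exp(logh)
}

#' @rdname olinh
#' @export
orf_olinh <- function(x, alpha, beta, delta, theta) {
  check_olinh_params(alpha, beta, delta, theta)
  if (any(!is.finite(x) | x <= 0))
    stop("'x' must be strictly positive and finite", call. = FALSE)
  tm <- olinh_terms(x, delta, theta)
  # F/(1-F) = beta^{-alpha} [beta + G/(1-G)]^{alpha} - 1
  expm1(alpha * (logaddexp(log(beta), tm$logR) - log(beta)))
}

#' Odd Lomax transform of a baseline CDF value
#'
#' The odd Lomax-G construction maps a baseline CDF value \eqn{g \in [0,1)}
#' to \eqn{1 - \beta^\alpha[\beta + g/(1-g)]^{-\alpha}}.  `polg` evaluates
#' this transform; composing it with [pinh()] gives [polinh()].
#'
#' @param g baseline CDF value(s) in \eqn{[0, 1]}; the value 1 is mapped to
#'   the limit 1.
#' @param alpha,beta odd Lomax shape parameters, both \eqn{> 0}.
#' @return transformed probabilities in \eqn{[0, 1]}.
#' @examples
#' polg(0.5, 2, 1)  # 1 - 2^{-2} = 0.75
#' @export
polg <- function(g, alpha, beta) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  if (any(!is.finite(g) | g < 0 | g > 1))
    stop("'g' must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(g))
  lim <- g == 1
  gg <- ifelse(lim, 0.5, g)
  out <- -expm1(alpha * (log(beta) - logaddexp(log(beta), log(gg) - log1p(-gg))))
  out[lim] <- 1
  out
}
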