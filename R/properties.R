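# Distributional summaries for the OLINH law.
#
# Quadrature against the exact density is the authoritative computation for
# every integral quantity here.  The doubly-indexed linear representation of
# the odd Lomax-G density is provided as a truncated cross-check of the core
# pdf/cdf only: the published series expansions for the moments, the MGF and
# the Renyi entropy do not terminate in computable form, so they are treated
# as formal and are not evaluated.

#' Linear-representation coefficient of the odd Lomax-G density
#'
#' The odd Lomax-G density admits the expansion
#' \deqn{f(x) = \sum_{k,j \ge 0} \Delta_{k,j}\,(k+j+1)\, g(x)\, G(x)^{k+j}}
#' in powers of the baseline CDF \eqn{G}, obtained from the binomial series
#' of \eqn{[\beta + G/(1-G)]^{-\alpha-1}} in \eqn{G/\beta(1-G)} followed by
#' the expansion of \eqn{(1-G)^{-(k+2)}}.  The coefficient is
#' \deqn{\Delta_{k,j} = (-1)^j \frac{\alpha}{k+j+1}\, \beta^{-(k+1)}
#'   \binom{-\alpha-1}{k} \binom{-k-2}{j},}
#' evaluated through log-gamma so that non-integer generalized binomials
#' stay exact; note \eqn{\Delta_{0,0} = \alpha/\beta}, matching the
#' small-\eqn{G} limit \eqn{f \to (\alpha/\beta)\,g}.  The expansion
#' converges where the baseline odds \eqn{G/(1-G)} are below \eqn{\beta}.
#'
#' @param k,j non-negative integer indices.
#' @param alpha,beta odd Lomax shape parameters.
#' @return the coefficient \eqn{\Delta_{k,j}}.
#' @seealso [dolinh_series()], [polinh_series()]
#' @export
olg_linrep_coef <- function(k, j, alpha, beta) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  if (any(k < 0) || any(j < 0) || any(k != floor(k)) || any(j != floor(j)))
    stop("'k' and 'j' must be non-negative integers", call. = FALSE)
  # choose(-alpha-1, k) = (-1)^k choose(alpha+k, k);
  # choose(-k-2, j)     = (-1)^j choose(k+j+1, j)
  log_c1 <- lgamma(alpha + k + 1) - lgamma(k + 1) - lgamma(alpha + 1)
  log_c2 <- lgamma(k + j + 2) - lgamma(j + 1) - lgamma(k + 2)
  (-1)^k * alpha / (k + j + 1) * exp(log_c1 + log_c2 - (k + 1) * log(beta))
}

#' Truncated linear-representation series for the OLINH pdf and CDF
#'
#' Partial sums of the odd Lomax-G expansion of [dolinh()] and [polinh()]
#' over \eqn{0 \le k \le K}, \eqn{0 \le j \le J}.  Intended as a convergence
#' cross-check of the closed-form density, not as a substitute for it: the
#' series converges only where the baseline odds are below \eqn{\beta}.
#'
#' @param x strictly positive evaluation point(s).
#' @param alpha,beta,delta,theta OLINH parameters.
#' @param K,J truncation orders of the two indices.
#' @return the truncated series value(s).
#' @export
dolinh_series <- function(x, alpha, beta, delta, theta, K = 40, J = 40) {
  check_olinh_params(alpha, beta, delta, theta)
  g <- dinh(x, delta, theta)
  G <- pinh(x, delta, theta)
  out <- 0
  for (k in 0:K) {
    coefs <- olg_linrep_coef(k, 0:J, alpha, beta)
    kj <- k + 0:J
    out <- out + g * colSums(t(outer(G, kj, `^`)) * (coefs * (kj + 1)))
  }
  out
}

#' @rdname dolinh_series
#' @export
polinh_series <- function(x, alpha, beta, delta, theta, K = 40, J = 40) {
  check_olinh_params(alpha, beta, delta, theta)
  G <- pinh(x, delta, theta)
  out <- 0
  for (k in 0:K) {
    coefs <- olg_linrep_coef(k, 0:J, alpha, beta)
    kj <- k + 0:J
    out <- out + colSums(t(outer(G, kj + 1, `^`)) * coefs)
  }
  out
}

# integrate h(x) f(x) dx over (0, upper); the region below the median is
# mapped through x = delta/u so the quadrature grid resolves the x -> 0
# boundary layer of the inverted baseline
olinh_expectation <- function(h, alpha, beta, delta, theta,
                              upper = Inf, rel.tol = 1e-9) {
  f <- function(x) h(x) * dolinh(x, alpha, beta, delta, theta)
  med <- qolinh(0.5, alpha, beta, delta, theta)
  split <- min(med, upper)
  lower_part <- stats::integrate(function(u) f(delta / u) * delta / u^2,
                                 delta / split, Inf, rel.tol = rel.tol,
                                 abs.tol = 1e-12, stop.on.error = FALSE)$value
  upper_part <- if (upper > split)
    stats::integrate(f, split, upper, rel.tol = rel.tol,
                     abs.tol = 1e-12, stop.on.error = FALSE)$value
  else 0
  lower_part + upper_part
}

#' Raw moments of the OLINH distribution
#'
#' \eqn{E[X^r]} by adaptive quadrature of \eqn{x^r f(x)}.  Because the OLINH
#' right tail is power-law of index \eqn{\alpha}, the moment of order
#' \eqn{r} exists iff \eqn{r < \alpha}; for \eqn{r \ge \alpha} the function
#' returns `Inf` with a warning.
#'
#' @param r moment order, \eqn{r > 0}.
#' @param alpha,beta,delta,theta OLINH parameters.
#' @return the moment, or `Inf` when it does not exist.
#' @examples
#' olinh_moment(1, 5, 1, 1, 1)
#' olinh_moment(1, 0.8, 1, 1, 1)  # Inf: tail index below 1
#' @export
olinh_moment <- function(r, alpha, beta, delta, theta) {
  check_olinh_params(alpha, beta, delta, theta)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("'r' must be a single positive number", call. = FALSE)
  if (r >= alpha) {
    warning(sprintf("moment of order %g does not exist (tail index alpha = %g)",
                    r, alpha))
    return(Inf)
  }
  olinh_expectation(function(x) x^r, alpha, beta, delta, theta)
}

#' Incomplete moments of the OLINH distribution
#'
#' \eqn{m_r(y) = \int_0^y x^r f(x)\,dx} by quadrature.  Non-decreasing in
#' `y` and converging to [olinh_moment()] as \eqn{y \to \infty} whenever the
#' full moment exists.
#'
#' @param r moment order, \eqn{r > 0}.
#' @param y upper limit, \eqn{y > 0}.
#' @param alpha,beta,delta,theta OLINH parameters.
#' @return the incomplete moment.
#' @export
olinh_incomplete_moment <- function(r, y, alpha, beta, delta, theta) {
  check_olinh_params(alpha, beta, delta, theta)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("'r' must be a single positive number", call. = FALSE)
  if (!is.numeric(y) || length(y) != 1L || y <= 0)
    stop("'y' must be a single positive number", call. = FALSE)
  olinh_expectation(function(x) x^r, alpha, beta, delta, theta, upper = y)
}

#' Moment generating function of the OLINH distribution
#'
#' \eqn{E[e^{tX}]} by quadrature, defined only for \eqn{t \le 0}: the
#' power-law right tail makes \eqn{E[e^{tX}]} divergent for every
#' \eqn{t > 0}, and requesting such a value is an error.
#'
#' @param t argument, \eqn{t \le 0}.
#' @param alpha,beta,delta,theta OLINH parameters.
#' @return the MGF value; `olinh_mgf(0, ...)` is 1.
#' @export
olinh_mgf <- function(t, alpha, beta, delta, theta) {
  check_olinh_params(alpha, beta, delta, theta)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("'t' must be a single finite number", call. = FALSE)
  if (t > 0)
    stop("MGF divergent for t > 0: the OLINH right tail is power-law of index alpha",
         call. = FALSE)
  if (t == 0) return(1)
  olinh_expectation(function(x) exp(t * x), alpha, beta, delta, theta)
}

#' Renyi entropy of the OLINH distribution
#'
#' \eqn{I_\zeta = (1-\zeta)^{-1} \log \int f(x)^\zeta dx} by quadrature.
#' The integral converges iff \eqn{(\alpha+1)\zeta > 1} (right tail); for
#' smaller orders the entropy is infinite and `Inf` is returned with a
#' warning.  Empirically the entropy decreases in \eqn{\zeta}.
#'
#' @param zeta entropy order, \eqn{\zeta > 0}, \eqn{\zeta \ne 1}.
#' @param alpha,beta,delta,theta OLINH parameters.
#' @return the Renyi entropy of order `zeta`.
#' @export
olinh_renyi <- function(zeta, alpha, beta, delta, theta) {
  check_olinh_params(alpha, beta, delta, theta)
  if (!is.numeric(zeta) || length(zeta) != 1L || zeta <= 0 || zeta == 1)
    stop("'zeta' must be positive and different from 1", call. = FALSE)
  if ((alpha + 1) * zeta <= 1) {
    warning("integral of f^zeta diverges: (alpha + 1) * zeta <= 1")
    return(Inf)
  }
  med <- qolinh(0.5, alpha, beta, delta, theta)
  fz <- function(x) dolinh(x, alpha, beta, delta, theta)^zeta
  val <- stats::integrate(function(u) fz(delta / u) * delta / u^2,
                          delta / med, Inf, rel.tol = 1e-10,
                          stop.on.error = FALSE)$value +
    stats::integrate(fz, med, Inf, rel.tol = 1e-10,
                     stop.on.error = FALSE)$value
  log(val) / (1 - zeta)
}

#' Density of OLINH order statistics
#'
#' Exact density of the \eqn{k}-th order statistic of an i.i.d. OLINH sample
#' of size \eqn{n}:
#' \deqn{f_{k:n}(x) = \frac{F(x)^{k-1}\,[1-F(x)]^{n-k} f(x)}{B(k, n-k+1)}.}
#'
#' @param x strictly positive evaluation point(s).
#' @param k rank, \eqn{1 \le k \le n}.
#' @param n sample size.
#' @param alpha,beta,delta,theta OLINH parameters.
#' @param log logical; return the log density.
#' @return the order-statistic density at `x`.
#' @export
dolinh_order <- function(x, k, n, alpha, beta, delta, theta, log = FALSE) {
  check_olinh_params(alpha, beta, delta, theta)
  if (k < 1 || k > n || k != floor(k) || n != floor(n))
    stop("rank 'k' must be an integer in 1..n", call. = FALSE)
  logF <- polinh(x, alpha, beta, delta, theta, log.p = TRUE)
  logS <- polinh(x, alpha, beta, delta, theta, lower.tail = FALSE, log.p = TRUE)
  lpdf <- (k - 1) * logF + (n - k) * logS +
    dolinh(x, alpha, beta, delta, theta, log = TRUE) - lbeta(k, n - k + 1)
  if (log) lpdf else exp(lpdf)
}

#' Quantile-based shape measures of the OLINH distribution
#'
#' Bowley skewness \eqn{(Q_{3/4} + Q_{1/4} - 2 Q_{1/2})/(Q_{3/4} -
#' Q_{1/4})} and Moors kurtosis \eqn{(Q_{7/8} - Q_{5/8} + Q_{3/8} -
#' Q_{1/8})/(Q_{6/8} - Q_{2/8})}, both computed from [qolinh()].  These
#' octile-based measures stay finite for every parameter value, unlike
#' moment-based skewness/kurtosis which require \eqn{\alpha > 3} resp.
#' \eqn{\alpha > 4}.
#'
#' @param alpha,beta,delta,theta OLINH parameters.
#' @return a list with components `bowley` and `moors`.
#' @export
olinh_shape <- function(alpha, beta, delta, theta) {
  Q <- function(p) qolinh(p, alpha, beta, delta, theta)
  o <- Q((1:7) / 8)
  list(bowley = (o[6] + o[2] - 2 * o[4]) / (o[6] - o[2]),
       moors = (o[7] - o[5] + o[3] - o[1]) / (o[6] - o[2]))
}
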