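# Goodness-of-fit statistics and information criteria for fitted
# univariate distributions, built on the probability integral transform
# u_(i) = F(x_(i)) of the ordered sample.

# asymptotic Kolmogorov law: P(sqrt(n) D > lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Goodness-of-fit report for a fitted distribution
#'
#' Computes the one-sample Kolmogorov-Smirnov statistic with its
#' asymptotic p-value, the Cramer-von Mises and Anderson-Darling
#' statistics, and the AIC, corrected AIC, BIC and Hannan-Quinn
#' information criteria for a fitted distribution with `k` estimated
#' parameters.  With \eqn{u_{(i)} = F(x_{(i)})}:
#' \deqn{KS = \max_i \max\{i/n - u_{(i)},\, u_{(i)} - (i-1)/n\},}
#' \deqn{CvM = \frac{1}{12n} + \sum_i \left(u_{(i)} -
#'   \frac{2i-1}{2n}\right)^2,}
#' \deqn{AD = -n - \frac{1}{n}\sum_i (2i-1)\left[\log u_{(i)} +
#'   \log(1-u_{(n+1-i)})\right].}
#' The criteria are \eqn{AIC = 2k - 2\ell}, \eqn{CAIC = AIC +
#' 2k(k+1)/(n-k-1)} (the small-sample corrected AIC), \eqn{BIC = k\log n -
#' 2\ell} and \eqn{HQIC = 2k\log\log n - 2\ell}.
#'
#' @param x strictly positive sample.
#' @param cdf fitted distribution function taking the sample as its only
#'   argument.
#' @param k number of estimated parameters, \eqn{k \ge 1}.
#' @param loglik maximized log-likelihood of the fit.
#' @param name label for the fitted model.
#' @return an object of class `gof_report`: a list with `name`, `n`, `k`,
#'   `loglik`, `ks`, `ks_p`, `cvm`, `ad`, `aic`, `caic`, `bic` and `hqic`.
#' @examples
#' x <- rolinh(100, 1.25, 1.5, 1.5, 1.5, seed = 3)
#' fit <- olinh_mle(x)
#' gof_report(x, function(q) polinh(q, fit$estimate[1], fit$estimate[2],
#'                                  fit$estimate[3], fit$estimate[4]),
#'            k = 4, loglik = fit$loglik, name = "OLINH")
#' @export
gof_report <- function(x, cdf, k, loglik, name = "model") {
  check_sample(x)
  n <- length(x)
  if (k < 1 || n <= k + 1)
    stop("need k >= 1 and n > k + 1", call. = FALSE)
  u <- sort(cdf(sort(x)))
  if (any(u <= 0) || any(u >= 1)) {
    warning("PIT values at 0 or 1 clipped for log-safety")
    u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
  }
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  cvm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  ad <- -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
  structure(list(name = name, n = n, k = as.integer(k), loglik = loglik,
                 ks = ks, ks_p = kolmogorov_sf(sqrt(n) * ks),
                 cvm = cvm, ad = ad,
                 aic = 2 * k - 2 * loglik,
                 caic = 2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1),
                 bic = k * log(n) - 2 * loglik,
                 hqic = 2 * k * log(log(n)) - 2 * loglik),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("%s  (n = %d, k = %d, loglik = %.4f)\n", x$name, x$n, x$k, x$loglik))
  cat(sprintf("  KS %.4f (p = %.4f)  CvM %.4f  AD %.4f\n", x$ks, x$ks_p, x$cvm, x$ad))
  cat(sprintf("  AIC %.4f  CAIC %.4f  BIC %.4f  HQIC %.4f\n",
              x$aic, x$caic, x$bic, x$hqic))
  invisible(x)
}

#' Goodness-of-fit report from a maximum-likelihood fit object
#'
#' Convenience wrapper building the [gof_report()] of an [olinh_mle()] or
#' [inh_mle()] fit on the data it was fitted to.
#'
#' @param fit an `olinh_fit` object.
#' @param x the sample the fit was computed from.
#' @return a `gof_report`.
#' @export
gof_report_fit <- function(fit, x) {
  stopifnot(inherits(fit, "olinh_fit"))
  e <- fit$estimate
  cdf <- if (fit$distribution == "olinh") {
    function(q) polinh(q, e[["alpha"]], e[["beta"]], e[["delta"]], e[["theta"]])
  } else {
    function(q) pinh(q, e[["delta"]], e[["theta"]])
  }
  gof_report(x, cdf, k = fit$k, loglik = fit$loglik,
             name = toupper(fit$distribution))
}

#' Ranked goodness-of-fit comparison of fitted models
#'
#' Builds one [gof_report()] per fitted model and ranks the models by AIC
#' (ascending), breaking ties by BIC and then by name.
#'
#' @param x strictly positive sample.
#' @param fits a named list; each element is either an `olinh_fit` or a
#'   list with components `cdf`, `k` and `loglik`.
#' @return a `data.frame` of class `gof_comparison`, one row per model in
#'   rank order, with the statistics of each report as columns.
#' @export
compare_models <- function(x, fits) {
  if (length(fits) < 2L) stop("need at least two fits", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("'fits' must be a fully named list", call. = FALSE)
  reports <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "olinh_fit")) {
      r <- gof_report_fit(f, x); r$name <- nm; r
    } else {
      gof_report(x, f$cdf, f$k, f$loglik, name = nm)
    }
  })
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$name, k = r$k, loglik = r$loglik, ks = r$ks,
               ks_p = r$ks_p, cvm = r$cvm, ad = r$ad, aic = r$aic,
               caic = r$caic, bic = r$bic, hqic = r$hqic,
               stringsAsFactors = FALSE)))
  tab <- tab[order(tab$aic, tab$bic, tab$model), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("gof_comparison", "data.frame")
  tab
}
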