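test_that("log-likelihood agrees with its expanded analytic form", {
  # single observation reduces to the log density
  expect_equal(olinh_loglik(1, 1, 1, 1, 1),
               dolinh(1, 1, 1, 1, 1, log = TRUE), tolerance = 1e-12)
  # term-by-term expansion on random parameter points
  set.seed(12)
  x <- rolinh(25, 1.25, 1.5, 1.5, 1.5)
  for (i in 1:20) {
    w <- exp(runif(4, -1, 1))
    expect_equal(olinh_loglik(x, w[1], w[2], w[3], w[4]),
                 loglik_expanded(x, w[1], w[2], w[3], w[4]),
                 tolerance = 1e-8)
  }
  # vaccination data at the published parameter values: the likelihood
  # implied by AIC = 292.1784 with k = 4
  expect_equal(olinh_loglik(vacc, 9.0385, 1.8521, 716.7624, 0.2115),
               -142.0892, tolerance = 1e-5)
})

test_that("analytic score matches numerical differentiation", {
  x <- rolinh(50, 1.25, 1.5, 1.5, 1.5, seed = 21)
  w <- c(1.25, 1.5, 1.5, 1.5)
  s <- olinh_score(x, w[1], w[2], w[3], w[4])
  num <- sapply(1:4, function(i) {
    h <- w[i] * 1e-6
    wp <- wm <- w
    wp[i] <- w[i] + h
    wm[i] <- w[i] - h
    (olinh_loglik(x, wp[1], wp[2], wp[3], wp[4]) -
       olinh_loglik(x, wm[1], wm[2], wm[3], wm[4])) / (2 * h)
  })
  expect_equal(unname(s), num, tolerance = 1e-5)
})

test_that("profiled alpha zeroes its score component and maximizes in 1-D", {
  x <- c(0.5, 1, 2)
  a_hat <- olinh_profile_alpha(x, 1, 1, 1)
  expect_gt(a_hat, 0)
  s <- olinh_score(x, a_hat, 1, 1, 1)
  expect_lt(abs(s[["alpha"]]), 1e-10)
  # 1-D maximization oracle over alpha at fixed (beta, delta, theta)
  opt <- optimize(function(a) olinh_loglik(x, a, 1, 1, 1),
                  c(1e-3, 50), maximum = TRUE, tol = 1e-10)
  expect_equal(a_hat, opt$maximum, tolerance = 1e-6)
  # denominator positivity on an arbitrary sample
  x2 <- rolinh(40, 2, 0.5, 1, 1, seed = 8)
  expect_true(is.finite(olinh_profile_alpha(x2, 0.5, 2, 0.3)))
})

test_that("the vaccination-data fit attains the published optimum", {
  fit <- olinh_mle(vacc)
  expect_true(fit$converged)
  aic <- 2 * fit$k - 2 * fit$loglik
  expect_equal(aic, 292.1784, tolerance = 5e-4)
  expect_equal(unname(fit$estimate[["alpha"]]), 9.0385, tolerance = 0.01)
  # the optimum dominates the printed parameter point
  expect_gte(fit$loglik,
             olinh_loglik(vacc, 9.0385, 1.8521, 716.7624, 0.2115) - 1e-6)
  # stationarity of the analytic score at the reported optimum
  s <- olinh_score(vacc, fit$estimate[1], fit$estimate[2],
                   fit$estimate[3], fit$estimate[4])
  expect_lt(max(abs(s)), 1e-4)
  # likelihood value recorded in the fit is the likelihood of the estimate
  expect_equal(fit$loglik,
               olinh_loglik(vacc, fit$estimate[1], fit$estimate[2],
                            fit$estimate[3], fit$estimate[4]),
               tolerance = 1e-10)
  # interval plumbing
  expect_true(all(fit$ci[, "lower"] < fit$ci[, "upper"]))
  expect_true(all(fit$ci[, "lower"] >= 0))
})

test_that("multi-start optimum dominates random restart endpoints", {
  fit <- olinh_mle(vacc)
  set.seed(33)
  endpoint_best <- -Inf
  for (i in 1:100) {
    p0 <- runif(3, -2, 2) + c(0, log(median(vacc)), 0)
    o <- optim(p0, olinh:::olinh_profile_nll, x = vacc,
               method = "Nelder-Mead", control = list(maxit = 400))
    endpoint_best <- max(endpoint_best, -o$value)
  }
  expect_gte(fit$loglik, endpoint_best - 1e-6)
})

test_that("estimates are consistent and scale-equivariant", {
  # large-sample recovery: the tail index is well identified, and the
  # fitted distribution function converges even where the (beta, delta,
  # theta) ridge coordinate itself has large finite-sample variance
  x <- rolinh(5000, 1.25, 1.5, 1.5, 1.5, seed = 99)
  fit <- olinh_mle(x)
  e <- fit$estimate
  expect_lt(abs(e[["alpha"]] / 1.25 - 1), 0.10)
  grid <- qolinh(seq(0.001, 0.999, length.out = 400), 1.25, 1.5, 1.5, 1.5)
  sup_dist <- max(abs(polinh(grid, e[1], e[2], e[3], e[4]) -
                        polinh(grid, 1.25, 1.5, 1.5, 1.5)))
  expect_lt(sup_dist, 0.01)
  # delta carries the scale: fitting c*x multiplies delta by c only
  x0 <- rolinh(400, 1.25, 1.5, 1.5, 1.5, seed = 55)
  f1 <- olinh_mle(x0, start = c(1.5, 1.5, 1.5))
  f2 <- olinh_mle(10 * x0, start = c(1.5, 15, 1.5))
  expect_equal(unname(f2$estimate[["delta"]] / f1$estimate[["delta"]]), 10,
               tolerance = 1e-3)
  expect_equal(unname(f2$estimate[c("alpha", "beta", "theta")]),
               unname(f1$estimate[c("alpha", "beta", "theta")]),
               tolerance = 1e-3)
})

test_that("INH baseline fit matches an independent optimizer and nests below OLINH", {
  fit <- inh_mle(vacc)
  # frozen from an independent fit of the same likelihood (fitdistrplus
  # agrees to four decimals): the INH maximum is at (11.216, 0.3535)
  expect_equal(fit$loglik, -143.5483, tolerance = 1e-4)
  expect_equal(unname(fit$estimate[["delta"]]), 11.216, tolerance = 1e-3)
  expect_equal(unname(fit$estimate[["theta"]]), 0.3535, tolerance = 1e-3)
  # consistency on simulated data
  xs <- rinh(5000, 1.5, 1.5, seed = 13)
  fs <- inh_mle(xs)
  expect_true(all(abs(fs$estimate / c(1.5, 1.5) - 1) < 0.10))
  # the four-parameter family contains the baseline, so its optimum is
  # at least as high
  expect_gte(olinh_mle(vacc)$loglik, fit$loglik - 1e-8)
  expect_error(inh_mle(c(1, 2)), "at least 3")
})
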