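test_that("INH baseline matches closed form, derivative and normalization", {
  # direct substitution at x = delta = theta = 1: both cdf and pdf are e^{-1}
  expect_equal(pinh(1, 1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(dinh(1, 1, 1), exp(-1), tolerance = 1e-12)
  # limits
  expect_equal(pinh(0, 2, 3), 0)
  expect_equal(pinh(Inf, 2, 3), 1)
  # pdf is the derivative of the cdf
  h <- 1e-5
  num <- (pinh(2 + h, 1.5, 0.8) - pinh(2 - h, 1.5, 0.8)) / (2 * h)
  expect_equal(dinh(2, 1.5, 0.8), num, tolerance = 1e-6)
  # density integrates to one
  expect_equal(integrate(dinh, 0, Inf, delta = 1.5, theta = 1.5,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-7)
  # domain errors
  expect_error(dinh(-1, 1, 1), "positive")
  expect_error(pinh(2, -1, 1), "delta")
})

test_that("odd Lomax transform has the identity, endpoint and algebraic values", {
  g <- seq(0, 0.99, by = 0.01)
  # alpha = beta = 1 is the identity map
  expect_equal(polg(g, 1, 1), g, tolerance = 1e-12)
  expect_equal(polg(0, 3, 0.7), 0)
  expect_equal(polg(1, 3, 0.7), 1)
  expect_equal(polg(0.5, 2, 1), 0.75, tolerance = 1e-12)
  # monotone in g
  expect_true(all(diff(polg(g, 1.7, 0.4)) > 0))
  expect_error(polg(1.2, 1, 1), "0, 1")
})

test_that("OLINH cdf is the transform of the baseline and reduces to it", {
  xg <- c(0.05, 0.2, 0.7, 1.5, 4, 20, 200)
  for (w in shape_grid) {
    composed <- polg(pinh(xg, w[3], w[4]), w[1], w[2])
    expect_equal(polinh(xg, w[1], w[2], w[3], w[4]), composed,
                 tolerance = 1e-12)
  }
  # exact family reduction at alpha = beta = 1
  expect_equal(polinh(xg, 1, 1, 1.5, 1.5), pinh(xg, 1.5, 1.5),
               tolerance = 1e-12)
  # monotone and with the right limits
  expect_true(all(diff(polinh(xg, 1.25, 1.5, 1.5, 1.5)) > 0))
  expect_equal(polinh(0, 1.25, 1.5, 1.5, 1.5), 0)
  expect_equal(polinh(Inf, 1.25, 1.5, 1.5, 1.5), 1)
})

test_that("OLINH cdf agrees with the empirical cdf of its own draws", {
  n <- 1e5
  draws <- rolinh(n, 1.25, 1.5, 1.5, 1.5, seed = 101)
  Fx <- polinh(2, 1.25, 1.5, 1.5, 1.5)
  expect_lt(abs(mean(draws <= 2) - Fx), 3 * sqrt(Fx * (1 - Fx) / n))
})

test_that("OLINH density integrates to one and differentiates the cdf", {
  for (w in shape_grid) {
    total <- integrate(function(z) dolinh(z, w[1], w[2], w[3], w[4]),
                       0, qolinh(0.5, w[1], w[2], w[3], w[4]),
                       rel.tol = 1e-9)$value +
      integrate(function(z) dolinh(z, w[1], w[2], w[3], w[4]),
                qolinh(0.5, w[1], w[2], w[3], w[4]), Inf,
                rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  h <- 5e-5
  num <- (polinh(5 + h, 1.25, 1.5, 1.5, 1.5) -
            polinh(5 - h, 1.25, 1.5, 1.5, 1.5)) / (2 * h)
  expect_equal(dolinh(5, 1.25, 1.5, 1.5, 1.5), num, tolerance = 1e-6)
  # reduction to the baseline density
  xg <- c(0.1, 0.5, 1, 2, 10)
  expect_equal(dolinh(xg, 1, 1, 2, 0.7), dinh(xg, 2, 0.7), tolerance = 1e-12)
})

test_that("log density is consistent and finite deep in both tails", {
  expect_equal(exp(dolinh(1, 1.25, 1.5, 1.5, 1.5, log = TRUE)),
               dolinh(1, 1.25, 1.5, 1.5, 1.5), tolerance = 1e-12)
  # right tail: baseline cdf within double-eps of 1
  expect_true(is.finite(dolinh(1e6, 1.25, 1.5, 1.5, 1.5, log = TRUE)))
  # left tail: (1 + delta/x)^theta around 1.8e6, e^{1-T} underflows
  expect_true(is.finite(dolinh(1e-4, 1.25, 1.5, 1.5, 1.5, log = TRUE)))
  expect_lt(dolinh(1e-4, 1.25, 1.5, 1.5, 1.5, log = TRUE), -1e5)
})

test_that("survival, hazard and odds of failure satisfy their identities", {
  xg <- exp(seq(log(0.02), log(50), length.out = 50))
  # complementarity without cancellation
  expect_equal(polinh(0.5, 1.25, 1.5, 1.5, 1.5) +
                 polinh(0.5, 1.25, 1.5, 1.5, 1.5, lower.tail = FALSE),
               1, tolerance = 1e-12)
  # hazard = pdf / sf on a grid
  w <- c(0.5, 2, 1, 3)
  hz <- holinh(xg, w[1], w[2], w[3], w[4])
  ratio <- dolinh(xg, w[1], w[2], w[3], w[4]) /
    polinh(xg, w[1], w[2], w[3], w[4], lower.tail = FALSE)
  expect_equal(hz, ratio, tolerance = 1e-10)
  # cumulative hazard equals -log survival
  ch <- integrate(function(z) holinh(z, 1.25, 1.5, 1.5, 1.5), 0, 2,
                  rel.tol = 1e-10)$value
  expect_equal(ch, -polinh(2, 1.25, 1.5, 1.5, 1.5, lower.tail = FALSE,
                           log.p = TRUE), tolerance = 1e-7)
  # odds of failure: definitional identity, zero limit, unit value at median
  w2 <- c(2, 0.5, 1, 1)
  orf <- orf_olinh(xg, w2[1], w2[2], w2[3], w2[4])
  expect_equal(orf, polinh(xg, w2[1], w2[2], w2[3], w2[4]) /
                 polinh(xg, w2[1], w2[2], w2[3], w2[4], lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(orf_olinh(1e-6, w2[1], w2[2], w2[3], w2[4]), 1e-10)
  med <- qolinh(0.5, w2[1], w2[2], w2[3], w2[4])
  expect_equal(orf_olinh(med, w2[1], w2[2], w2[3], w2[4]), 1,
               tolerance = 1e-9)
})

test_that("quantile function inverts the cdf and matches root-finding", {
  qs <- c(0.001, 0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99, 0.999)
  for (w in shape_grid) {
    x <- qolinh(qs, w[1], w[2], w[3], w[4])
    expect_true(all(diff(x) > 0))
    expect_equal(polinh(x, w[1], w[2], w[3], w[4]), qs, tolerance = 1e-9)
  }
  # alpha = beta = 1 reduction: INH quantile in closed form, checked
  # against a bracketed root of the cdf
  q <- 0.37
  x_red <- qolinh(q, 1, 1, 1.5, 2)
  expect_equal(x_red, 1.5 / ((1 - log(q))^(1 / 2) - 1), tolerance = 1e-12)
  root <- uniroot(function(z) pinh(z, 1.5, 2) - q, c(1e-8, 1e8),
                  tol = 1e-12)$root
  expect_equal(x_red, root, tolerance = 1e-8)
  # median of (2,1,1,1) versus bisection on the OLINH cdf
  med <- qolinh(0.5, 2, 1, 1, 1)
  root2 <- uniroot(function(z) polinh(z, 2, 1, 1, 1) - 0.5, c(1e-8, 1e8),
                   tol = 1e-12)$root
  expect_equal(med, root2, tolerance = 1e-8)
  expect_error(qolinh(1.5, 1, 1, 1, 1), "inside")
})

test_that("random generation is seed-reproducible and distributed as the cdf", {
  expect_identical(rolinh(50, 1.25, 1.5, 1.5, 1.5, seed = 5),
                   rolinh(50, 1.25, 1.5, 1.5, 1.5, seed = 5))
  # KS statistic below the 1% critical value in >= 19 of 20 replicates
  n <- 1e4
  crit <- 1.63 / sqrt(n)
  hits <- 0
  for (s in 1:20) {
    draws <- rolinh(n, 1.25, 1.5, 1.5, 1.5, seed = 300 + s)
    u <- sort(polinh(draws, 1.25, 1.5, 1.5, 1.5))
    i <- seq_len(n)
    ks <- max(pmax(i / n - u, u - (i - 1) / n))
    hits <- hits + (ks < crit)
  }
  expect_gte(hits, 19)
  # quarter of the draws fall below the first quartile
  draws <- rolinh(n, 1.25, 1.5, 1.5, 1.5, seed = 77)
  q25 <- qolinh(0.25, 1.25, 1.5, 1.5, 1.5)
  expect_lt(abs(mean(draws <= q25) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("right tail follows the power law of index alpha", {
  w <- c(1.25, 1.5, 1.5, 1.5)
  lim <- (w[2] * w[4] * w[3])^w[1]  # beta^alpha (theta delta)^alpha
  xs <- 10^(4:6)
  ratio <- polinh(xs, w[1], w[2], w[3], w[4], lower.tail = FALSE) * xs^w[1]
  expect_true(all(abs(ratio / lim - 1) < 0.01))
  # the ratio stabilizes: successive values get closer to the limit
  expect_true(all(diff(abs(ratio - lim)) < 0))
})
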