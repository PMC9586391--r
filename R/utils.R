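# internal numerical helpers

# elementwise log(exp(a) + exp(b)) without overflow
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(-abs(a - b)))
  # if both are -Inf, pmax gives -Inf and the correction is NaN; fix up
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

check_positive_scalar <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop(sprintf("'%s' must be a single strictly positive finite number", name),
         call. = FALSE)
  invisible(value)
}

# validates the OLINH parameter vector (alpha, beta, delta, theta)
check_olinh_params <- function(alpha, beta, delta, theta) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  check_positive_scalar(delta, "delta")
  check_positive_scalar(theta, "theta")
  invisible(NULL)
}

check_inh_params <- function(delta, theta) {
  check_positive_scalar(delta, "delta")
  check_positive_scalar(theta, "theta")
  invisible(NULL)
}

# a strictly positive sample; rejects NA/NaN/non-positive values
check_sample <- function(x, n_min = 1L) {
  if (!is.numeric(x) || length(x) < n_min)
    stop(sprintf("sample must be numeric with at least %d observation(s)", n_min),
         call. = FALSE)
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop(sprintf("sample values must be finite and strictly positive (first offender at position %d: %s)",
                 bad[1L], format(x[bad[1L]])), call. = FALSE)
  invisible(x)
}

# central-difference gradient with per-coordinate relative step
num_gradient <- function(fn, x, rel_step = 1e-6) {
  k <- length(x)
  g <- numeric(k)
  h <- pmax(abs(x), 1e-8) * rel_step
  for (i in seq_len(k)) {
    e <- rep(0, k); e[i] <- h[i]
    g[i] <- (fn(x + e) - fn(x - e)) / (2 * h[i])
  }
  g
}

# central-difference Hessian with per-coordinate relative step
num_hessian <- function(fn, x, rel_step = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  h <- pmax(abs(x), 1e-8) * rel_step
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- rep(0, k); ei[i] <- h[i]
      ej <- rep(0, k); ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# adaptive quadrature of h(x) * f(x) over (0, Inf), split at the median so the
# integrand is well scaled on both sides of the bulk of the mass
quad_split <- function(integrand, split, rel.tol = 1e-9, abs.tol = 1e-12) {
  lo <- stats::integrate(integrand, 0, split, rel.tol = rel.tol,
                         abs.tol = abs.tol, stop.on.error = FALSE)
  hi <- stats::integrate(integrand, split, Inf, rel.tol = rel.tol,
                         abs.tol = abs.tol, stop.on.error = FALSE)
  lo$value + hi$value
}
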