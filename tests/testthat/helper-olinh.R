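# shared fixtures for the test suite

# parameter sets spanning the documented density shapes (right-skewed,
# reverse-J, heavy and light Lomax tails), plus the vaccination-data fit
shape_grid <- list(
  c(1.25, 1.5, 1.5, 1.5),
  c(0.5, 2, 1, 3),
  c(2, 0.5, 1, 1),
  c(5, 1, 1, 1),
  c(9.0385, 1.8521, 716.7624, 0.2115)
)

w_ref <- c(1.25, 1.5, 1.5, 1.5)

vacc <- covid_vaccination_africa()

# independent log-likelihood: the expanded analytic form, term by term,
# written without the package's shared intermediates
loglik_expanded <- function(x, a, b, d, t) {
  n <- length(x)
  T_ <- (1 + d / x)^t
  G <- exp(1 - T_)
  n * (log(a) + log(t) + a * log(b) + log(d)) - 2 * sum(log(x)) +
    (t - 1) * sum(log(1 + d / x)) + sum(1 - T_) -
    2 * sum(log(1 - G)) - (a + 1) * sum(log(b + G / (1 - G)))
}
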