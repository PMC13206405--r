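# Straight-line scalar transcription of the component-level update
# equations, kept independent of the package implementation: predictions,
# precision-weighted value update, noise prediction error, noise update.
# Used as the reference the vectorised implementation must match.

oracle_predict <- function(zeta, mu_v, pi_v, mu_n, pi_n, omega) {
  list(
    mu_hat_input = mu_v,
    pi_hat_input = 1 / exp(zeta + mu_n),
    mu_hat_value = mu_v,
    pi_hat_value = 1 / (1 / pi_v + exp(omega)),
    mu_hat_noise = mu_n,
    pi_hat_noise = 1 / (1 / pi_n + exp(omega))
  )
}

oracle_update <- function(zeta, mu_v, pi_v, mu_n, pi_n, omega, o, a) {
  p <- oracle_predict(zeta, mu_v, pi_v, mu_n, pi_n, omega)
  delta <- o - p$mu_hat_input
  pi_value <- p$pi_hat_value + p$pi_hat_input * a
  mu_value <- p$mu_hat_value + (p$pi_hat_input / pi_value) * delta * a
  epsilon <- p$pi_hat_input / pi_value + p$pi_hat_input * delta^2 - 1
  pi_noise <- p$pi_hat_noise + ((1 + epsilon) / 2) * a
  mu_noise <- p$mu_hat_noise + (epsilon / (2 * pi_noise)) * a
  list(mu_value = mu_value, pi_value = pi_value,
       mu_noise = mu_noise, pi_noise = pi_noise,
       delta = delta, epsilon = epsilon)
}

# Reference activity computation in plain linear arithmetic (no log-space
# tricks): g * f * w for established components, alpha^2 * f for the
# candidate, jointly normalised.
oracle_activity <- function(o, mu, tau, w, lambda, alpha, sigma) {
  g <- ifelse((o - mu)^2 * tau == 0, 1,
              (2 / pi) * atan(exp(lambda) / ((o - mu)^2 * tau)))
  f <- sqrt(tau / (2 * pi)) * exp(-tau * (o - mu)^2 / 2)
  tau_c <- exp(-sigma)
  f_c <- sqrt(tau_c / (2 * pi))
  s <- c(g * f * w, alpha^2 * f_c)
  s / sum(s)
}
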