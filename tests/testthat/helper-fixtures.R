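# Shared small fixtures, built in code.

small_conn <- function(n = 10, seed = 7) synth_connectome(n, seed = seed)

default_grid <- frequency_grid()

# Independent mesoscopic oracle: solve the two-population frequency-domain
# system as a literal 2x2 linear solve (no closed-form algebra).
local_transfer_oracle <- function(tau_e, tau_i, g_ei, g_ii, omega) {
  fe <- (1 / tau_e^2) / (1i * omega + 1 / tau_e)^2
  fi <- (1 / tau_i^2) / (1i * omega + 1 / tau_i)^2
  M <- matrix(c(1i * omega + fe / tau_e, g_ei * fi / tau_e,
                -g_ei * fe / tau_i, 1i * omega + g_ii * fi / tau_i),
              2, 2, byrow = TRUE)
  x <- solve(M, c(1 + 0i, 1 + 0i))
  sum(x)
}

# Independent stability oracle: roots of the degree-6 characteristic
# polynomial located as eigenvalues of its companion matrix.
stability_oracle <- function(tau_e, tau_i, g_ei, g_ii) {
  a <- 1 / tau_e; b <- 1 / tau_i
  pa <- c(a^3, a^2, 2 * a, 1)
  pb <- c(g_ii * b^3, b^2, 2 * b, 1)
  cc <- numeric(7)
  for (i in 1:4) cc[i:(i + 3)] <- cc[i:(i + 3)] + pa[i] * pb
  cc[1] <- cc[1] + g_ei^2 * a^3 * b^3
  monic <- cc / cc[7]
  comp <- rbind(cbind(rep(0, 5), diag(5)), -monic[1:6])
  all(Re(eigen(comp, only.values = TRUE)$values) < -1e-9)
}

random_stable_params <- function(seed, bounds = default_bounds()) {
  set.seed(seed)
  repeat {
    p <- theta_to_sgm(stats::rnorm(7, 0, 10), bounds)
    if (stability_check(p)) return(p)
  }
}
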