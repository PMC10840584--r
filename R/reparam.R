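#' The seven global SGM parameters
#'
#' Constructs a named parameter vector for the spectral graph model:
#' excitatory/inhibitory time constants `tau_e`, `tau_i` (s), long-range
#' coupling `alpha` (unitless), conduction speed `speed` (m/s), alternating
#' and inhibitory neural gains `g_ei`, `g_ii` (unitless), and the graph
#' (long-range excitatory) time constant `tau_G` (s).
#'
#' @param tau_e,tau_i,alpha,speed,g_ei,g_ii,tau_G Numeric scalars.
#' @return A named numeric vector of class `sgm_params`.
#' @export
sgm_params <- function(tau_e, tau_i, alpha, speed, g_ei, g_ii, tau_G) {
  p <- c(tau_e = tau_e, tau_i = tau_i, alpha = alpha, speed = speed,
         g_ei = g_ei, g_ii = g_ii, tau_G = tau_G)
  if (!all(is.finite(p))) stop("non-finite parameter value")
  structure(p, class = "sgm_params")
}

#' @export
print.sgm_params <- function(x, ...) {
  cat("SGM parameters:\n")
  print(signif(unclass(x), 4))
  invisible(x)
}

.sgm_param_names <- c("tau_e", "tau_i", "alpha", "speed", "g_ei", "g_ii", "tau_G")

as_sgm_params <- function(x) {
  x <- unlist(x)[.sgm_param_names]
  if (anyNA(x)) stop("parameter vector must contain all of: ",
                     paste(.sgm_param_names, collapse = ", "))
  structure(x, class = "sgm_params")
}

#' Box constraints on the SGM parameters
#'
#' The default bounds are the estimation bounds used with this model family:
#' `tau_e` in \[0.005, 0.03\] s, `tau_i` in \[0.005, 0.2\] s, `alpha` in
#' \[0.1, 1\], `speed` in \[5, 20\] m/s, `tau_G` in \[0.005, 0.03\] s, and
#' gain bounds given by ordered tiers (widest first):
#' `g_ei` in \[0.001, 0.7\] -> \[0.001, 0.5\] -> \[0.001, 0.4\] and
#' `g_ii` in \[0.001, 2.0\] -> \[0.001, 1.5\] -> \[0.001, 1.5\]. For
#' simulation-based inference the widest gain tier defines the box; the
#' narrower tiers are used sequentially by the annealing baseline when the
#' widest-tier optimum is unstable.
#'
#' @param tier Gain tier to adopt (1 = widest, default).
#' @return An object of class `sgm_bounds`: list with numeric vectors
#'   `lower`, `upper` (named by parameter) and matrix `gain_tiers` with
#'   columns `g_ei_upper`, `g_ii_upper`.
#' @export
default_bounds <- function(tier = 1L) {
  tiers <- cbind(g_ei_upper = c(0.7, 0.5, 0.4),
                 g_ii_upper = c(2.0, 1.5, 1.5))
  stopifnot(tier >= 1, tier <= nrow(tiers))
  lower <- c(tau_e = 0.005, tau_i = 0.005, alpha = 0.1, speed = 5,
             g_ei = 0.001, g_ii = 0.001, tau_G = 0.005)
  upper <- c(tau_e = 0.03, tau_i = 0.2, alpha = 1, speed = 20,
             g_ei = unname(tiers[tier, 1]), g_ii = unname(tiers[tier, 2]),
             tau_G = 0.03)
  structure(list(lower = lower, upper = upper, gain_tiers = tiers,
                 tier = as.integer(tier)),
            class = "sgm_bounds")
}

#' @export
print.sgm_bounds <- function(x, ...) {
  cat("SGM parameter bounds (gain tier", x$tier, "):\n")
  print(data.frame(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Midpoint of the parameter box
#'
#' @param bounds An `sgm_bounds` (default [default_bounds()]).
#' @return `sgm_params` at the interval midpoints.
#' @export
midpoint_params <- function(bounds = default_bounds()) {
  as_sgm_params((bounds$lower + bounds$upper) / 2)
}

#' Scaled logit transform
#'
#' Maps a value in the open interval (lo, hi) to the real line:
#' `10 * log(u / (1 - u))` with `u = (x - lo) / (hi - lo)` (natural log).
#' Strictly increasing; the interval midpoint maps to 0.
#'
#' @param x Numeric vector, strictly inside `(lo, hi)` elementwise.
#' @param lo,hi Interval bounds (vectors recycle).
#' @return Unconstrained values.
#' @export
scaled_logit <- function(x, lo, hi) {
  if (any(x <= lo | x >= hi))
    stop("values must lie strictly inside the bounds: x = ",
         paste(signif(x[x <= lo | x >= hi], 6), collapse = ", "))
  u <- (x - lo) / (hi - lo)
  10 * log(u / (1 - u))
}

#' Inverse scaled logit transform
#'
#' @param theta Numeric vector (any finite values).
#' @param lo,hi Interval bounds.
#' @return Values strictly inside `(lo, hi)`.
#' @export
inverse_scaled_logit <- function(theta, lo, hi) {
  lo + (hi - lo) * stats::plogis(theta / 10)
}

#' Map SGM parameters to unconstrained coordinates and back
#'
#' `sgm_to_theta` applies the scaled logit componentwise using the bounds;
#' `theta_to_sgm` inverts it, always landing strictly inside the box.
#'
#' @param params `sgm_params` (or named vector).
#' @param theta Length-7 numeric vector (ordering `tau_e, tau_i, alpha,
#'   speed, g_ei, g_ii, tau_G`), or an n x 7 matrix of rows to transform.
#' @param bounds `sgm_bounds`.
#' @return A length-7 numeric (or matrix) for `sgm_to_theta`; `sgm_params`
#'   (or matrix of parameter rows) for `theta_to_sgm`.
#' @export
sgm_to_theta <- function(params, bounds = default_bounds()) {
  p <- unclass(as_sgm_params(params))
  unname(scaled_logit(p, bounds$lower, bounds$upper))
}

#' @rdname sgm_to_theta
#' @export
theta_to_sgm <- function(theta, bounds = default_bounds()) {
  if (is.matrix(theta)) {
    s <- t(apply(theta, 1, inverse_scaled_logit, lo = bounds$lower,
                 hi = bounds$upper))
    colnames(s) <- .sgm_param_names
    return(s)
  }
  as_sgm_params(stats::setNames(
    inverse_scaled_logit(theta, bounds$lower, bounds$upper),
    .sgm_param_names))
}

#' Log absolute Jacobian determinant of the bounded-to-unconstrained map
#'
#' The componentwise scaled logit has diagonal Jacobian with entries
#' `10 / ((hi - lo) * u * (1 - u))`, so the log absolute determinant is the
#' sum of their logs. Used to transform posterior densities between the
#' unconstrained and bounded parameterizations.
#'
#' @param params `sgm_params` strictly inside the bounds.
#' @param bounds `sgm_bounds`.
#' @return A scalar, `sum(log(10 / ((hi - lo) * u * (1 - u))))`.
#' @export
log_abs_det_jacobian <- function(params, bounds = default_bounds()) {
  p <- unclass(as_sgm_params(params))
  lo <- bounds$lower; hi <- bounds$upper
  if (any(p <= lo | p >= hi))
    stop("parameters on or outside the bounds; Jacobian undefined")
  u <- (p - lo) / (hi - lo)
  sum(log(10 / ((hi - lo) * u * (1 - u))))
}

#' Draw from the Gaussian prior on unconstrained parameters
#'
#' The prior on the unconstrained coordinates is N(0, 100 I): independent
#' normals with standard deviation 10 in each of the 7 dimensions. Mapped
#' through the inverse scaled logit this induces a heavy-shouldered prior
#' over the parameter box that never violates the bounds.
#'
#' @param m Number of draws.
#' @param seed Integer seed.
#' @param sd Prior standard deviation (default 10).
#' @return An `m x 7` matrix of unconstrained draws.
#' @export
sample_prior <- function(m, seed = 1L, sd = 10) {
  stopifnot(m >= 1)
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  matrix(stats::rnorm(m * 7, 0, sd), nrow = m,
         dimnames = list(NULL, .sgm_param_names))
}
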