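#' Frequency grid for spectral evaluation
#'
#' @param fmin,fmax Band edges in Hz (defaults 2 and 45).
#' @param n_freq Number of equally spaced frequencies (default 40).
#' @param frequencies_hz Alternatively, an explicit strictly increasing
#'   positive frequency vector.
#' @return Object of class `sgm_grid`: list with `frequencies_hz` and the
#'   derived angular frequencies `angular` (rad/s).
#' @export
frequency_grid <- function(fmin = 2, fmax = 45, n_freq = 40,
                           frequencies_hz = NULL) {
  f <- if (is.null(frequencies_hz)) seq(fmin, fmax, length.out = n_freq)
       else as.numeric(frequencies_hz)
  if (any(f <= 0) || any(diff(f) <= 0))
    stop("frequencies must be positive and strictly increasing")
  structure(list(frequencies_hz = f, angular = 2 * pi * f),
            class = "sgm_grid")
}

#' Gamma-kernel frequency response
#'
#' Fourier transform of the gamma-shaped neural impulse response
#' `f(t) = t / tau^2 * exp(-t / tau)`:
#' `F(omega) = (1 / tau^2) / (1i * omega + 1 / tau)^2`.
#' A unit-gain low-pass kernel: `|F| <= F(0) = 1`.
#'
#' @param tau Time constant in seconds (> 0).
#' @param omega Angular frequencies (rad/s), vectorized.
#' @return Complex response values.
#' @export
gamma_response <- function(tau, omega) {
  if (tau <= 0) stop("time constant must be positive")
  (1 / tau^2) / (1i * omega + 1 / tau)^2
}

#' Complex (delayed) graph Laplacian
#'
#' Builds `L(alpha, v; omega) = I - alpha * C*(omega)` where `C*(omega)` is
#' the degree-normalized connectivity whose entries carry conduction-delay
#' phase factors `exp(-1i * omega * d_ij / v)`. Distances are stored in mm
#' and converted to metres so delays are `d / v` seconds with `v` in m/s.
#' Degrees are computed from the delay-free weights; normalization is
#' symmetric (`w_ij / sqrt(deg_i deg_j)`) by default, with row-degree as an
#' option.
#'
#' @param conn `sgm_connectome`.
#' @param alpha Long-range coupling constant.
#' @param speed Conduction speed in m/s (> 0).
#' @param omega Angular frequency (rad/s), scalar.
#' @param norm `"symmetric"` (default) or `"row"` degree normalization.
#' @return N x N complex matrix.
#' @export
complex_laplacian <- function(conn, alpha, speed, omega,
                              norm = c("symmetric", "row")) {
  norm <- match.arg(norm)
  if (speed <= 0) stop("speed must be positive")
  cn <- degree_normalize(conn$weights, scheme = switch(norm, symmetric = "symmetric", row = "row"))
  attributes(cn) <- list(dim = dim(cn))
  phase <- exp(-1i * omega * (conn$distances / 1000) / speed)
  diag(1 + 0i, conn$n_regions) - alpha * (unclass(cn) * unname(phase))
}

# Frequency-independent pieces of the Laplacian, for reuse across a grid.
.laplacian_parts <- function(conn, norm = "symmetric") {
  list(cn = degree_normalize(conn$weights,
                             scheme = if (norm == "symmetric") "symmetric" else "row"),
       dist_m = conn$distances / 1000,
       n = conn$n_regions)
}

#' Mesoscopic excitatory-inhibitory transfer function
#'
#' Scalar complex gain of the local two-population loop. With gamma-kernel
#' synaptic responses `Fe`, `Fi` (see [gamma_response()]), excitatory
#' self-gain fixed at 1, alternating gain `g_ei` coupling the populations
#' in both directions, and inhibitory self-gain `g_ii`, the
#' frequency-domain population equations
#' \deqn{j\omega X_e = -(F_e/\tau_e) X_e - (g_{ei} F_i/\tau_e) X_i + P}
#' \deqn{j\omega X_i = +(g_{ei} F_e/\tau_i) X_e - (g_{ii} F_i/\tau_i) X_i + P}
#' solve to `He = Xe/P`, `Hi = Xi/P`, and the local transfer function is
#' their sum `Hlocal = He + Hi`.
#'
#' @param tau_e,tau_i Time constants in seconds (> 0).
#' @param g_ei,g_ii Gains (>= 0).
#' @param omega Angular frequencies (rad/s), vectorized.
#' @return Complex vector of gains.
#' @export
local_transfer <- function(tau_e, tau_i, g_ei, g_ii, omega) {
  if (tau_e <= 0 || tau_i <= 0) stop("time constants must be positive")
  if (g_ei < 0 || g_ii < 0) stop("gains must be nonnegative")
  fe <- gamma_response(tau_e, omega)
  fi <- gamma_response(tau_i, omega)
  jw <- 1i * omega
  ae <- jw + fe / tau_e
  ai <- jw + g_ii * fi / tau_i
  he <- (1 - g_ei * fi / (tau_e * ai)) /
        (ae + g_ei^2 * fe * fi / (tau_e * tau_i * ai))
  hi <- (1 + g_ei * (fe / tau_i) * he) / ai
  he + hi
}

#' Stability of the mesoscopic loop
#'
#' The local loop is stable iff every pole of its transfer function lies in
#' the open left half plane. Clearing the gamma-kernel denominators, the
#' characteristic function becomes the degree-6 polynomial
#' `A(s) * B(s) + g_ei^2 * a^3 * b^3` with `a = 1/tau_e`, `b = 1/tau_i`,
#' `A(s) = s(s+a)^2 + a^3` and `B(s) = s(s+b)^2 + g_ii * b^3`. All six
#' roots must satisfy `Re(root) < -1e-9`. For `g_ei -> 0` this reduces to
#' the classical boundary `g_ii < 2`.
#'
#' @param params `sgm_params` (only `tau_e`, `tau_i`, `g_ei`, `g_ii` are
#'   used).
#' @param tol Pole real-part tolerance (default `-1e-9`).
#' @return Logical: `TRUE` iff stable.
#' @export
stability_check <- function(params, tol = -1e-9) {
  p <- as_sgm_params(params)
  a <- 1 / p[["tau_e"]]; b <- 1 / p[["tau_i"]]
  ca <- c(a^3, a^2, 2 * a, 1)                 # ascending coefficients of A
  cb <- c(p[["g_ii"]] * b^3, b^2, 2 * b, 1)   # ascending coefficients of B
  cc <- .poly_mult(ca, cb)
  cc[1] <- cc[1] + p[["g_ei"]]^2 * a^3 * b^3
  # scale to unit leading coefficient for root-finder conditioning
  roots <- polyroot(cc / cc[length(cc)])
  all(Re(roots) < tol)
}

.poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Closed-form SGM spectrum on a connectome
#'
#' For each angular frequency `omega` in the grid, solves
#' \deqn{X(\omega) = [j\omega I + (1/\tau_G) F_G(\omega) L(\omega)]^{-1}
#'   H_{local}(\omega) P(\omega)}
#' yielding the complex regional spectrum, and the PSD in dB as
#' `20*log10(|X|)`. `method = "direct"` solves the linear system per
#' frequency; `method = "eigen"` diagonalizes the complex Laplacian per
#' frequency and solves in its eigenbasis (the delay phases make the
#' Laplacian frequency-dependent, so the decomposition is per-frequency).
#' The two paths agree to high precision and serve as mutual checks.
#'
#' @param params `sgm_params`.
#' @param conn `sgm_connectome`.
#' @param grid `sgm_grid` (default [frequency_grid()]).
#' @param noise Input noise spectrum `P(omega)`: scalar 1 for white unit
#'   input (default), or an N x F complex (or numeric) matrix.
#' @param method `"direct"` (default) or `"eigen"`.
#' @param norm Laplacian degree normalization (see [complex_laplacian()]).
#' @return Object of class `sgm_spectrum`: list with `complex_spectrum`
#'   (N x F complex), `psd_db` (N x F real), `grid`, `params`.
#' @export
forward_spectrum <- function(params, conn, grid = frequency_grid(),
                             noise = 1, method = c("direct", "eigen"),
                             norm = "symmetric") {
  method <- match.arg(method)
  params <- as_sgm_params(params)
  n <- conn$n_regions
  nf <- length(grid$frequencies_hz)
  P <- if (is.matrix(noise)) {
    stopifnot(nrow(noise) == n, ncol(noise) == nf)
    noise
  } else {
    matrix(noise, n, nf)
  }
  parts <- .laplacian_parts(conn, norm)
  attributes(parts$cn) <- list(dim = dim(parts$cn))
  dimnames(parts$dist_m) <- NULL
  tau_G <- params[["tau_G"]]
  hl <- local_transfer(params[["tau_e"]], params[["tau_i"]],
                       params[["g_ei"]], params[["g_ii"]], grid$angular)
  fg <- gamma_response(tau_G, grid$angular)
  X <- matrix(0i, n, nf)
  eye <- diag(1 + 0i, n)
  for (f in seq_len(nf)) {
    w <- grid$angular[f]
    L <- eye - params[["alpha"]] *
      (parts$cn * exp(-1i * w * parts$dist_m / params[["speed"]]))
    M <- 1i * w * eye + (fg[f] / tau_G) * L
    b <- hl[f] * P[, f]
    X[, f] <- if (method == "direct") {
      tryCatch(solve(M, b),
               error = function(e) stop("singular system at ",
                                        signif(grid$frequencies_hz[f], 4),
                                        " Hz: ", conditionMessage(e)))
    } else {
      ed <- eigen(L)
      coef <- tryCatch(solve(ed$vectors, b),
                       error = function(e) stop("degenerate eigenbasis at ",
                                                signif(grid$frequencies_hz[f], 4),
                                                " Hz: ", conditionMessage(e)))
      drop(ed$vectors %*% (coef / (1i * w + (fg[f] / tau_G) * ed$values)))
    }
  }
  rownames(X) <- conn$labels
  structure(list(complex_spectrum = X, psd_db = to_db(X), grid = grid,
                 params = params),
            class = "sgm_spectrum")
}

#' @export
print.sgm_spectrum <- function(x, ...) {
  cat(sprintf("SGM spectrum: %d regions x %d frequencies (%.3g-%.3g Hz)\n",
              nrow(x$psd_db), ncol(x$psd_db),
              min(x$grid$frequencies_hz), max(x$grid$frequencies_hz)))
  cat(sprintf("  PSD range [%.4g, %.4g] dB\n", min(x$psd_db), max(x$psd_db)))
  invisible(x)
}

#' Magnitude spectrum to dB
#'
#' `20 * log10(|X| + 1e-20)`; the floor keeps exact zeros finite.
#'
#' @param spectrum Complex (or numeric magnitude) matrix.
#' @return Real matrix of the same shape, in dB.
#' @export
to_db <- function(spectrum) {
  if (any(!is.finite(Mod(spectrum)))) stop("non-finite spectrum")
  20 * log10(Mod(spectrum) + 1e-20)
}
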