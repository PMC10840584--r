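test_that("gamma response is a unit-gain low-pass kernel", {
  expect_equal(gamma_response(0.01, 0), 1 + 0i)
  # frozen from independent complex arithmetic at tau = 0.01, f = 10 Hz
  expect_equal(gamma_response(0.01, 2 * pi * 10),
               0.31109730673933295 - 0.6459454460491604i, tolerance = 1e-12)
  expect_equal(Mod(gamma_response(0.01, 2 * pi * 10)), 0.7169568,
               tolerance = 1e-6)
  mags <- Mod(gamma_response(0.01, c(0, 10, 100, 1000)))
  expect_true(all(diff(mags) < 0))
  expect_lte(max(mags), 1)
  expect_error(gamma_response(0, 1), "positive")
})

test_that("complex Laplacian reduces correctly and matches a literal loop", {
  conn <- small_conn(5, seed = 11)
  expect_equal(complex_laplacian(conn, 0, 10, 50), diag(1 + 0i, 5))

  # omega = 0: real, eigenvalues within [0, 1 + alpha] under symmetric norm
  for (s in 1:5) {
    cz <- small_conn(10, seed = 100 + s)
    alpha <- runif(1, 0.1, 1)
    L0 <- complex_laplacian(cz, alpha, 10, 0)
    expect_equal(max(abs(Im(L0))), 0)
    ev <- eigen(Re(L0), only.values = TRUE)$values
    expect_true(all(ev > -1e-12 & ev < 1 + alpha + 1e-12))
  }

  # entrywise equality with an unvectorized construction
  alpha <- 0.7; v <- 8; w <- 2 * pi * 17
  L <- complex_laplacian(conn, alpha, v, w)
  deg <- rowSums(conn$weights)
  ref <- matrix(0i, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    cij <- conn$weights[i, j] / sqrt(deg[i] * deg[j])
    delay <- (conn$distances[i, j] / 1000) / v
    ref[i, j] <- (i == j) - alpha * cij * exp(-1i * w * delay)
  }
  expect_equal(unname(L), ref, tolerance = 1e-12)
  expect_error(complex_laplacian(conn, 0.5, 0, 1), "speed")
})

test_that("local transfer matches the independent linear-system oracle", {
  set.seed(2)
  for (rep in 1:10) {
    p <- theta_to_sgm(rnorm(7, 0, 10))
    for (w in c(0.1, 2 * pi * c(2, 10, 45))) {
      expect_equal(local_transfer(p[["tau_e"]], p[["tau_i"]],
                                  p[["g_ei"]], p[["g_ii"]], w),
                   local_transfer_oracle(p[["tau_e"]], p[["tau_i"]],
                                         p[["g_ei"]], p[["g_ii"]], w),
                   tolerance = 1e-10)
    }
  }
  # high-frequency rolloff
  r <- Mod(local_transfer(0.01, 0.1, 0.3, 1, 1e5)) /
       Mod(local_transfer(0.01, 0.1, 0.3, 1, 1e3))
  expect_lt(r, 1e-2)
  h <- local_transfer(0.0175, 0.1025, 0.3505, 1.0005, default_grid$angular)
  expect_true(all(is.finite(Mod(h))))
  expect_error(local_transfer(-0.01, 0.1, 0.3, 1, 1), "positive")
})

test_that("stability predicate agrees with the companion-matrix oracle", {
  # minimal gains at midpoint time constants: stable
  p0 <- midpoint_params()
  p0[["g_ei"]] <- 0.001; p0[["g_ii"]] <- 0.001
  expect_true(stability_check(p0))
  expect_true(stability_oracle(0.0175, 0.1025, 0.001, 0.001))

  set.seed(9)
  agree <- 0L
  for (rep in 1:40) {
    p <- theta_to_sgm(rnorm(7, 0, 10))
    expect_identical(stability_check(p),
                     stability_oracle(p[["tau_e"]], p[["tau_i"]],
                                      p[["g_ei"]], p[["g_ii"]]))
    agree <- agree + 1L
  }
  expect_equal(agree, 40L)

  # doubling the gains (clipped to bounds) never restores stability
  b <- default_bounds()
  set.seed(10)
  found <- 0L
  while (found < 10L) {
    p <- theta_to_sgm(rnorm(7, 0, 10))
    if (!stability_check(p)) {
      found <- found + 1L
      p[["g_ei"]] <- min(2 * p[["g_ei"]], b$upper[["g_ei"]])
      p[["g_ii"]] <- min(2 * p[["g_ii"]], b$upper[["g_ii"]])
      expect_false(stability_check(p))
    }
  }
  # deterministic
  expect_identical(stability_check(p0), stability_check(p0))
})

test_that("forward spectrum paths agree and the model is linear in the input", {
  p <- midpoint_params()
  for (s in 1:3) {
    conn <- small_conn(10, seed = 200 + s)
    sd_ <- forward_spectrum(p, conn, default_grid, method = "direct")
    se <- forward_spectrum(p, conn, default_grid, method = "eigen")
    rel <- max(Mod(sd_$complex_spectrum - se$complex_spectrum) /
               Mod(sd_$complex_spectrum))
    expect_lt(rel, 1e-8)
  }
  conn <- small_conn(10, seed = 201)
  sp <- forward_spectrum(p, conn, default_grid)
  expect_equal(dim(sp$complex_spectrum), c(10L, 40L))
  expect_equal(dim(sp$psd_db), c(10L, 40L))
  expect_true(all(is.finite(sp$psd_db)))

  sp2 <- forward_spectrum(p, conn, default_grid, noise = 2)
  expect_equal(Mod(sp2$complex_spectrum), 2 * Mod(sp$complex_spectrum),
               tolerance = 1e-12)
  lam <- 3.7
  sp3 <- forward_spectrum(p, conn, default_grid,
                          noise = matrix(lam, 10, 40))
  expect_equal(sp3$complex_spectrum, lam * sp$complex_spectrum,
               tolerance = 1e-12)
})

test_that("dB conversion follows the 20 log10 magnitude convention", {
  expect_equal(to_db(matrix(1 + 0i)), matrix(0), tolerance = 1e-12)
  expect_equal(to_db(matrix(10 + 0i)), matrix(20), tolerance = 1e-12)
  expect_equal(to_db(matrix(0i)), matrix(-400))  # floored, finite
  x <- matrix(complex(modulus = c(5, 2, 9, 0.1), argument = c(0, 1, 2, 3)), 2)
  expect_true(all(order(to_db(x)) == order(Mod(x))))
})
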