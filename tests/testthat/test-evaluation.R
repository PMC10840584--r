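test_that("per-region PSD correlation matches the Pearson formula", {
  set.seed(14)
  obs <- matrix(rnorm(3 * 10), 3)
  expect_equal(psd_correlation(obs, obs)$per_roi, rep(1, 3))
  expect_equal(psd_correlation(obs, obs)$mean, 1)
  expect_equal(psd_correlation(-obs, obs)$per_roi, rep(-1, 3))

  rec <- matrix(c(1, 3, 2, 5, 0, 1, 1, 2), 2, byrow = TRUE)
  ob2 <- matrix(c(2, 2, 1, 4, 1, 0, 3, 1), 2, byrow = TRUE)
  manual <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  pc <- psd_correlation(rec, ob2)
  expect_equal(pc$per_roi, c(manual(rec[1, ], ob2[1, ]),
                             manual(rec[2, ], ob2[2, ])), tolerance = 1e-12)
  expect_equal(pc$mean, mean(pc$per_roi), tolerance = 1e-12)

  # zero-variance region is excluded from the mean, not fabricated
  flat <- rec; flat[2, ] <- 5
  pf <- psd_correlation(flat, ob2)
  expect_true(is.na(pf$per_roi[2]))
  expect_equal(pf$mean, pf$per_roi[1])
})

test_that("spatial correlation is a weighted cosine with the expected limits", {
  conn <- small_conn(3, seed = 61)
  a <- c(1.2, -0.3, 0.8)
  expect_equal(spatial_correlation(a, a, conn), 1, tolerance = 1e-12)

  # empty graph: reduces to plain cosine for any w > 0
  empty <- connectome(matrix(0, 3, 3), conn$distances)
  b <- c(0.5, 1, -0.2)
  cosab <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(spatial_correlation(a, b, empty, w = 10), cosab,
               tolerance = 1e-12)
  expect_equal(spatial_correlation(a, b, empty, w = 2), cosab,
               tolerance = 1e-12)

  # hand computation with the explicit symmetrized W
  D <- degree_normalize(conn$weights, "row")
  W <- D + diag(10, 3); W <- (W + t(W)) / 2
  manual <- drop(a %*% W %*% b) /
    sqrt(drop(a %*% W %*% a) * drop(b %*% W %*% b))
  expect_equal(spatial_correlation(a, b, conn), manual, tolerance = 1e-12)
  # symmetric in its vector arguments; bounded
  expect_equal(spatial_correlation(a, b, conn),
               spatial_correlation(b, a, conn), tolerance = 1e-12)
  expect_lte(abs(spatial_correlation(a, b, conn)), 1 + 1e-12)
  expect_error(spatial_correlation(rep(0, 3), b, conn), "zero")
})

test_that("partial correlations invert the covariance correctly", {
  set.seed(15)
  z <- matrix(rnorm(1e5 * 7), ncol = 7)
  pc <- partial_correlation_matrix(z)
  expect_equal(diag(pc), rep(1, 7))
  expect_equal(pc, t(pc))
  expect_lt(max(abs(pc[upper.tri(pc)])), 0.02)

  # exact affine invariance
  zz <- sweep(sweep(z, 2, c(2, 3, 0.1, 5, 1, 7, 0.5), "*"),
              2, c(1, -2, 0, 4, 0, 0, 9), "+")
  expect_equal(partial_correlation_matrix(zz), pc, tolerance = 1e-9)

  # known precision matrix: AR(1)-like tridiagonal
  Om <- diag(4); Om[cbind(1:3, 2:4)] <- Om[cbind(2:4, 1:3)] <- -0.4
  Sig <- solve(Om)
  ch <- chol(Sig)
  x <- matrix(rnorm(1e5 * 4), ncol = 4) %*% ch
  pcx <- partial_correlation_matrix(x)
  target <- -Om / sqrt(diag(Om) %o% diag(Om)); diag(target) <- 1
  expect_equal(pcx, target, tolerance = 0.02, ignore_attr = TRUE)

  # two parameters: partial correlation equals plain Pearson correlation
  x2 <- x[, 1:2]
  expect_equal(partial_correlation_matrix(x2)[1, 2], cor(x2)[1, 2],
               tolerance = 1e-10)

  expect_error(partial_correlation_matrix(cbind(z[, 1], z[, 1], z[, 2])),
               "singular|degenerate")
})

test_that("method comparison is a symmetric two-sided Welch test", {
  a <- c(0.8, 0.85, 0.9, 0.82)
  expect_equal(compare_methods(a, a), 1)
  b <- a + 0.01
  expect_equal(compare_methods(a, b), compare_methods(b, a))
  set.seed(16)
  g1 <- rnorm(50); g2 <- rnorm(50, 3)
  expect_lt(compare_methods(g1, g2), 1e-6)
  expect_equal(compare_methods(g1, g2),
               t.test(g1, g2, var.equal = FALSE)$p.value)
  expect_equal(compare_methods(rep(1, 3), rep(1, 4)), 1)
  expect_equal(compare_methods(rep(1, 3), rep(2, 4)), 0)
})

test_that("evaluation reports bundle the statistics with correct ranges", {
  conn <- small_conn(6, seed = 62)
  subj <- make_synthetic_subject(conn, 0.4, seed = 17)
  other <- make_synthetic_subject(conn, 0.4, seed = 18)
  set.seed(19)
  draws <- matrix(rnorm(500 * 7), ncol = 7,
                  dimnames = list(NULL, names(subj$params)))
  ev <- evaluation_report(other$y_obs, subj$y_obs, conn, s_draws = draws)
  expect_true(all(abs(ev$per_roi_r) <= 1 + 1e-12))
  expect_true(abs(ev$spatial_r) <= 1 + 1e-12)
  expect_equal(dim(ev$partial_corr), c(7L, 7L))
  self <- evaluation_report(subj$y_obs, subj$y_obs, conn)
  expect_equal(self$mean_r, 1, tolerance = 1e-12)
  expect_equal(self$spatial_r, 1, tolerance = 1e-12)
})
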