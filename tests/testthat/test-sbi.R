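# Shared tiny training setup reused across blocks in this file.
.sbi_conn <- small_conn(10, seed = 77)
.sbi_ts <- simulate_training_set(3000, sigma = 0.5, .sbi_conn, default_grid,
                                 seed = 21, store_clean = TRUE)
.sbi_tp <- train_posterior(.sbi_ts, n_pca = 40, seed = 22, hidden = 48,
                           max_epochs = 60, patience = 10)

test_that("training-pair simulation is reproducible and noise is calibrated", {
  ts0 <- simulate_training_set(10, sigma = 0, .sbi_conn, default_grid,
                               seed = 5, store_clean = TRUE)
  ts0b <- simulate_training_set(10, sigma = 0, .sbi_conn, default_grid,
                                seed = 5, store_clean = TRUE)
  expect_identical(ts0$features, ts0b$features)
  expect_identical(ts0$thetas, ts0b$thetas)
  expect_equal(ts0$features, ts0$clean)  # sigma = 0: noiseless

  ts16 <- simulate_training_set(150, sigma = 1.6, .sbi_conn, default_grid,
                                seed = 6, store_clean = TRUE)
  resid <- ts16$features - ts16$clean
  expect_gt(sd(resid), 1.55)
  expect_lt(sd(resid), 1.65)
  expect_equal(ncol(ts16$features), 10 * 40 + 10)
})

test_that("one trained posterior is amortized across observations", {
  for (s in 1:3) {
    subj <- make_synthetic_subject(.sbi_conn, 0.5, seed = 400 + s)
    ps <- sample_posterior(.sbi_tp, subj$y_obs, n = 200, seed = s)
    expect_s3_class(ps, "sgm_posterior_samples")
    b <- default_bounds()
    for (j in 1:7) {
      expect_true(all(ps$s_draws[, j] > b$lower[j]))
      expect_true(all(ps$s_draws[, j] < b$upper[j]))
    }
    ret <- ps$s_draws[ps$stable, , drop = FALSE]
    ok <- vapply(seq_len(nrow(ret)),
                 function(i) stability_check(ret[i, ]), logical(1))
    expect_true(all(ok))
  }
  subj <- make_synthetic_subject(.sbi_conn, 0.5, seed = 404)
  a <- sample_posterior(.sbi_tp, subj$y_obs, n = 50, seed = 11)
  b2 <- sample_posterior(.sbi_tp, subj$y_obs, n = 50, seed = 11)
  expect_identical(a$theta_draws, b2$theta_draws)
})

test_that("posterior contracts relative to the prior", {
  # average posterior sd in unconstrained space, over several observations,
  # is below the prior sd of 10 for every parameter
  sds <- sapply(c(500, 501, 502, 503), function(s) {
    subj <- make_synthetic_subject(.sbi_conn, 0.5, seed = s)
    ps <- sample_posterior(.sbi_tp, subj$y_obs, n = 500, seed = 2)
    apply(ps$theta_draws, 2, sd)
  })
  expect_true(all(rowMeans(sds) < 10))
})

test_that("layout mismatches are a hard error", {
  other <- small_conn(12, seed = 3)
  subj <- make_synthetic_subject(other, 0.5, seed = 1)
  expect_error(sample_posterior(.sbi_tp, subj$y_obs, n = 10),
               "layout mismatch")
})

test_that("posterior predictive summarizes the feature stack coherently", {
  subj <- make_synthetic_subject(.sbi_conn, 0.5, seed = 600)
  ps <- sample_posterior(.sbi_tp, subj$y_obs, n = 100, seed = 3)
  pp <- posterior_predictive(ps, .sbi_conn, default_grid, max_draws = 40)
  expect_equal(length(pp$mean), 10 * 40 + 10)
  # mean inside the pointwise envelope; 95% band contains the mean
  expect_true(all(pp$mean >= apply(pp$features, 2, min) - 1e-12))
  expect_true(all(pp$mean <= apply(pp$features, 2, max) + 1e-12))
  expect_true(all(pp$lower <= pp$mean & pp$mean <= pp$upper))

  # single retained draw: the mean is that draw's features exactly
  one <- ps
  keep <- which(ps$stable)[1]
  one$stable <- rep(FALSE, ps$n); one$stable[keep] <- TRUE
  one$retained <- 1L
  pp1 <- posterior_predictive(one, .sbi_conn, default_grid)
  y1 <- forward_spectrum(ps$s_draws[keep, ], .sbi_conn, default_grid)
  yf <- build_features(y1$psd_db, default_grid)
  expect_equal(pp1$mean, unclass(yf), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("SBC ranks stay in range and uniformity testing is well-formed", {
  ranks <- sbc_calibration(.sbi_tp, .sbi_conn, default_grid, sigma = 0.5,
                           n_replicates = 25, n_draws = 40, seed = 31)
  expect_true(all(ranks >= 0 & ranks <= 40))
  expect_equal(dim(ranks), c(25L, 7L))
  u <- sbc_uniformity(ranks, n_bins = 5)
  expect_equal(nrow(u), 7)
  expect_true(all(u$p_value >= 0 & u$p_value <= 1))
})
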