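#' Synthetic subject with known ground-truth parameters
#'
#' Emulates the generative process the inference assumes: a ground-truth
#' parameter vector (drawn from the prior with stability rejection when
#' not supplied), its noiseless forward features on the subject's
#' connectome, plus i.i.d. Gaussian feature noise of sd `sigma`.
#'
#' @param conn `sgm_connectome`.
#' @param sigma Feature-noise sd (>= 0).
#' @param seed Integer seed (truth draw and noise).
#' @param params Optional `sgm_params` ground truth (must be stable).
#' @param grid `sgm_grid`.
#' @param bounds `sgm_bounds`.
#' @return Object of class `sgm_subject`: `params` (truth), `theta`
#'   (unconstrained truth), `y_obs` (`sgm_features` + noise), `y_clean`,
#'   `sigma`, `seed`.
#' @export
make_synthetic_subject <- function(conn, sigma, seed = 1L, params = NULL,
                                   grid = frequency_grid(),
                                   bounds = default_bounds()) {
  stopifnot(sigma >= 0)
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  if (is.null(params)) {
    for (try in seq_len(1000L)) {
      th <- stats::rnorm(7, 0, 10)
      cand <- theta_to_sgm(th, bounds)
      if (stability_check(cand)) { params <- cand; break }
    }
    if (is.null(params))
      stop("1000 consecutive unstable prior draws; check the bounds")
  } else {
    params <- as_sgm_params(params)
    if (!stability_check(params)) stop("supplied ground truth is unstable")
    th <- sgm_to_theta(params, bounds)
  }
  y_clean <- .sgm_features_at(params, conn, grid)
  y_obs <- y_clean
  y_obs[] <- unclass(y_clean) + stats::rnorm(length(y_clean), 0, sigma)
  structure(list(params = params, theta = th, y_obs = y_obs,
                 y_clean = y_clean, sigma = sigma, seed = seed),
            class = "sgm_subject")
}

#' @export
print.sgm_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject (sigma = %g, seed = %d)\n", x$sigma, x$seed))
  print(x$params)
  invisible(x)
}

#' End-to-end parameter-recovery experiment
#'
#' Trains one amortized posterior on a template connectome, then infers a
#' cohort of synthetic subjects with known ground truth, reporting
#' per-parameter 95% credible-interval coverage of the truth,
#' truth-vs-posterior-mean correlation across subjects, and
#' simulation-based-calibration ranks.
#'
#' @param n_subjects Number of synthetic subjects (default 20).
#' @param m_train Number of training simulations (default 5000).
#' @param sigma Feature-noise sd used both for training and for subject
#'   observations (default 0.5).
#' @param conn Template `sgm_connectome`.
#' @param n_draws Posterior draws per subject (default 1000).
#' @param seed Integer seed driving the whole experiment.
#' @param grid `sgm_grid`.
#' @param n_sbc Number of SBC replicates (default 200; 0 disables).
#' @param n_sbc_draws Posterior draws per SBC replicate (default 100).
#' @param subject_conn Optional connectome (or list of connectomes) for
#'   the subjects, emulating the template/individual split; defaults to
#'   the template.
#' @param tp Optional pre-trained `sgm_posterior` to reuse (skips
#'   simulation + training).
#' @param ... Passed to [train_posterior()].
#' @return Object of class `sgm_recovery_report`: per-parameter coverage,
#'   truth/posterior-mean correlations, interval table, SBC ranks and
#'   uniformity tests, and the trained posterior.
#' @export
recovery_experiment <- function(n_subjects = 20L, m_train = 5000L,
                                sigma = 0.5, conn, n_draws = 1000L,
                                seed = 1L, grid = frequency_grid(),
                                n_sbc = 200L, n_sbc_draws = 100L,
                                subject_conn = NULL, tp = NULL, ...) {
  stopifnot(n_subjects >= 1, m_train >= 1, n_draws >= 1)
  bounds <- default_bounds()
  if (is.null(tp)) {
    ts <- simulate_training_set(m_train, sigma, conn, grid,
                                seed = seed)
    tp <- train_posterior(ts, seed = seed + 1L, ...)
  }
  if (is.null(subject_conn)) subject_conn <- conn
  conn_for <- function(i) {
    if (inherits(subject_conn, "sgm_connectome")) subject_conn
    else subject_conn[[((i - 1L) %% length(subject_conn)) + 1L]]
  }

  truths <- post_mean <- matrix(NA_real_, n_subjects, 7,
                                dimnames = list(NULL, .sgm_param_names))
  lo <- hi <- covered <- matrix(NA_real_, n_subjects, 7,
                                dimnames = list(NULL, .sgm_param_names))
  for (i in seq_len(n_subjects)) {
    subj <- make_synthetic_subject(conn_for(i), sigma, seed = seed + 100L + i,
                                   grid = grid, bounds = bounds)
    ps <- sample_posterior(tp, subj$y_obs, n = n_draws, bounds = bounds,
                           seed = seed + 10000L + i)
    sd_ret <- ps$s_draws[ps$stable, , drop = FALSE]
    truths[i, ] <- unclass(subj$params)
    post_mean[i, ] <- colMeans(sd_ret)
    lo[i, ] <- apply(sd_ret, 2, stats::quantile, 0.025)
    hi[i, ] <- apply(sd_ret, 2, stats::quantile, 0.975)
    covered[i, ] <- as.numeric(truths[i, ] >= lo[i, ] & truths[i, ] <= hi[i, ])
  }
  coverage <- colMeans(covered)
  truth_corr <- vapply(seq_len(7), function(j)
    stats::cor(truths[, j], post_mean[, j]), numeric(1))
  names(truth_corr) <- .sgm_param_names

  sbc <- sbc_p <- NULL
  if (n_sbc > 0) {
    sbc <- sbc_calibration(tp, conn, grid, sigma, n_replicates = n_sbc,
                           n_draws = n_sbc_draws, seed = seed + 50000L,
                           bounds = bounds)
    sbc_p <- sbc_uniformity(sbc)
  }

  structure(list(coverage = coverage, truth_corr = truth_corr,
                 truths = truths, post_mean = post_mean,
                 interval_lo = lo, interval_hi = hi,
                 sbc_ranks = sbc, sbc_uniformity = sbc_p,
                 posterior = tp, sigma = sigma,
                 n_subjects = n_subjects, m_train = m_train, seed = seed),
            class = "sgm_recovery_report")
}

#' @export
print.sgm_recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d subjects, %d training sims, sigma = %g\n",
              x$n_subjects, x$m_train, x$sigma))
  df <- data.frame(coverage_95 = round(x$coverage, 3),
                   truth_corr = round(x$truth_corr, 3))
  if (!is.null(x$sbc_uniformity))
    df$sbc_p <- round(x$sbc_uniformity$p_value, 3)
  print(df)
  invisible(x)
}

#' Write a recovery report as JSON
#'
#' One entry per parameter with coverage, truth correlation, per-subject
#' intervals, and SBC p-value.
#'
#' @param report `sgm_recovery_report`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_recovery_report <- function(report, path) {
  stopifnot(inherits(report, "sgm_recovery_report"))
  params <- lapply(seq_len(7), function(j) {
    entry <- list(
      coverage_95 = report$coverage[[j]],
      truth_corr = report$truth_corr[[j]],
      interval_lo = unname(report$interval_lo[, j]),
      interval_hi = unname(report$interval_hi[, j]),
      truth = unname(report$truths[, j]),
      posterior_mean = unname(report$post_mean[, j]))
    if (!is.null(report$sbc_uniformity))
      entry$sbc_p_value <- report$sbc_uniformity$p_value[j]
    entry
  })
  names(params) <- .sgm_param_names
  jsonlite::write_json(
    list(n_subjects = report$n_subjects, m_train = report$m_train,
         sigma = report$sigma, parameters = params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
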