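#' Simulate training pairs for amortized posterior estimation
#'
#' Draws unconstrained parameters from the Gaussian prior N(0, 100 I),
#' maps them through the inverse scaled logit into the bounded box,
#' evaluates the SGM forward model on the (template) connectome, builds
#' observation features, and adds i.i.d. Gaussian noise of standard
#' deviation `sigma` to every feature entry. Parameters whose forward
#' simulation fails (degenerate spectrum) are resampled, never silently
#' dropped; the number of resamples is recorded.
#'
#' @param m Number of pairs.
#' @param sigma Feature-noise standard deviation (the working default of
#'   this model family is 1.6; suggested range 0.8-2.0).
#' @param conn Template `sgm_connectome`.
#' @param grid `sgm_grid`.
#' @param seed Integer seed (drives both prior draws and noise).
#' @param bounds `sgm_bounds` (widest gain tier for inference).
#' @param store_clean Also keep the noiseless features (for diagnostics).
#' @return Object of class `sgm_training_set`: list with `thetas` (m x 7),
#'   `features` (m x (N*F+N)), `sigma`, `layout`, `seed`, `n_resampled`,
#'   and optionally `clean`.
#' @export
simulate_training_set <- function(m, sigma, conn, grid = frequency_grid(),
                                  seed = 1L, bounds = default_bounds(),
                                  store_clean = FALSE) {
  stopifnot(m >= 1, sigma >= 0)
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  nfeat <- conn$n_regions * length(grid$frequencies_hz) + conn$n_regions
  thetas <- matrix(NA_real_, m, 7,
                   dimnames = list(NULL, .sgm_param_names))
  features <- matrix(NA_real_, m, nfeat)
  clean <- if (store_clean) matrix(NA_real_, m, nfeat) else NULL
  n_resampled <- 0L
  for (i in seq_len(m)) {
    repeat {
      th <- stats::rnorm(7, 0, 10)
      s <- theta_to_sgm(th, bounds)
      y0 <- tryCatch(unclass(.sgm_features_at(s, conn, grid)),
                     error = function(e) NULL)
      if (!is.null(y0) && all(is.finite(y0))) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100 * m)
        stop("forward model failing persistently; check the connectome")
    }
    thetas[i, ] <- th
    if (store_clean) clean[i, ] <- y0
    features[i, ] <- y0 + stats::rnorm(nfeat, 0, sigma)
  }
  structure(list(thetas = thetas, features = features, sigma = sigma,
                 layout = feature_layout(conn$n_regions,
                                         length(grid$frequencies_hz)),
                 grid = grid, seed = seed, n_resampled = n_resampled,
                 clean = clean),
            class = "sgm_training_set")
}

#' @export
print.sgm_training_set <- function(x, ...) {
  cat(sprintf("SGM training set: %d pairs, %d features, sigma = %g\n",
              nrow(x$thetas), ncol(x$features), x$sigma))
  if (x$n_resampled > 0)
    cat("  resampled", x$n_resampled, "failed forward draws\n")
  invisible(x)
}

# Whitening preprocessor: center/scale features, project on the top
# principal components, rescale scores to unit variance.
.fit_whitener <- function(x, n_pca) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  n_pca <- min(n_pca, ncol(xs), nrow(xs) - 1L)
  sv <- svd(xs, nu = 0, nv = n_pca)
  score_sd <- sv$d[seq_len(n_pca)] / sqrt(nrow(xs) - 1)
  score_sd[score_sd < 1e-12] <- 1
  list(mu = mu, sd = sdv, rot = sv$v, score_sd = score_sd)
}

.apply_whitener <- function(w, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  xs <- sweep(sweep(x, 2, w$mu), 2, w$sd, "/")
  sweep(xs %*% w$rot, 2, w$score_sd, "/")
}

#' Train the amortized posterior estimator
#'
#' Fits the conditional density q(theta | y) on simulated pairs: features
#' are whitened (per-dimension standardization followed by PCA projection
#' to `n_pca` unit-variance scores), unconstrained parameters are scaled
#' by the prior standard deviation, and a full-covariance conditional
#' mixture density network is trained by maximum mean log-likelihood with
#' early stopping. Once trained, the estimator is amortized: it yields a
#' posterior for any observation with the same feature layout without
#' retraining.
#'
#' @param ts `sgm_training_set`.
#' @param n_pca Number of principal components of the feature matrix kept
#'   as network input (default 50, capped by the data).
#' @param seed Integer seed for network initialization/shuffling.
#' @param ... Passed to [mdn_fit()] (`n_components`, `hidden`,
#'   `learn_rate`, `batch_size`, `max_epochs`, `patience`, `val_frac`).
#' @return Object of class `sgm_posterior`: the fitted density estimator,
#'   whitener, feature-layout fingerprint, and training metadata.
#' @export
train_posterior <- function(ts, n_pca = 50L, seed = 1L, ...) {
  stopifnot(inherits(ts, "sgm_training_set"))
  wh <- .fit_whitener(ts$features, n_pca)
  z <- .apply_whitener(wh, ts$features)
  theta_scale <- 10
  fit <- mdn_fit(z, ts$thetas / theta_scale, seed = seed, ...)
  structure(list(mdn = fit, whitener = wh, theta_scale = theta_scale,
                 layout = ts$layout,
                 metadata = list(m = nrow(ts$thetas), sigma = ts$sigma,
                                 sim_seed = ts$seed, train_seed = seed,
                                 n_pca = length(wh$score_sd),
                                 val_loss = fit$val_loss,
                                 train_trace = fit$train_trace,
                                 val_trace = fit$val_trace)),
            class = "sgm_posterior")
}

#' @export
print.sgm_posterior <- function(x, ...) {
  cat(sprintf(
    "Amortized SGM posterior: trained on %d pairs (sigma = %g, %d PCs)\n",
    x$metadata$m, x$metadata$sigma, x$metadata$n_pca))
  cat(sprintf("  validation loss %.4f\n", x$metadata$val_loss))
  invisible(x)
}

.check_layout <- function(tp, features) {
  lay <- attr(features, "layout")
  if (is.null(lay) && length(features) == tp$layout$length) return(invisible())
  if (is.null(lay) || !identical(lay[c("n_regions", "n_freqs", "length")],
                                 tp$layout[c("n_regions", "n_freqs", "length")]))
    stop("feature layout mismatch: the posterior was trained for ",
         tp$layout$n_regions, " regions x ", tp$layout$n_freqs,
         " frequencies (length ", tp$layout$length, ")")
  invisible()
}

#' Draw posterior samples for an observation
#'
#' Feeds the observed feature vector through the trained estimator, draws
#' `n` unconstrained samples, maps them through the inverse scaled logit
#' into the parameter box (this is the density-with-Jacobian posterior on
#' the bounded scale), and flags each draw with the mesoscopic stability
#' predicate. Retained draws are the stable ones.
#'
#' @param tp `sgm_posterior`.
#' @param y_obs Observed feature vector (layout must match training).
#' @param n Number of draws (default 1000).
#' @param bounds `sgm_bounds` (widest gain tier).
#' @param seed Integer seed.
#' @return Object of class `sgm_posterior_samples`: `theta_draws` (n x 7),
#'   `s_draws` (n x 7 bounded parameters), logical `stable`, `retained`
#'   count.
#' @export
sample_posterior <- function(tp, y_obs, n = 1000L, bounds = default_bounds(),
                             seed = 1L) {
  stopifnot(inherits(tp, "sgm_posterior"))
  .check_layout(tp, y_obs)
  z <- drop(.apply_whitener(tp$whitener, unclass(y_obs)))
  th <- mdn_sample(tp$mdn, z, n, seed = seed) * tp$theta_scale
  colnames(th) <- .sgm_param_names
  s <- theta_to_sgm(th, bounds)
  stable <- vapply(seq_len(n), function(i) stability_check(s[i, ]), logical(1))
  if (!any(stable))
    stop("no stable posterior draws; consider more training simulations ",
         "or a narrower gain tier")
  structure(list(theta_draws = th, s_draws = s, stable = stable,
                 retained = sum(stable), n = n, bounds = bounds),
            class = "sgm_posterior_samples")
}

#' @export
print.sgm_posterior_samples <- function(x, ...) {
  cat(sprintf("SGM posterior samples: %d draws, %d retained after stability filtering\n",
              x$n, x$retained))
  print(signif(apply(x$s_draws[x$stable, , drop = FALSE], 2, stats::quantile,
                     probs = c(0.025, 0.5, 0.975)), 3))
  invisible(x)
}

#' Posterior-predictive reconstruction of the observation features
#'
#' Pushes every retained posterior draw through the forward model on the
#' (individual) connectome and the feature map, and summarizes the
#' resulting feature stack: the pointwise mean is the reconstructed
#' standardized PSD / alpha distribution, with a 95% pointwise quantile
#' band.
#'
#' @param ps `sgm_posterior_samples`.
#' @param conn Connectome used for reconstruction (the individual's, which
#'   may differ from the training template).
#' @param grid `sgm_grid`.
#' @param max_draws Cap on the number of retained draws pushed through the
#'   forward model (default all).
#' @return Object of class `sgm_predictive`: `features` (draws x length
#'   matrix), `mean`, `lower`, `upper` (2.5%/97.5%), `layout`, `n_used`,
#'   `n_failed`.
#' @export
posterior_predictive <- function(ps, conn, grid = frequency_grid(),
                                 max_draws = Inf) {
  stopifnot(inherits(ps, "sgm_posterior_samples"), ps$retained >= 1)
  idx <- which(ps$stable)
  if (length(idx) > max_draws) idx <- idx[seq_len(max_draws)]
  rows <- vector("list", length(idx))
  failed <- 0L
  for (i in seq_along(idx)) {
    y <- tryCatch(unclass(.sgm_features_at(as_sgm_params(ps$s_draws[idx[i], ]),
                                           conn, grid)),
                  error = function(e) NULL)
    if (is.null(y)) failed <- failed + 1L else rows[[i]] <- y
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("all posterior-predictive forward runs failed")
  Y <- do.call(rbind, rows)
  structure(list(features = Y, mean = colMeans(Y),
                 lower = apply(Y, 2, stats::quantile, 0.025),
                 upper = apply(Y, 2, stats::quantile, 0.975),
                 layout = feature_layout(conn$n_regions,
                                         length(grid$frequencies_hz)),
                 n_used = nrow(Y), n_failed = failed),
            class = "sgm_predictive")
}

#' @export
print.sgm_predictive <- function(x, ...) {
  cat(sprintf("Posterior predictive: %d draws, feature length %d\n",
              x$n_used, length(x$mean)))
  invisible(x)
}

#' Simulation-based calibration of the trained posterior
#'
#' For each replicate, draws a ground-truth parameter from the prior,
#' simulates an observation at that truth, samples the trained posterior,
#' and records the rank of the truth among the draws per parameter. For a
#' calibrated estimator the ranks are uniform on {0, ..., n_draws}.
#' Replicate truths are drawn from the unrestricted prior (the estimator
#' is trained on the unrestricted prior too, so rank uniformity is exact
#' in the well-trained limit); ranks use the unfiltered draws.
#'
#' @param tp `sgm_posterior`.
#' @param conn Template connectome (must match training layout).
#' @param grid `sgm_grid`.
#' @param sigma Observation noise sd (use the training sigma).
#' @param n_replicates Number of SBC replicates (default 200).
#' @param n_draws Posterior draws per replicate (default 100).
#' @param seed Integer seed.
#' @param bounds `sgm_bounds`.
#' @return Matrix `n_replicates x 7` of integer ranks in
#'   `[0, n_draws]`, with attribute `n_draws`.
#' @export
sbc_calibration <- function(tp, conn, grid = frequency_grid(), sigma,
                            n_replicates = 200L, n_draws = 100L, seed = 1L,
                            bounds = default_bounds()) {
  stopifnot(inherits(tp, "sgm_posterior"))
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  nfeat <- tp$layout$length
  ranks <- matrix(NA_integer_, n_replicates, 7,
                  dimnames = list(NULL, .sgm_param_names))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  for (r in seq_len(n_replicates)) {
    repeat {
      th0 <- stats::rnorm(7, 0, 10)
      s0 <- theta_to_sgm(th0, bounds)
      y0 <- tryCatch(unclass(.sgm_features_at(s0, conn, grid)),
                     error = function(e) NULL)
      if (!is.null(y0) && all(is.finite(y0))) break
    }
    y <- y0 + stats::rnorm(nfeat, 0, sigma)
    z <- drop(.apply_whitener(tp$whitener, y))
    th <- mdn_sample(tp$mdn, z, n_draws, seed = rep_seeds[r]) * tp$theta_scale
    ranks[r, ] <- colSums(th < rep(th0, each = n_draws))
  }
  attr(ranks, "n_draws") <- n_draws
  ranks
}

#' Chi-square uniformity test of SBC ranks
#'
#' Bins the ranks of each parameter into `n_bins` bins (exact bin
#' probabilities over the `n_draws + 1` possible ranks) and applies a
#' chi-square goodness-of-fit test.
#'
#' @param ranks Output of [sbc_calibration()].
#' @param n_bins Number of rank bins (default 10).
#' @return Data frame with one row per parameter: chi-square statistic and
#'   p-value.
#' @export
sbc_uniformity <- function(ranks, n_bins = 10L) {
  n_draws <- attr(ranks, "n_draws")
  nvals <- n_draws + 1L
  edges <- floor(seq(0, nvals, length.out = n_bins + 1L))
  probs <- diff(edges) / nvals
  out <- data.frame(parameter = colnames(ranks), statistic = NA_real_,
                    p_value = NA_real_)
  for (j in seq_len(ncol(ranks))) {
    counts <- table(cut(ranks[, j], breaks = edges - 0.5,
                        include.lowest = TRUE))
    ct <- suppressWarnings(stats::chisq.test(as.numeric(counts), p = probs))
    out$statistic[j] <- unname(ct$statistic)
    out$p_value[j] <- ct$p.value
  }
  out
}
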