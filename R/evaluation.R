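#' Per-region PSD correlation
#'
#' Pearson correlation between reconstructed and observed PSD computed per
#' region across frequencies, and its average over regions. Regions with
#' zero variance in either input get an undefined (NA) correlation and are
#' excluded from the mean.
#'
#' @param recon,obs N x F real matrices (same shape).
#' @return List with `per_roi` (length-N vector, possibly with NAs) and
#'   `mean`.
#' @export
psd_correlation <- function(recon, obs) {
  recon <- as.matrix(recon); obs <- as.matrix(obs)
  stopifnot(all(dim(recon) == dim(obs)), ncol(recon) >= 3)
  per <- vapply(seq_len(nrow(recon)), function(i) {
    if (stats::sd(recon[i, ]) == 0 || stats::sd(obs[i, ]) == 0)
      return(NA_real_)
    stats::cor(recon[i, ], obs[i, ])
  }, numeric(1))
  list(per_roi = per, mean = mean(per, na.rm = TRUE))
}

#' Connectivity-weighted spatial correlation of alpha power
#'
#' Weighted cosine similarity between the reconstructed and observed
#' spatial distributions of alpha-band power:
#' `t(a_hat) W a / sqrt((t(a_hat) W a_hat) (t(a) W a))` with
#' `W = (D + w I)` symmetrized as `(W + t(W))/2`, where `D` is the
#' row-degree-normalized structural connectivity. For `w > 0` and a
#' zero connectome this reduces to plain cosine similarity. The
#' unnormalized weighted inner product is available via
#' `normalize = FALSE`.
#'
#' @param recon_alpha,obs_alpha Length-N vectors.
#' @param conn `sgm_connectome`.
#' @param w Identity weight (default 10).
#' @param normalize Normalize to a cosine in \[-1, 1\] (default TRUE).
#' @return Scalar.
#' @export
spatial_correlation <- function(recon_alpha, obs_alpha, conn, w = 10,
                                normalize = TRUE) {
  stopifnot(length(recon_alpha) == conn$n_regions,
            length(obs_alpha) == conn$n_regions, w >= 0)
  if (all(recon_alpha == 0) || all(obs_alpha == 0))
    stop("zero alpha-power vector")
  D <- if (all(conn$weights == 0)) conn$weights * 0
       else degree_normalize(conn$weights, "row")
  W <- D + diag(w, conn$n_regions)
  W <- (W + t(W)) / 2
  ip <- drop(recon_alpha %*% W %*% obs_alpha)
  if (!normalize) return(ip)
  ip / sqrt(drop(recon_alpha %*% W %*% recon_alpha) *
            drop(obs_alpha %*% W %*% obs_alpha))
}

#' Partial correlations among posterior parameter draws
#'
#' Pairwise correlation between parameters after removing the linear
#' effect of all the others, computed from the inverse covariance:
#' `rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`, unit diagonal.
#'
#' @param s_draws n x p matrix of draws (n > p).
#' @return p x p symmetric matrix with unit diagonal.
#' @export
partial_correlation_matrix <- function(s_draws) {
  s_draws <- as.matrix(s_draws)
  p <- ncol(s_draws)
  if (nrow(s_draws) <= p + 1)
    stop("need more draws than parameters")
  cv <- stats::cov(s_draws)
  om <- tryCatch(solve(cv),
                 error = function(e) stop("singular covariance: degenerate draws"))
  dd <- sqrt(diag(om))
  pc <- -om / tcrossprod(dd)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(cv)
  pc
}

#' Two-sample comparison of method scores
#'
#' Two-sided Welch t-test p-value for the difference between two score
#' vectors (e.g. per-subject PSD correlations from two fitting methods).
#' If both groups are constant the p-value is 1 when the means agree and
#' 0 otherwise.
#'
#' @param scores_a,scores_b Numeric vectors (length >= 2).
#' @return p-value.
#' @export
compare_methods <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 2, length(scores_b) >= 2)
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0)
    return(if (isTRUE(all.equal(mean(scores_a), mean(scores_b)))) 1 else 0)
  stats::t.test(scores_a, scores_b, var.equal = FALSE)$p.value
}

#' Evaluation report for a reconstruction
#'
#' Bundles the comparison statistics for a reconstructed observation:
#' per-region and mean PSD correlation, weighted spatial correlation of
#' alpha power, and (when posterior draws are supplied) the partial
#' correlation matrix among parameters.
#'
#' @param recon_features,obs_features Feature vectors with layout
#'   attributes (e.g. [build_features()] output and a predictive mean with
#'   the same layout).
#' @param conn `sgm_connectome`.
#' @param w Spatial weight (default 10).
#' @param s_draws Optional n x 7 matrix of posterior parameter draws.
#' @return Object of class `sgm_evaluation`: list with `per_roi_r`,
#'   `mean_r`, `spatial_r`, and optionally `partial_corr`.
#' @export
evaluation_report <- function(recon_features, obs_features, conn, w = 10,
                              s_draws = NULL) {
  lay <- attr(obs_features, "layout")
  if (is.null(lay)) stop("obs_features carry no layout attribute")
  rec <- .with_layout(recon_features, lay)
  sp_rec <- split_features(rec)
  sp_obs <- split_features(.with_layout(obs_features, lay))
  pc <- psd_correlation(sp_rec$psd, sp_obs$psd)
  sr <- spatial_correlation(sp_rec$alpha, sp_obs$alpha, conn, w = w)
  out <- list(per_roi_r = pc$per_roi, mean_r = pc$mean, spatial_r = sr)
  if (!is.null(s_draws)) out$partial_corr <- partial_correlation_matrix(s_draws)
  structure(out, class = "sgm_evaluation")
}

.with_layout <- function(x, lay) {
  if (is.null(attr(x, "layout"))) attr(x, "layout") <- lay
  x
}

#' @export
print.sgm_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation: mean PSD correlation %.4f, spatial correlation %.4f\n",
              x$mean_r, x$spatial_r))
  invisible(x)
}
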