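#' Point-estimation objective: negative feature correlation
#'
#' The fit quality of a parameter point is measured as the Pearson
#' correlation between the model's observation features at those
#' parameters and the observed features; the objective to minimize is its
#' negative. Unstable parameter points receive a large sentinel value so
#' the search avoids them.
#'
#' @param params `sgm_params`.
#' @param y_obs Observed feature vector.
#' @param conn `sgm_connectome`.
#' @param grid `sgm_grid`.
#' @return Scalar objective (lower is better; -1 is a perfect match).
#' @export
annealing_objective <- function(params, y_obs, conn, grid = frequency_grid()) {
  params <- as_sgm_params(params)
  if (!stability_check(params)) return(1e6)
  y <- tryCatch(unclass(.sgm_features_at(params, conn, grid)),
                error = function(e) NULL)
  if (is.null(y) || !all(is.finite(y))) return(1e6)
  -stats::cor(y, unclass(y_obs))
}

#' Dual-phase annealing point estimate of the SGM parameters
#'
#' Global stochastic search for the parameter point maximizing the feature
#' correlation with an observation: a simulated-annealing phase explores
#' the unconstrained (scaled-logit) space, followed by a Nelder-Mead
#' polish from the best point found (annealing plus local search). Gain
#' bounds are tried tier by tier, widest first: if the optimum under a
#' tier violates the mesoscopic stability condition, the search moves to
#' the next (narrower) tier; the first tier whose optimum is stable wins.
#'
#' @param y_obs Observed feature vector.
#' @param conn `sgm_connectome`.
#' @param grid `sgm_grid`.
#' @param seed Integer seed (the search is deterministic given the seed).
#' @param budget Approximate number of objective evaluations per tier
#'   (default 10000).
#' @param bounds_template `sgm_bounds` supplying the non-gain bounds and
#'   gain tiers.
#' @return Object of class `sgm_annealing_fit`: `params`, `objective`
#'   (negative correlation at the optimum), `tier`, `evaluations`, `seed`.
#' @export
fit_annealing <- function(y_obs, conn, grid = frequency_grid(), seed = 1L,
                          budget = 10000L,
                          bounds_template = default_bounds()) {
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  n_tiers <- nrow(bounds_template$gain_tiers)
  for (tier in seq_len(n_tiers)) {
    bounds <- default_bounds(tier)
    evals <- 0L
    fn <- function(theta) {
      evals <<- evals + 1L
      annealing_objective(theta_to_sgm(theta, bounds), y_obs, conn, grid)
    }
    # prior-shaped random scan picks the annealing start
    scan_n <- max(50L, as.integer(budget * 0.1))
    cand <- rbind(rep(0, 7),
                  matrix(stats::rnorm((scan_n - 1L) * 7, 0, 10), scan_n - 1L))
    vals <- apply(cand, 1, fn)
    scan_best <- list(par = cand[which.min(vals), ], value = min(vals))
    # annealing phase in unconstrained coordinates
    sann_it <- max(100L, as.integer(budget * 0.5))
    sa <- stats::optim(scan_best$par, fn, method = "SANN",
                       control = list(maxit = sann_it, temp = 6,
                                      tmax = 10, parscale = rep(3, 7)))
    # local polish phase
    nm_it <- max(100L, as.integer(budget * 0.4))
    nm <- stats::optim(sa$par, fn, method = "Nelder-Mead",
                       control = list(maxit = nm_it, reltol = 1e-10))
    cands <- list(scan_best, sa, nm)
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
    params <- theta_to_sgm(best$par, bounds)
    if (stability_check(params) && best$value < 1e5) {
      return(structure(list(params = params, objective = best$value,
                            tier = tier, evaluations = evals, seed = seed),
                       class = "sgm_annealing_fit"))
    }
  }
  stop("no gain tier produced a stable optimum")
}

#' @export
print.sgm_annealing_fit <- function(x, ...) {
  cat(sprintf("Annealing fit: feature correlation %.4f (gain tier %d, %d evaluations)\n",
              -x$objective, x$tier, x$evaluations))
  print(x$params)
  invisible(x)
}
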