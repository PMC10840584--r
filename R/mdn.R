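#' @name mdn
#' @title Conditional mixture density network
#'
#' @description
#' A conditional density estimator q(y | x): a single-hidden-layer network
#' (tanh) whose outputs parameterize a mixture of K multivariate Gaussians
#' with full covariance (Cholesky factors with exp-diagonal), trained by
#' maximizing the mean conditional log-likelihood with Adam and early
#' stopping on a held-out split. This is the density-estimation engine
#' behind the amortized posterior: the proper scoring rule it optimizes is
#' the same objective as in neural posterior estimation, so given enough
#' simulated pairs the fitted conditional density approaches the true
#' posterior.
#'
#' Internal engine; the user-facing surface is [train_posterior()] and
#' friends. Exported for direct use on toy problems.
NULL

# Lower-triangle index bookkeeping for dimension d.
.tri_index <- function(d) {
  pairs <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  pmap <- matrix(NA_integer_, d, d)
  if (nrow(pairs)) pmap[pairs] <- seq_len(nrow(pairs))
  list(pairs = pairs, pmap = pmap, noff = nrow(pairs))
}

.mdn_layout <- function(d, K) {
  ti <- .tri_index(d)
  per <- d + d + ti$noff                   # mu, ldiag, loff
  P <- K + K * per
  mu_idx <- ld_idx <- lo_idx <- vector("list", K)
  off <- K
  for (k in seq_len(K)) {
    mu_idx[[k]] <- off + seq_len(d); off <- off + d
    ld_idx[[k]] <- off + seq_len(d); off <- off + d
    lo_idx[[k]] <- if (ti$noff) off + seq_len(ti$noff) else integer(0)
    off <- off + ti$noff
  }
  list(d = d, K = K, P = P, logit_idx = seq_len(K),
       mu_idx = mu_idx, ld_idx = ld_idx, lo_idx = lo_idx,
       pmap = ti$pmap, noff = ti$noff)
}

.mdn_init <- function(p, lay, hidden) {
  list(W1 = matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * lay$P, 0, 0.01), hidden, lay$P),
       b2 = numeric(lay$P))
}

.LDIAG_CLAMP <- 7

# Batched forward substitution: solve L u = r for each row, L given by
# diagonal Ld (B x d) and strict lower entries Loff (B x noff).
.tri_fwd <- function(Ld, Loff, r, pmap) {
  d <- ncol(Ld)
  u <- matrix(0, nrow(r), d)
  u[, 1] <- r[, 1] / Ld[, 1]
  if (d > 1) for (i in 2:d) {
    acc <- r[, i]
    for (j in seq_len(i - 1)) acc <- acc - Loff[, pmap[i, j]] * u[, j]
    u[, i] <- acc / Ld[, i]
  }
  u
}

# Batched back substitution: solve t(L) x = v.
.tri_bwd <- function(Ld, Loff, v, pmap) {
  d <- ncol(Ld)
  x <- matrix(0, nrow(v), d)
  x[, d] <- v[, d] / Ld[, d]
  if (d > 1) for (i in (d - 1):1) {
    acc <- v[, i]
    for (j in (i + 1):d) acc <- acc - Loff[, pmap[j, i]] * x[, j]
    x[, i] <- acc / Ld[, i]
  }
  x
}

.logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

# Loss (negative mean conditional log-likelihood) and gradients for one
# minibatch. Returns list(loss, grads).
.mdn_loss_grad <- function(net, lay, X, Y, want_grad = TRUE) {
  B <- nrow(X); d <- lay$d; K <- lay$K
  Z1 <- X %*% net$W1
  Z1 <- sweep(Z1, 2, net$b1, "+")
  H1 <- tanh(Z1)
  A <- H1 %*% net$W2
  A <- sweep(A, 2, net$b2, "+")

  S <- A[, lay$logit_idx, drop = FALSE]
  logpi <- S - .logsumexp_rows(S)
  logN <- matrix(0, B, K)
  comp <- vector("list", K)
  for (k in seq_len(K)) {
    mu <- A[, lay$mu_idx[[k]], drop = FALSE]
    ldraw <- A[, lay$ld_idx[[k]], drop = FALSE]
    mask <- abs(ldraw) < .LDIAG_CLAMP
    ldraw <- pmin(pmax(ldraw, -.LDIAG_CLAMP), .LDIAG_CLAMP)
    Ld <- exp(ldraw)
    Loff <- if (lay$noff) A[, lay$lo_idx[[k]], drop = FALSE]
            else matrix(0, B, 0)
    u <- .tri_fwd(Ld, Loff, Y - mu, lay$pmap)
    logN[, k] <- -0.5 * rowSums(u^2) - rowSums(ldraw) - 0.5 * d * log(2 * pi)
    comp[[k]] <- list(Ld = Ld, Loff = Loff, u = u, mask = mask)
  }
  ll <- .logsumexp_rows(logpi + logN)
  loss <- -mean(ll)
  if (!is.finite(loss)) stop("divergent training: non-finite loss")
  if (!want_grad) return(list(loss = loss))

  W <- exp(logpi + logN - ll)            # responsibilities, B x K
  dA <- matrix(0, B, lay$P)
  dA[, lay$logit_idx] <- -(W - exp(logpi)) / B
  for (k in seq_len(K)) {
    ck <- comp[[k]]
    wk <- W[, k] / B
    v <- .tri_bwd(ck$Ld, ck$Loff, ck$u, lay$pmap)   # d logN / d mu
    dA[, lay$mu_idx[[k]]] <- -wk * v
    # G[, i, c] = (L^-T (u u^T - I))_{i c}, lower triangle used
    dld <- matrix(0, B, d)
    dlo <- if (lay$noff) matrix(0, B, lay$noff) else NULL
    for (cc in seq_len(d)) {
      rhs <- ck$u * ck$u[, cc]
      rhs[, cc] <- rhs[, cc] - 1
      Gc <- .tri_bwd(ck$Ld, ck$Loff, rhs, lay$pmap)
      dld[, cc] <- Gc[, cc]
      if (cc < d) for (i in (cc + 1):d) dlo[, lay$pmap[i, cc]] <- Gc[, i]
    }
    dA[, lay$ld_idx[[k]]] <- -wk * (dld * ck$Ld) * ck$mask
    if (lay$noff) dA[, lay$lo_idx[[k]]] <- -wk * dlo
  }

  dW2 <- crossprod(H1, dA)
  db2 <- colSums(dA)
  dH1 <- tcrossprod(dA, net$W2)
  dZ1 <- dH1 * (1 - H1^2)
  dW1 <- crossprod(X, dZ1)
  db1 <- colSums(dZ1)
  list(loss = loss, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Fit a conditional mixture density network
#'
#' @param x Numeric matrix of conditioning inputs (n x p), already on a
#'   sensible scale (the higher-level wrappers whiten features first).
#' @param y Numeric matrix of targets (n x d).
#' @param n_components Number of mixture components K (default 3).
#' @param hidden Hidden layer width (default 64).
#' @param learn_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 256).
#' @param max_epochs Maximum epochs (default 60).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 10).
#' @param val_frac Held-out validation fraction (default 0.1).
#' @param seed Integer seed for initialization and shuffling.
#' @param verbose Print per-epoch losses.
#' @return Object of class `sgm_mdn`: network weights, layout, and
#'   training/validation loss traces.
#' @export
mdn_fit <- function(x, y, n_components = 3L, hidden = 64L,
                    learn_rate = 1e-3, batch_size = 256L, max_epochs = 60L,
                    patience = 10L, val_frac = 0.1, seed = 1L,
                    verbose = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 20)
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  n <- nrow(x)
  lay <- .mdn_layout(ncol(y), as.integer(n_components))
  net <- .mdn_init(ncol(x), lay, as.integer(hidden))

  n_val <- max(1L, floor(val_frac * n))
  perm <- sample.int(n)
  val_i <- perm[seq_len(n_val)]
  tr_i <- perm[-seq_len(n_val)]
  xt <- x[tr_i, , drop = FALSE]; yt <- y[tr_i, , drop = FALSE]
  xv <- x[val_i, , drop = FALSE]; yv <- y[val_i, , drop = FALSE]

  adam <- lapply(net, function(w) list(m = w * 0, v = w * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  ntr <- nrow(xt)
  nb <- max(1L, ceiling(ntr / batch_size))
  train_trace <- val_trace <- numeric(0)
  best <- list(loss = Inf, net = net, epoch = 0L)

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0
    for (bidx in seq_len(nb)) {
      rows <- ord[(((bidx - 1L) * batch_size + 1L):min(bidx * batch_size, ntr))]
      lg <- .mdn_loss_grad(net, lay, xt[rows, , drop = FALSE],
                           yt[rows, , drop = FALSE])
      ep_loss <- ep_loss + lg$loss * length(rows)
      gn <- sqrt(sum(vapply(lg$grads, function(g) sum(g^2), numeric(1))))
      clip <- if (gn > 50) 50 / gn else 1
      t <- t + 1L
      for (nm in names(net)) {
        g <- lg$grads[[nm]] * clip
        adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * g
        adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * g^2
        mhat <- adam[[nm]]$m / (1 - b1^t)
        vhat <- adam[[nm]]$v / (1 - b2^t)
        net[[nm]] <- net[[nm]] - learn_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    train_trace <- c(train_trace, ep_loss / ntr)
    vl <- .mdn_loss_grad(net, lay, xv, yv, want_grad = FALSE)$loss
    val_trace <- c(val_trace, vl)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ntr, vl))
    if (vl < best$loss - 1e-6) best <- list(loss = vl, net = net, epoch = epoch)
    if (epoch - best$epoch >= patience) break
  }

  structure(list(net = best$net, layout = lay, p = ncol(x),
                 train_trace = train_trace, val_trace = val_trace,
                 best_epoch = best$epoch, val_loss = best$loss,
                 config = list(n_components = n_components, hidden = hidden,
                               learn_rate = learn_rate,
                               batch_size = batch_size,
                               max_epochs = max_epochs, patience = patience,
                               val_frac = val_frac, seed = seed)),
            class = "sgm_mdn")
}

#' @export
print.sgm_mdn <- function(x, ...) {
  cat(sprintf("Conditional MDN: %d -> %d dims, K = %d, hidden = %d\n",
              x$p, x$layout$d, x$layout$K, x$config$hidden))
  cat(sprintf("  best validation loss %.4f at epoch %d of %d run\n",
              x$val_loss, x$best_epoch, length(x$val_trace)))
  invisible(x)
}

# Mixture parameters conditional on a single input row.
.mdn_cond <- function(fit, xrow) {
  lay <- fit$layout; d <- lay$d; K <- lay$K
  h <- tanh(drop(xrow %*% fit$net$W1) + fit$net$b1)
  a <- drop(h %*% fit$net$W2) + fit$net$b2
  s <- a[lay$logit_idx]
  pi_k <- exp(s - max(s)); pi_k <- pi_k / sum(pi_k)
  mu <- matrix(NA_real_, K, d)
  Ls <- vector("list", K)
  for (k in seq_len(K)) {
    mu[k, ] <- a[lay$mu_idx[[k]]]
    L <- matrix(0, d, d)
    diag(L) <- exp(pmin(pmax(a[lay$ld_idx[[k]]], -.LDIAG_CLAMP), .LDIAG_CLAMP))
    if (lay$noff) L[lower.tri(L)] <- a[lay$lo_idx[[k]]][lay$pmap[lower.tri(lay$pmap)]]
    Ls[[k]] <- L
  }
  list(pi = pi_k, mu = mu, L = Ls)
}

#' Sample from the fitted conditional density
#'
#' @param fit `sgm_mdn`.
#' @param xrow Single conditioning input (length p).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return n x d matrix of draws from q(y | x).
#' @export
mdn_sample <- function(fit, xrow, n, seed = 1L) {
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  cp <- .mdn_cond(fit, xrow)
  d <- fit$layout$d
  comp <- sample.int(fit$layout$K, n, replace = TRUE, prob = cp$pi)
  out <- matrix(NA_real_, n, d)
  for (k in unique(comp)) {
    rows <- which(comp == k)
    eps <- matrix(stats::rnorm(length(rows) * d), length(rows), d)
    out[rows, ] <- sweep(eps %*% t(cp$L[[k]]), 2, cp$mu[k, ], "+")
  }
  out
}

#' Conditional log-density under the fitted network
#'
#' @param fit `sgm_mdn`.
#' @param xrow Single conditioning input (length p).
#' @param y Matrix of points (n x d) at which to evaluate log q(y | x).
#' @return Numeric vector of log densities.
#' @export
mdn_log_density <- function(fit, xrow, y) {
  y <- as.matrix(y)
  cp <- .mdn_cond(fit, xrow)
  d <- fit$layout$d
  lognk <- sapply(seq_len(fit$layout$K), function(k) {
    u <- forwardsolve(cp$L[[k]], t(y) - cp$mu[k, ])
    -0.5 * colSums(u^2) - sum(log(diag(cp$L[[k]]))) - 0.5 * d * log(2 * pi)
  })
  lognk <- matrix(lognk, ncol = fit$layout$K)
  .logsumexp_rows(sweep(lognk, 2, log(cp$pi), "+"))
}

#' Mean and covariance of the fitted conditional density
#'
#' Exact mixture moments (no sampling error).
#'
#' @param fit `sgm_mdn`.
#' @param xrow Single conditioning input (length p).
#' @return List with `mean` (length d) and `cov` (d x d).
#' @export
mdn_moments <- function(fit, xrow) {
  cp <- .mdn_cond(fit, xrow)
  d <- fit$layout$d
  m <- colSums(cp$pi * cp$mu)
  M2 <- matrix(0, d, d)
  for (k in seq_len(fit$layout$K)) {
    M2 <- M2 + cp$pi[k] *
      (tcrossprod(cp$L[[k]]) + tcrossprod(cp$mu[k, ]))
  }
  list(mean = m, cov = M2 - tcrossprod(m))
}
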