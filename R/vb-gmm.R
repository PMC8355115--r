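# Variational Bayesian Gaussian mixture with a (truncated) Dirichlet-process
# stick-breaking prior over component weights.  Full covariances; standard
# Gaussian-Wishart variational updates; the stick-breaking posterior lets the
# data switch off surplus components, so k_max is an upper bound, not a
# choice of k.

#' Fit a Dirichlet-process Gaussian mixture by variational inference
#'
#' @param X numeric matrix (n observations by d dimensions).
#' @param k_max truncation level: maximum number of mixture components.
#' @param seed integer seed (k-means initialization is the only stochastic
#'   step; identical seeds give bit-identical fits).
#' @param alpha stick-breaking concentration (default `1/k_max`).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   per-observation variational log-likelihood bound proxy.
#' @return list with `weights`, `means` (k by d), `covariances` (list of
#'   d by d matrices), `converged`, `n_iter`, `log_resp_norm`.
#' @export
vb_dpgmm <- function(X, k_max = 10L, seed = 1L, alpha = NULL,
                     max_iter = 200L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 1, d >= 1)
  if (is.null(alpha)) alpha <- 1 / k_max
  k <- min(as.integer(k_max), nrow(unique(X)))

  # priors: empirical mean/covariance center the Gaussian-Wishart prior
  m0 <- colMeans(X)
  cov_emp <- if (n > 1) stats::cov(X) else matrix(0, d, d)
  reg <- 1e-6 * max(1, mean(diag(cov_emp)))
  W0_inv <- cov_emp + diag(reg, d)
  beta0 <- 1; nu0 <- d

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  resp <- init_resp_kmeans(X, k)

  prev <- -Inf; converged <- FALSE; ll <- -Inf
  for (iter in seq_len(max_iter)) {
    ## M-step
    Nk <- colSums(resp) + 1e-10
    xbar <- t(resp) %*% X / Nk                       # k x d
    beta_k <- beta0 + Nk
    nu_k <- nu0 + Nk
    m_k <- (beta0 * matrix(m0, k, d, byrow = TRUE) + Nk * xbar) / beta_k
    a_k <- 1 + Nk
    b_k <- alpha + rev(cumsum(rev(Nk))) - Nk         # sum over j > k
    W_inv <- vector("list", k)
    for (j in seq_len(k)) {
      Xc <- sweep(X, 2, xbar[j, ])
      Sk <- crossprod(Xc * resp[, j], Xc)            # N_k * S_k
      dm <- xbar[j, ] - m0
      W_inv[[j]] <- W0_inv + Sk +
        (beta0 * Nk[j] / beta_k[j]) * tcrossprod(dm) + diag(reg, d)
    }

    ## E-step
    e_ln_v <- digamma(a_k) - digamma(a_k + b_k)
    e_ln_1mv <- digamma(b_k) - digamma(a_k + b_k)
    e_ln_pi <- e_ln_v + c(0, cumsum(e_ln_1mv)[-k])
    log_rho <- matrix(0, n, k)
    for (j in seq_len(k)) {
      ch <- chol(W_inv[[j]])
      log_det_W <- -2 * sum(log(diag(ch)))           # log |W| = -log |W^-1|
      e_log_det <- sum(digamma((nu_k[j] + 1 - seq_len(d)) / 2)) +
        d * log(2) + log_det_W
      Xc <- sweep(X, 2, m_k[j, ])
      maha <- rowSums((Xc %*% chol2inv(ch)) * Xc)
      log_rho[, j] <- e_ln_pi[j] + 0.5 * e_log_det - d / 2 * log(2 * pi) -
        0.5 * (d / beta_k[j] + nu_k[j] * maha)
    }
    mx <- apply(log_rho, 1, max)
    lse <- mx + log(rowSums(exp(log_rho - mx)))
    resp <- exp(log_rho - lse)
    ll <- mean(lse)
    if (is.finite(prev) && abs(ll - prev) < tol) { converged <- TRUE; break }
    prev <- ll
  }

  # posterior-mean stick weights, normalized
  stick <- a_k / (a_k + b_k)
  w <- stick * c(1, cumprod(1 - stick)[-k])
  w <- w / sum(w)
  # expected precision is nu_k * W_k, so the component covariance is
  # W_k^{-1} / nu_k (W_inv already holds W_k^{-1})
  covs <- lapply(seq_len(k), function(j) W_inv[[j]] / nu_k[j])
  list(weights = as.numeric(w), means = m_k, covariances = covs,
       converged = converged, n_iter = iter, bound = ll)
}

solve_spd <- function(A) chol2inv(chol(A))

init_resp_kmeans <- function(X, k) {
  n <- nrow(X)
  if (k == 1) return(matrix(1, n, 1))
  km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 1L,
                                       iter.max = 50L))
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  resp
}

#' Mixture density of a fitted DP-GMM
#'
#' Evaluates the posterior-mean Gaussian mixture (weights, means, expected
#' covariances) at the given points.  The log form stays finite far from
#' every component, where the plain density underflows to zero, and is what
#' peak ranking uses.
#'
#' @param fit result of [vb_dpgmm()].
#' @param X points (n by d matrix).
#' @param log return log densities (default `FALSE`).
#' @return numeric vector of (log) densities.
#' @export
dpgmm_density <- function(fit, X, log = FALSE) {
  X <- as.matrix(X)
  d <- ncol(X)
  k <- length(fit$weights)
  log_terms <- matrix(-Inf, nrow(X), k)
  for (j in seq_len(k)) {
    S <- fit$covariances[[j]]
    ch <- chol(S)
    Xc <- sweep(X, 2, fit$means[j, ])
    maha <- rowSums((Xc %*% chol2inv(ch)) * Xc)
    log_norm <- -sum(base::log(diag(ch))) - d / 2 * base::log(2 * pi)
    log_terms[, j] <- base::log(fit$weights[j]) + log_norm - maha / 2
  }
  mx <- apply(log_terms, 1, max)
  ld <- mx + base::log(rowSums(exp(log_terms - mx)))
  if (log) ld else exp(ld)
}
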