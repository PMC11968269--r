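# Gaussian-emission HMM fitted by Baum-Welch with scaled forward-backward.
# Observations may contain NA (treated as unobserved: emission density 1
# for every state). Initialization is deterministic: emission means at
# evenly spread quantiles of the finite observations, a common SD, and a
# sticky transition matrix. With `anchor_state` set, that state's emission
# mean is pinned at 0 (the "unbiased" state of a directionality profile),
# which keeps two states from splitting a single biased mode. Returns
# unordered states; callers relabel.
.gaussian_hmm_em <- function(x, n_states, max_iter = 200, tol = 1e-6,
                             anchor_state = NULL) {
  n <- length(x)
  obs <- is.finite(x)
  if (sum(obs) < n_states) stop("too few finite observations for the HMM")
  qs <- stats::quantile(x[obs], probs = seq(0.1, 0.9,
                                            length.out = n_states),
                        names = FALSE)
  mu <- qs
  if (!is.null(anchor_state)) mu[anchor_state] <- 0
  # start narrower than the overall spread so well-separated modes are not
  # swallowed by a single state in the first E step
  sigma <- rep(max(stats::sd(x[obs]) / n_states, 1e-6), n_states)
  trans <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(trans) <- 0.9
  init <- rep(1 / n_states, n_states)
  sd_floor <- max(1e-6, 1e-4 * stats::sd(x[obs]))

  emis <- function() {
    b <- matrix(1, n, n_states)
    for (k in seq_len(n_states))
      b[obs, k] <- stats::dnorm(x[obs], mu[k], sigma[k])
    # guard against total underflow at outlier points
    b[obs, ][rowSums(b[obs, , drop = FALSE]) == 0, ] <- 1e-300
    b
  }

  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    b <- emis()
    # scaled forward
    alpha <- matrix(0, n, n_states)
    scale <- numeric(n)
    a <- init * b[1, ]
    scale[1] <- sum(a)
    alpha[1, ] <- a / scale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% trans) * b[t, ]
      scale[t] <- sum(a)
      alpha[t, ] <- a / scale[t]
    }
    ll <- sum(log(scale))
    loglik <- c(loglik, ll)
    # scaled backward
    beta <- matrix(0, n, n_states)
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- as.vector(trans %*% (b[t + 1, ] * beta[t + 1, ])) /
        scale[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    # expected transitions
    xi <- matrix(0, n_states, n_states)
    for (t in seq_len(n - 1)) {
      m <- outer(alpha[t, ], b[t + 1, ] * beta[t + 1, ]) * trans /
        scale[t + 1]
      xi <- xi + m
    }
    # M step
    init <- gamma[1, ]
    trans <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    w <- gamma[obs, , drop = FALSE]
    xo <- x[obs]
    wsum <- pmax(colSums(w), 1e-12)
    mu_new <- colSums(w * xo) / wsum
    mu_new[!is.finite(mu_new)] <- mu[!is.finite(mu_new)]
    if (!is.null(anchor_state)) mu_new[anchor_state] <- 0
    mu <- mu_new
    sigma <- sqrt(colSums(w * (outer(xo, mu, "-"))^2) / wsum)
    sigma[!is.finite(sigma)] <- sd_floor
    sigma <- pmax(sigma, sd_floor)
    if (iter > 1 && abs(ll - loglik[iter - 1]) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
  }
  # final posteriors with the updated parameters
  b <- emis()
  alpha <- matrix(0, n, n_states)
  scale <- numeric(n)
  a <- init * b[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% trans) * b[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, n, n_states)
  beta[n, ] <- 1
  for (t in (n - 1):1)
    beta[t, ] <- as.vector(trans %*% (b[t + 1, ] * beta[t + 1, ])) /
      scale[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  if (!converged)
    warning("HMM EM did not converge in ", max_iter,
            " iterations; see the log-likelihood trace")
  list(posterior = gamma, means = mu, sds = sigma, transition = trans,
       init = init, loglik = loglik, converged = converged)
}
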