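# MCMC machinery for the Bayesian model family.
#
# Two independent samplers:
#  * .sample_gibbs() - data-augmentation Gibbs sampler. With censoring =
#    "latent" each censored observation's working-scale value is a bounded
#    latent parameter redrawn from its truncated-normal full conditional;
#    conditional on the latents the model is a conjugate Gaussian linear
#    mixed model, so coefficients and subject intercepts have closed-form
#    draws and only the two SDs need univariate slice updates.
#  * .sample_integrated() - slice-within-Gibbs on the marginal posterior in
#    which censored rows contribute the upper-tail probability directly.
# The two routes target the same coefficient posterior (latent augmentation
# marginalises to the integrated likelihood), which is exercised by the
# package's validation suite.

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
.slice_1d <- function(f, x0, fx0 = NULL, w = 1, max_steps = 50) {
  if (is.null(fx0)) fx0 <- f(x0)
  logy <- fx0 - stats::rexp(1)
  lo <- x0 - stats::runif(1) * w
  hi <- lo + w
  steps <- floor(stats::runif(1) * max_steps)
  k <- steps
  while (k > 0 && f(lo) > logy) {
    lo <- lo - w
    k <- k - 1
  }
  k <- max_steps - 1 - steps
  while (k > 0 && f(hi) > logy) {
    hi <- hi + w
    k <- k - 1
  }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    fx1 <- f(x1)
    if (fx1 >= logy) return(list(x = x1, fx = fx1))
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# truncated-normal draws above `lower` by inversion (vectorised)
.rtnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- p_lo + stats::runif(n) * (1 - p_lo)
  u <- pmin(u, 1 - 1e-15)
  stats::qnorm(u, mean, sd)
}

# log full conditional of log(sigma) given a sum of squares `ss` over `m`
# terms and a half-normal(scale) prior, including the log-scale Jacobian
.lsig_target <- function(t, m, ss, scale) {
  s2 <- exp(2 * t)
  -m * t - ss / (2 * s2) - s2 / (2 * scale^2) + t
}

# one chain of the conjugate data-augmentation sampler.
# md: .model_data() list; pv: .prior_vectors(); priors: lt_priors
.gibbs_chain <- function(md, pv, priors, censoring, subject_effects,
                         n_keep, warmup, thin = 1) {
  X <- md$X
  p <- ncol(X)
  n <- md$n
  J <- md$J
  cidx <- which(md$cens & censoring == "latent")
  z <- md$z
  XtX <- crossprod(X)
  prior_prec <- 1 / pv$s0^2
  prior_mp <- pv$m0 / pv$s0^2

  # initial values: ridge least squares, jittered
  beta <- tryCatch(
    solve(XtX + diag(1e-6, p), crossprod(X, z)),
    error = function(e) matrix(0, p, 1)
  )
  beta <- as.numeric(beta) + stats::rnorm(p, 0, 0.1 * pv$s0)
  u <- rep(0, J)
  lsig_u <- log(priors$sigma_subject_scale / 2) + stats::rnorm(1, 0, 0.2)
  resid0 <- z - as.numeric(X %*% beta)
  lsig_e <- log(max(stats::sd(resid0), 1e-3)) + stats::rnorm(1, 0, 0.2)

  total <- warmup + n_keep * thin
  keep <- matrix(NA_real_, n_keep,
                 p + 2 + (if (subject_effects) J else 0) + length(cidx))
  krow <- 0L
  ns <- tabulate(md$subj, J)

  # marginal log-likelihood of (sigma_u, sigma_e) given beta and working
  # values, with subject intercepts integrated out (per-subject compound
  # symmetry); avoids the funnel of the centered sigma_subject update
  marg_ll <- function(sig_u, sig_e, rbar, ssw) {
    v <- sig_e^2 + ns * sig_u^2
    -0.5 * (sum((ns - 1)) * log(sig_e^2) + sum(log(v)) +
              ssw / sig_e^2 + sum(ns * rbar^2 / v))
  }

  for (it in seq_len(total)) {
    sig_e <- exp(lsig_e)
    sig_u <- exp(lsig_u)
    mu_fix <- as.numeric(X %*% beta)
    mu <- mu_fix + u[md$subj]

    # 1. latent working-scale values for censored rows
    if (length(cidx)) {
      z[cidx] <- .rtnorm_lower(length(cidx), mu[cidx], sig_e, md$limit)
    }

    # 2. coefficients (conjugate multivariate normal)
    r <- z - u[md$subj]
    A <- XtX / sig_e^2
    diag(A) <- diag(A) + prior_prec
    b <- as.numeric(crossprod(X, r)) / sig_e^2 + prior_mp
    R <- chol(A)
    mean_b <- backsolve(R, forwardsolve(t(R), b))
    beta <- mean_b + backsolve(R, stats::rnorm(p))
    mu_fix <- as.numeric(X %*% beta)

    # 3. variance components from the collapsed posterior (u integrated out)
    res <- z - mu_fix
    rbar <- rowsum(res, md$subj, reorder = TRUE)[, 1] / ns
    ssw <- sum(res^2) - sum(ns * rbar^2)
    if (subject_effects) {
      lsig_u <- .slice_1d(
        function(t) {
          s <- exp(t)
          marg_ll(s, exp(lsig_e), rbar, ssw) -
            s^2 / (2 * priors$sigma_subject_scale^2) + t
        },
        lsig_u, w = 0.7
      )$x
    }
    lsig_e <- .slice_1d(
      function(t) {
        s <- exp(t)
        marg_ll(exp(lsig_u) * subject_effects, s, rbar, ssw) -
          s^2 / (2 * priors$sigma_obs_scale^2) + t
      },
      lsig_e, w = 0.3
    )$x
    sig_e <- exp(lsig_e)
    sig_u <- exp(lsig_u)

    # 4. subject intercepts (conjugate normal given the new SDs)
    if (subject_effects) {
      prec <- ns / sig_e^2 + 1 / sig_u^2
      u <- (rbar * ns) / sig_e^2 / prec + stats::rnorm(J) / sqrt(prec)
    }

    if (it > warmup && (it - warmup) %% thin == 0) {
      krow <- krow + 1L
      keep[krow, ] <- c(beta, exp(lsig_u), exp(lsig_e),
                        if (subject_effects) u, z[cidx])
    }
  }
  keep
}

# one chain of the slice-within-Gibbs sampler on the integrated posterior
.integrated_chain <- function(md, pv, priors, subject_effects,
                              n_keep, warmup, thin = 1) {
  X <- md$X
  p <- ncol(X)
  n <- md$n
  J <- md$J
  obs <- !md$cens
  z_obs <- md$z[obs]
  limit <- md$limit
  rows_of <- split(seq_len(n), md$subj)

  loglik_mu <- function(mu, sig_e) {
    sum(stats::dnorm(z_obs, mu[obs], sig_e, log = TRUE)) +
      (if (any(md$cens)) {
        sum(stats::pnorm(limit, mu[md$cens], sig_e,
                         lower.tail = FALSE, log.p = TRUE))
      } else 0)
  }

  beta <- tryCatch(
    as.numeric(solve(crossprod(X) + diag(1e-6, p), crossprod(X, md$z))),
    error = function(e) rep(0, p)
  ) + stats::rnorm(p, 0, 0.1 * pv$s0)
  u <- rep(0, J)
  lsig_u <- log(priors$sigma_subject_scale / 2) + stats::rnorm(1, 0, 0.2)
  lsig_e <- log(max(stats::sd(md$z - X %*% beta), 1e-3)) +
    stats::rnorm(1, 0, 0.2)

  total <- warmup + n_keep * thin
  keep <- matrix(NA_real_, n_keep,
                 p + 2 + (if (subject_effects) J else 0))
  krow <- 0L
  mu <- as.numeric(X %*% beta) + u[md$subj]

  for (it in seq_len(total)) {
    sig_e <- exp(lsig_e)
    sig_u <- exp(lsig_u)

    for (k in seq_len(p)) {
      xk <- X[, k]
      bk <- beta[k]
      res <- .slice_1d(
        function(v) {
          loglik_mu(mu + xk * (v - bk), sig_e) +
            stats::dnorm(v, pv$m0[k], pv$s0[k], log = TRUE)
        },
        bk, w = 0.5
      )
      beta[k] <- res$x
      mu <- mu + xk * (beta[k] - bk)
    }

    if (subject_effects) {
      for (j in seq_len(J)) {
        rj <- rows_of[[j]]
        muj <- mu[rj]
        censj <- md$cens[rj]
        zj <- md$z[rj][!censj]
        uj <- u[j]
        llj <- function(v) {
          m <- muj + (v - uj)
          sum(stats::dnorm(zj, m[!censj], sig_e, log = TRUE)) +
            (if (any(censj)) {
              sum(stats::pnorm(limit, m[censj], sig_e,
                               lower.tail = FALSE, log.p = TRUE))
            } else 0) +
            stats::dnorm(v, 0, sig_u, log = TRUE)
        }
        res <- .slice_1d(llj, uj, w = max(sig_u, 0.1))
        u[j] <- res$x
        mu[rj] <- muj + (u[j] - uj)
      }
      lsig_u <- .slice_1d(
        function(t) .lsig_target(t, J, sum(u^2), priors$sigma_subject_scale),
        lsig_u, w = 0.5
      )$x
      sig_u <- exp(lsig_u)
      # interweaved non-centered update (ASIS): rescale u = sigma_u * u_tilde
      # and move sigma_u against the likelihood, breaking the funnel near 0
      if (sig_u > 1e-12) {
        ut <- u / sig_u
        mu_fix <- mu - u[md$subj]
        lsig_u <- .slice_1d(
          function(t) {
            s <- exp(t)
            loglik_mu(mu_fix + s * ut[md$subj], sig_e) -
              s^2 / (2 * priors$sigma_subject_scale^2) + t
          },
          lsig_u, w = 0.7
        )$x
        sig_u <- exp(lsig_u)
        u <- sig_u * ut
        mu <- mu_fix + u[md$subj]
      }
    }

    lsig_e <- .slice_1d(
      function(t) {
        loglik_mu(mu, exp(t)) +
          (-exp(2 * t) / (2 * priors$sigma_obs_scale^2) + t)
      },
      lsig_e, w = 0.3
    )$x

    if (it > warmup && (it - warmup) %% thin == 0) {
      krow <- krow + 1L
      keep[krow, ] <- c(beta, exp(lsig_u), exp(lsig_e),
                        if (subject_effects) u)
    }
  }
  keep
}

# split-R-hat over an iterations x chains matrix
.split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  m <- cbind(x[seq_len(half), , drop = FALSE],
             x[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(m)
  vars <- apply(m, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size over an iterations x chains matrix (Geyer initial
# monotone sequence on the multi-chain autocorrelation, as used by Stan)
.ess <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  acov <- apply(x, 2, function(v) {
    a <- stats::acf(v, lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer pairs
  max_pairs <- floor((n - 1) / 2)
  tau <- 0
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (is.na(pair) || pair <= 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}
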