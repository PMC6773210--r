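# Observed-data log-likelihood of the four model variants.

# internal: assemble model data on the sampler's working scale
# (log seconds for the lognormal likelihood, seconds for the normal one)
.model_data <- function(trials, design, likelihood, censor_limit_s) {
  trials <- as.data.frame(trials)
  y <- trials$looking_s
  if (likelihood == "lognormal" && any(y <= 0)) {
    stop("non-positive looking time under the lognormal likelihood",
         call. = FALSE)
  }
  z <- if (likelihood == "lognormal") log(y) else y
  limit <- if (likelihood == "lognormal") log(censor_limit_s) else censor_limit_s
  subj <- factor(trials$subject_id, levels = unique(trials$subject_id))
  list(
    z = z, y = y, X = design, cens = trials$censored,
    subj = as.integer(subj), subj_levels = levels(subj),
    n = length(y), J = nlevels(subj), limit = limit,
    likelihood = likelihood
  )
}

#' Observed-data log-likelihood of a looking-time model
#'
#' Evaluates the log-likelihood of the trial data at a given parameter
#' point, under either likelihood and any of the three censoring treatments.
#' Under the normal likelihood the density is evaluated on raw seconds;
#' under the lognormal likelihood on log seconds with the change-of-variable
#' Jacobian, so values are comparable across likelihoods. Censored rows
#' contribute: nothing special (`"none"`: the recorded ceiling value is
#' treated as exact), the log upper-tail probability beyond the limit
#' (`"integrated"`), or the density at their latent value (`"latent"`,
#' values must lie above the limit).
#'
#' @param params List with `beta` (coefficient vector aligned to the design
#'   columns), `sigma_obs` (> 0), optional `u` (subject intercepts, in the
#'   order subjects first appear; defaults to 0), and `latent` (one working
#'   scale value per censored row, required for `censoring = "latent"`).
#' @param trials An `lt_trials` table.
#' @param design Design matrix aligned with `trials`.
#' @param likelihood `"lognormal"` or `"normal"`.
#' @param censoring `"none"`, `"integrated"` or `"latent"`.
#' @param censor_limit_s Censoring limit in seconds.
#' @return Scalar log-likelihood.
#' @export
lt_loglik <- function(params, trials, design,
                      likelihood = c("lognormal", "normal"),
                      censoring = c("integrated", "latent", "none"),
                      censor_limit_s = 60) {
  likelihood <- match.arg(likelihood)
  censoring <- match.arg(censoring)
  md <- .model_data(trials, design, likelihood, censor_limit_s)
  beta <- params$beta
  sigma <- params$sigma_obs
  stopifnot(length(beta) == ncol(md$X), sigma > 0)
  u <- params$u %||% rep(0, md$J)
  mu <- as.numeric(md$X %*% beta) + u[md$subj]
  jac <- if (likelihood == "lognormal") -md$z else rep(0, md$n)

  obs <- !md$cens
  ll <- sum(stats::dnorm(md$z[obs], mu[obs], sigma, log = TRUE) + jac[obs])
  if (any(md$cens)) {
    ll <- ll + switch(
      censoring,
      none = sum(stats::dnorm(md$z[md$cens], mu[md$cens], sigma, log = TRUE) +
                   jac[md$cens]),
      integrated = sum(stats::pnorm(md$limit, mu[md$cens], sigma,
                                    lower.tail = FALSE, log.p = TRUE)),
      latent = {
        lat <- params$latent
        if (is.null(lat) || length(lat) != sum(md$cens)) {
          stop("latent mode needs one latent value per censored row",
               call. = FALSE)
        }
        if (any(lat < md$limit)) {
          stop("latent values must lie above the censoring limit",
               call. = FALSE)
        }
        # latent values are parameters on the working scale, so no
        # change-of-variable term: integrating this density over the
        # censored coordinate recovers the integrated-mode tail probability
        sum(stats::dnorm(lat, mu[md$cens], sigma, log = TRUE))
      }
    )
  }
  ll
}
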