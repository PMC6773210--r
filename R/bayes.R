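# The Bayesian hierarchical looking-time model family: normal or lognormal
# likelihood, censoring treated as bounded latent parameters, by integrating
# the likelihood beyond the ceiling, or ignored.

#' Fit a Bayesian hierarchical looking-time model
#'
#' The core model of the package. Looking times are modelled as
#' `working_scale(y) = X beta + u_subject + eps`, with `u ~ Normal(0,
#' sigma_subject)`, `eps ~ Normal(0, sigma_obs)`, and the working scale
#' either log seconds (`likelihood = "lognormal"`) or raw seconds
#' (`"normal"`). Ceiling-censored observations (looks still ongoing at the
#' maximum trial length) are handled per `censoring`:
#'
#' * `"latent"` (default): each censored observation is an extra bounded
#'   parameter constrained above the limit and sampled jointly with the
#'   model parameters (data augmentation; conjugate Gibbs sampler).
#' * `"integrated"`: censored rows contribute the upper-tail probability to
#'   the likelihood; sampled by slice-within-Gibbs. Marginally equivalent to
#'   `"latent"` and used as its independent validation route.
#' * `"none"`: censored values are treated as exact observations at the
#'   ceiling.
#'
#' At least 4 chains are run; split R-hat and effective sample size are
#' reported per parameter and a convergence warning is attached to the fit
#' when any reported parameter has R-hat above 1.01 or ESS below 400.
#' Sampling is deterministic given `seed` and the sampler settings.
#'
#' @param trials An `lt_trials` table (see [read_trial_table()],
#'   [simulate_experiment()]).
#' @param likelihood `"lognormal"` or `"normal"`.
#' @param censoring `"latent"`, `"integrated"` or `"none"`.
#' @param scheme Contrast scheme; defaults to the 13-term single-experiment
#'   scheme (use the aggregate scheme via [fit_aggregate()]).
#' @param priors An [lt_priors()]; defaults to the weakly informative priors
#'   for the chosen likelihood.
#' @param chains Number of MCMC chains (minimum 4).
#' @param n_draws Kept draws per chain after warmup.
#' @param warmup Warmup iterations per chain (discarded).
#' @param seed Integer seed for the sampler.
#' @param subject_effects Set `FALSE` to drop the subject intercepts (used
#'   for small validation models).
#' @param censor_limit_s Censoring ceiling in seconds.
#' @return Object of class `lt_bayes` with posterior draws (coefficients,
#'   SDs, subject intercepts, and one bounded latent value per censored
#'   observation in latent mode), diagnostics, and the model frame. Methods:
#'   `print`, `summary`, `coef`, `plot`, `predict`, `simulate`, `residuals`.
#' @examples
#' \donttest{
#' trials <- simulate_experiment(lt_config(seed = 1))
#' fit <- lt_bayes(trials, n_draws = 250, warmup = 250, seed = 1)
#' summary(fit)
#' }
#' @export
lt_bayes <- function(trials,
                     likelihood = c("lognormal", "normal"),
                     censoring = c("latent", "integrated", "none"),
                     scheme = build_contrast_scheme("single_experiment"),
                     priors = lt_priors(likelihood),
                     chains = 4, n_draws = 500, warmup = 500,
                     seed = 1L,
                     subject_effects = TRUE,
                     censor_limit_s = attr(trials, "censor_limit_s") %||% 60) {
  likelihood <- match.arg(likelihood)
  censoring <- match.arg(censoring)
  stopifnot(chains >= 1, n_draws >= 2, warmup >= 0)
  design <- build_design_matrix(trials, scheme)
  .lt_bayes_fit(trials, design, scheme, likelihood, censoring, priors,
                chains, n_draws, warmup, seed, subject_effects,
                censor_limit_s)
}

# shared fitting core (also used by fit_aggregate)
.lt_bayes_fit <- function(trials, design, scheme, likelihood, censoring,
                          priors, chains, n_draws, warmup, seed,
                          subject_effects, censor_limit_s) {
  md <- .model_data(trials, design, likelihood, censor_limit_s)
  pv <- .prior_vectors(priors, colnames(design))
  p <- ncol(design)
  cens_rows <- which(md$cens)
  par_names <- c(
    colnames(design), "sigma_subject", "sigma_obs",
    if (subject_effects) paste0("u[", md$subj_levels, "]"),
    if (censoring == "latent" && length(cens_rows)) {
      paste0("latent[", cens_rows, "]")
    }
  )
  draws <- array(NA_real_, c(n_draws, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  .with_seed(seed, {
    for (ch in seq_len(chains)) {
      mat <- if (censoring == "integrated") {
        .integrated_chain(md, pv, priors, subject_effects, n_draws, warmup)
      } else {
        .gibbs_chain(md, pv, priors, censoring, subject_effects,
                     n_draws, warmup)
      }
      if (!subject_effects) {
        # insert a zero sigma_subject/u-free layout consistent with names
        mat <- cbind(mat[, seq_len(p), drop = FALSE],
                     sigma_subject = 0,
                     mat[, -seq_len(p), drop = FALSE])[, seq_along(par_names),
                                                       drop = FALSE]
      }
      draws[, ch, ] <- mat
    }
  })

  reported <- c(colnames(design),
                if (subject_effects) "sigma_subject", "sigma_obs")
  rhat <- vapply(reported, function(nm) .split_rhat(draws[, , nm]), 0)
  ess <- vapply(reported, function(nm) .ess(draws[, , nm]), 0)
  conv_warning <- NULL
  if (any(rhat > 1.01, na.rm = TRUE) || any(ess < 400, na.rm = TRUE)) {
    conv_warning <- sprintf(
      "convergence gate not met: max R-hat %.3f, min ESS %.0f (gate: R-hat <= 1.01, ESS >= 400); increase n_draws/warmup",
      max(rhat, na.rm = TRUE), min(ess, na.rm = TRUE)
    )
    warning(conv_warning, call. = FALSE)
  }

  structure(
    list(
      draws = draws, par_names = par_names, terms = colnames(design),
      likelihood = likelihood, censoring = censoring, scheme = scheme,
      priors = priors, trials = as.data.frame(trials), design = design,
      subj = md$subj, subj_levels = md$subj_levels,
      cens_rows = cens_rows, censor_limit_s = censor_limit_s,
      subject_effects = subject_effects,
      chains = chains, n_draws = n_draws, warmup = warmup, seed = seed,
      rhat = rhat, ess = ess, convergence_warning = conv_warning
    ),
    class = "lt_bayes"
  )
}

# flattened draw matrix (chains stacked) for a set of parameters
.draw_matrix <- function(fit, pars = fit$terms) {
  d <- fit$draws[, , pars, drop = FALSE]
  matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = length(pars),
         dimnames = list(NULL, pars))
}

#' Persist posterior draws as a columnar table
#'
#' Writes the kept draws (all chains stacked, chain and iteration indices in
#' the leading columns) as headered CSV, one column per parameter.
#'
#' @param fit An `lt_bayes` fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "lt_bayes"))
  dm <- .draw_matrix(fit, fit$par_names)
  out <- data.frame(
    chain = rep(seq_len(fit$chains), each = fit$n_draws),
    iteration = rep(seq_len(fit$n_draws), fit$chains)
  )
  out <- cbind(out, as.data.frame(dm, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.lt_bayes <- function(x, ...) {
  cat(sprintf(
    "Bayesian hierarchical looking-time model (%s likelihood, censoring: %s)\n",
    x$likelihood, x$censoring
  ))
  cat(sprintf(
    "%d trials, %d subjects, %d censored at %g s; %d chains x %d draws\n",
    nrow(x$trials), length(x$subj_levels), length(x$cens_rows),
    x$censor_limit_s, x$chains, x$n_draws
  ))
  if (!is.null(x$convergence_warning)) {
    cat("NOTE:", x$convergence_warning, "\n")
  }
  cat("Coefficient posterior medians:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.lt_bayes <- function(object, ...) {
  apply(.draw_matrix(object), 2, stats::median)
}

#' Summarize a Bayesian looking-time fit
#'
#' Per-term posterior median, equal-tailed credible intervals at the
#' requested levels, a credibility flag per level (interval excludes zero),
#' and convergence diagnostics.
#'
#' @param object An `lt_bayes` fit.
#' @param levels Credible-interval levels in percent (default 90 and 95).
#' @param ... Unused.
#' @return Data.frame of class `lt_bayes_summary`, one row per coefficient
#'   plus the two SDs.
#' @export
summary.lt_bayes <- function(object, levels = c(90, 95), ...) {
  pars <- c(object$terms,
            if (object$subject_effects) "sigma_subject", "sigma_obs")
  dm <- .draw_matrix(object, pars)
  out <- data.frame(term = pars, median = apply(dm, 2, stats::median),
                    stringsAsFactors = FALSE)
  for (lv in levels) {
    a <- (1 - lv / 100) / 2
    qs <- apply(dm, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    out[[sprintf("lower_%g", lv)]] <- qs[1, ]
    out[[sprintf("upper_%g", lv)]] <- qs[2, ]
    out[[sprintf("credible_%g", lv)]] <- qs[1, ] > 0 | qs[2, ] < 0
  }
  out$rhat <- unname(object$rhat[pars])
  out$ess <- unname(object$ess[pars])
  rownames(out) <- NULL
  structure(out, class = c("lt_bayes_summary", "data.frame"),
            levels = levels)
}

#' @export
print.lt_bayes_summary <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 3))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

# posterior draws of the design-cell means on the working scale (covariate
# at its centred zero), cells x draws
.cell_mu_draws <- function(fit) {
  sch <- fit$scheme
  code_cols <- setdiff(names(sch$cells),
                       c("condition", "experiment", "trial_type", "first_test"))
  codes <- as.matrix(sch$cells[code_cols])
  beta <- .draw_matrix(fit, fit$terms)
  beta_cells <- beta[, setdiff(fit$terms, "Familiarization Time"),
                     drop = FALSE]
  list(cells = sch$cells[intersect(
    c("condition", "experiment", "trial_type", "first_test"),
    names(sch$cells))],
    mu = codes %*% t(beta_cells))
}

#' Bayesian R-squared
#'
#' Per posterior draw, the ratio `var(linear predictor) / (var(linear
#' predictor) + residual variance)`, with the linear predictor evaluated
#' over the observed trials (including subject intercepts) on the model's
#' working scale (log seconds for the lognormal likelihood).
#'
#' @param fit An `lt_bayes` fit.
#' @return Numeric vector of R-squared draws with the posterior median as
#'   attribute `median`.
#' @export
bayes_r2 <- function(fit) {
  stopifnot(inherits(fit, "lt_bayes"))
  beta <- .draw_matrix(fit, fit$terms)
  lp <- fit$design %*% t(beta)
  if (fit$subject_effects) {
    u <- .draw_matrix(fit, paste0("u[", fit$subj_levels, "]"))
    lp <- lp + t(u)[fit$subj, , drop = FALSE]
  }
  sig_e <- .draw_matrix(fit, "sigma_obs")[, 1]
  vf <- apply(lp, 2, stats::var)
  r2 <- vf / (vf + sig_e^2)
  attr(r2, "median") <- stats::median(r2)
  r2
}

#' Posterior predictive intervals per design cell
#'
#' Simulates one replicate observation per posterior draw per design cell
#' (new subject intercept, new residual) and summarises predictive medians
#' and 50/95% intervals on the seconds scale. When the fitted model accounts
#' for censoring the replicates are clamped at the ceiling, mirroring the
#' measurement process.
#'
#' @param fit An `lt_bayes` fit.
#' @param apply_censoring Clamp replicates at the fitted censor limit
#'   (default: `TRUE` whenever the fitted model censors).
#' @param seed Seed for the replicate draws (defaults to the fit's seed, so
#'   repeated calls on the same fit are identical).
#' @return Data.frame: one row per design cell with predictive median and
#'   interval bounds.
#' @export
posterior_predictive_cells <- function(fit,
                                       apply_censoring = fit$censoring != "none",
                                       seed = fit$seed) {
  cm <- .cell_mu_draws(fit)
  sig_u <- .draw_matrix(fit, "sigma_subject")[, 1]
  sig_e <- .draw_matrix(fit, "sigma_obs")[, 1]
  ndr <- length(sig_e)
  out <- cm$cells
  qs <- .with_seed(seed, {
    q <- matrix(NA_real_, nrow(out), 5)
    for (i in seq_len(nrow(out))) {
      z <- cm$mu[i, ] + stats::rnorm(ndr, 0, sig_u) +
        stats::rnorm(ndr, 0, sig_e)
      y <- if (fit$likelihood == "lognormal") exp(z) else z
      if (apply_censoring) y <- pmin(y, fit$censor_limit_s)
      q[i, ] <- stats::quantile(y, c(0.025, 0.25, 0.5, 0.75, 0.975),
                                names = FALSE)
    }
    q
  })
  out$lower_95 <- qs[, 1]
  out$lower_50 <- qs[, 2]
  out$median <- qs[, 3]
  out$upper_50 <- qs[, 4]
  out$upper_95 <- qs[, 5]
  out
}

#' Posterior of the within-subject trial-type difference
#'
#' For each condition (by trial order), the posterior of the difference
#' between the 2-Change and 1-Change cell means implied by the coefficients:
#' on the log scale, and on the seconds scale as the difference of implied
#' cell medians (`exp` of the log-scale cell means for the lognormal
#' likelihood).
#'
#' @param fit An `lt_bayes` fit.
#' @return List with `draws` (named list per subcondition, each with
#'   `log_diff` and `seconds_diff` vectors) and `summary` (median and 95%
#'   interval of the seconds-scale difference per subcondition).
#' @export
within_subject_difference <- function(fit) {
  cm <- .cell_mu_draws(fit)
  cells <- cm$cells
  key_vars <- intersect(c("condition", "experiment", "first_test"),
                        names(cells))
  key <- interaction(cells[key_vars], drop = TRUE, sep = " ")
  draws <- list()
  summ <- list()
  for (lv in levels(key)) {
    i2 <- which(key == lv & cells$trial_type == "two_change")
    i1 <- which(key == lv & cells$trial_type == "one_change")
    stopifnot(length(i2) == 1, length(i1) == 1)
    ld <- cm$mu[i2, ] - cm$mu[i1, ]
    sd_ <- if (fit$likelihood == "lognormal") {
      exp(cm$mu[i2, ]) - exp(cm$mu[i1, ])
    } else {
      ld
    }
    draws[[lv]] <- list(log_diff = ld, seconds_diff = sd_)
    qt <- stats::quantile(sd_, c(0.025, 0.5, 0.975), names = FALSE)
    summ[[lv]] <- data.frame(
      subcondition = lv, median_s = qt[2], lower_95 = qt[1],
      upper_95 = qt[3],
      credible = qt[1] > 0 | qt[3] < 0, stringsAsFactors = FALSE
    )
  }
  list(draws = draws, summary = do.call(rbind, summ))
}

#' @export
predict.lt_bayes <- function(object, type = c("cells", "linear"), ...) {
  type <- match.arg(type)
  if (type == "cells") return(posterior_predictive_cells(object, ...))
  beta <- coef(object)
  mu <- as.numeric(object$design %*% beta)
  if (object$subject_effects) {
    u <- apply(.draw_matrix(object, paste0("u[", object$subj_levels, "]")),
               2, stats::median)
    mu <- mu + u[object$subj]
  }
  mu
}

#' @export
residuals.lt_bayes <- function(object, ...) {
  z <- if (object$likelihood == "lognormal") {
    log(object$trials$looking_s)
  } else {
    object$trials$looking_s
  }
  r <- z - predict(object, type = "linear")
  attr(r, "censored") <- object$trials$censored
  r
}

#' Simulate replicate trial tables from the posterior predictive
#'
#' Draws `nsim` replicate datasets of the fitted design: for each replicate
#' a posterior draw is selected, new subject intercepts and residuals are
#' drawn, and the working-scale values are transformed back to seconds and
#' censored at the ceiling.
#'
#' @param object An `lt_bayes` fit.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `lt_trials` tables.
#' @export
simulate.lt_bayes <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    beta_all <- .draw_matrix(object, object$terms)
    sig_u <- .draw_matrix(object, "sigma_subject")[, 1]
    sig_e <- .draw_matrix(object, "sigma_obs")[, 1]
    lapply(seq_len(nsim), function(s) {
      i <- sample.int(nrow(beta_all), 1)
      mu <- as.numeric(object$design %*% beta_all[i, ])
      J <- length(object$subj_levels)
      u <- stats::rnorm(J, 0, sig_u[i])
      z <- mu + u[object$subj] + stats::rnorm(length(mu), 0, sig_e[i])
      y <- if (object$likelihood == "lognormal") exp(z) else pmax(z, 1e-3)
      cens <- y >= object$censor_limit_s
      rep_tab <- object$trials
      rep_tab$looking_s <- ifelse(cens, object$censor_limit_s, y)
      rep_tab$censored <- cens
      validate_trials(rep_tab, censor_limit_s = object$censor_limit_s)
    })
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' @export
plot.lt_bayes <- function(x, level = 95, ...) {
  s <- summary(x, levels = level)
  s <- s[s$term %in% x$terms, ]
  k <- nrow(s)
  lo <- s[[sprintf("lower_%g", level)]]
  hi <- s[[sprintf("upper_%g", level)]]
  old <- graphics::par(mar = c(4, 18, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(
    s$median, rev(seq_len(k)), xlim = range(c(lo, hi, 0)),
    ylim = c(0.5, k + 0.5), yaxt = "n", pch = 19,
    xlab = "coefficient (working scale)", ylab = "",
    main = sprintf("%s / %s censoring: %g%% intervals",
                   x$likelihood, x$censoring, level), ...
  )
  graphics::segments(lo, rev(seq_len(k)), hi, rev(seq_len(k)))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = rev(seq_len(k)), labels = s$term, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}
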