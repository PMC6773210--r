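# Bayesian model family: likelihood oracles, sampler correctness against a
# grid-quadrature oracle, summaries, Bayesian R2, posterior predictive and
# within-subject difference posteriors.

test_that("integrated and uncensored log-likelihoods coincide without censoring, and a censored row at the mean contributes log(1/2)", {
  tr <- toy_trials(c(10, 20, 30, 40))
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  par <- list(beta = 3.2, sigma_obs = 0.5)
  for (lik in c("lognormal", "normal")) {
    expect_equal(
      lt_loglik(par, tr, X, lik, "integrated"),
      lt_loglik(par, tr, X, lik, "none")
    )
  }

  tr2 <- toy_trials(c(30, 60), censored = c(FALSE, TRUE))
  X2 <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  par2 <- list(beta = log(60), sigma_obs = 0.7)
  base <- dnorm(log(30), log(60), 0.7, log = TRUE) - log(30)
  expect_equal(lt_loglik(par2, tr2, X2, "lognormal", "integrated"),
               base + log(1 / 2))

  expect_error(
    lt_loglik(par2, toy_trials(c(-1, 30)), X2, "lognormal", "integrated"),
    "non-positive"
  )
})

test_that("integrated likelihood matches quadrature of the latent-mode density on a toy set", {
  set.seed(5)
  n <- 10
  y <- c(12, 25, 33, 60, 60, 41, 8, 60, 55, 19)
  cens <- y == 60
  tr <- toy_trials(y, censored = cens)
  X <- cbind(`(Intercept)` = rep(1, n), slope = seq(-0.5, 0.5, length.out = n))
  for (lik in c("lognormal", "normal")) {
    par <- if (lik == "lognormal") {
      list(beta = c(3.5, 0.4), sigma_obs = 0.6)
    } else {
      list(beta = c(35, 10), sigma_obs = 12)
    }
    ll_int <- lt_loglik(par, tr, X, lik, "integrated")
    limit <- if (lik == "lognormal") log(60) else 60
    mu <- as.numeric(X %*% par$beta)
    # quadrature over each censored coordinate of the latent-mode density
    ll_quad <- sum(vapply(which(!cens), function(i) {
      d <- dnorm(if (lik == "lognormal") log(y[i]) else y[i], mu[i],
                 par$sigma_obs, log = TRUE)
      if (lik == "lognormal") d - log(y[i]) else d
    }, 0)) +
      sum(vapply(which(cens), function(i) {
        log(integrate(function(z) dnorm(z, mu[i], par$sigma_obs),
                      limit, Inf, rel.tol = 1e-12)$value)
      }, 0))
    expect_equal(ll_int, ll_quad, tolerance = 1e-6)
  }
})

test_that("latent-mode likelihood evaluates the density at supplied bounded latents", {
  tr <- toy_trials(c(30, 60), censored = c(FALSE, TRUE))
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  par <- list(beta = 3.5, sigma_obs = 0.5, latent = log(75))
  ll <- lt_loglik(par, tr, X, "lognormal", "latent")
  expect_equal(ll,
               dnorm(log(30), 3.5, 0.5, log = TRUE) - log(30) +
                 dnorm(log(75), 3.5, 0.5, log = TRUE))
  par$latent <- log(50) # below the ceiling: not a valid latent value
  expect_error(lt_loglik(par, tr, X, "lognormal", "latent"), "above")
})

test_that("intercept-only posterior matches a dense 2-D grid-quadrature oracle", {
  set.seed(8)
  y <- round(exp(rnorm(12, 3.3, 0.45)), 3)
  tr <- toy_trials(y)
  X <- matrix(1, 12, 1, dimnames = list(NULL, "(Intercept)"))
  pri <- lt_priors("lognormal")
  fit <- suppressWarnings(ltcens:::.lt_bayes_fit(
    tr, X, scheme = NULL, likelihood = "lognormal", censoring = "integrated",
    priors = pri, chains = 4, n_draws = 1000, warmup = 300, seed = 2,
    subject_effects = FALSE, censor_limit_s = 60
  ))
  dm <- ltcens:::.draw_matrix(fit, c("(Intercept)", "sigma_obs"))

  z <- log(y)
  lpost <- function(m, s) {
    sum(dnorm(z, m, s, log = TRUE)) +
      dnorm(m, pri$intercept_location, pri$intercept_scale, log = TRUE) -
      s^2 / (2 * pri$sigma_obs_scale^2)
  }
  mg <- seq(2.6, 4.0, length.out = 400)
  sg <- seq(0.12, 1.6, length.out = 400)
  lp <- outer(mg, sg, Vectorize(lpost))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mean_m <- sum(rowSums(w) * mg)
  mean_s <- sum(colSums(w) * sg)

  ess_m <- ltcens:::.ess(fit$draws[, , "(Intercept)"])
  ess_s <- ltcens:::.ess(fit$draws[, , "sigma_obs"])
  expect_lt(abs(mean(dm[, 1]) - mean_m), 3 * sd(dm[, 1]) / sqrt(ess_m))
  expect_lt(abs(mean(dm[, 2]) - mean_s), 3 * sd(dm[, 2]) / sqrt(ess_s))
})

test_that("summary intervals match an order-statistics oracle and flag credibility", {
  tr <- simulate_experiment(lt_config(seed = 51, n_per_cell = 4))
  fit <- quiet_bayes(tr, scheme = reduced_scheme(), seed = 3,
                     n_draws = 250, warmup = 250)
  s <- summary(fit, levels = c(90, 95))
  expect_identical(s$term[seq_along(fit$terms)], fit$terms)
  for (i in seq_len(nrow(s))) {
    x <- sort(ltcens:::.draw_matrix(fit, s$term[i])[, 1])
    n <- length(x)
    # type-7 quantile by hand
    q7 <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
    }
    expect_equal(s$lower_95[i], q7(0.025), tolerance = 1e-10)
    expect_equal(s$upper_90[i], q7(0.95), tolerance = 1e-10)
    expect_identical(s$credible_95[i],
                     unname(q7(0.025) > 0 | q7(0.975) < 0))
  }
  # symmetric toy draws: median 0, no credible exclusion
  expect_identical(median(c(-1, 0, 1)), 0)
})

test_that("13-term summary has one row per printed coefficient", {
  tr <- simulate_experiment(lt_config(seed = 52, n_per_cell = 4))
  fit <- quiet_bayes(tr, seed = 3, n_draws = 150, warmup = 150)
  s <- summary(fit)
  expect_equal(sum(s$term %in% fit$terms), 13)
})

test_that("Bayesian R2 matches a by-hand ratio per draw, and behaves at the noise limits", {
  tr <- simulate_experiment(lt_config(seed = 53, n_per_cell = 4))
  fit <- quiet_bayes(tr, scheme = reduced_scheme(), seed = 4,
                     n_draws = 200, warmup = 200)
  r2 <- bayes_r2(fit)
  # recompute draw 7 by hand from the stored draws
  i <- 7
  beta <- ltcens:::.draw_matrix(fit, fit$terms)[i, ]
  u <- ltcens:::.draw_matrix(fit, paste0("u[", fit$subj_levels, "]"))[i, ]
  sig <- ltcens:::.draw_matrix(fit, "sigma_obs")[i, 1]
  lp <- as.numeric(fit$design %*% beta) + u[fit$subj]
  expect_equal(r2[i], unname(var(lp) / (var(lp) + sig^2)),
               tolerance = 1e-10)

  # near-noiseless generator: R2 -> 1
  cfg_hi <- lt_config(seed = 54, sigma_obs = 1e-3, sigma_subject = 0.3,
                      coder_sd_s = 0, censor_limit_s = Inf,
                      beta = reduced_beta(trial = 0.4, order = 0.2),
                      n_per_cell = 4)
  tr_hi <- simulate_experiment(cfg_hi, reduced_scheme())
  fit_hi <- quiet_bayes(tr_hi, scheme = reduced_scheme(), seed = 5,
                        n_draws = 200, warmup = 200)
  expect_gte(attr(bayes_r2(fit_hi), "median"), 0.99)

  # null generator, intercept-only hierarchical model: R2 near zero
  cfg0 <- lt_config(seed = 55, beta = reduced_beta(trial = 0, order = 0),
                    sigma_subject = 0, coder_sd_s = 0, censor_limit_s = Inf,
                    n_per_cell = 8)
  tr0 <- simulate_experiment(cfg0, reduced_scheme())
  X0 <- matrix(1, nrow(tr0), 1, dimnames = list(NULL, "(Intercept)"))
  fit0 <- suppressWarnings(ltcens:::.lt_bayes_fit(
    tr0, X0, scheme = NULL, likelihood = "lognormal", censoring = "none",
    priors = lt_priors("lognormal"), chains = 4, n_draws = 200,
    warmup = 200, seed = 6, subject_effects = TRUE, censor_limit_s = Inf
  ))
  expect_lte(attr(bayes_r2(fit0), "median"), 0.05)
})

test_that("posterior predictive cells clamp at the ceiling and match the median transform", {
  tr <- simulate_experiment(lt_config(seed = 56, n_per_cell = 4))
  fit <- quiet_bayes(tr, scheme = reduced_scheme(), seed = 7,
                     n_draws = 300, warmup = 300)
  pp <- posterior_predictive_cells(fit)
  expect_true(all(pp$upper_95 <= fit$censor_limit_s))
  expect_true(all(pp$lower_95 > 0))
  expect_identical(posterior_predictive_cells(fit), pp) # seeded: repeatable

  # uncensored intercept-only-like fit: predictive median ~ exp(median mu)
  cfg <- lt_config(seed = 57, beta = reduced_beta(intercept = 3.0,
                                                  trial = 0, order = 0),
                   sigma_subject = 0.2, coder_sd_s = 0,
                   censor_limit_s = Inf, n_per_cell = 8)
  tru <- simulate_experiment(cfg, reduced_scheme())
  fitu <- quiet_bayes(tru, scheme = reduced_scheme(), seed = 8,
                      n_draws = 500, warmup = 300,
                      censor_limit_s = Inf)
  ppu <- posterior_predictive_cells(fitu)
  cm <- ltcens:::.cell_mu_draws(fitu)
  for (i in seq_len(nrow(ppu))) {
    expect_equal(ppu$median[i], exp(median(cm$mu[i, ])), tolerance = 0.12)
  }
})

test_that("within-subject difference posteriors cover six subconditions and equal the direct cell-mean contrast", {
  tr <- simulate_experiment(lt_config(seed = 58, n_per_cell = 4))
  fit <- quiet_bayes(tr, seed = 9, n_draws = 200, warmup = 200)
  wd <- within_subject_difference(fit)
  expect_equal(nrow(wd$summary), 6)
  expect_setequal(
    wd$summary$subcondition,
    as.vector(outer(c("congruent", "incongruent", "shape_change"),
                    c("one_change_first", "two_change_first"), paste))
  )
  # two-route equality: recompute one subcondition directly from the draws
  cm <- ltcens:::.cell_mu_draws(fit)
  sel2 <- cm$cells$condition == "congruent" &
    cm$cells$first_test == "one_change_first" &
    cm$cells$trial_type == "two_change"
  sel1 <- cm$cells$condition == "congruent" &
    cm$cells$first_test == "one_change_first" &
    cm$cells$trial_type == "one_change"
  direct <- exp(cm$mu[which(sel2), ]) - exp(cm$mu[which(sel1), ])
  expect_equal(wd$draws[["congruent one_change_first"]]$seconds_diff,
               direct)

  # generator with zero trial-type structure: differences centred at 0
  cfg0 <- lt_config(seed = 59, beta = reduced_beta(trial = 0, txo = 0),
                    coder_sd_s = 0, n_per_cell = 8)
  tr0 <- simulate_experiment(cfg0, reduced_scheme())
  fit0 <- quiet_bayes(tr0, scheme = reduced_scheme(), seed = 10,
                      n_draws = 300, warmup = 300)
  wd0 <- within_subject_difference(fit0)
  expect_true(all(wd0$summary$lower_95 < 0 & wd0$summary$upper_95 > 0))
})

test_that("with no observation at the ceiling, censored and uncensored fits coincide", {
  tr <- simulate_experiment(lt_config(seed = 62, n_per_cell = 4,
                                      censor_limit_s = Inf))
  f_cens <- quiet_bayes(tr, scheme = reduced_scheme(), censoring = "latent",
                        seed = 15, n_draws = 100, warmup = 100,
                        censor_limit_s = Inf)
  f_none <- quiet_bayes(tr, scheme = reduced_scheme(), censoring = "none",
                        seed = 15, n_draws = 100, warmup = 100,
                        censor_limit_s = Inf)
  expect_identical(f_cens$draws, f_none$draws)
})

test_that("sampling is deterministic given seed and settings", {
  tr <- simulate_experiment(lt_config(seed = 60, n_per_cell = 4))
  f1 <- quiet_bayes(tr, scheme = reduced_scheme(), seed = 11,
                    n_draws = 100, warmup = 100)
  f2 <- quiet_bayes(tr, scheme = reduced_scheme(), seed = 11,
                    n_draws = 100, warmup = 100)
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_bayes(tr, scheme = reduced_scheme(), seed = 12,
                    n_draws = 100, warmup = 100)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("latent censored draws respect the bound and the convergence gate warns", {
  cfg <- lt_config(seed = 61, beta = reduced_beta(intercept = 4.0),
                   n_per_cell = 4)
  tr <- simulate_experiment(cfg, reduced_scheme())
  expect_gt(sum(tr$censored), 0)
  fit <- quiet_bayes(tr, scheme = reduced_scheme(), censoring = "latent",
                     seed = 13, n_draws = 200, warmup = 200)
  lat <- ltcens:::.draw_matrix(
    fit, grep("^latent\\[", fit$par_names, value = TRUE))
  expect_true(all(lat >= log(60)))
  expect_warning(
    lt_bayes(tr, scheme = reduced_scheme(), seed = 14,
             n_draws = 20, warmup = 5),
    "convergence gate"
  )
})
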