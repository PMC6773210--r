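# Cross-experiment aggregate model: censored log-normal fit over the
# 21-term nested contrast scheme combining the brightness and length
# experiments.

#' Fit the cross-experiment aggregate model
#'
#' Fits the censored log-normal hierarchical regression over the combined
#' brightness + length dataset using the 21-term aggregate contrast scheme
#' (nested condition-by-dimension coding over the five condition-experiment
#' cells; subject intercept variance shared across experiments). This is the
#' aggregate analogue of [lt_bayes()] restricted to the likelihood and
#' censoring treatment appropriate for ceiling-censored looking times.
#'
#' @param trials An `lt_trials` table spanning both experiments (the length
#'   experiment contains only the congruent and incongruent conditions).
#' @param priors An [lt_priors()] for the lognormal likelihood.
#' @param censoring Censoring treatment (default latent-parameter
#'   augmentation).
#' @inheritParams lt_bayes
#' @return An `lt_bayes` fit whose scheme is the aggregate one; all
#'   `lt_bayes` methods apply.
#' @export
fit_aggregate <- function(trials,
                          priors = lt_priors("lognormal"),
                          censoring = c("latent", "integrated", "none"),
                          chains = 4, n_draws = 500, warmup = 500,
                          seed = 1L,
                          censor_limit_s = attr(trials, "censor_limit_s") %||% 60) {
  censoring <- match.arg(censoring)
  trials <- validate_trials(as.data.frame(trials),
                            censor_limit_s = censor_limit_s)
  present <- unique(trials$experiment)
  if (!all(c("brightness", "length") %in% present)) {
    stop("aggregate model requires trials from both experiments; missing: ",
         paste(setdiff(c("brightness", "length"), present), collapse = ", "),
         call. = FALSE)
  }
  scheme <- build_contrast_scheme("aggregate")
  design <- build_design_matrix(trials, scheme)
  .lt_bayes_fit(trials, design, scheme, "lognormal", censoring, priors,
                chains, n_draws, warmup, seed, TRUE, censor_limit_s)
}

#' Posterior of a weighted combination of design-cell means
#'
#' Computes, per posterior draw, a weighted combination of the model-implied
#' design-cell means on the working (log) scale, for derived contrasts not
#' parameterised directly — e.g. the incongruent brightness-minus-length
#' offset averaged over trial type and order.
#'
#' @param fit An `lt_bayes` fit (single-experiment or aggregate).
#' @param weights Data.frame with the scheme's cell key columns
#'   (`condition`, `experiment` for aggregate fits, `trial_type`,
#'   `first_test` — any subset; omitted factors are averaged with equal
#'   weight) and a numeric `w` column. Rows matching multiple cells spread
#'   their weight equally over them.
#' @return List with `draws` (numeric vector, log scale), and `summary`
#'   (median and 95% equal-tailed interval).
#' @examples
#' \donttest{
#' agg <- simulate_aggregate(lt_config(seed = 1))
#' fit <- fit_aggregate(agg, n_draws = 250, warmup = 250, seed = 1)
#' w <- data.frame(condition = "incongruent",
#'                 experiment = c("brightness", "length"), w = c(1, -1))
#' derived_contrast(fit, w)$summary
#' }
#' @export
derived_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "lt_bayes"), is.data.frame(weights),
            "w" %in% names(weights))
  cm <- .cell_mu_draws(fit)
  cells <- cm$cells
  key_cols <- intersect(names(weights), names(cells))
  if (!length(key_cols)) {
    stop("weights must name at least one cell key column", call. = FALSE)
  }
  wvec <- numeric(nrow(cells))
  for (i in seq_len(nrow(weights))) {
    sel <- rep(TRUE, nrow(cells))
    for (col in key_cols) {
      sel <- sel & cells[[col]] == weights[[col]][i]
    }
    if (!any(sel)) {
      stop("weight row ", i, " matches no design cell", call. = FALSE)
    }
    wvec[sel] <- wvec[sel] + weights$w[i] / sum(sel)
  }
  draws <- as.numeric(t(wvec) %*% cm$mu)
  qt <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  list(
    draws = draws,
    summary = data.frame(median = qt[2], lower_95 = qt[1], upper_95 = qt[3],
                         credible = qt[1] > 0 | qt[3] < 0)
  )
}
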