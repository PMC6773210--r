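# Simulation-based power analysis for design effects of the mixed ANOVA.

#' Simulation-based power for a mixed-ANOVA effect
#'
#' Estimates the power of a named effect of the mixed-design ANOVA under
#' the generator's conditions: datasets are simulated from `config`, each is
#' analysed with [mixed_anova()], and power is the fraction of simulations
#' whose p-value for the effect falls below `alpha`. The binomial
#' Monte-Carlo standard error is reported. The effect size is whatever
#' `config$beta` implies — the module takes effects as input and makes no
#' claim about any particular historical effect size.
#'
#' @param config An [lt_config()]; `config$beta` encodes the assumed true
#'   effects (log-seconds scale).
#' @param effect Effect name as it appears in the [mixed_anova()] table:
#'   one of `condition`, `first_test`, `trial_type`, `condition:first_test`,
#'   `condition:trial_type`, `first_test:trial_type`,
#'   `condition:first_test:trial_type`.
#' @param n_per_cell Subjects per condition-by-order cell (16 per condition
#'   corresponds to 8).
#' @param alpha Significance level (default 0.05).
#' @param n_sims Number of simulated datasets (>= 100).
#' @param seed Root seed; simulation `i` uses a deterministic derived seed.
#' @param scheme Contrast scheme aligned with `config$beta`.
#' @return List of class `lt_power`: `power`, `mc_se`, `n_sims`, `effect`,
#'   `alpha`, `n_per_cell`.
#' @export
estimate_power <- function(config = lt_config(),
                           effect = "condition:trial_type",
                           n_per_cell = config$n_per_cell,
                           alpha = 0.05,
                           n_sims = 200,
                           seed = config$seed,
                           scheme = build_contrast_scheme("single_experiment")) {
  stopifnot(n_sims >= 100, alpha > 0, alpha < 1)
  known <- c("condition", "first_test", "trial_type", "condition:first_test",
             "condition:trial_type", "first_test:trial_type",
             "condition:first_test:trial_type")
  if (!effect %in% known) {
    stop("unknown effect '", effect, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  cfg <- config
  cfg$n_per_cell <- n_per_cell
  hits <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    cfg$seed <- .subject_seed(seed, paste0("power-sim-", i))
    tr <- simulate_experiment(cfg, scheme)
    tab <- mixed_anova(tr)$table
    p <- tab$p[tab$effect == effect]
    hits[i] <- is.finite(p) && p < alpha
  }
  pw <- mean(hits)
  structure(
    list(power = pw, mc_se = sqrt(pw * (1 - pw) / n_sims), n_sims = n_sims,
         effect = effect, alpha = alpha, n_per_cell = n_per_cell),
    class = "lt_power"
  )
}

#' @export
print.lt_power <- function(x, ...) {
  cat(sprintf(
    "Power for %s at alpha = %g, %d subjects/cell: %.3f (MC-SE %.3f, %d sims)\n",
    x$effect, x$alpha, x$n_per_cell, x$power, x$mc_se, x$n_sims
  ))
  invisible(x)
}

#' Power curve over sample size and effect scale
#'
#' Evaluates [estimate_power()] on a grid: sample sizes crossed with
#' multiplicative scalings of a set of `config$beta` entries (by default the
#' condition-by-trial-type interaction contrasts).
#'
#' @inheritParams estimate_power
#' @param n_per_cell Vector of subjects per condition-by-order cell.
#' @param effect_scale Vector of multipliers applied to `effect_terms`.
#' @param effect_terms Names of `config$beta` entries scaled by
#'   `effect_scale`.
#' @return Data.frame: `n_per_cell`, `effect_scale`, `power`, `mc_se`.
#' @export
power_curve <- function(config = lt_config(),
                        effect = "condition:trial_type",
                        n_per_cell = c(4, 8, 16),
                        effect_scale = 1,
                        effect_terms = grep(
                          "Shape\\) x \\(2-Change - 1-Change\\)$",
                          names(config$beta), value = TRUE),
                        alpha = 0.05, n_sims = 200, seed = config$seed) {
  rows <- list()
  for (sc in effect_scale) {
    cfg <- config
    cfg$beta[effect_terms] <- cfg$beta[effect_terms] * sc
    for (n in n_per_cell) {
      pw <- estimate_power(cfg, effect = effect, n_per_cell = n,
                           alpha = alpha, n_sims = n_sims,
                           seed = .subject_seed(seed, paste0("curve", sc, n)))
      rows[[length(rows) + 1]] <- data.frame(
        n_per_cell = n, effect_scale = sc, power = pw$power, mc_se = pw$mc_se
      )
    }
  }
  do.call(rbind, rows)
}
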