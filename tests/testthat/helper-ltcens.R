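# shared test utilities: small fits never need the full convergence gate
quiet_bayes <- function(...) suppressWarnings(lt_bayes(...))

# within-factors-only scheme (intercept, covariate, trial type, order, their
# interaction): the smallest design the samplers accept, used where a full
# 13-term model would only add Monte-Carlo noise
reduced_scheme <- function() {
  build_contrast_scheme(
    "single_experiment",
    cell_codes = data.frame(
      condition = c("congruent", "incongruent", "shape_change")
    )
  )
}

reduced_beta <- function(intercept = 3.6, trial = 0.3, order = 0.1,
                         txo = 0, famil = 0) {
  sch <- reduced_scheme()
  stats::setNames(c(intercept, famil, trial, order, txo), sch$terms)
}

# study-condition coefficients with the condition-by-trial-type structure
# (and its order modulation) removed: the null for the interaction test
.default_null_interaction_beta <- function() {
  b <- lt_config()$beta
  b[grep("Shape\\) x \\(2-Change - 1-Change\\)", names(b))] <- 0
  b
}

# mixed-ANOVA sums of squares from first principles: factorial effect
# decomposition by inclusion-exclusion over margin means, and the two error
# strata from subject means (independent of aov)
mixed_anova_oracle <- function(trials) {
  d <- data.frame(
    y = trials$looking_s,
    A = trials$condition, B = trials$first_test, W = trials$trial_type,
    s = trials$subject_id
  )
  g <- mean(d$y)
  m <- function(...) {
    k <- interaction(lapply(list(...), function(v) d[[v]]), drop = TRUE)
    ave(d$y, k)
  }
  effA <- m("A") - g
  effB <- m("B") - g
  effW <- m("W") - g
  effAB <- m("A", "B") - m("A") - m("B") + g
  effAW <- m("A", "W") - m("A") - m("W") + g
  effBW <- m("B", "W") - m("B") - m("W") + g
  effABW <- m("A", "B", "W") - m("A", "B") - m("A", "W") - m("B", "W") +
    m("A") + m("B") + m("W") - g
  subj_mean <- ave(d$y, d$s)
  err_b <- subj_mean - m("A", "B")
  err_w <- d$y - subj_mean - m("A", "B", "W") + m("A", "B")
  ss <- function(x) sum(x^2)
  list(
    ss = c(condition = ss(effA), first_test = ss(effB),
           `condition:first_test` = ss(effAB),
           trial_type = ss(effW), `condition:trial_type` = ss(effAW),
           `first_test:trial_type` = ss(effBW),
           `condition:first_test:trial_type` = ss(effABW)),
    ss_err_between = ss(err_b), ss_err_within = ss(err_w)
  )
}

# minimal unvalidated trial frame for likelihood-level tests (one subject
# per row keeps the random-intercept structure trivial)
toy_trials <- function(looking_s, censored = rep(FALSE, length(looking_s)),
                       subject_id = paste0("T", seq_along(looking_s))) {
  data.frame(
    subject_id = subject_id, experiment = "brightness",
    condition = "congruent", familiarization_group = "small",
    first_test = "one_change_first", trial_type = "one_change",
    trial_index = 1L, familiarization_looking_s = 30,
    looking_s = looking_s, censored = censored, stringsAsFactors = FALSE
  )
}
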