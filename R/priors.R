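# Weakly informative default priors for the Bayesian model family.
#
# Scales are justified by the 0-60 s range of the measurement: on the log
# scale a unit-scale coefficient prior spans multiplicative effects of about
# e^2 at 2 SD, and the intercept prior centres on a typical 30-s look; on the
# raw scale 20 s plays the same role.

#' Prior specification for the Bayesian looking-time models
#'
#' All coefficient priors are normal with location 0 (the intercept has its
#' own location), variance components half-normal.
#'
#' @param likelihood `"lognormal"` (log-seconds scale) or `"normal"`
#'   (seconds scale); sets the default scales.
#' @param intercept_location,intercept_scale Normal prior on the intercept.
#' @param coef_scale Normal prior scale for all non-intercept coefficients
#'   (including the standardized familiarization covariate).
#' @param sigma_subject_scale,sigma_obs_scale Half-normal prior scales for
#'   the subject-intercept SD and residual SD.
#' @return List of class `lt_priors`.
#' @export
lt_priors <- function(likelihood = c("lognormal", "normal"),
                      intercept_location = NULL,
                      intercept_scale = NULL,
                      coef_scale = NULL,
                      sigma_subject_scale = NULL,
                      sigma_obs_scale = NULL) {
  likelihood <- match.arg(likelihood)
  def <- if (likelihood == "lognormal") {
    list(intercept_location = log(30), intercept_scale = 1,
         coef_scale = 1, sigma_subject_scale = 1, sigma_obs_scale = 1)
  } else {
    list(intercept_location = 30, intercept_scale = 20,
         coef_scale = 20, sigma_subject_scale = 20, sigma_obs_scale = 20)
  }
  out <- list(
    likelihood = likelihood,
    intercept_location = intercept_location %||% def$intercept_location,
    intercept_scale = intercept_scale %||% def$intercept_scale,
    coef_scale = coef_scale %||% def$coef_scale,
    sigma_subject_scale = sigma_subject_scale %||% def$sigma_subject_scale,
    sigma_obs_scale = sigma_obs_scale %||% def$sigma_obs_scale
  )
  stopifnot(out$intercept_scale > 0, out$coef_scale > 0,
            out$sigma_subject_scale > 0, out$sigma_obs_scale > 0)
  structure(out, class = "lt_priors")
}

# expand prior locations/scales to the scheme's coefficient vector
.prior_vectors <- function(priors, terms) {
  m0 <- ifelse(terms == "(Intercept)", priors$intercept_location, 0)
  s0 <- ifelse(terms == "(Intercept)", priors$intercept_scale,
               priors$coef_scale)
  list(m0 = m0, s0 = s0)
}
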