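# Synthetic trial-table generator.
#
# Emulates the statistical structure the models assume: log-normally
# distributed looking times with subject-level heterogeneity, right-censoring
# at the trial ceiling, and the two-coder measurement rule (average of the
# two closest of up to three coders, a third coder being consulted when the
# first two disagree by more than the threshold).

# Default true coefficients on the log-seconds scale, aligned to the
# single-experiment scheme. These are the package's reference estimates for
# the brightness study design under the censored log-normal model, with
# coefficients reading as labelled cell-mean differences.
.default_beta_single <- function() {
  c(
    `(Intercept)` = 3.43,
    `Familiarization Time` = 0.01,
    `Congruent--Shape Change` = -0.54,
    `Incongruent--Shape Change` = -0.20,
    `2-Change - 1-Change` = 0.34,
    `2-Change First - 1-Change First` = 0.11,
    `(Cong--Shape) x (2-Change - 1-Change)` = 0.69,
    `(Incong--Shape) x (2-Change - 1-Change)` = 0.42,
    `(Cong--Shape) x (2-Change First - 1-Change First)` = -0.85,
    `(Incong--Shape) x (2-Change First - 1-Change First)` = -0.40,
    `(2-Change - 1-Change) x (2-Change First - 1-Change First)` = 0.30,
    `(Cong--Shape) x (2-Change - 1-Change) x (2-Change First - 1-Change First)` = -0.30,
    `(Incong--Shape) x (2-Change - 1-Change) x (2-Change First - 1-Change First)` = 0.75
  )
}

#' Generator configuration
#'
#' Bundles the true parameter vector and nuisance structure of the synthetic
#' experiment. Defaults reproduce the reference study conditions: 48 subjects
#' (8 per condition-by-order cell, 16 per condition), log-normal looking
#' times with subject SD 0.4 and residual SD 0.6 on the log scale
#' (back-derived from the study's marginal/conditional pseudo-R-squared of
#' 0.29/0.50), right-censoring at the 60-s maximum trial length, per-coder
#' measurement SD 3.7 s (back-derived from the reported 34% third-coder rate
#' under the 5-s disagreement rule), and a 60-s familiarization phase.
#'
#' @param beta Named true coefficient vector on the log-seconds scale aligned
#'   to the contrast scheme (intercept, familiarization covariate in
#'   standardized units, then the cell contrasts).
#' @param sigma_subject SD of subject intercepts on the log scale (>= 0).
#' @param sigma_obs Residual SD on the log scale (> 0).
#' @param censor_limit_s Maximum trial length in seconds (may be `Inf`).
#' @param n_per_cell Subjects per condition-by-order cell (the reference
#'   design has 8, i.e. 16 per condition). Must be even for exact
#'   counterbalancing of the familiarization group.
#' @param coder_sd_s Per-coder measurement SD in seconds (>= 0).
#' @param coder_threshold_s Disagreement threshold (seconds) beyond which a
#'   third coder is consulted.
#' @param familiarization_duration_s Length of the familiarization phase.
#' @param fam_shape1,fam_shape2 Beta-distribution shapes of the subject
#'   attentiveness fraction; familiarization looking is
#'   `familiarization_duration_s` times this fraction.
#' @param fam_cor Gaussian-copula correlation between the attentiveness
#'   fraction and the subject intercept.
#' @param seed Root integer seed; per-subject substreams are derived
#'   deterministically from it, so adding subjects never perturbs existing
#'   ones.
#' @return A list of class `lt_config`.
#' @export
lt_config <- function(beta = .default_beta_single(),
                      sigma_subject = 0.4,
                      sigma_obs = 0.6,
                      censor_limit_s = 60,
                      n_per_cell = 8,
                      coder_sd_s = 3.7,
                      coder_threshold_s = 5,
                      familiarization_duration_s = 60,
                      fam_shape1 = 3,
                      fam_shape2 = 2.2,
                      fam_cor = 0.3,
                      seed = 1L) {
  stopifnot(
    sigma_subject >= 0, sigma_obs > 0, censor_limit_s > 0,
    n_per_cell >= 1, coder_sd_s >= 0, coder_threshold_s > 0,
    familiarization_duration_s > 0, fam_shape1 > 0, fam_shape2 > 0,
    abs(fam_cor) <= 1
  )
  structure(
    list(beta = beta, sigma_subject = sigma_subject, sigma_obs = sigma_obs,
         censor_limit_s = censor_limit_s, n_per_cell = n_per_cell,
         coder_sd_s = coder_sd_s, coder_threshold_s = coder_threshold_s,
         familiarization_duration_s = familiarization_duration_s,
         fam_shape1 = fam_shape1, fam_shape2 = fam_shape2,
         fam_cor = fam_cor, seed = as.integer(seed)),
    class = "lt_config"
  )
}

#' @export
print.lt_config <- function(x, ...) {
  cat("Looking-time generator config:\n")
  cat("  subjects/cell:", x$n_per_cell,
      " sigma_subject:", x$sigma_subject, " sigma_obs:", x$sigma_obs, "\n")
  cat("  censor limit:", x$censor_limit_s, "s  coder sd:", x$coder_sd_s,
      "s  threshold:", x$coder_threshold_s, "s  seed:", x$seed, "\n")
  invisible(x)
}

# deterministic 31-bit hash of a subject key combined with the root seed
.subject_seed <- function(seed, key) {
  m <- 2147483647
  x <- as.numeric(seed %% m)
  for (ch in utf8ToInt(key)) x <- (x * 31 + ch) %% m
  as.integer(x)
}

# run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Two-coder measurement model
#'
#' Applies the coding rule to true looking times: two coder readings are
#' drawn as `true + Normal(0, coder_sd_s)`; when they disagree by more than
#' `coder_threshold_s` a third reading is drawn and the average of the two
#' closest readings is taken, otherwise the first two are averaged. The
#' recorded value is clamped to the censor limit afterwards (online coding
#' ends the trial at the ceiling) and floored just above zero.
#'
#' @param true_looking_s Vector of true looking times (> 0, seconds).
#' @param config An [lt_config()]; uses `coder_sd_s`, `coder_threshold_s`,
#'   `censor_limit_s`.
#' @return Numeric vector of recorded looking times with logical attribute
#'   `third_coder` marking trials on which a third coder was consulted.
#'   Draws come from the current RNG stream.
#' @export
apply_coder_model <- function(true_looking_s, config) {
  stopifnot(all(true_looking_s > 0))
  n <- length(true_looking_s)
  sd <- config$coder_sd_s
  if (sd == 0) {
    rec <- pmin(true_looking_s, config$censor_limit_s)
    attr(rec, "third_coder") <- rep(FALSE, n)
    return(rec)
  }
  r1 <- true_looking_s + stats::rnorm(n, 0, sd)
  r2 <- true_looking_s + stats::rnorm(n, 0, sd)
  third <- abs(r1 - r2) > config$coder_threshold_s
  rec <- (r1 + r2) / 2
  if (any(third)) {
    r3 <- true_looking_s[third] + stats::rnorm(sum(third), 0, sd)
    rec[third] <- .closest_pair_mean(r1[third], r2[third], r3)
  }
  rec <- pmin(rec, config$censor_limit_s)
  rec <- pmax(rec, 1e-3)
  attr(rec, "third_coder") <- third
  rec
}

# mean of the two closest of three readings (vectorised); ties resolved in
# favour of the earlier pair (1-2, then 1-3)
.closest_pair_mean <- function(r1, r2, r3) {
  d12 <- abs(r1 - r2)
  d13 <- abs(r1 - r3)
  d23 <- abs(r2 - r3)
  out <- (r1 + r2) / 2
  use13 <- d13 < d12 & d13 <= d23
  use23 <- d23 < d12 & d23 < d13
  out[use13] <- (r1[use13] + r3[use13]) / 2
  out[use23] <- (r2[use23] + r3[use23]) / 2
  out
}

#' Stimulus schedule metadata
#'
#' Returns the auditory/visual stimulus metadata for a familiarization or
#' test sequence: sequence duration at constant per-syllable timing (the
#' 6-syllable sequence lasts 1.4 s, so each syllable slot is 1.4/6 s), an
#' inter-sequence silence drawn uniformly between 2 and 3 s, and the display
#' luminance levels used by the design (6 and 46 cd/m2 for the dim/bright
#' star, 31 cd/m2 for the gray control shapes).
#'
#' @param n_syllables 6 or 18.
#' @return List of class `lt_stimulus`: `n_syllables`, `sequence_duration_s`,
#'   `inter_sequence_silence_s`, `luminance_cd_m2`.
#' @export
stimulus_schedule <- function(n_syllables) {
  if (!(length(n_syllables) == 1 && n_syllables %in% c(6, 18))) {
    stop("n_syllables must be 6 or 18", call. = FALSE)
  }
  structure(
    list(
      n_syllables = n_syllables,
      sequence_duration_s = n_syllables * (1.4 / 6),
      inter_sequence_silence_s = stats::runif(1, 2, 3),
      luminance_cd_m2 = c(dim = 6, bright = 46, gray = 31)
    ),
    class = "lt_stimulus"
  )
}

# align a coefficient vector with the scheme's term order (names optional)
.align_beta <- function(beta, scheme) {
  if (length(beta) != length(scheme$terms)) {
    stop("beta must have one entry per scheme term (",
         length(scheme$terms), ")", call. = FALSE)
  }
  if (is.null(names(beta))) {
    names(beta) <- scheme$terms
  } else if (!setequal(names(beta), scheme$terms)) {
    stop("names(beta) do not match the scheme terms", call. = FALSE)
  }
  beta[scheme$terms]
}

# log-scale cell means implied by (scheme, beta), covariate column excluded
.cell_mu_table <- function(scheme, beta) {
  beta <- .align_beta(beta, scheme)
  code_cols <- setdiff(names(scheme$cells),
                       c("condition", "experiment", "trial_type", "first_test"))
  b <- beta[setdiff(scheme$terms, "Familiarization Time")]
  cells <- scheme$cells
  cells$mu <- as.numeric(as.matrix(cells[code_cols]) %*% b)
  cells[c(intersect(c("condition", "experiment"), names(cells)),
          "trial_type", "first_test", "mu")]
}

# moments of the familiarization looking distribution (used to standardise
# the generating covariate on its population scale)
.fam_moments <- function(config) {
  a <- config$fam_shape1
  b <- config$fam_shape2
  d <- config$familiarization_duration_s
  list(mean = d * a / (a + b),
       sd = d * sqrt(a * b / ((a + b)^2 * (a + b + 1))))
}

#' Simulate a looking-time experiment
#'
#' Generates a full counterbalanced trial table under the censored log-normal
#' measurement model. For each subject an intercept `u ~ Normal(0,
#' sigma_subject)` is drawn; each test trial's latent log looking time is the
#' design-cell mean plus the familiarization covariate effect plus `u` plus
#' `Normal(0, sigma_obs)` noise; the exponentiated true time passes through
#' the two-coder model and is then right-censored at the trial ceiling.
#' Familiarization looking is the familiarization duration times a
#' Beta-distributed attentiveness fraction correlated with the subject
#' intercept through a Gaussian copula.
#'
#' Counterbalancing of first test trial and familiarization group is exact
#' within condition. Each subject's draws come from a dedicated substream
#' keyed by (experiment, condition, order, slot), so the table is
#' reproducible given `config$seed` and enlarging the design leaves existing
#' subjects' records unchanged.
#'
#' @param config An [lt_config()].
#' @param scheme Contrast scheme aligned with `config$beta`; defaults to the
#'   13-term single-experiment scheme.
#' @return An `lt_trials` table (`3 conditions x 2 orders x n_per_cell`
#'   subjects, two rows each).
#' @examples
#' trials <- simulate_experiment(lt_config(seed = 42))
#' table(trials$condition) / 2
#' @export
simulate_experiment <- function(config = lt_config(),
                                scheme = build_contrast_scheme("single_experiment")) {
  config$beta <- .align_beta(config$beta, scheme)
  mu <- .cell_mu_table(scheme, config$beta)
  conditions <- unique(mu$condition)
  .simulate_cells(config, mu, conditions,
                  experiment = "brightness", id_prefix = "S")
}

# core generator over an explicit cell-mean table
.simulate_cells <- function(config, mu_table, conditions, experiment,
                            id_prefix) {
  if (config$n_per_cell %% 2 != 0) {
    stop("n_per_cell must be even for exact counterbalancing of the ",
         "familiarization group", call. = FALSE)
  }
  lv <- lt_levels()
  fam <- .fam_moments(config)
  beta_fam <- config$beta[["Familiarization Time"]]
  mu_key <- do.call(paste, mu_table[intersect(
    c("condition", "experiment", "trial_type", "first_test"),
    names(mu_table))])
  abbrev <- c(congruent = "cong", incongruent = "incong",
              shape_change = "shape")
  ordab <- c(one_change_first = "1f", two_change_first = "2f")
  n_subj <- length(conditions) * 2L * config$n_per_cell
  sid <- cond_v <- ord_v <- fam_v <- character(n_subj)
  fam_look <- numeric(n_subj)
  t1 <- t2 <- numeric(n_subj) # recorded looks, trial index 1 and 2
  type1 <- character(n_subj)
  serial <- 0L
  for (cond in conditions) {
    for (ord in lv$first_test) {
      for (slot in seq_len(config$n_per_cell)) {
        serial <- serial + 1L
        key <- paste(experiment, cond, ord, slot, sep = "|")
        res <- .with_seed(
          .subject_seed(config$seed, key),
          .simulate_subject(cond, ord, config, mu_table, mu_key, fam,
                            beta_fam, experiment)
        )
        sid[serial] <- sprintf("%s-%s-%s-%02d", id_prefix, abbrev[[cond]],
                               ordab[[ord]], slot)
        cond_v[serial] <- cond
        ord_v[serial] <- ord
        fam_v[serial] <- if (slot %% 2 == 1) "small" else "large"
        fam_look[serial] <- res$fam_look
        t1[serial] <- res$rec[1]
        t2[serial] <- res$rec[2]
        type1[serial] <- res$types[1]
      }
    }
  }
  idx <- rep(seq_len(n_subj), each = 2)
  out <- data.frame(
    subject_id = sid[idx], experiment = experiment,
    condition = cond_v[idx], familiarization_group = fam_v[idx],
    first_test = ord_v[idx],
    trial_type = as.vector(rbind(type1,
                                 ifelse(type1 == "one_change",
                                        "two_change", "one_change"))),
    trial_index = rep(1:2, n_subj),
    familiarization_looking_s = fam_look[idx],
    looking_s = as.vector(rbind(t1, t2)),
    censored = as.vector(rbind(t1, t2)) >= config$censor_limit_s,
    stringsAsFactors = FALSE
  )
  validate_trials(out, censor_limit_s = config$censor_limit_s)
}

.simulate_subject <- function(cond, ord, config, mu_table, mu_key, fam,
                              beta_fam, experiment) {
  z_u <- stats::rnorm(1)
  u <- config$sigma_subject * z_u
  z2 <- stats::rnorm(1)
  w <- config$fam_cor * z_u + sqrt(1 - config$fam_cor^2) * z2
  frac <- stats::qbeta(stats::pnorm(w), config$fam_shape1, config$fam_shape2)
  fam_look <- max(config$familiarization_duration_s * frac, 1e-3)
  fam_code <- (fam_look - fam$mean) / fam$sd

  types <- if (ord == "two_change_first") {
    c("two_change", "one_change")
  } else {
    c("one_change", "two_change")
  }
  rec <- numeric(2)
  for (k in 1:2) {
    cell <- paste(c(cond,
                    if ("experiment" %in% names(mu_table)) experiment,
                    types[k], ord), collapse = " ")
    mu_i <- mu_table$mu[match(cell, mu_key)] + beta_fam * fam_code + u
    latent <- mu_i + stats::rnorm(1, 0, config$sigma_obs)
    true_s <- exp(latent)
    r <- apply_coder_model(true_s, config)
    rec[k] <- min(r, config$censor_limit_s)
  }
  list(fam_look = fam_look, rec = rec, types = types)
}

#' Simulate the cross-experiment aggregate dataset
#'
#' Combines a brightness-experiment simulation with a length-experiment
#' block. The length experiment has only the congruent and incongruent
#' conditions; its default cell means are derived from the brightness cell
#' means by (i) keeping the congruent cells identical across experiments,
#' (ii) shifting every incongruent length cell down by
#' `incongruent_offset_log` log-units (the cross-dimension incongruent
#' offset), and (iii) swapping the trial-order dependence of the incongruent
#' trial-type effect, reflecting the opposite order pattern of the two
#' dimensions. Variance components, coder model and censoring are shared.
#'
#' @param config Brightness-experiment [lt_config()].
#' @param scheme Single-experiment scheme aligned with `config$beta`.
#' @param n_per_cell_length Subjects per condition-by-order cell in the
#'   length experiment (default 8, i.e. 16 per condition).
#' @param incongruent_offset_log Log-scale drop of the incongruent length
#'   cells relative to incongruent brightness (default 0.43).
#' @param flip_incongruent_order Swap the trial-order dependence of the
#'   incongruent trial-type effect in the length experiment (default
#'   `TRUE`); set `FALSE` (with a zero offset) for experiments with
#'   identical generating parameters.
#' @return An `lt_trials` table spanning both experiments.
#' @export
simulate_aggregate <- function(config = lt_config(),
                               scheme = build_contrast_scheme("single_experiment"),
                               n_per_cell_length = config$n_per_cell,
                               incongruent_offset_log = 0.43,
                               flip_incongruent_order = TRUE) {
  config$beta <- .align_beta(config$beta, scheme)
  bright <- simulate_experiment(config, scheme)
  mu_b <- .cell_mu_table(scheme, config$beta)
  mu_l <- mu_b[mu_b$condition != "shape_change", ]
  mu_l$experiment <- "length"
  flip <- if (flip_incongruent_order) {
    c(one_change_first = "two_change_first",
      two_change_first = "one_change_first")
  } else {
    c(one_change_first = "one_change_first",
      two_change_first = "two_change_first")
  }
  incong <- mu_l$condition == "incongruent"
  src <- mu_b[mu_b$condition == "incongruent", ]
  src_key <- paste(src$trial_type, flip[src$first_test])
  mu_l$mu[incong] <- src$mu[match(
    paste(mu_l$trial_type[incong], mu_l$first_test[incong]), src_key
  )] - incongruent_offset_log

  cfg_l <- config
  cfg_l$n_per_cell <- n_per_cell_length
  long <- .simulate_cells(cfg_l, mu_l, c("congruent", "incongruent"),
                          experiment = "length", id_prefix = "L")
  validate_trials(rbind(as.data.frame(bright), as.data.frame(long)),
                  censor_limit_s = config$censor_limit_s)
}
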