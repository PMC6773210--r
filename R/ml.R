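# Maximum-likelihood multilevel regression on raw or log-transformed looking
# times (subject random intercepts via lme4), with the coefficient table,
# variance components, marginal/conditional pseudo R-squared and a
# Type-III-style term-set ANOVA summary.

# term sets for the ANOVA summary of the single-experiment scheme, in the
# conventional reporting order
.ml_term_sets <- function(terms) {
  is_cond <- grepl("^(Congruent|Incongruent)--", terms)
  is_ct <- grepl("^\\((Cong|Incong)--Shape\\) x \\(2-Change - 1-Change\\)$",
                 terms)
  is_cf <- grepl(
    "^\\((Cong|Incong)--Shape\\) x \\(2-Change First - 1-Change First\\)$",
    terms)
  is_3way <- grepl("x \\(2-Change - 1-Change\\) x", terms)
  list(
    `Familiarization Time` = which(terms == "Familiarization Time"),
    `First Test` = which(terms == "2-Change First - 1-Change First"),
    `Condition` = which(is_cond),
    `Trial Type` = which(terms == "2-Change - 1-Change"),
    `First Test x Condition` = which(is_cf),
    `First Test x Trial Type` = which(
      terms == "(2-Change - 1-Change) x (2-Change First - 1-Change First)"),
    `Condition x Trial Type` = which(is_ct),
    `First Test x Condition x Trial Type` = which(is_3way)
  )
}

#' Maximum-likelihood multilevel regression
#'
#' Fits a subject random-intercept linear model by maximum likelihood
#' (`lme4::lmer`, `REML = FALSE`) on the raw or log-transformed looking
#' times, using the named design matrix from [build_design_matrix()].
#' Coefficient degrees of freedom follow the containment rule, observations
#' minus subject-level units (96 - 48 = 48 on the reference design).
#' Marginal pseudo R-squared is `var(fixed predictions) / (var(fixed) +
#' var(subject) + var(residual))`; conditional adds the subject variance to
#' the numerator. The term-set ANOVA summary reports Type-III-style Wald F
#' tests consistent with the sum-to-zero coding, with sums of squares on the
#' residual-mean-square scale.
#'
#' @param trials An `lt_trials` table.
#' @param design Design matrix from [build_design_matrix()] (rows aligned
#'   with `trials`).
#' @param response_scale `"raw"` (seconds) or `"log"` (natural log seconds).
#' @return Object of class `lt_ml`: `coefficients` table (estimate, SE, df,
#'   t, p), `varcomp`, `r2` (marginal, conditional), `anova` term-set table,
#'   and the underlying `lme4` fit.
#' @export
fit_ml_multilevel <- function(trials, design,
                              response_scale = c("raw", "log")) {
  response_scale <- match.arg(response_scale)
  trials <- as.data.frame(trials)
  stopifnot(nrow(trials) == nrow(design))
  y <- if (response_scale == "log") log(trials$looking_s) else trials$looking_s
  terms <- colnames(design)
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  d <- as.data.frame(design)
  names(d) <- paste0("x", seq_along(terms))
  d$.y <- y
  d$.subject <- factor(trials$subject_id)
  form <- stats::as.formula(paste(
    ".y ~ 0 +", paste(names(d)[seq_along(terms)], collapse = " + "),
    "+ (1 | .subject)"
  ))
  fit <- lme4::lmer(form, data = d, REML = FALSE)
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("ML fit did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)
  }
  est <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sig_u2 <- vc$vcov[vc$grp == ".subject"]
  sig_e2 <- vc$vcov[vc$grp == "Residual"]
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  df_contain <- nrow(trials) - nlevels(d$.subject)
  tval <- est / se
  coefs <- data.frame(
    term = terms, estimate = unname(est), se = unname(se), df = df_contain,
    t = unname(tval),
    p = 2 * stats::pt(abs(unname(tval)), df_contain, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  yhat <- as.numeric(design %*% est)
  var_f <- stats::var(yhat)
  r2 <- c(
    marginal = var_f / (var_f + sig_u2 + sig_e2),
    conditional = (var_f + sig_u2) / (var_f + sig_u2 + sig_e2)
  )
  sets <- .ml_term_sets(terms)
  sets <- sets[lengths(sets) > 0]
  arows <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    k <- length(idx)
    wald <- drop(t(est[idx]) %*% solve(V[idx, idx, drop = FALSE], est[idx]))
    f <- wald / k
    data.frame(
      term_set = nm, ss = f * k * sig_e2, ms = f * sig_e2,
      df1 = k, df2 = df_contain, F = f,
      p = stats::pf(f, k, df_contain, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(
      coefficients = coefs,
      varcomp = c(sigma2_subject = sig_u2, sigma2_residual = sig_e2),
      r2 = r2,
      anova = do.call(rbind, arows),
      response_scale = response_scale,
      df = df_contain,
      fit = fit,
      design_attrs = attributes(design)[c("covariate_center",
                                          "covariate_scale")]
    ),
    class = "lt_ml"
  )
}

#' @export
print.lt_ml <- function(x, ...) {
  cat("ML multilevel regression (", x$response_scale, " scale), ",
      nrow(x$coefficients), " terms, coefficient df = ", x$df, "\n", sep = "")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf(
    "sigma_subject = %.3f  sigma_residual = %.3f  R2 marginal = %.2f, conditional = %.2f\n",
    sqrt(x$varcomp[1]), sqrt(x$varcomp[2]), x$r2["marginal"],
    x$r2["conditional"]
  ))
  invisible(x)
}

#' @export
coef.lt_ml <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
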