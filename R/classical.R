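# Classical (frequentist) inference: one-way and mixed-design ANOVA with
# partial eta squared, via base aov() error strata.

.anova_row <- function(effect, ss, df1, ss_err, df2) {
  ms <- ss / df1
  f <- ms / (ss_err / df2)
  data.frame(
    effect = effect, ss = ss, ms = ms, df1 = df1, df2 = df2,
    F = f, partial_eta2 = ss / (ss + ss_err),
    p = stats::pf(f, df1, df2, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' One-way ANOVA on familiarization looking times
#'
#' Classical fixed-effects decomposition of familiarization looking time by
#' condition (one value per subject), with partial eta squared. On the
#' reference 3 x 16 design the degrees of freedom are (2, 45).
#'
#' @param trials An `lt_trials` table, or a data.frame with columns
#'   `subject_id`, `condition`, `familiarization_looking_s` (one or two rows
#'   per subject; familiarization is constant within subject).
#' @return An `lt_anova` table (effect, SS, MS, df pair, F, partial eta
#'   squared, p).
#' @export
oneway_anova <- function(trials) {
  d <- as.data.frame(trials)
  d <- d[!duplicated(d$subject_id),
         c("subject_id", "condition", "familiarization_looking_s")]
  grp <- split(d$familiarization_looking_s, d$condition)
  grp <- grp[lengths(grp) > 0]
  if (length(grp) < 2 || any(lengths(grp) < 2)) {
    stop("need at least 2 groups with at least 2 subjects each", call. = FALSE)
  }
  ss_within <- sum(vapply(grp, function(v) sum((v - mean(v))^2), 0))
  if (ss_within == 0) {
    stop("zero within-group variance: F is undefined", call. = FALSE)
  }
  gm <- mean(d$familiarization_looking_s)
  ss_between <- sum(vapply(grp, function(v) length(v) * (mean(v) - gm)^2, 0))
  out <- .anova_row("condition", ss_between, length(grp) - 1,
                    ss_within, nrow(d) - length(grp))
  structure(out, class = c("lt_anova", "data.frame"))
}

#' Mixed-design repeated-measures ANOVA on test-trial looking times
#'
#' The design is Condition (3, between) x First Test Trial (2, between) x
#' Trial Type (2, within), one observation per subject per within level.
#' Between-subject effects are tested against the subject-within-cell error
#' stratum; within effects and their interactions against the trial-type by
#' subject stratum (both with 42 error df on the 48-subject design). Computed
#' through `aov()` with an `Error(subject/trial_type)` term; partial eta
#' squared uses each effect's own error stratum.
#'
#' @param trials An `lt_trials` table (validated; every subject must have
#'   both within levels).
#' @param response Column used as the dependent measure (default raw
#'   `looking_s`).
#' @return An object of class `lt_mixed_anova`: the `lt_anova` table plus the
#'   cell means and pooled error strata needed by [marginal_means()].
#' @export
mixed_anova <- function(trials, response = "looking_s") {
  trials <- validate_trials(as.data.frame(trials),
                            censor_limit_s = attr(trials, "censor_limit_s") %||% 60)
  d <- data.frame(
    y = as.data.frame(trials)[[response]],
    subject = factor(trials$subject_id),
    condition = factor(trials$condition, lt_levels()$condition),
    first_test = factor(trials$first_test, lt_levels()$first_test),
    trial_type = factor(trials$trial_type, lt_levels()$trial_type)
  )
  d$condition <- droplevels(d$condition)
  counts <- table(d$condition, d$first_test) / 2
  if (length(unique(as.vector(counts))) != 1 || any(counts < 2)) {
    stop("design must be balanced with at least 2 subjects per ",
         "condition x order cell", call. = FALSE)
  }
  a <- stats::aov(y ~ condition * first_test * trial_type +
                    Error(subject / trial_type), data = d)
  s <- summary(a)
  tab_b <- as.data.frame(s[["Error: subject"]][[1]])
  tab_w <- as.data.frame(s[["Error: subject:trial_type"]][[1]])
  clean <- function(tab) {
    rn <- trimws(rownames(tab))
    data.frame(effect = rn, df = tab$Df, ss = tab$`Sum Sq`,
               stringsAsFactors = FALSE)
  }
  tab_b <- clean(tab_b)
  tab_w <- clean(tab_w)
  err_b <- tab_b[tab_b$effect == "Residuals", ]
  err_w <- tab_w[tab_w$effect == "Residuals", ]
  rows <- list()
  for (i in which(tab_b$effect != "Residuals")) {
    rows[[length(rows) + 1]] <- .anova_row(tab_b$effect[i], tab_b$ss[i],
                                           tab_b$df[i], err_b$ss, err_b$df)
  }
  for (i in which(tab_w$effect != "Residuals")) {
    rows[[length(rows) + 1]] <- .anova_row(tab_w$effect[i], tab_w$ss[i],
                                           tab_w$df[i], err_w$ss, err_w$df)
  }
  out <- do.call(rbind, rows)
  cells <- stats::aggregate(y ~ condition + first_test + trial_type, d, mean)
  n_group <- as.vector(counts)[1]
  structure(
    list(
      table = structure(out, class = c("lt_anova", "data.frame")),
      cells = cells,
      n_per_group = n_group,
      ms_between = err_b$ss / err_b$df, df_between = err_b$df,
      ms_within = err_w$ss / err_w$df, df_within = err_w$df,
      data = d
    ),
    class = "lt_mixed_anova"
  )
}

#' @export
print.lt_anova <- function(x, ...) {
  df <- as.data.frame(x)
  for (col in intersect(c("ss", "ms", "F", "partial_eta2"), names(df))) {
    df[[col]] <- round(df[[col]], 2)
  }
  if ("p" %in% names(df)) df$p <- signif(df$p, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.lt_mixed_anova <- function(x, ...) {
  cat("Mixed-design ANOVA (", nlevels(x$data$subject), " subjects):\n",
      sep = "")
  print(x$table)
  invisible(x)
}
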