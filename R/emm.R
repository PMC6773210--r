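# Estimated marginal means and Tukey-adjusted pairwise comparisons for the
# mixed-design ANOVA, computed from the pooled error strata (the model-based
# analogue of post-hoc t-tests on subsets of data).

# variance of a weighted combination of the 12 cell means, decomposed over
# the two error strata. Cells sharing a (condition, first_test) group share
# subjects; for each group g with n subjects,
#   Var = (1/n) [ (sum_g w)^2 * sigma_s^2 + sum_g w^2 * sigma^2 ]
# with sigma_s^2 = (MS_between - MS_within)/2 and sigma^2 = MS_within on the
# observation scale. A combination whose weights sum to zero within every
# group is a pure within-subject contrast (trial-type stratum df); one whose
# weights are constant across trial types within every group is a pure
# between-subject contrast (subject stratum df). Mixed combinations would
# need approximate df and are refused.
.emm_var <- function(w, cells, n, ms_b, ms_w) {
  grp <- interaction(cells$condition, cells$first_test, drop = TRUE)
  sum_w <- tapply(w, grp, sum)
  sum_w2 <- tapply(w^2, grp, sum)
  sig_s2 <- max((ms_b - ms_w) / 2, 0)
  v <- sum((sum_w^2 * sig_s2 + sum_w2 * ms_w)) / n
  within_pure <- all(abs(sum_w) < 1e-12)
  between_pure <- all(vapply(
    split(w, grp),
    function(wi) length(unique(round(wi, 12))) == 1, TRUE
  ))
  type <- if (within_pure) "within" else if (between_pure) "between" else "mixed"
  # a between-type combination is estimated from subject means only
  if (type == "between") {
    v <- sum(sum_w^2 * (sig_s2 + ms_w / 2)) / n
  }
  list(var = v, type = type)
}

#' Estimated marginal means from a mixed ANOVA
#'
#' Model-implied cell means averaged over unconditioned factors with equal
#' cell weights, with standard errors pooled over the appropriate error
#' strata of the mixed design.
#'
#' @param fit An `lt_mixed_anova` from [mixed_anova()].
#' @param specs Character vector of factor names to estimate means for
#'   (subset of `condition`, `first_test`, `trial_type`).
#' @param by Optional conditioning factor(s); means and subsequent pairwise
#'   comparisons are computed separately within each level combination.
#' @return An object of class `lt_emm`: data.frame of means with `se` and
#'   `df`, plus the comparison machinery used by [tukey_pairwise()].
#' @export
marginal_means <- function(fit, specs, by = NULL) {
  stopifnot(inherits(fit, "lt_mixed_anova"))
  facs <- c("condition", "first_test", "trial_type")
  if (!all(c(specs, by) %in% facs)) {
    stop("unknown factor(s): ",
         paste(setdiff(c(specs, by), facs), collapse = ", "), call. = FALSE)
  }
  cells <- fit$cells
  key_vars <- c(specs, by)
  key <- interaction(cells[key_vars], drop = TRUE, sep = " ")
  levs <- levels(key)
  out <- list()
  for (lv in levs) {
    w <- as.numeric(key == lv) / sum(key == lv)
    vr <- .emm_var(w, cells, fit$n_per_group, fit$ms_between, fit$ms_within)
    df <- if (vr$type == "within") fit$df_within else fit$df_between
    out[[lv]] <- data.frame(
      level = lv, mean = sum(w * cells$y), se = sqrt(vr$var), df = df,
      stringsAsFactors = FALSE
    )
  }
  means <- do.call(rbind, out)
  rownames(means) <- NULL
  split_lab <- do.call(rbind, strsplit(means$level, " ", fixed = TRUE))
  colnames(split_lab) <- key_vars
  means <- cbind(as.data.frame(split_lab, stringsAsFactors = FALSE),
                 means[c("mean", "se", "df")])
  structure(
    list(means = means, specs = specs, by = by, fit = fit),
    class = "lt_emm"
  )
}

#' @export
print.lt_emm <- function(x, ...) {
  cat("Estimated marginal means over", paste(x$specs, collapse = " x "))
  if (!is.null(x$by)) cat(" | ", paste(x$by, collapse = " x "))
  cat(":\n")
  print.data.frame(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey-adjusted pairwise comparisons of marginal means
#'
#' All pairwise differences among the `specs` means of an [marginal_means()]
#' object, within each `by` level, with standard errors pooled from the
#' design's error strata and p-values from the studentized-range
#' distribution (family size = number of means compared, model error df).
#'
#' @param emm An `lt_emm`.
#' @return Data.frame of class `lt_emm_contrasts`: contrast label, estimate,
#'   SE, df, t, Tukey-adjusted p.
#' @export
tukey_pairwise <- function(emm) {
  stopifnot(inherits(emm, "lt_emm"))
  fit <- emm$fit
  cells <- fit$cells
  spec_key <- interaction(cells[emm$specs], drop = TRUE, sep = " ")
  by_key <- if (is.null(emm$by)) {
    factor(rep("", nrow(cells)))
  } else {
    interaction(cells[emm$by], drop = TRUE, sep = " ")
  }
  res <- list()
  for (bl in levels(by_key)) {
    sel <- by_key == bl
    levs <- levels(droplevels(spec_key[sel]))
    k <- length(levs)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        w <- numeric(nrow(cells))
        wi <- sel & spec_key == levs[i]
        wj <- sel & spec_key == levs[j]
        w[wi] <- 1 / sum(wi)
        w[wj] <- -1 / sum(wj)
        vr <- .emm_var(w, cells, fit$n_per_group, fit$ms_between,
                       fit$ms_within)
        if (vr$type == "mixed") {
          stop("between-within mixed contrasts are not supported ",
               "(no approximate-df method)", call. = FALSE)
        }
        df <- if (vr$type == "within") fit$df_within else fit$df_between
        est <- sum(w * cells$y)
        se <- sqrt(vr$var)
        tval <- est / se
        p <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k, df = df,
                           lower.tail = FALSE)
        res[[length(res) + 1]] <- data.frame(
          contrast = paste(levs[i], "-", levs[j]),
          by = bl, estimate = est, se = se, df = df, t = tval,
          p_tukey = p, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(emm$by)) out$by <- NULL
  structure(out, class = c("lt_emm_contrasts", "data.frame"))
}

#' @export
print.lt_emm_contrasts <- function(x, ...) {
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
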