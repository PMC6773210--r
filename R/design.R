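# Experimental design vocabulary and contrast/design-matrix construction.
#
# All downstream fits (classical, Bayesian, aggregate) are parameterised
# through a named contrast scheme in which every coefficient equals a labelled
# cell-mean difference, so model output reads directly as the quantity named
# in its row label.

#' Factor levels of the looking-time design
#'
#' Canonical level sets for the trial-table factors. `condition` levels
#' `congruent` and `incongruent` describe whether the brightness (or length)
#' change direction matches the number/duration change; `shape_change` is the
#' visual-novelty control and occurs only in the brightness experiment.
#'
#' @return Named list of character vectors.
#' @export
lt_levels <- function() {
  list(
    experiment = c("brightness", "length"),
    condition = c("congruent", "incongruent", "shape_change"),
    familiarization_group = c("small", "large"),
    first_test = c("one_change_first", "two_change_first"),
    trial_type = c("one_change", "two_change")
  )
}

# between-cell base codes, single experiment (3 conditions).
# Coefficients equal labelled differences: e.g. the "Congruent--Shape Change"
# coefficient is mean(congruent) - mean(shape_change).
.codes_condition_single <- function(condition) {
  c1 <- c(congruent = 2 / 3, incongruent = -1 / 3, shape_change = -1 / 3)
  c2 <- c(congruent = -1 / 3, incongruent = 2 / 3, shape_change = -1 / 3)
  cbind(
    `Congruent--Shape Change` = unname(c1[condition]),
    `Incongruent--Shape Change` = unname(c2[condition])
  )
}

# aggregate between-cell codes over the 5 condition-by-experiment cells
# (congruent/incongruent x brightness/length, plus shape_change which exists
# only in the brightness experiment). Nested coding: the dimension contrasts
# are defined on the four magnitude cells and are 0 on shape_change rows;
# "Shape Change--Magnitude" compares shape_change with the pooled magnitude
# cells.
.codes_condition_aggregate <- function(condition, experiment) {
  shape <- condition == "shape_change"
  ci <- ifelse(shape, 0, ifelse(condition == "congruent", 1 / 2, -1 / 2))
  bl <- ifelse(shape, 0, ifelse(experiment == "brightness", 1 / 2, -1 / 2))
  cbind(
    `Congruent--Incongruent` = ci,
    `Brightness--Length` = bl,
    `(Congruent-Incongruent) x (Brightness-Length)` = ci * bl,
    `Shape Change--Magnitude` = ifelse(shape, 4 / 5, -1 / 5)
  )
}

.code_trial_type <- function(trial_type) {
  ifelse(trial_type == "two_change", 1 / 2, -1 / 2)
}

.code_first_test <- function(first_test) {
  ifelse(first_test == "two_change_first", 1 / 2, -1 / 2)
}

#' Build a named contrast scheme
#'
#' Constructs the contrast scheme used by every model in the package: 13 terms
#' for a single experiment (intercept, familiarization covariate, two
#' condition contrasts against the shape-change control, trial-type and
#' trial-order difference contrasts, and their two- and three-way
#' interactions), or 21 terms for the cross-experiment aggregate model (nested
#' condition-by-dimension contrasts over the five condition-experiment cells).
#'
#' Coding is chosen so that each coefficient equals the cell-mean difference
#' named by its label: two-level factors are difference-coded (+1/2, -1/2),
#' the three-level condition factor uses (2/3, -1/3, -1/3)-style pairs against
#' the shape-change control, and the aggregate dimension contrasts are coded 0
#' on shape-change rows with "Shape Change--Magnitude" coded (4/5, -1/5).
#' Interaction codes are elementwise products of their parents. Every
#' non-intercept, non-covariate column sums to zero over the balanced cell set
#' it is defined on.
#'
#' @param scope `"single_experiment"` (13 terms) or `"aggregate"` (21 terms).
#' @param cell_codes Optional user-supplied between-cell code table replacing
#'   the built-in condition coding: a data.frame with columns `condition` (and
#'   `experiment` for aggregate scope) followed by one numeric column per
#'   custom between-subject contrast.
#' @return An object of class `lt_scheme`: list with elements `scope`,
#'   `terms` (ordered term labels), `cells` (the full cell-to-code table over
#'   the design cells), and `covariates`.
#' @examples
#' sch <- build_contrast_scheme("single_experiment")
#' sch$terms
#' @export
build_contrast_scheme <- function(scope = c("single_experiment", "aggregate"),
                                  cell_codes = NULL) {
  scope <- match.arg(scope)
  lv <- lt_levels()
  if (scope == "single_experiment") {
    cells <- expand.grid(
      condition = lv$condition,
      trial_type = lv$trial_type,
      first_test = lv$first_test,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    between <- .codes_condition_single(cells$condition)
  } else {
    cond_exp <- data.frame(
      condition = c("congruent", "incongruent", "shape_change",
                    "congruent", "incongruent"),
      experiment = c("brightness", "brightness", "brightness",
                     "length", "length"),
      stringsAsFactors = FALSE
    )
    within <- expand.grid(
      trial_type = lv$trial_type,
      first_test = lv$first_test,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    cells <- merge(cond_exp, within, by = NULL)
    between <- .codes_condition_aggregate(cells$condition, cells$experiment)
  }
  if (!is.null(cell_codes)) {
    key <- intersect(c("condition", "experiment"), names(cell_codes))
    idx <- match(
      do.call(paste, cells[key]),
      do.call(paste, cell_codes[key])
    )
    if (anyNA(idx)) {
      stop("cell_codes does not cover every design cell", call. = FALSE)
    }
    between <- as.matrix(cell_codes[idx, setdiff(names(cell_codes), key),
                                    drop = FALSE])
    rownames(between) <- NULL
    # zero custom contrasts yields the within-factors-only scheme
  }

  tt <- .code_trial_type(cells$trial_type)
  ft <- .code_first_test(cells$first_test)
  bnames <- colnames(between)

  code <- cbind(`(Intercept)` = rep(1, nrow(cells)))
  code <- cbind(code, between)
  code <- cbind(code, `2-Change - 1-Change` = tt,
                `2-Change First - 1-Change First` = ft)
  txf <- cbind(`(2-Change - 1-Change) x (2-Change First - 1-Change First)` =
                 tt * ft)
  if (ncol(between)) {
    bxt <- between * tt
    colnames(bxt) <- paste0("(", .short_label(bnames),
                            ") x (2-Change - 1-Change)")
    bxf <- between * ft
    colnames(bxf) <- paste0("(", .short_label(bnames),
                            ") x (2-Change First - 1-Change First)")
    bxtxf <- between * tt * ft
    colnames(bxtxf) <- paste0(
      "(", .short_label(bnames),
      ") x (2-Change - 1-Change) x (2-Change First - 1-Change First)"
    )
  } else {
    bxt <- bxf <- bxtxf <- between
  }
  # conventional table ordering: condition x trial-type, condition x order,
  # trial-type x order, then the three-ways
  code <- cbind(code, bxt, bxf, txf, bxtxf)

  covariates <- list(list(name = "Familiarization Time", transform = "zscore"))
  terms <- c(colnames(code)[1], covariates[[1]]$name, colnames(code)[-1])

  structure(
    list(scope = scope, terms = terms,
         cells = cbind(cells, as.data.frame(code)),
         covariates = covariates),
    class = "lt_scheme"
  )
}

# abbreviations used inside interaction labels (mirrors the conventional
# table row labels)
.short_label <- function(x) {
  map <- c(
    "Congruent--Shape Change" = "Cong--Shape",
    "Incongruent--Shape Change" = "Incong--Shape",
    "Congruent--Incongruent" = "Congruent--Incongruent",
    "Brightness--Length" = "Brightness--Length",
    "(Congruent-Incongruent) x (Brightness-Length)" =
      "Cong-Incong x Bright-Length",
    "Shape Change--Magnitude" = "Shape Change--Magnitude"
  )
  out <- map[x]
  out[is.na(out)] <- x[is.na(out)]
  unname(out)
}

#' @export
print.lt_scheme <- function(x, ...) {
  cat("Contrast scheme (", x$scope, "), ", length(x$terms), " terms:\n",
      sep = "")
  cat(paste0("  ", seq_along(x$terms), ". ", x$terms, collapse = "\n"), "\n")
  invisible(x)
}

#' Export a contrast scheme as JSON
#'
#' Serialises the full cell-to-code table (one entry per design cell, term
#' name to numeric code) for audit.
#'
#' @param scheme An `lt_scheme`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "lt_scheme"))
  json <- jsonlite::toJSON(
    list(scope = scheme$scope, terms = scheme$terms,
         covariates = scheme$covariates, cells = scheme$cells),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# keys identifying a design cell for a scheme
.cell_key_vars <- function(scheme) {
  if (scheme$scope == "aggregate") {
    c("condition", "experiment", "trial_type", "first_test")
  } else {
    c("condition", "trial_type", "first_test")
  }
}

#' Build the model design matrix for a trial table
#'
#' Maps each trial to its design-cell code row under `scheme` and appends the
#' familiarization covariate (centered and scaled as configured; z-score by
#' default). Interaction columns are elementwise products of their parent
#' columns by construction of the scheme.
#'
#' @param trials A validated trial table (see [read_trial_table()]).
#' @param scheme An `lt_scheme` from [build_contrast_scheme()].
#' @param covariate_scale `"zscore"` (center, divide by sample SD), `"center"`
#'   (center only) or `"none"`. The applied centering/scale constants are
#'   recorded in the matrix attributes so fitted coefficients can be mapped
#'   back to seconds.
#' @return Numeric matrix, one row per trial, columns in scheme term order,
#'   with attributes `terms`, `covariate_center`, `covariate_scale`.
#' @export
build_design_matrix <- function(trials, scheme,
                                covariate_scale = c("zscore", "center", "none")) {
  stopifnot(inherits(scheme, "lt_scheme"))
  covariate_scale <- match.arg(covariate_scale)
  trials <- as.data.frame(trials)
  if (scheme$scope == "aggregate" &&
      !all(c("brightness", "length") %in% unique(trials$experiment))) {
    stop("aggregate scheme requires data from both the brightness and the ",
         "length experiment", call. = FALSE)
  }
  key <- .cell_key_vars(scheme)
  idx <- match(do.call(paste, trials[key]), do.call(paste, scheme$cells[key]))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("trial row ", bad, " does not match any design cell of the ",
         scheme$scope, " scheme", call. = FALSE)
  }
  code_cols <- setdiff(names(scheme$cells),
                       c("condition", "experiment", "trial_type", "first_test"))
  codes <- as.matrix(scheme$cells[idx, code_cols, drop = FALSE])
  rownames(codes) <- NULL

  fam <- trials$familiarization_looking_s
  ctr <- if (covariate_scale == "none") 0 else mean(fam)
  scl <- if (covariate_scale == "zscore") stats::sd(fam) else 1
  if (covariate_scale == "zscore" && (!is.finite(scl) || scl == 0)) {
    scl <- 1 # constant covariate: centered column of zeros
  }
  fam_col <- (fam - ctr) / scl

  x <- cbind(codes[, 1, drop = FALSE],
             `Familiarization Time` = fam_col,
             codes[, -1, drop = FALSE])
  stopifnot(identical(colnames(x), scheme$terms))
  attr(x, "terms") <- scheme$terms
  attr(x, "covariate_center") <- ctr
  attr(x, "covariate_scale") <- scl
  x
}
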