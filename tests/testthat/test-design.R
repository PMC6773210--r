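# Contrast schemes, design matrices, and the trial-table schema.

single_terms <- c(
  "(Intercept)",
  "Familiarization Time",
  "Congruent--Shape Change",
  "Incongruent--Shape Change",
  "2-Change - 1-Change",
  "2-Change First - 1-Change First",
  "(Cong--Shape) x (2-Change - 1-Change)",
  "(Incong--Shape) x (2-Change - 1-Change)",
  "(Cong--Shape) x (2-Change First - 1-Change First)",
  "(Incong--Shape) x (2-Change First - 1-Change First)",
  "(2-Change - 1-Change) x (2-Change First - 1-Change First)",
  "(Cong--Shape) x (2-Change - 1-Change) x (2-Change First - 1-Change First)",
  "(Incong--Shape) x (2-Change - 1-Change) x (2-Change First - 1-Change First)"
)

aggregate_terms <- c(
  "(Intercept)",
  "Familiarization Time",
  "Congruent--Incongruent",
  "Brightness--Length",
  "(Congruent-Incongruent) x (Brightness-Length)",
  "Shape Change--Magnitude",
  "2-Change - 1-Change",
  "2-Change First - 1-Change First",
  "(Congruent--Incongruent) x (2-Change - 1-Change)",
  "(Brightness--Length) x (2-Change - 1-Change)",
  "(Cong-Incong x Bright-Length) x (2-Change - 1-Change)",
  "(Shape Change--Magnitude) x (2-Change - 1-Change)",
  "(Congruent--Incongruent) x (2-Change First - 1-Change First)",
  "(Brightness--Length) x (2-Change First - 1-Change First)",
  "(Cong-Incong x Bright-Length) x (2-Change First - 1-Change First)",
  "(Shape Change--Magnitude) x (2-Change First - 1-Change First)",
  "(2-Change - 1-Change) x (2-Change First - 1-Change First)",
  "(Congruent--Incongruent) x (2-Change - 1-Change) x (2-Change First - 1-Change First)",
  "(Brightness--Length) x (2-Change - 1-Change) x (2-Change First - 1-Change First)",
  "(Cong-Incong x Bright-Length) x (2-Change - 1-Change) x (2-Change First - 1-Change First)",
  "(Shape Change--Magnitude) x (2-Change - 1-Change) x (2-Change First - 1-Change First)"
)

test_that("schemes have the expected term sets in reporting order", {
  expect_identical(build_contrast_scheme("single_experiment")$terms,
                   single_terms)
  expect_identical(build_contrast_scheme("aggregate")$terms, aggregate_terms)
  expect_error(build_contrast_scheme("other"))
})

test_that("every non-intercept contrast column sums to zero over its balanced cell set", {
  for (scope in c("single_experiment", "aggregate")) {
    sch <- build_contrast_scheme(scope)
    codes <- sch$cells[setdiff(names(sch$cells),
                               c("condition", "experiment", "trial_type",
                                 "first_test", "(Intercept)"))]
    expect_true(all(abs(colSums(codes)) < 1e-12), info = scope)
  }
})

test_that("coefficients recover the labelled cell-mean differences exactly", {
  # regress arbitrary cell means on the cell-code matrix: the scheme is full
  # rank on the cells, so the fit is exact and each coefficient must equal
  # the quantity its label names
  set.seed(42)
  for (scope in c("single_experiment", "aggregate")) {
    sch <- build_contrast_scheme(scope)
    cells <- sch$cells
    codes <- as.matrix(cells[setdiff(names(cells),
                                     c("condition", "experiment",
                                       "trial_type", "first_test"))])
    mu <- rnorm(nrow(cells), 3, 1)
    b <- solve(crossprod(codes), crossprod(codes, mu))[, 1]
    expect_equal(max(abs(codes %*% b - mu)), 0, tolerance = 1e-9)
    m <- function(sel) mean(mu[sel])
    expect_equal(b[["2-Change - 1-Change"]],
                 m(cells$trial_type == "two_change") -
                   m(cells$trial_type == "one_change"))
    expect_equal(b[["2-Change First - 1-Change First"]],
                 m(cells$first_test == "two_change_first") -
                   m(cells$first_test == "one_change_first"))
    if (scope == "single_experiment") {
      expect_equal(b[["Congruent--Shape Change"]],
                   m(cells$condition == "congruent") -
                     m(cells$condition == "shape_change"))
      expect_equal(b[["Incongruent--Shape Change"]],
                   m(cells$condition == "incongruent") -
                     m(cells$condition == "shape_change"))
      # interaction = difference of trial-type differences
      dT <- function(cond) {
        m(cells$condition == cond & cells$trial_type == "two_change") -
          m(cells$condition == cond & cells$trial_type == "one_change")
      }
      expect_equal(b[["(Cong--Shape) x (2-Change - 1-Change)"]],
                   dT("congruent") - dT("shape_change"))
    } else {
      mag <- cells$condition != "shape_change"
      expect_equal(b[["Congruent--Incongruent"]],
                   m(cells$condition == "congruent") -
                     m(cells$condition == "incongruent"))
      expect_equal(b[["Brightness--Length"]],
                   m(mag & cells$experiment == "brightness") -
                     m(cells$experiment == "length"))
      expect_equal(b[["Shape Change--Magnitude"]],
                   m(cells$condition == "shape_change") - m(mag))
      dd <- function(exp_) {
        m(cells$condition == "congruent" & cells$experiment == exp_) -
          m(cells$condition == "incongruent" & cells$experiment == exp_)
      }
      expect_equal(b[["(Congruent-Incongruent) x (Brightness-Length)"]],
                   dd("brightness") - dd("length"))
    }
  }
})

test_that("a single trial row is coded as the hand-derived product structure", {
  sch <- build_contrast_scheme("single_experiment")
  tr <- toy_trials(30)
  tr$condition <- "congruent"
  tr$trial_type <- "two_change"
  tr$first_test <- "two_change_first"
  x <- build_design_matrix(tr, sch, covariate_scale = "none")
  # congruent codes 2/3 and -1/3 against shape change; two-change +1/2;
  # two-change-first +1/2; interactions are products
  expect_equal(
    unname(x[1, ]),
    c(1, 30, 2 / 3, -1 / 3, 1 / 2, 1 / 2,
      2 / 3 * 1 / 2, -1 / 3 * 1 / 2, 2 / 3 * 1 / 2, -1 / 3 * 1 / 2,
      1 / 4, 2 / 3 * 1 / 4, -1 / 3 * 1 / 4)
  )
})

test_that("balanced-design matrices are orthogonal and dimensioned as printed", {
  tr <- simulate_experiment(lt_config(seed = 21))
  sch <- build_contrast_scheme("single_experiment")
  X <- build_design_matrix(tr, sch)
  expect_identical(dim(X), c(96L, 13L))
  noncov <- X[, -2]
  expect_true(all(abs(colSums(noncov[, -1])) < 1e-9))
  # on balanced data, columns from different term families are orthogonal;
  # the two condition contrasts within a family are deliberately correlated
  # (difference coding trades orthogonality for directly readable
  # coefficients)
  fam <- c("int", "cond", "cond", "T", "O", "condT", "condT",
           "condO", "condO", "TO", "cond3", "cond3")
  G <- crossprod(noncov)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      if (fam[i] != fam[j]) expect_lt(abs(G[i, j]), 1e-9)
    }
  }
  # covariate is z-scored
  expect_equal(mean(X[, 2]), 0, tolerance = 1e-12)
  expect_equal(sd(X[, 2]), 1, tolerance = 1e-12)
})

test_that("aggregate coding nests the dimension contrasts within magnitude cells", {
  agg <- simulate_aggregate(lt_config(seed = 21))
  sch <- build_contrast_scheme("aggregate")
  X <- build_design_matrix(agg, sch)
  expect_identical(ncol(X), 21L)
  shape <- agg$condition == "shape_change"
  expect_true(all(X[shape, "Brightness--Length"] == 0))
  expect_true(all(X[shape, "Congruent--Incongruent"] == 0))
  expect_true(all(X[shape, "Shape Change--Magnitude"] == 4 / 5))
  expect_true(all(X[!shape, "Shape Change--Magnitude"] == -1 / 5))
  # aggregate scheme refuses single-experiment data
  bright_only <- validate_trials(
    as.data.frame(agg)[agg$experiment == "brightness", ])
  expect_error(build_design_matrix(bright_only, sch), "aggregate")
})

test_that("trial tables round-trip through CSV and schema errors name the row", {
  tr <- simulate_experiment(lt_config(seed = 3))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  write_trial_table(tr, f)
  back <- read_trial_table(f)
  expect_s3_class(back, "lt_trials")
  expect_equal(nrow(back), 96)
  expect_equal(as.data.frame(back)$looking_s, as.data.frame(tr)$looking_s,
               tolerance = 1e-5)
  expect_equal(table(back$condition) / 2,
               table(tr$condition) / 2)

  # empty file with a valid header is an empty table
  writeLines(paste(
    "subject_id,experiment,condition,familiarization_group,first_test",
    "trial_type,trial_index,familiarization_looking_s,looking_s,censored",
    sep = ","), f)
  expect_equal(nrow(read_trial_table(f)), 0)

  bad <- as.data.frame(tr)
  bad$looking_s[5] <- 61
  expect_error(validate_trials(bad), "row 5")

  bad <- as.data.frame(tr)
  bad$censored[2] <- !bad$censored[2]
  expect_error(validate_trials(bad), "censored flag")

  bad <- as.data.frame(tr)[-1, ]
  expect_error(validate_trials(bad), "exactly one")

  expect_error(validate_trials(as.data.frame(tr)[, -3]), "missing column")

  bad <- as.data.frame(tr)
  bad$experiment[bad$condition == "shape_change"] <- "length"
  expect_error(validate_trials(bad), "shape_change")
})

test_that("schemes export to JSON with the full cell-to-code table", {
  sch <- build_contrast_scheme("aggregate")
  parsed <- jsonlite::fromJSON(scheme_to_json(sch))
  expect_identical(parsed$terms, sch$terms)
  expect_equal(nrow(parsed$cells), 20)
  expect_equal(parsed$cells[["Shape Change--Magnitude"]],
               sch$cells[["Shape Change--Magnitude"]])
})
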