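# Printed reference tables for the replay checks: counts by exposure group
# (columns: unexposed, exposed).
table1_counts <- list(
  sex = matrix(c(3609, 2772, 224, 395), 2,
               dimnames = list(c("M", "F"), c("No CSA", "CSA"))),
  ethnicity = matrix(c(3462, 1418, 485, 257, 465, 294,
                       411, 108, 25, 43, 22, 10), 6,
                     dimnames = list(c("White", "Black", "Asian", "Mixed",
                                       "Other", "Unknown"),
                                     c("No CSA", "CSA"))),
  marital = matrix(c(4244, 741, 680, 189, 527, 476, 49, 58, 8, 28), 5,
                   dimnames = list(c("Single", "Married", "Divorced",
                                     "Widowed", "Unknown"),
                                   c("No CSA", "CSA"))),
  deprivation = matrix(c(957, 1418, 1718, 1729, 559, 83, 145, 174, 183, 34), 5,
                       dimnames = list(c("Q1", "Q2", "Q3", "Q4", "Unknown"),
                                       c("No CSA", "CSA"))),
  mdd = matrix(c(5895, 486, 536, 83), 2,
               dimnames = list(c("No", "Yes"), c("No CSA", "CSA")))
)

test_that("cross-tabulation matches a hand tally and keeps Unknown rows", {
  toy <- data.frame(
    sex = c("M", "M", "F", "F", "F", "M"),
    marital = c("Single", "Unknown", "Single", "Married", "Unknown", "Single"),
    csa = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  tab <- build_table(toy, "sex", "csa")
  expect_identical(tab["M", "No CSA"], 2L)
  expect_identical(tab["M", "CSA"], 1L)
  expect_identical(tab["F", "CSA"], 2L)
  tab <- build_table(toy, "marital", "csa")
  expect_identical(rownames(tab), c("Married", "Single", "Unknown"))
  tab <- build_table(toy, "marital", "csa", drop_unknown = TRUE)
  expect_false("Unknown" %in% rownames(tab))

  toy$one <- "A"
  expect_error(build_table(toy, "one", "csa"), "degenerate")
  expect_error(build_table(toy, "nope", "csa"), "not found")
})

test_that("uncorrected Pearson chi-square reproduces the published statistics", {
  stats <- vapply(table1_counts, function(m) pearson_chi_square(m)$statistic,
                  numeric(1))
  expect_equal(round(unname(stats), 2), c(94.52, 64.92, 32.27, 9.99, 25.35))
  p <- vapply(table1_counts, function(m) pearson_chi_square(m)$p_value,
              numeric(1))
  expect_true(all(p[c("sex", "ethnicity", "marital", "mdd")] < 0.001))
  expect_equal(pearson_chi_square(table1_counts$deprivation)$p_value, 0.041,
               tolerance = 0.01)
})

test_that("chi-square basics: independence, margins, invariances", {
  prop <- matrix(c(10, 20, 30, 60), 2)  # proportional rows
  expect_equal(pearson_chi_square(prop)$statistic, 0)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2)), "zero margin")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "2 x 2")

  set.seed(8)
  m <- matrix(rpois(6, 30) + 1, 3)
  base <- pearson_chi_square(m)$statistic
  expect_equal(pearson_chi_square(m[3:1, ])$statistic, base)
  expect_equal(pearson_chi_square(m[, 2:1])$statistic, base)
  expect_equal(pearson_chi_square(5 * m)$statistic, 5 * base)
  # brute-force formula agreement
  expect_equal(base, chisq_oracle(m), tolerance = 1e-12)
})

test_that("2x2 odds ratios and Woolf intervals follow the closed form", {
  eq <- odds_ratio_2x2(50, 50, 20, 20)
  expect_equal(eq$point, 1)

  sym <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(sym$point, 1)
  expect_equal(sym$ci_low, 0.2895, tolerance = 1e-3)
  expect_equal(sym$ci_high, 3.4543, tolerance = 1e-3)

  expect_warning(z <- odds_ratio_2x2(10, 0, 5, 5), "continuity")
  expect_true(is.finite(z$point))
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "negative")

  # reciprocal when one margin is swapped; invariant when both are
  set.seed(9)
  for (i in 1:20) {
    cells <- rpois(4, 20) + 1
    o <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    swap_rows <- odds_ratio_2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(swap_rows$point, 1 / o$point)
    both <- odds_ratio_2x2(cells[4], cells[3], cells[2], cells[1])
    expect_equal(both$point, o$point)
  }
})

test_that("odds ratios reconstructed from printed percentages match the source", {
  n_no <- 6381
  n_csa <- 619
  adm <- odds_ratio_from_props(0.511, 0.670, n_no, n_csa)
  n_adm_no <- round(0.511 * n_no)
  n_adm_csa <- round(0.670 * n_csa)
  days <- odds_ratio_from_props(0.501, 0.569, n_adm_no, n_adm_csa)
  ap <- odds_ratio_from_props(0.895, 0.955, n_no, n_csa)
  dose <- odds_ratio_from_props(0.476, 0.609,
                                round(0.895 * n_no), round(0.955 * n_csa))
  expect_equal(round(days$point, 2), 1.31)
  expect_equal(round(adm$point, 2), 1.95)
  expect_equal(round(ap$point, 2), 2.48)
  expect_equal(round(dose$point, 2), 1.72)
})

test_that("logistic regression agrees with the 2x2 odds ratio when saturated", {
  set.seed(12)
  n <- 400
  e <- rbinom(n, 1, 0.3) == 1
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * e)) == 1
  df <- data.frame(y = y, e = e)
  a <- sum(!e & !y); b <- sum(!e & y); c <- sum(e & !y); d <- sum(e & y)
  closed <- odds_ratio_2x2(a, b, c, d)
  fit <- fit_logistic(df, "y", "e")
  expect_equal(fit$point, closed$point, tolerance = 1e-8)
  expect_false(fit$adjusted)

  # a covariate independent of exposure and outcome leaves the OR alone
  df$z <- rnorm(n)
  adj <- fit_logistic(df, "y", "e", covariates = "z")
  expect_true(adj$adjusted)
  expect_equal(adj$point, fit$point, tolerance = 0.02)
})

test_that("separation and missing columns raise explicit diagnostics", {
  df <- data.frame(y = c(rep(FALSE, 20), rep(TRUE, 20)),
                   e = c(rep(FALSE, 20), rep(TRUE, 20)))
  expect_error(suppressWarnings(fit_logistic(df, "y", "e")), "separation")
  expect_error(fit_logistic(df, "y", "missing_col"), "not found")
})
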