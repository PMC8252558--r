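#' Cross-tabulate a categorical variable against exposure
#'
#' Builds the r x 2 contingency table comparing a characteristic between
#' exposure groups. `Unknown` categories are retained as ordinary rows by
#' default (they carry information about differential recording) but can be
#' dropped.
#'
#' @param data Data frame of analytic-cohort patients.
#' @param variable Name of the categorical column.
#' @param exposure Name of the binary/logical exposure column (TRUE/second
#'   level = exposed).
#' @param drop_unknown Drop rows whose category is `"Unknown"` before
#'   tabulating.
#' @return An integer matrix (rows = categories, columns = `No CSA`, `CSA`).
#' @export
build_table <- function(data, variable, exposure, drop_unknown = FALSE) {
  if (!variable %in% names(data)) {
    stop("variable not found: ", variable, call. = FALSE)
  }
  if (!exposure %in% names(data)) {
    stop("exposure not found: ", exposure, call. = FALSE)
  }
  v <- data[[variable]]
  e <- data[[exposure]]
  if (drop_unknown) {
    keep <- is.na(v) | v != "Unknown"
    v <- v[keep]
    e <- e[keep]
  }
  if (is.logical(e)) e <- factor(e, levels = c(FALSE, TRUE),
                                 labels = c("No CSA", "CSA"))
  tab <- table(v, e)
  if (nrow(tab) < 2L) {
    stop("degenerate table: variable '", variable,
         "' has fewer than 2 observed categories", call. = FALSE)
  }
  if (ncol(tab) < 2L) {
    stop("degenerate table: exposure has fewer than 2 observed levels",
         call. = FALSE)
  }
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c(variable, exposure)
  m
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with
#' expected counts from the product of margins, df = (r-1)(c-1) and the
#' upper-tail p-value.
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2, with all row
#'   and column margins positive.
#' @return An `effect_estimate` with `measure = "chi_square"`, `statistic`,
#'   `df`, `p_value`.
#' @examples
#' pearson_chi_square(matrix(c(3609, 2772, 224, 395), 2))
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin invalidates the chi-square test", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  effect_estimate(measure = "chi_square",
                  statistic = unname(ct$statistic),
                  df = unname(ct$parameter),
                  p_value = unname(ct$p.value))
}

#' Odds ratio for a 2x2 exposure-outcome table
#'
#' Cells follow the exposure-rows layout: `a` unexposed without the
#' outcome, `b` unexposed with it, `c` exposed without, `d` exposed with.
#' The odds ratio is `(d/c) / (b/a)` with the Woolf (log-normal) 95%
#' confidence interval `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' A zero cell triggers the documented 0.5 continuity correction on all
#' cells, with a warning.
#'
#' @param a,b,c,d Non-negative counts.
#' @return An `effect_estimate` with `measure = "OR"`, `point`, `ci_low`,
#'   `ci_high`, `p_value` (Wald).
#' @examples
#' odds_ratio_2x2(10, 10, 10, 10)
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative counts", call. = FALSE)
  if (any(cells == 0)) {
    warning("zero cell: applying 0.5 continuity correction", call. = FALSE)
    cells <- cells + 0.5
  }
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  or <- (d / c) / (b / a)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  effect_estimate(measure = "OR",
                  point = or,
                  ci_low = exp(log(or) - 1.96 * se),
                  ci_high = exp(log(or) + 1.96 * se),
                  p_value = 2 * stats::pnorm(-abs(z)))
}

#' Odds ratio reconstructed from reported group proportions
#'
#' When only rounded percentages and group sizes are available (published
#' outcome tables), cell counts are reconstructed as `round(p * n)` per
#' group before computing the odds ratio. The rounding discrepancy against
#' an odds ratio taken directly on the proportions is typically below 0.01
#' and is documented rather than corrected.
#'
#' @param p_unexposed,p_exposed Outcome proportions in each group (0-1).
#' @param n_unexposed,n_exposed Group sizes.
#' @return An `effect_estimate` (see [odds_ratio_2x2()]).
#' @export
odds_ratio_from_props <- function(p_unexposed, p_exposed,
                                  n_unexposed, n_exposed) {
  stopifnot(p_unexposed >= 0, p_unexposed <= 1, p_exposed >= 0, p_exposed <= 1)
  b <- round(p_unexposed * n_unexposed)
  d <- round(p_exposed * n_exposed)
  odds_ratio_2x2(n_unexposed - b, b, n_exposed - d, d)
}

#' Covariate-adjusted logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic fit of `outcome ~ exposure + covariates`;
#' the adjusted odds ratio is `exp()` of the exposure coefficient with a
#' Wald 95% interval. Categorical covariates are expanded against stated
#' reference levels (largest groups: male sex, White ethnicity, when those
#' columns are supplied). Non-convergence or separation (|coefficient| >
#' 10) raises an explicit diagnostic instead of silent output.
#'
#' @param data Data frame.
#' @param outcome,exposure Names of binary (logical/0-1) columns.
#' @param covariates Character vector of adjustment column names (default
#'   none, giving the unadjusted logistic fit).
#' @param reference Named list of reference levels for categorical
#'   covariates, default `list(sex = "M", ethnicity = "White")`.
#' @return An `effect_estimate` with `measure = "OR"`, `adjusted`,
#'   `covariates`, plus the fitted `model`.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(0),
                         reference = list(sex = "M", ethnicity = "White")) {
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, cols, drop = FALSE]
  for (cv in covariates) {
    if (is.character(df[[cv]]) || is.factor(df[[cv]])) {
      lev <- unique(as.character(df[[cv]]))
      ref <- reference[[cv]]
      if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
      df[[cv]] <- factor(as.character(df[[cv]]), levels = lev)
    }
  }
  df[[exposure]] <- as.numeric(df[[exposure]])
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::glm(fml, data = df, family = stats::binomial())
  if (!fit$converged) {
    stop("logistic fit did not converge for outcome ", outcome, call. = FALSE)
  }
  beta <- stats::coef(fit)[exposure]
  if (abs(beta) > 10) {
    stop("apparent separation on exposure (|log-OR| > 10) for outcome ",
         outcome, call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit))[exposure])
  est <- effect_estimate(measure = "OR",
                         point = exp(unname(beta)),
                         ci_low = exp(unname(beta - 1.96 * se)),
                         ci_high = exp(unname(beta + 1.96 * se)),
                         p_value = unname(2 * stats::pnorm(-abs(beta / se))),
                         adjusted = length(covariates) > 0L,
                         covariates = covariates)
  est$model <- fit
  est
}

# Constructor for the common result container.
effect_estimate <- function(measure, point = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, statistic = NA_real_,
                            df = NA_integer_, p_value = NA_real_,
                            adjusted = FALSE, covariates = character(0)) {
  structure(list(measure = measure, point = point, ci_low = ci_low,
                 ci_high = ci_high, statistic = statistic, df = df,
                 p_value = p_value, adjusted = adjusted,
                 covariates = covariates),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$measure == "chi_square") {
    cat(sprintf("Pearson chi-square: X2 = %.2f, df = %d, p = %.3g\n",
                x$statistic, x$df, x$p_value))
  } else {
    lab <- if (isTRUE(x$adjusted)) "Adjusted OR" else "OR"
    cat(sprintf("%s = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                lab, x$point, x$ci_low, x$ci_high, x$p_value))
    if (length(x$covariates)) {
      cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
    }
  }
  invisible(x)
}
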