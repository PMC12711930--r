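#' Student's t-test (paired or pooled two-sample)
#'
#' Two-tailed Student's t-test: paired, or unpaired with pooled variance
#' (classical Student, not Welch, matching standard Prism defaults for
#' "Student's t test").
#'
#' @param x,y numeric samples
#' @param paired paired test (equal lengths required)
#' @return list of class `ach_test` with `statistic`, `df`, `p_value`,
#'   `test_name`; zero variance in both groups gives `NA` with a warning
#' @export
t_test <- function(x, y, paired = FALSE) {
  if (paired) stopifnot(length(x) == length(y), length(x) >= 2)
  else stopifnot(length(x) >= 2, length(y) >= 2)
  novar <- if (paired) stats::sd(x - y) == 0
           else stats::sd(x) == 0 && stats::sd(y) == 0
  if (novar && (paired || mean(x) == mean(y)) &&
      (!paired || mean(x - y) == 0)) {
    # identical data: t = 0, P = 1 by convention
    df <- if (paired) length(x) - 1 else length(x) + length(y) - 2
    return(structure(list(statistic = 0, df = df, p_value = 1,
                          test_name = if (paired) "paired t" else
                            "Student t (pooled)"),
                     class = "ach_test"))
  }
  if (novar) {
    warning("zero variance: t statistic undefined")
    return(structure(list(statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_,
                          test_name = "t (undefined)"),
                     class = "ach_test"))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = !paired,
                      alternative = "two.sided")
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 test_name = if (paired) "paired t" else
                   "Student t (pooled)"),
            class = "ach_test")
}

#' @export
print.ach_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, P = %.3g\n",
              x$test_name, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction;
#' df = (rows - 1)(cols - 1). All expected counts must be positive.
#'
#' @param tab numeric matrix of counts
#' @return an `ach_test` result
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected <= 0)) stop("non-positive expected count")
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 test_name = "Pearson chi-square"),
            class = "ach_test")
}

#' Pearson correlation with significance
#'
#' @param x,y numeric vectors, n >= 3, finite
#' @return list with `r`, `p_value`, `n` (P from the t transform of r)
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Cohen's d with 95% confidence interval
#'
#' Standardized mean difference using the pooled standard deviation,
#' d = (mean_x - mean_y) / s_pooled, with the normal-approximation
#' standard error SE = sqrt((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))) and
#' a 95% CI d +/- 1.96 SE.
#'
#' @param x,y numeric samples, each n >= 2
#' @return list with `d`, `ci_low`, `ci_high`; pooled SD of zero gives NA
#'   with a warning
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    warning("pooled SD is zero: effect size undefined")
    return(list(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se)
}

#' Two-way repeated-measures ANOVA
#'
#' Standard within-subject decomposition for a balanced complete
#' subject x factor A x factor B design, via `aov` with an
#' `Error(subject/(A*B))` stratum. Returns F, degrees of freedom and P for
#' both main effects and the interaction. Missing cells are an error (no
#' imputation).
#'
#' @param values numeric response
#' @param subject,factor_a,factor_b factors (coerced), one entry per value
#' @return data.frame with rows `A`, `B`, `A:B` and columns `F`, `df1`,
#'   `df2`, `p_value`
#' @export
rm_anova_2way <- function(values, subject, factor_a, factor_b) {
  d <- data.frame(y = values, s = factor(subject), A = factor(factor_a),
                  B = factor(factor_b))
  tab <- table(d$s, d$A, d$B)
  if (any(tab != 1))
    stop("design must be balanced and complete (one value per cell)")
  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = d)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    st <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(st)))
    c(F = st[i, "F value"], df1 = st[i, "Df"],
      df2 = st[nrow(st), "Df"], p = st[i, "Pr(>F)"])
  }
  a <- grab("Error: s:A", "A")
  b <- grab("Error: s:B", "B")
  ab <- grab("Error: s:A:B", "A:B")
  out <- data.frame(effect = c("A", "B", "A:B"),
                    F = c(a["F"], b["F"], ab["F"]),
                    df1 = c(a["df1"], b["df1"], ab["df1"]),
                    df2 = c(a["df2"], b["df2"], ab["df2"]),
                    p_value = c(a["p"], b["p"], ab["p"]))
  rownames(out) <- NULL
  out
}

#' Percentage with half-up rounding
#'
#' `100 * count / total`, rounded half-up to the requested number of
#' decimals (matching how printed percentages are usually rounded, unlike
#' banker's rounding).
#'
#' @param count,total non-negative counts, `0 <= count <= total`,
#'   `total > 0`
#' @param decimals decimal places, default 1
#' @return percentage on the 0-100 scale
#' @export
proportion <- function(count, total, decimals = 1) {
  stopifnot(total > 0, count >= 0, count <= total)
  p <- 100 * count / total
  f <- 10^decimals
  floor(p * f + 0.5) / f
}
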