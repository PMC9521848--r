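#' Normality-routed two-sample or paired comparison
#'
#' Mirrors the routing convention of clinical trial reports: each variable is
#' checked for normality with the Shapiro-Wilk test at `alpha_normal` (on the
#' within-pair differences for paired designs); normal data go to the t-test
#' (pooled-variance for independent groups), non-normal data to the
#' Mann-Whitney U / Wilcoxon signed-rank test. Rank tests use the asymptotic
#' tie-corrected statistic. All p-values are two-tailed. The effect size is
#' the magnitude of the pooled-SD standardized mean difference of the two
#' samples (see [cohens_d_pooled()]).
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Compare within-subject (baseline vs post)?
#' @param alpha_normal Significance level of the Shapiro-Wilk routing test.
#' @return An object of class `"capen_comparison"`: list with `test_name`,
#'   `statistic`, `p_value`, `n` (per-group sizes), `effect_size`.
#' @examples
#' route_and_compare(rnorm(12), rnorm(12, 5))
#' @export
route_and_compare <- function(a, b, paired = FALSE, alpha_normal = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) { keep <- !(is.na(a) | is.na(b))
    if (paired) { a <- a[keep]; b <- b[keep] } else { a <- a[!is.na(a)]; b <- b[!is.na(b)] } }
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 observations per sample")
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length")

  normal <- function(x) {
    if (length(unique(x)) < 3L) return(FALSE)  # ties/constant: rank route
    stats::shapiro.test(x)$p.value >= alpha_normal
  }
  d_es <- tryCatch(
    abs(cohens_d_pooled(mean(a), stats::sd(a), mean(b), stats::sd(b))),
    error = function(e) 0)

  if (paired) {
    dif <- a - b
    if (stats::sd(dif) == 0) {
      out <- list(test_name = "paired t-test (degenerate: identical samples)",
                  statistic = 0, p_value = 1,
                  n = c(length(a), length(b)), effect_size = d_es)
      return(structure(out, class = "capen_comparison"))
    }
    if (normal(dif)) {
      tt <- stats::t.test(a, b, paired = TRUE)
      out <- list(test_name = "paired t-test", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                exact = FALSE, correct = FALSE))
      out <- list(test_name = "Wilcoxon signed-rank test",
                  statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  } else {
    if (normal(a) && normal(b)) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      out <- list(test_name = "independent t-test",
                  statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = FALSE))
      out <- list(test_name = "Mann-Whitney U test",
                  statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  }
  out$n <- c(length(a), length(b))
  out$effect_size <- d_es
  structure(out, class = "capen_comparison")
}

#' @export
print.capen_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, d = %.3f (n = %s)\n",
              x$test_name, x$statistic, x$p_value, x$effect_size,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Pooled-SD standardized mean difference (Cohen's d)
#'
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2) / 2)`: the denominator is the root
#' mean of the two variances (not sample-size weighted, and for pre/post
#' comparisons not the change-score SD). This is the convention under which
#' the effect sizes printed in the emulated trial's tables reproduce exactly.
#'
#' @param m1,s1 Mean and SD of the first sample.
#' @param m2,s2 Mean and SD of the second sample.
#' @return Signed standardized difference (reports typically print the
#'   magnitude).
#' @examples
#' cohens_d_pooled(5.63, 2.41, 1.21, 2.10)  # 1.955
#' @export
cohens_d_pooled <- function(m1, s1, m2, s2) {
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  if (s1 == 0 && s2 == 0) stop("both SDs are zero: effect size undefined")
  (m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' Pearson statistic without continuity correction, df = k - 1, two-sided
#' asymptotic p-value.
#'
#' @param table Matrix of non-negative integer counts, 2 rows, k >= 2 columns.
#' @return A `"capen_comparison"` with the statistic, df and p-value.
#' @examples
#' chi_square(rbind(c(10, 2), c(9, 3)))  # p = 0.615
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("expected a 2 x k table with k >= 2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column total: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(test_name = "Pearson chi-square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n = rowSums(table), effect_size = NA_real_),
            class = "capen_comparison")
}

#' Univariate screening followed by multivariate linear regression
#'
#' Each candidate is first fit in a univariate ordinary least squares model
#' of the outcome; candidates with univariate p < `screen_p` are carried,
#' together with the group term (always retained), into one multivariate OLS
#' model. Standardized coefficients are `B * sd(x) / sd(y)`.
#'
#' @param outcome Numeric response vector.
#' @param candidates Data frame of numeric candidate predictors (code
#'   categorical variables ordinally beforehand).
#' @param group Numeric/0-1 group indicator, always kept in the multivariate
#'   model and screened univariately like the candidates.
#' @param screen_p Univariate retention threshold (default 0.2).
#' @return An object of class `"capen_regression"`: list with `univariate`
#'   (data.frame: term, B, SE, b, t, p, r2), `multivariate` (same columns),
#'   `r2` (multivariate), `retained` (character).
#' @examples
#' set.seed(1)
#' x <- data.frame(age = rnorm(24, 50, 10))
#' g <- rep(0:1, each = 12)
#' y <- 3 * g + rnorm(24)
#' screen_then_model(y, x, g)
#' @export
screen_then_model <- function(outcome, candidates, group, screen_p = 0.2) {
  stopifnot(is.data.frame(candidates))
  y <- as.numeric(outcome)
  dat <- cbind(group = as.numeric(group), candidates)
  if (nrow(dat) != length(y)) stop("outcome and predictors differ in length")

  uni_row <- function(x, nm) {
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    co <- s$coefficients
    if (nrow(co) < 2L)  # constant predictor
      return(data.frame(term = nm, B = NA, SE = NA, b = NA, t = NA, p = 1,
                        r2 = 0))
    data.frame(term = nm, B = co[2L, 1L], SE = co[2L, 2L],
               b = co[2L, 1L] * stats::sd(x) / stats::sd(y),
               t = co[2L, 3L], p = co[2L, 4L], r2 = s$r.squared)
  }
  uni <- do.call(rbind, lapply(names(dat), function(nm) uni_row(dat[[nm]], nm)))
  rownames(uni) <- NULL

  retained <- setdiff(uni$term[uni$p < screen_p], "group")
  terms <- c("group", retained)
  if (length(y) <= length(terms) + 1L)
    stop("too few observations for ", length(terms), " retained predictors")
  X <- dat[, terms, drop = FALSE]
  fit <- stats::lm(y ~ ., data = X)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear retained predictors: ", paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  co <- s$coefficients[-1L, , drop = FALSE]
  multi <- data.frame(term = rownames(co), B = co[, 1L], SE = co[, 2L],
                      b = co[, 1L] * vapply(X, stats::sd, 0.0) / stats::sd(y),
                      t = co[, 3L], p = co[, 4L], r2 = s$r.squared)
  rownames(multi) <- NULL
  structure(list(univariate = uni, multivariate = multi, r2 = s$r.squared,
                 retained = retained, screen_p = screen_p),
            class = "capen_regression")
}

#' @export
print.capen_regression <- function(x, ...) {
  cat("Univariate screening (retain p <", x$screen_p, "):\n")
  print(x$univariate, digits = 3)
  cat("\nMultivariate model (R^2 =", round(x$r2, 3), "), group always kept:\n")
  print(x$multivariate, digits = 3)
  invisible(x)
}

#' Achieved power of the paired t-test
#'
#' Power via the noncentral t distribution with `df = n - 1` and
#' noncentrality `dz * sqrt(n)`, where `dz` is the paired effect size (mean
#' difference over SD of differences). The default is a one-sided test at
#' level `alpha`, the convention under which the emulated trial's sample
#' size was planned (dz = 1, n = 11 per arm, alpha = 0.05 gives power
#' 0.924); `alternative = "two.sided"` gives the two-tailed power.
#'
#' @param dz Paired standardized effect size, >= 0.
#' @param n Number of pairs (>= 2).
#' @param alpha Test level, in (0, 1).
#' @param alternative `"one.sided"` (default) or `"two.sided"`.
#' @return Achieved power in \[0, 1\]; equals `alpha` at `dz = 0`.
#' @examples
#' paired_t_power(1.0, 11)          # 0.924
#' paired_t_power(1.0, 11, alternative = "two.sided")
#' @export
paired_t_power <- function(dz, n, alpha = 0.05,
                           alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(dz) || dz < 0) stop("dz must be a non-negative number")
  if (n < 2) stop("need n >= 2 pairs")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (alternative == "one.sided") {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
}
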