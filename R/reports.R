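# Report tables mirroring the layouts of clinical trial papers:
# within-group pre/post comparisons, between-group change comparisons,
# per-pair connectivity tables and the regression screen.

fmt_ms <- function(m, s) sprintf("%.2f ± %.2f", m, s)

#' Within-group speech-score report (baseline vs post per arm)
#'
#' One row per subtest and arm: baseline and post mean/SD, the
#' normality-routed paired comparison p-value and the pooled-SD effect size.
#'
#' @param subjects Subject table (from [simulate_trial()] / [read_trial()]).
#' @param alpha_normal Shapiro-Wilk routing level.
#' @return data.frame: subtest, arm, baseline, post (formatted mean +/- SD),
#'   p, effect_size, test.
#' @export
speech_prepost_report <- function(subjects, alpha_normal = 0.05) {
  subtests <- c("counting", "imitation", "alphabet", "mono", "di")
  rows <- list()
  for (arm in unique(subjects$arm)) for (st in subtests) {
    b <- subjects[subjects$arm == arm, paste0(st, "_baseline")]
    p <- subjects[subjects$arm == arm, paste0(st, "_post")]
    cmp <- route_and_compare(p, b, paired = TRUE, alpha_normal = alpha_normal)
    rows[[length(rows) + 1L]] <- data.frame(
      subtest = st, arm = arm,
      baseline = fmt_ms(mean(b), stats::sd(b)),
      post = fmt_ms(mean(p), stats::sd(p)),
      p = cmp$p_value, effect_size = cmp$effect_size,
      test = cmp$test_name, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Between-group speech change-score report
#'
#' One row per subtest: per-arm change mean/SD, the routed two-group
#' comparison p-value and the pooled-SD effect size.
#'
#' @inheritParams speech_prepost_report
#' @return data.frame: subtest, tDCS, control, p, effect_size, test.
#' @export
speech_change_report <- function(subjects, alpha_normal = 0.05) {
  subtests <- c("counting", "imitation", "alphabet", "mono", "di")
  rows <- list()
  for (st in subtests) {
    ch <- subjects[[paste0(st, "_post")]] - subjects[[paste0(st, "_baseline")]]
    a <- ch[subjects$arm == "tDCS"]; b <- ch[subjects$arm == "control"]
    cmp <- route_and_compare(a, b, alpha_normal = alpha_normal)
    rows[[length(rows) + 1L]] <- data.frame(
      subtest = st,
      tDCS = fmt_ms(mean(a), stats::sd(a)),
      control = fmt_ms(mean(b), stats::sd(b)),
      p = cmp$p_value, effect_size = cmp$effect_size,
      test = cmp$test_name, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-pair pre/post comparison of difference values within one arm
#'
#' For each electrode pair (montage report order): baseline and post
#' difference-value mean/SD, the paired routed comparison and pooled-SD
#' effect size.
#'
#' @param conn A `"connectivity_table"`.
#' @param arm Arm label.
#' @param adjust `"none"` or `"BH"` across the pairs.
#' @param alpha_normal Shapiro-Wilk routing level.
#' @return data.frame: pair, category, baseline, post, p, effect_size, n.
#' @export
compare_prepost <- function(conn, arm, adjust = c("none", "BH"),
                            alpha_normal = 0.05) {
  adjust <- match.arg(adjust)
  sub <- conn[conn$arm == arm, ]
  rows <- list()
  for (pr in unique(conn$pair)) {
    d <- sub[sub$pair == pr, ]
    ok <- !is.na(d$diff_baseline) & !is.na(d$diff_post)
    cmp <- route_and_compare(d$diff_post[ok], d$diff_baseline[ok],
                             paired = TRUE, alpha_normal = alpha_normal)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = pr, category = d$category[1L],
      baseline = fmt_ms(mean(d$diff_baseline[ok]), stats::sd(d$diff_baseline[ok])),
      post = fmt_ms(mean(d$diff_post[ok]), stats::sd(d$diff_post[ok])),
      p = cmp$p_value, effect_size = cmp$effect_size, n = sum(ok),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Per-pair between-arm comparison of change scores
#'
#' For each electrode pair: per-arm change mean/SD, the routed two-group
#' comparison p-value and the pooled-SD effect size. This is the table from
#' which treatment-specific connectivity topology is read.
#'
#' @inheritParams compare_prepost
#' @return data.frame: pair, category, tDCS, control, p, effect_size, n.
#' @export
compare_changes <- function(conn, adjust = c("none", "BH"),
                            alpha_normal = 0.05) {
  adjust <- match.arg(adjust)
  arms <- unique(conn$arm)
  stopifnot(length(arms) == 2L)
  rows <- list()
  for (pr in unique(conn$pair)) {
    d <- conn[conn$pair == pr, ]
    a <- d$change[d$arm == arms[1L]]; b <- d$change[d$arm == arms[2L]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    cmp <- route_and_compare(a, b, alpha_normal = alpha_normal)
    row <- data.frame(pair = pr, category = d$category[1L],
                      stringsAsFactors = FALSE)
    row[[arms[1L]]] <- fmt_ms(mean(a), stats::sd(a))
    row[[arms[2L]]] <- fmt_ms(mean(b), stats::sd(b))
    row$p <- cmp$p_value; row$effect_size <- cmp$effect_size
    row$n <- length(a) + length(b)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Regression screen for predictors of word-repetition improvement
#'
#' Outcome: change in the summed monosyllable + disyllable repetition score.
#' Candidates: age, sex, education, lesion size, post-stroke onset, aphasia
#' type (ordinal Global=0, Mixed=1, Broca=2) and severity (0/1/2); the
#' treatment arm is the group term. Univariate screening at `screen_p`
#' feeds the multivariate model (see [screen_then_model()]).
#'
#' @param subjects Subject table.
#' @param screen_p Univariate retention threshold.
#' @return A `"capen_regression"`.
#' @export
word_repetition_regression <- function(subjects, screen_p = 0.2) {
  outcome <- (subjects$mono_post + subjects$di_post) -
    (subjects$mono_baseline + subjects$di_baseline)
  cand <- data.frame(
    age = subjects$age,
    sex = as.numeric(subjects$sex == "male"),
    education = subjects$education,
    lesion_size = subjects$lesion_size,
    onset_weeks = subjects$onset_weeks,
    aphasia_type = match(subjects$aphasia_type,
                         c("Global", "Mixed", "Broca")) - 1,
    severity = as.numeric(subjects$severity))
  screen_then_model(outcome, cand,
                    group = as.numeric(subjects$arm == "tDCS"),
                    screen_p = screen_p)
}

#' Recompute the emulated trial's printed comparisons from its summaries
#'
#' Worked examples on the published summary statistics this package ships
#' as [reference_stats()] / [reference_connectivity()]: pooled-SD effect
#' sizes for the pre/post and between-arm speech tables and the
#' connectivity difference/change tables, chi-square p-values for the
#' baseline categorical comparisons, and the design power of the paired
#' test. All quantities are recomputed, not transcribed.
#'
#' @return A list with `effect_sizes` (data.frame: table, row, arm, d),
#'   `chi_square` (data.frame: variable, statistic, df, p) and `power`
#'   (design power at dz = 1, n = 11, alpha = 0.05).
#' @examples
#' ex <- reference_worked_examples()
#' subset(ex$effect_sizes, row == "imitation" & table == "speech_change")
#' @export
reference_worked_examples <- function() {
  ref <- reference_stats()
  sc <- ref$scores
  es <- list()
  add <- function(tab, row, arm, d)
    es[[length(es) + 1L]] <<- data.frame(table = tab, row = row, arm = arm,
                                         d = abs(d), stringsAsFactors = FALSE)
  for (arm in c("tDCS", "control")) for (st in unique(sc$subtest)) {
    b <- sc[sc$arm == arm & sc$subtest == st & sc$phase == "baseline", ]
    p <- sc[sc$arm == arm & sc$subtest == st & sc$phase == "post", ]
    add("speech_prepost", st, arm, cohens_d_pooled(p$mean, p$sd, b$mean, b$sd))
  }
  for (st in unique(sc$subtest)) {
    a <- sc[sc$arm == "tDCS" & sc$subtest == st & sc$phase == "change", ]
    b <- sc[sc$arm == "control" & sc$subtest == st & sc$phase == "change", ]
    add("speech_change", st, "both", cohens_d_pooled(a$mean, a$sd, b$mean, b$sd))
  }
  cn <- reference_connectivity()
  for (arm in c("tDCS", "control")) for (pr in unique(cn$pair)) {
    b <- cn[cn$arm == arm & cn$pair == pr & cn$phase == "baseline", ]
    p <- cn[cn$arm == arm & cn$pair == pr & cn$phase == "post", ]
    add("connectivity_prepost", pr, arm,
        cohens_d_pooled(p$mean, p$sd, b$mean, b$sd))
  }
  for (pr in unique(cn$pair)) {
    a <- cn[cn$arm == "tDCS" & cn$pair == pr & cn$phase == "change", ]
    b <- cn[cn$arm == "control" & cn$pair == pr & cn$phase == "change", ]
    add("connectivity_change", pr, "both",
        cohens_d_pooled(a$mean, a$sd, b$mean, b$sd))
  }
  chi <- do.call(rbind, lapply(names(ref$categorical), function(v) {
    ct <- chi_square(ref$categorical[[v]])
    data.frame(variable = v, statistic = ct$statistic, df = ct$df,
               p = ct$p_value, stringsAsFactors = FALSE)
  }))
  list(effect_sizes = do.call(rbind, es), chi_square = chi,
       power = paired_t_power(1.0, 11, 0.05))
}
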