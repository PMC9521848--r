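# Published summary statistics of the two-arm speech/tDCS trial that this
# package's generator emulates. These are inputs: the generator draws
# covariates and speech scores from them, and the worked-example helpers
# recompute effect sizes and chi-square p-values from them.

#' Reference clinical summary statistics
#'
#' Summary statistics (means, SDs, counts) of the emulated two-arm trial:
#' baseline demographics and stroke characteristics, the five
#' apraxia-of-speech subtest scores at baseline and post-treatment per arm,
#' and between-arm change-score summaries. The speech subtests and their
#' ranges: counting 0-10, imitation of face/tongue/lip movements 0-20,
#' phonetic-alphabet repetition 0-20, monosyllable repetition 0-10,
#' disyllable repetition 0-10.
#'
#' @return A list with components:
#'   `covariates` (data.frame: variable, arm, mean, sd, lo, hi),
#'   `categorical` (list of 2-row count matrices by variable: sex, etiology,
#'   temporal, parietal, insula, basal_ganglia, aphasia_type, severity),
#'   `scores` (data.frame: subtest, arm, phase in baseline/post/change,
#'   mean, sd, lo, hi).
#' @examples
#' ref <- reference_stats()
#' ref$categorical$sex
#' @export
reference_stats <- function() {
  covariates <- data.frame(
    variable = rep(c("age", "education", "lesion_size", "onset_weeks"), each = 2L),
    arm      = rep(c("tDCS", "control"), 4L),
    mean     = c(47.42, 52.17, 12.25, 10.33, 64.42, 60.00, 7.50, 5.67),
    sd       = c(10.87, 14.10, 2.90, 3.47, 13.92, 11.80, 3.29, 2.64),
    lo       = c(18, 18, 0, 0, 5, 5, 4, 4),
    hi       = c(80, 80, 22, 22, 150, 150, 17, 17),
    stringsAsFactors = FALSE)

  cat2 <- function(a, b) {
    m <- rbind(tDCS = a, control = b)
    colnames(m) <- paste0("k", seq_along(a))
    m
  }
  categorical <- list(
    sex            = cat2(c(10, 2), c(9, 3)),      # male / female
    etiology       = cat2(c(12, 0), c(11, 1)),     # thrombosis / hemorrhage
    temporal       = cat2(c(12, 0), c(11, 1)),
    parietal       = cat2(c(11, 1), c(11, 1)),
    insula         = cat2(c(2, 10), c(1, 11)),     # involved / spared
    basal_ganglia  = cat2(c(7, 5), c(8, 4)),
    aphasia_type   = cat2(c(6, 4, 2), c(6, 4, 2)), # Global / Mixed / Broca
    severity       = cat2(c(5, 5, 2), c(6, 4, 2))) # grades 0 / 1 / 2

  sub <- c("counting", "imitation", "alphabet", "mono", "di")
  rng <- c(counting = 10, imitation = 20, alphabet = 20, mono = 10, di = 10)
  sc <- rbind(
    data.frame(subtest = sub, arm = "tDCS", phase = "baseline",
               mean = c(3.58, 4.88, 2.58, 1.00, 0.75),
               sd   = c(4.17, 3.00, 3.45, 2.37, 2.05)),
    data.frame(subtest = sub, arm = "tDCS", phase = "post",
               mean = c(7.25, 10.50, 9.08, 6.00, 4.67),
               sd   = c(3.02, 3.85, 4.03, 3.28, 3.08)),
    data.frame(subtest = sub, arm = "control", phase = "baseline",
               mean = c(1.67, 5.38, 2.00, 0.75, 0.58),
               sd   = c(3.14, 2.87, 3.05, 2.01, 1.16)),
    data.frame(subtest = sub, arm = "control", phase = "post",
               mean = c(5.50, 6.58, 4.75, 2.50, 2.00),
               sd   = c(3.83, 3.35, 2.70, 2.07, 2.17)),
    data.frame(subtest = sub, arm = "tDCS", phase = "change",
               mean = c(3.67, 5.63, 6.50, 5.00, 3.92),
               sd   = c(2.96, 2.41, 4.48, 3.10, 2.81)),
    data.frame(subtest = sub, arm = "control", phase = "change",
               mean = c(3.83, 1.21, 2.75, 1.75, 1.42),
               sd   = c(3.30, 2.10, 3.14, 1.91, 1.88)))
  sc$lo <- 0
  sc$hi <- rng[sc$subtest]
  rownames(sc) <- NULL

  list(covariates = covariates, categorical = categorical, scores = sc)
}

#' Reference connectivity difference-value summaries
#'
#' Per-pair summaries of the task-minus-rest C-ApEn difference value in the
#' emulated trial: baseline and post-treatment mean and SD per arm, and the
#' between-arm change-score summaries. Rows follow montage report order.
#'
#' @return A data.frame: pair, arm, phase (baseline/post/change), mean, sd.
#' @export
reference_connectivity <- function() {
  pairs <- build_default_montage()$pairs$pair
  num <- function(...) c(...)
  tab <- rbind(
    data.frame(pair = pairs, arm = "tDCS", phase = "baseline",
      mean = num(0.03, 0.05, 0.03, 0.05, 0.05, 0.05, 0.05, 0.05,
                 0.02, 0.05, 0.02, 0.03, 0.05, 0.03, 0.04, 0.02,
                 0.03, 0.02, 0.03, 0.06, 0.05),
      sd   = num(0.05, 0.04, 0.05, 0.04, 0.04, 0.04, 0.04, 0.04,
                 0.09, 0.06, 0.09, 0.07, 0.08, 0.08, 0.09, 0.09,
                 0.04, 0.06, 0.05, 0.04, 0.05)),
    data.frame(pair = pairs, arm = "tDCS", phase = "post",
      mean = num(0.12, 0.10, 0.11, 0.12, 0.10, 0.10, 0.11, 0.12,
                 0.05, 0.06, 0.06, 0.06, 0.07, 0.07, 0.08, 0.05,
                 0.07, 0.06, 0.07, 0.08, 0.08),
      sd   = num(0.09, 0.07, 0.09, 0.07, 0.07, 0.08, 0.08, 0.08,
                 0.10, 0.06, 0.07, 0.07, 0.06, 0.08, 0.08, 0.09,
                 0.06, 0.08, 0.05, 0.05, 0.05)),
    data.frame(pair = pairs, arm = "control", phase = "baseline",
      mean = num(0.02, 0.03, 0.02, 0.03, 0.04, 0.05, 0.05, 0.03,
                 -0.01, 0.00, -0.01, 0.00, 0.01, 0.00, 0.00, -0.02,
                 0.00, -0.02, 0.02, 0.02, 0.02),
      sd   = num(0.03, 0.03, 0.03, 0.04, 0.03, 0.04, 0.05, 0.03,
                 0.06, 0.04, 0.05, 0.05, 0.04, 0.04, 0.06, 0.05,
                 0.04, 0.07, 0.03, 0.03, 0.04)),
    data.frame(pair = pairs, arm = "control", phase = "post",
      mean = num(0.01, 0.05, 0.03, 0.03, 0.05, 0.04, 0.04, 0.03,
                 0.02, 0.03, 0.04, 0.03, 0.05, 0.03, 0.03, 0.03,
                 0.03, 0.02, 0.04, 0.04, 0.04),
      sd   = num(0.06, 0.05, 0.06, 0.07, 0.05, 0.04, 0.05, 0.05,
                 0.06, 0.06, 0.06, 0.06, 0.06, 0.06, 0.06, 0.05,
                 0.05, 0.05, 0.05, 0.05, 0.05)),
    data.frame(pair = pairs, arm = "tDCS", phase = "change",
      mean = num(0.09, 0.05, 0.08, 0.07, 0.05, 0.05, 0.06, 0.07,
                 0.02, 0.01, 0.04, 0.03, 0.02, 0.04, 0.04, 0.03,
                 0.04, 0.04, 0.04, 0.03, 0.03),
      sd   = num(0.10, 0.09, 0.09, 0.08, 0.08, 0.09, 0.08, 0.08,
                 0.12, 0.08, 0.09, 0.09, 0.10, 0.10, 0.11, 0.11,
                 0.06, 0.10, 0.06, 0.07, 0.06)),
    data.frame(pair = pairs, arm = "control", phase = "change",
      mean = num(0.00, 0.02, 0.01, 0.00, 0.02, 0.00, -0.01, 0.00,
                 0.03, 0.03, 0.04, 0.03, 0.04, 0.03, 0.03, 0.05,
                 0.03, 0.04, 0.02, 0.02, 0.02),
      sd   = num(0.06, 0.04, 0.07, 0.06, 0.04, 0.04, 0.04, 0.05,
                 0.06, 0.05, 0.05, 0.05, 0.07, 0.06, 0.08, 0.06,
                 0.04, 0.07, 0.05, 0.06, 0.05)))
  rownames(tab) <- NULL
  tab
}
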