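# Seeded synthetic trial generator: two-arm, two-timepoint, two-condition
# EEG datasets with clinical covariates and speech scores carrying the
# statistical structure the downstream analysis assumes.

#' Trial design for the synthetic dataset generator
#'
#' Defaults mirror the emulated study: 12 subjects per arm, 500 Hz sampling,
#' about 5 minutes of eyes-closed rest and a shorter eyes-closed repetition
#' task per timepoint. Recordings are mixtures of resonant AR(2) latent
#' sources (alpha-band peak) plus private white noise.
#'
#' @param n_per_arm Subjects per arm (>= 2; default 12).
#' @param rate Sampling rate in samples/second.
#' @param duration_rest,duration_task Recording lengths in seconds.
#' @param n_extra_channels Unanalyzed channels also written to each
#'   recording (a standard session records 16 while 10 are analyzed).
#' @param noise_sd Additional sensor white-noise SD on top of the unit-SD
#'   mixed signal (the private broadband remainder is part of the mixture).
#' @param ar_freq,ar_rho Resonance frequency (Hz) and pole radius of the
#'   AR(2) latent sources.
#' @param rho_scores Latent baseline-post correlation of the speech scores.
#' @return An object of class `"capen_design"`.
#' @examples
#' trial_design(n_per_arm = 2, duration_rest = 4, duration_task = 4)
#' @export
trial_design <- function(n_per_arm = 12L, rate = 500, duration_rest = 300,
                         duration_task = 60, n_extra_channels = 6L,
                         noise_sd = 0.05, ar_freq = 10, ar_rho = 0.95,
                         rho_scores = 0.5) {
  stopifnot(n_per_arm >= 2L, rate > 0, duration_rest > 0, duration_task > 0,
            noise_sd >= 0, ar_rho > 0, ar_rho < 1,
            rho_scores >= 0, rho_scores < 1)
  structure(list(n_per_arm = as.integer(n_per_arm), rate = rate,
                 duration_rest = duration_rest, duration_task = duration_task,
                 n_extra_channels = as.integer(n_extra_channels),
                 noise_sd = noise_sd, ar_freq = ar_freq, ar_rho = ar_rho,
                 rho_scores = rho_scores),
            class = "capen_design")
}

#' Per-pair coupling effect specification
#'
#' Couplings are source-level correlations in \[0, 1\]; higher coupling means
#' more shared signal and therefore a *lower* C-ApEn (less asynchrony). The
#' task condition starts from `base_coupling + task_offset`; after treatment
#' the task coupling of each arm's programmed pairs moves by `post_offset`
#' (negative = decoupling = higher task C-ApEn = larger task-minus-rest
#' difference value). Per subject, pair and cell an independent Gaussian
#' jitter of SD `subject_sd` is added, so between-subject variability in the
#' connectivity table is controlled in coupling units.
#'
#' The default programmed topology concentrates the post-treatment effect in
#' left-hemisphere pairs for the active arm (F3-F7, F7-C3, P3-F7, T5-P3,
#' T5-F7) and right/inter-hemispheric pairs for the control arm (F8-C4,
#' T6-F8, F3-F4, F7-F8). `post_offset` should normally come from
#' [calibrate_effect_delta()], which chooses it so the programmed
#' between-arm change-score effect size is a target value (~1 SD).
#'
#' @param post_offset Post-treatment task coupling shift applied to the
#'   programmed pairs (negative decouples).
#' @param pairs_active,pairs_control Character vectors of programmed pair
#'   labels per arm.
#' @param base_coupling Resting coupling shared by all analyzed pairs.
#' @param task_offset Task-minus-rest coupling shift at baseline (all pairs,
#'   both arms).
#' @param subject_sd SD of the per-subject/pair/cell coupling jitter.
#' @return An object of class `"capen_effects"`.
#' @examples
#' effect_spec(post_offset = -0.15)
#' null_effect_spec()
#' @export
effect_spec <- function(post_offset,
                        pairs_active = c("F3-F7", "F7-C3", "P3-F7",
                                         "T5-P3", "T5-F7"),
                        pairs_control = c("F8-C4", "T6-F8", "F3-F4", "F7-F8"),
                        base_coupling = 0.15, task_offset = -0.03,
                        subject_sd = 0.03) {
  stopifnot(base_coupling >= 0, base_coupling < 1, subject_sd >= 0)
  structure(list(post_offset = post_offset, pairs_active = pairs_active,
                 pairs_control = pairs_control, base_coupling = base_coupling,
                 task_offset = task_offset, subject_sd = subject_sd),
            class = "capen_effects")
}

#' @rdname effect_spec
#' @export
null_effect_spec <- function(base_coupling = 0.15, subject_sd = 0.03) {
  effect_spec(post_offset = 0, pairs_active = character(0),
              pairs_control = character(0), base_coupling = base_coupling,
              task_offset = 0, subject_sd = subject_sd)
}

# Keep every channel's summed coupling inside its variance budget after
# jitter, by proportionally shrinking the couplings of any channel that
# overflows (rare at the default scales: worst-case channel sits at 0.75).
enforce_budget <- function(cp, montage, cap = 0.98) {
  prs <- montage$pairs
  for (it in 1:10) {
    budget <- vapply(montage$sites$electrode, function(e)
      sum(cp[prs$el1 == e | prs$el2 == e]), 0.0)
    if (all(budget <= cap)) break
    bad <- names(budget)[which.max(budget)]
    own <- prs$pair[prs$el1 == bad | prs$el2 == bad]
    cp[own] <- cp[own] * cap / max(budget)
  }
  cp
}

# Expected (noise-free) coupling per pair for one arm/condition/timepoint.
coupling_profile <- function(effects, montage, arm, condition, timepoint) {
  cp <- rep(effects$base_coupling, nrow(montage$pairs))
  names(cp) <- montage$pairs$pair
  if (condition == "task") {
    cp <- cp + effects$task_offset
    if (timepoint == "post") {
      prog <- if (arm == "tDCS") effects$pairs_active else effects$pairs_control
      cp[prog] <- cp[prog] + effects$post_offset
    }
  }
  cp
}

# ---- truncated normal with mean matching --------------------------------

etrunc <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# latent mean such that the truncated-normal mean equals `target`
latent_mean <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi)
    stop("target mean must lie strictly inside the truncation range")
  f <- function(mu) etrunc(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = lo - 8 * sd, upper = hi + 8 * sd,
                 extendInt = "yes")$root
}

# inverse-CDF truncated-normal draw from a uniform u (keeps exact marginals
# under a Gaussian copula, so baseline-post correlation can be injected)
qtrunc <- function(u, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mu, sd); pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(pa + u * (pb - pa)) * sd + mu
}

# mean-matched truncated-normal sampler
rtrunc_matched <- function(n, target_mean, sd, lo, hi) {
  mu <- latent_mean(target_mean, sd, lo, hi)
  qtrunc(stats::runif(n), mu, sd, lo, hi)
}

# ---- channel synthesis ---------------------------------------------------

ar2_source <- function(n, rate, f0, rho) {
  a1 <- 2 * rho * cos(2 * pi * f0 / rate)
  a2 <- -rho^2
  burn <- 200L
  x <- stats::filter(stats::rnorm(n + burn), c(a1, a2), method = "recursive")
  x <- as.numeric(x)[(burn + 1L):(burn + n)]
  (x - mean(x)) / stats::sd(x)
}

# Channels as mixtures of pair-dedicated resonant AR(2) latent sources plus
# a white private remainder: channel_i = sum over its pairs of
# sqrt(c_p) * s_p + sqrt(1 - sum c_p) * eps_i (+ sensor noise). A pair's
# coupling is then exactly the channel correlation contributed by its shared
# source, and decoupling shifts a channel's rhythmic-vs-broadband balance —
# the feature a template-matching entropy statistic is sensitive to.
# Feasible iff every channel's coupling budget sum c_p <= 1 (which implies a
# valid covariance).
synth_channels <- function(n, rate, coupling, montage, noise_sd,
                           ar_freq, ar_rho) {
  els <- montage$sites$electrode
  prs <- montage$pairs
  cp <- stats::setNames(rep(0, nrow(prs)), prs$pair)
  cp[names(coupling)] <- coupling
  budget <- vapply(els, function(e)
    sum(cp[prs$el1 == e | prs$el2 == e]), 0.0)
  if (any(budget > 1 + 1e-12)) {
    bad <- names(budget)[which.max(budget)]
    own <- prs$pair[(prs$el1 == bad | prs$el2 == bad) & cp[prs$pair] > 0]
    stop("infeasible coupling pattern: channel ", bad,
         " exceeds its unit variance budget (sum = ",
         round(max(budget), 3), ") across pairs ",
         paste(own, collapse = ", "))
  }
  active <- which(cp > 0)
  S <- if (length(active))
    vapply(active, function(k) ar2_source(n, rate, ar_freq, ar_rho),
           numeric(n)) else NULL
  X <- matrix(0, n, length(els))
  colnames(X) <- els
  for (i in seq_along(els)) {
    own <- which(cp > 0 & (prs$el1 == els[i] | prs$el2 == els[i]))
    xi <- if (length(own))
      S[, match(own, active), drop = FALSE] %*% sqrt(cp[own]) else 0
    X[, i] <- xi + sqrt(max(1 - budget[i], 0)) * stats::rnorm(n)
  }
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * ncol(X), 0, noise_sd),
                                    n, ncol(X))
  X
}

#' Simulate one multichannel recording with programmed pairwise coupling
#'
#' Channels are mixtures of independent resonant AR(2) latent sources plus
#' private white noise; each analyzed electrode pair owns a dedicated shared
#' source whose weight realizes the requested coupling (the source-level
#' channel correlation). Decoupling a pair therefore both decorrelates its
#' channels and shifts them toward broadband noise, which is what raises
#' their cross approximate entropy. The construction is feasible whenever
#' every channel's summed couplings stay within its unit variance budget;
#' infeasible patterns raise an error naming the channel and its pairs.
#' Unanalyzed filler channels (independent sources) can be appended to mimic
#' a full 16-channel session.
#'
#' @param coupling Named vector of couplings in \[0, 1\], names being pair
#'   labels of the montage (missing pairs couple at 0).
#' @param duration Recording length in seconds.
#' @param design A [trial_design()] (rate, noise and source settings).
#' @param montage A `"capen_montage"`.
#' @param seed Optional integer seed.
#' @return A recording: list with `data` (samples x channels matrix, channel
#'   names in the header), `rate`, `channels`.
#' @examples
#' rec <- simulate_recording(c("F3-F7" = 0.8), duration = 2,
#'                           design = trial_design(), seed = 1)
#' dim(rec$data)
#' @export
simulate_recording <- function(coupling = numeric(0), duration,
                               design = trial_design(),
                               montage = build_default_montage(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(coupling < 0 | coupling > 1))
    stop("couplings must lie in [0, 1]")
  unknown <- setdiff(names(coupling), montage$pairs$pair)
  if (length(unknown))
    stop("unknown pairs in coupling: ", paste(unknown, collapse = ", "))
  n <- round(duration * design$rate)
  X <- synth_channels(n, design$rate, coupling, montage, design$noise_sd,
                      design$ar_freq, design$ar_rho)
  if (design$n_extra_channels > 0L) {
    extras <- paste0("X", seq_len(design$n_extra_channels))
    E <- vapply(extras, function(e)
      sqrt(0.5) * ar2_source(n, design$rate, design$ar_freq, design$ar_rho) +
        sqrt(0.5) * stats::rnorm(n) + stats::rnorm(n, 0, design$noise_sd),
      numeric(n))
    X <- cbind(X, E)
  }
  list(data = X, rate = design$rate, channels = colnames(X))
}

# ---- subjects ------------------------------------------------------------

simulate_subjects <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- reference_stats()
  n <- design$n_per_arm
  arms <- c("tDCS", "control")
  out <- NULL
  for (arm in arms) {
    cv <- ref$covariates[ref$covariates$arm == arm, ]
    draw_cov <- function(v) {
      r <- cv[cv$variable == v, ]
      rtrunc_matched(n, r$mean, r$sd, r$lo, r$hi)
    }
    sex_p <- ref$categorical$sex[arm, 1L] / sum(ref$categorical$sex[arm, ])
    type_p <- ref$categorical$aphasia_type[arm, ] /
      sum(ref$categorical$aphasia_type[arm, ])
    sev_p <- ref$categorical$severity[arm, ] /
      sum(ref$categorical$severity[arm, ])
    d <- data.frame(
      id = character(n), arm = arm,
      age = draw_cov("age"),
      sex = ifelse(stats::runif(n) < sex_p, "male", "female"),
      education = draw_cov("education"),
      lesion_size = draw_cov("lesion_size"),
      onset_weeks = draw_cov("onset_weeks"),
      aphasia_type = sample(c("Global", "Mixed", "Broca"), n, TRUE, type_p),
      severity = sample(0:2, n, TRUE, sev_p),
      stringsAsFactors = FALSE)
    sc <- ref$scores
    for (st in unique(sc$subtest)) {
      b <- sc[sc$subtest == st & sc$arm == arm & sc$phase == "baseline", ]
      p <- sc[sc$subtest == st & sc$arm == arm & sc$phase == "post", ]
      zb <- stats::rnorm(n)
      zp <- design$rho_scores * zb +
        sqrt(1 - design$rho_scores^2) * stats::rnorm(n)
      mb <- latent_mean(b$mean, b$sd, b$lo, b$hi)
      mp <- latent_mean(p$mean, p$sd, p$lo, p$hi)
      d[[paste0(st, "_baseline")]] <-
        round(qtrunc(stats::pnorm(zb), mb, b$sd, b$lo, b$hi))
      d[[paste0(st, "_post")]] <-
        round(qtrunc(stats::pnorm(zp), mp, p$sd, p$lo, p$hi))
    }
    out <- rbind(out, d)
  }
  out$id <- sprintf("S%02d", seq_len(nrow(out)))
  out
}

#' Simulate a full two-arm, pre/post, rest/task trial dataset
#'
#' Generates, for a fixed seed, the complete synthetic dataset the pipeline
#' consumes: per-subject clinical covariates and speech scores (drawn from
#' mean-matched truncated normals and categorical frequencies of the
#' reference summaries) and one multichannel recording per subject,
#' timepoint (baseline/post) and condition (rest/task), with pairwise
#' source couplings set by the effect specification plus per-cell subject
#' jitter. Bit-identical for identical seeds.
#'
#' @param design A [trial_design()].
#' @param effects A [effect_spec()] / [null_effect_spec()].
#' @param seed Integer seed.
#' @param montage A `"capen_montage"`.
#' @return An object of class `"capen_trial"`: list with `subjects`
#'   (data.frame), `recordings` (nested list `[[id]][[timepoint]][[condition]]`),
#'   `couplings` (long data.frame of realized couplings), `design`,
#'   `effects`, `seed`.
#' @examples
#' d <- trial_design(n_per_arm = 2, duration_rest = 3, duration_task = 3)
#' tr <- simulate_trial(d, null_effect_spec(), seed = 1)
#' names(tr$recordings)
#' @export
simulate_trial <- function(design = trial_design(), effects, seed,
                           montage = build_default_montage()) {
  stopifnot(inherits(design, "capen_design"), inherits(effects, "capen_effects"))
  set.seed(seed)
  subjects <- simulate_subjects(design)
  recordings <- list()
  coup_rows <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$id[i]; arm <- subjects$arm[i]
    recordings[[id]] <- list()
    for (tp in c("baseline", "post")) {
      recordings[[id]][[tp]] <- list()
      for (cond in c("rest", "task")) {
        cp <- coupling_profile(effects, montage, arm, cond, tp)
        cp <- cp + stats::rnorm(length(cp), 0, effects$subject_sd)
        cp <- enforce_budget(pmin(pmax(cp, 0.005), 0.95), montage)
        dur <- if (cond == "rest") design$duration_rest else design$duration_task
        recordings[[id]][[tp]][[cond]] <-
          simulate_recording(cp, dur, design, montage)
        coup_rows[[length(coup_rows) + 1L]] <-
          data.frame(id = id, arm = arm, timepoint = tp, condition = cond,
                     pair = names(cp), coupling = unname(cp),
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(subjects = subjects, recordings = recordings,
                 couplings = do.call(rbind, coup_rows),
                 design = design, effects = effects, seed = seed,
                 montage = montage),
            class = "capen_trial")
}

#' @export
print.capen_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial: %d subjects (%d per arm), seed %s\n",
              nrow(x$subjects), x$design$n_per_arm, format(x$seed)))
  cat(sprintf("  recordings: 2 timepoints x 2 conditions at %g Hz (%gs rest, %gs task)\n",
              x$design$rate, x$design$duration_rest, x$design$duration_task))
  invisible(x)
}
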