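# Recording -> per-subject, per-pair connectivity table.

# zero-phase band-pass plus mains notch; Butterworth designs are cached per
# (rate, band, notch) since the pipeline filters thousands of short windows
.filter_cache <- new.env(parent = emptyenv())

get_filters <- function(rate, band, notch) {
  key <- paste(rate, band[1], band[2], notch, sep = "|")
  f <- .filter_cache[[key]]
  if (is.null(f)) {
    ny <- rate / 2
    f <- list(bp = signal::butter(4, band / ny, type = "pass"))
    if (!is.null(notch) && is.finite(notch) && notch < ny)
      f$bs <- signal::butter(2, c(notch - 2, notch + 2) / ny, type = "stop")
    .filter_cache[[key]] <- f
  }
  f
}

filter_signal <- function(x, rate, band = c(1, 45), notch = 50) {
  f <- get_filters(rate, band, notch)
  y <- signal::filtfilt(f$bp, x)
  if (!is.null(f$bs)) y <- signal::filtfilt(f$bs, y)
  y
}

#' Preprocess a recording for connectivity analysis
#'
#' Restricts the recording to the montage's analyzed channels (in montage
#' order; extra recorded channels are dropped), band-passes to the analysis
#' band and applies a zero-phase mains notch.
#'
#' @param rec Recording: list with `data` (samples x channels, named
#'   columns), `rate`, `channels`.
#' @param config A [capen_config()] (band, notch, montage).
#' @return The filtered recording, channels in montage order.
#' @export
preprocess <- function(rec, config = capen_config()) {
  els <- config$montage$sites$electrode
  missing <- setdiff(els, rec$channels)
  if (length(missing))
    stop("recording is missing analyzed channels: ",
         paste(missing, collapse = ", "))
  X <- rec$data[, els, drop = FALSE]
  X <- apply(X, 2L, filter_signal, rate = rec$rate, band = config$band,
             notch = config$notch)
  colnames(X) <- els
  list(data = X, rate = rec$rate, channels = els)
}

#' Cut a recording into epochs and reject amplitude artifacts
#'
#' Non-overlapping windows of `epoch_len` samples. An epoch is dropped for
#' all channels when any analyzed channel's peak absolute amplitude within
#' it exceeds `reject_sd` times that channel's whole-recording SD — a simple
#' surrogate for manual electromyography/electrical-noise screening.
#'
#' @param rec Preprocessed recording.
#' @param epoch_len Samples per epoch.
#' @param reject_sd Rejection threshold in channel SDs (`Inf` disables).
#' @return List of retained epochs (each a samples x channels matrix), with
#'   attributes `n_total` and `n_rejected`.
#' @export
epoch_and_reject <- function(rec, epoch_len, reject_sd = 5) {
  n <- nrow(rec$data)
  n_ep <- n %/% epoch_len
  if (n_ep < 1L)
    stop("recording shorter than one epoch (", epoch_len, " samples)")
  sds <- apply(rec$data, 2L, stats::sd)
  keep <- list()
  rejected <- 0L
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * epoch_len + 1L):(e * epoch_len)
    ep <- rec$data[idx, , drop = FALSE]
    peaks <- apply(abs(ep), 2L, max)
    if (is.finite(reject_sd) && any(peaks > reject_sd * sds)) {
      rejected <- rejected + 1L
    } else {
      keep[[length(keep) + 1L]] <- ep
    }
  }
  if (!length(keep))
    stop("all ", n_ep, " epochs rejected at ", reject_sd, " SD")
  attr(keep, "n_total") <- n_ep
  attr(keep, "n_rejected") <- rejected
  keep
}

#' Mean cross approximate entropy of an electrode pair over epochs
#'
#' @param epochs List of epochs from [epoch_and_reject()].
#' @param pair Pair label `"E1-E2"` or character vector of two electrodes.
#' @param params A [capen_params()].
#' @param min_epochs Minimum epochs for a valid value; below it the value is
#'   `NA` (missing cell).
#' @return List: `value` (mean C-ApEn, NA if missing), `n_epochs`,
#'   `n_floored`, `n_degenerate`.
#' @export
pair_capen <- function(epochs, pair, params = capen_params(), min_epochs = 1L) {
  els <- if (length(pair) == 2L) pair else strsplit(pair, "-", fixed = TRUE)[[1]]
  if (length(epochs) < min_epochs)
    return(list(value = NA_real_, n_epochs = length(epochs),
                n_floored = 0L, n_degenerate = 0L))
  vals <- numeric(length(epochs)); nf <- 0L; nd <- 0L
  for (i in seq_along(epochs)) {
    cv <- cross_apen(epochs[[i]][, els[1]], epochs[[i]][, els[2]], params)
    vals[i] <- cv$value
    nf <- nf + cv$n_floored
    nd <- nd + cv$degenerate
  }
  list(value = mean(vals), n_epochs = length(epochs),
       n_floored = nf, n_degenerate = nd)
}

#' Task-minus-rest difference value
#'
#' The condition contrast of the connectivity analysis: C-ApEn during the
#' repetition task minus C-ApEn at rest, per electrode pair. Positive values
#' mean task-elevated asynchrony. Missing inputs propagate to `NA` (never
#' silently 0).
#'
#' @param capen_task,capen_rest Per-pair C-ApEn values.
#' @return `capen_task - capen_rest`, `NA` if either is missing.
#' @examples
#' difference_value(0.12, 0.03)  # 0.09
#' @export
difference_value <- function(capen_task, capen_rest) {
  ifelse(is.na(capen_task) | is.na(capen_rest), NA_real_,
         capen_task - capen_rest)
}

#' Pre/post change of the difference value
#'
#' @param diff_post,diff_baseline Difference values at the two timepoints.
#' @return `diff_post - diff_baseline`, `NA` if either is missing.
#' @examples
#' change_score(0.12, 0.03)  # 0.09
#' @export
change_score <- function(diff_post, diff_baseline) {
  ifelse(is.na(diff_post) | is.na(diff_baseline), NA_real_,
         diff_post - diff_baseline)
}

# analyze one recording cell: returns per-pair values + epoch bookkeeping
analyze_recording <- function(rec, config) {
  pp <- preprocess(rec, config)
  eps <- epoch_and_reject(pp, config$params$epoch_len, config$reject_sd)
  prs <- config$montage$pairs
  vals <- vector("list", nrow(prs))
  for (k in seq_len(nrow(prs)))
    vals[[k]] <- pair_capen(eps, c(prs$el1[k], prs$el2[k]), config$params,
                            config$min_epochs)
  list(values = vapply(vals, `[[`, 0.0, "value"),
       n_epochs = length(eps),
       n_floored = sum(vapply(vals, `[[`, 0L, "n_floored")),
       n_degenerate = sum(vapply(vals, `[[`, 0L, "n_degenerate")))
}

#' Build the per-subject, per-pair connectivity table
#'
#' Runs the full signal pipeline (preprocess, epoch, reject, pair-wise
#' C-ApEn averaged over epochs) for every subject, timepoint and condition,
#' then forms task-minus-rest difference values per timepoint and the
#' post-minus-baseline change score per pair.
#'
#' @param trial A `"capen_trial"` (from [simulate_trial()] or [read_trial()]).
#' @param config A [capen_config()].
#' @return A data.frame of class `"connectivity_table"`, one row per subject
#'   x pair, with columns `subject, arm, pair, category,
#'   capen_rest_baseline, capen_task_baseline, diff_baseline,
#'   capen_rest_post, capen_task_post, diff_post, change, epochs_rest,
#'   epochs_task, flags`. Epoch counts are the minimum retained across the
#'   two timepoints; `flags` collects `floor`, `degenerate` and
#'   `missing_<condition>_<timepoint>` tokens.
#' @export
connectivity_table <- function(trial, config = capen_config()) {
  stopifnot(inherits(trial, "capen_trial"))
  prs <- config$montage$pairs
  rows <- vector("list", nrow(trial$subjects))
  for (i in seq_len(nrow(trial$subjects))) {
    id <- trial$subjects$id[i]
    cells <- list()
    flags_global <- character(0)
    n_ep <- list()
    for (tp in c("baseline", "post")) for (cond in c("rest", "task")) {
      rec <- trial$recordings[[id]][[tp]][[cond]]
      key <- paste(cond, tp, sep = "_")
      if (is.null(rec)) {
        cells[[key]] <- rep(NA_real_, nrow(prs))
        n_ep[[key]] <- 0L
        flags_global <- c(flags_global, paste0("missing_", key))
      } else {
        a <- tryCatch(analyze_recording(rec, config), error = function(e) e)
        if (inherits(a, "error")) {
          # e.g. every epoch rejected: mark the cell missing, keep going
          cells[[key]] <- rep(NA_real_, nrow(prs))
          n_ep[[key]] <- 0L
          flags_global <- c(flags_global, paste0("missing_", key),
                            "all_rejected")
        } else {
          cells[[key]] <- a$values
          n_ep[[key]] <- a$n_epochs
          if (a$n_floored > 0L) flags_global <- c(flags_global, "floor")
          if (a$n_degenerate > 0L) flags_global <- c(flags_global, "degenerate")
        }
      }
    }
    diff_b <- difference_value(cells$task_baseline, cells$rest_baseline)
    diff_p <- difference_value(cells$task_post, cells$rest_post)
    rows[[i]] <- data.frame(
      subject = id, arm = trial$subjects$arm[i],
      pair = prs$pair, category = prs$category,
      capen_rest_baseline = cells$rest_baseline,
      capen_task_baseline = cells$task_baseline,
      diff_baseline = diff_b,
      capen_rest_post = cells$rest_post,
      capen_task_post = cells$task_post,
      diff_post = diff_p,
      change = change_score(diff_p, diff_b),
      epochs_rest = min(n_ep$rest_baseline, n_ep$rest_post),
      epochs_task = min(n_ep$task_baseline, n_ep$task_post),
      flags = paste(unique(flags_global), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("connectivity_table", "data.frame")
  out
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat(sprintf("Connectivity table: %d subjects x %d pairs (%d rows)\n",
              length(unique(x$subject)), length(unique(x$pair)), nrow(x)))
  NextMethod()
}

#' @export
summary.connectivity_table <- function(object, ...) {
  agg <- stats::aggregate(cbind(diff_baseline, diff_post, change) ~ arm + category,
                          data = object, FUN = mean, na.rm = TRUE)
  cat("Mean difference values and change by arm and pair category:\n")
  print(agg, digits = 3)
  invisible(agg)
}
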