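#' Embedding parameters for (cross-)approximate entropy
#'
#' Bundle of the delay-embedding parameters used by [cross_apen()] and
#' [apen()]. Defaults: template length `m = 2`, unit delay, and 1000-sample
#' analysis windows (2 s at a 500 Hz sampling rate). The tolerance `r` is a
#' fraction of the standard deviation (series are standardized internally,
#' so `r_frac` lives on the unit-SD scale); the default is 0.5. The classic
#' single-series ApEn convention of 0.2 SD is too tight for cross
#' comparison, where no self-match is guaranteed: at r = 0.2 most templates
#' find zero cross matches at dimension m+1, the zero-match floor dominates
#' the statistic, and sensitivity to genuine coupling is lost. Set
#' `r_frac = 0.2` explicitly to reproduce the single-series convention.
#'
#' @param m Embedding dimension (template length), positive integer.
#' @param r_frac Match tolerance as a fraction of the (unit) standard
#'   deviation, in (0, 1).
#' @param lag Embedding delay in samples, positive integer.
#' @param epoch_len Samples per analysis window; must exceed
#'   `(m + 1) * lag + 10` so both embedding levels have a usable number of
#'   templates.
#' @return An object of class `"capen_params"`.
#' @examples
#' capen_params()
#' capen_params(m = 3, r_frac = 0.15)
#' @export
capen_params <- function(m = 2L, r_frac = 0.5, lag = 1L, epoch_len = 1000L) {
  m <- as.integer(m); lag <- as.integer(lag); epoch_len <- as.integer(epoch_len)
  stopifnot(m >= 1L, lag >= 1L, r_frac > 0, r_frac < 1)
  if (epoch_len <= (m + 1L) * lag + 10L)
    stop("epoch_len must exceed (m+1)*lag + 10 = ", (m + 1L) * lag + 10L)
  structure(list(m = m, r_frac = r_frac, lag = lag, epoch_len = epoch_len),
            class = "capen_params")
}

#' @export
print.capen_params <- function(x, ...) {
  cat(sprintf("Embedding parameters: m = %d, r = %.3g * SD, lag = %d, epoch_len = %d\n",
              x$m, x$r_frac, x$lag, x$epoch_len))
  invisible(x)
}

#' Standardize a signal epoch to zero mean and unit variance
#'
#' Entropy tolerances are expressed as fractions of the standard deviation;
#' standardizing each epoch first makes the tolerance scale-free and the
#' resulting statistic invariant to amplifier gain and offset.
#'
#' @param x Numeric vector of samples.
#' @return Numeric vector with mean 0 and SD 1.
#' @examples
#' standardize_epoch(c(1, 2, 3))
#' @export
standardize_epoch <- function(x) {
  if (anyNA(x)) stop("epoch contains missing values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate epoch: zero variance (constant signal)")
  (x - mean(x)) / s
}

#' Delay-embed a series into m-dimensional template vectors
#'
#' @param x Numeric vector (typically standardized).
#' @param m Embedding dimension.
#' @param lag Delay in samples.
#' @return A matrix with `length(x) - (m - 1) * lag` rows; row `i` is
#'   `x[i + (0:(m-1)) * lag]`.
#' @examples
#' delay_embed(1:4, m = 2, lag = 1)
#' @export
delay_embed <- function(x, m, lag = 1L) {
  m <- as.integer(m); lag <- as.integer(lag)
  n <- length(x) - (m - 1L) * lag
  if (n < 1L)
    stop("series too short for embedding: need length >= ", (m - 1L) * lag + 1L)
  out <- matrix(0, n, m)
  for (k in seq_len(m)) out[, k] <- x[seq_len(n) + (k - 1L) * lag]
  out
}

#' Fraction of targets within Chebyshev tolerance of a template
#'
#' The conditional match probability term of the approximate-entropy family:
#' the proportion of target templates whose maximum-coordinate distance from
#' the query template is at most `r`.
#'
#' @param template Numeric vector (one embedded template).
#' @param targets Matrix of embedded targets, one per row, same dimension.
#' @param r Tolerance (on the standardized scale).
#' @return A fraction in \[0, 1\].
#' @examples
#' match_fraction(c(0, 0), rbind(c(0, 0), c(1, 1)), r = 0.5)
#' @export
match_fraction <- function(template, targets, r) {
  if (!is.matrix(targets) || nrow(targets) == 0L) stop("empty target set")
  if (length(template) != ncol(targets))
    stop("template dimension does not match targets")
  d <- abs(sweep(targets, 2L, template))
  cheb <- if (ncol(targets) == 1L) d[, 1L] else apply(d, 1L, max)
  mean(cheb <= r)
}

#' Mean log conditional match probability (Phi statistic)
#'
#' Averages `log(match_fraction)` of every query template against the target
#' set. In cross comparison a template may match nothing; with `floor = TRUE`
#' a zero fraction is replaced by `1 / nrow(targets)` (the smallest observable
#' nonzero probability) and counted, because dropping such templates biases
#' the average asymmetrically.
#'
#' @param query Matrix of query templates (rows).
#' @param targets Matrix of target templates (rows), same dimension.
#' @param r Tolerance.
#' @param floor Apply the zero-match floor instead of erroring.
#' @return List with `phi` (mean log fraction) and `n_floored`.
#' @examples
#' phi_stat(rbind(c(0, 0)), rbind(c(0, 0)), r = 0.2)
#' @export
phi_stat <- function(query, targets, r, floor = TRUE) {
  if (!is.matrix(query) || nrow(query) == 0L) stop("empty query set")
  if (!is.matrix(targets) || nrow(targets) == 0L) stop("empty target set")
  if (ncol(query) != ncol(targets)) stop("query/target dimension mismatch")
  fr <- vapply(seq_len(nrow(query)),
               function(i) match_fraction(query[i, ], targets, r), 0.0)
  zero <- fr == 0
  if (any(zero) && !floor)
    stop("zero match fraction encountered with floor disabled (log undefined)")
  fr[zero] <- 1 / nrow(targets)
  list(phi = mean(log(fr)), n_floored = sum(zero))
}

capen_value <- function(value, n_templates_m, n_floored, degenerate = FALSE) {
  structure(list(value = value, n_templates_m = n_templates_m,
                 n_floored = n_floored, floor_triggered = n_floored > 0L,
                 degenerate = degenerate),
            class = "capen_value")
}

#' @export
print.capen_value <- function(x, ...) {
  cat(sprintf("C-ApEn = %.6f  (templates at m: %d%s%s)\n", x$value,
              x$n_templates_m,
              if (x$floor_triggered) sprintf(", %d floored", x$n_floored) else "",
              if (x$degenerate) ", degenerate input" else ""))
  invisible(x)
}

#' @export
as.numeric.capen_value <- function(x, ...) x$value

#' Cross approximate entropy between two signals
#'
#' Measures the asynchrony of two equal-length series by comparing
#' delay-embedded templates of one series against the other: with
#' `Phi^m(r)` the mean log fraction of dimension-`m` targets within Chebyshev
#' tolerance `r` of each query template, the directed statistic is
#' `Phi^m - Phi^(m+1)`, and the returned value is the average over both
#' comparison directions (electrode pairs are unordered, so an arbitrary
#' argument order should not change the result). Higher values indicate less
#' synchrony — less mutual predictability between the two series.
#'
#' Both series are standardized internally, so the statistic is invariant
#' under positive affine rescaling of either input, and `r = r_frac` is on
#' the unit-SD scale. A constant (zero-variance) series is perfectly
#' predictable; by convention the value for a pair involving a constant
#' epoch is 0, flagged as degenerate rather than an error, so batch
#' pipelines survive flat channels. Zero match counts (possible in cross
#' comparison, which has no guaranteed self-match) are floored at
#' `1/n_targets` and reported via `floor_triggered`.
#'
#' @param u,v Numeric vectors of equal length (one analysis epoch each).
#' @param params A [capen_params()] object.
#' @return A `"capen_value"`: list with `value` (nats), `n_templates_m`,
#'   `n_floored`, `floor_triggered`, `degenerate`.
#' @seealso [apen()] for the single-series special case.
#' @examples
#' set.seed(1)
#' x <- rnorm(300)
#' cross_apen(x, rnorm(300), capen_params(epoch_len = 300))
#' @export
cross_apen <- function(u, v, params = capen_params()) {
  stopifnot(inherits(params, "capen_params"))
  if (length(u) != length(v))
    stop("length mismatch: u has ", length(u), " samples, v has ", length(v))
  su <- stats::sd(u); sv <- stats::sd(v)
  if (anyNA(u) || anyNA(v)) stop("epoch contains missing values")
  if (!is.finite(su) || !is.finite(sv)) stop("non-finite samples in epoch")
  if (su == 0 || sv == 0) {
    # constant-series convention: perfectly predictable, value 0
    return(capen_value(0, 0L, 0L, degenerate = TRUE))
  }
  us <- standardize_epoch(u); vs <- standardize_epoch(v)
  k <- .capen_kernel(us, vs, params$m, params$lag, params$r_frac, TRUE)
  val <- 0.5 * ((k$phi_m_uv - k$phi_m1_uv) + (k$phi_m_vu - k$phi_m1_vu))
  capen_value(val, k$n_templates_m, k$n_floored)
}

#' Approximate entropy of a single signal
#'
#' The self-comparison special case: `apen(u) == cross_apen(u, u)` exactly
#' (self-matches included at both embedding levels).
#'
#' @inheritParams cross_apen
#' @return A `"capen_value"`.
#' @examples
#' set.seed(1)
#' apen(rnorm(300), capen_params(epoch_len = 300))
#' @export
apen <- function(u, params = capen_params()) cross_apen(u, u, params)
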