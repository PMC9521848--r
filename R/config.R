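#' Analysis run configuration
#'
#' Bundles every tunable of the connectivity pipeline and statistics layer
#' so a run is reproducible from its serialized configuration alone.
#'
#' @param params Embedding parameters, see [capen_params()].
#' @param band Analysis pass band in Hz (default 1-45 Hz).
#' @param notch Mains notch frequency in Hz (50 in most of Asia/Europe);
#'   `NA` disables the notch.
#' @param reject_sd Artifact rejection threshold: an epoch is dropped when
#'   any analyzed channel's peak absolute amplitude exceeds `reject_sd`
#'   times that channel's whole-recording SD. `Inf` disables rejection.
#' @param min_epochs Minimum retained epochs per condition for a valid cell;
#'   below this the cell is marked missing (default 10).
#' @param alpha Two-tailed significance level of the statistics layer.
#' @param screen_p Univariate retention threshold of the regression screen.
#' @param adjust P-value adjustment across the 21 pairs: `"none"` (default,
#'   matching the emulated trial) or `"BH"`.
#' @param montage A `"capen_montage"` (default the 10-site speech montage).
#' @return An object of class `"capen_config"`.
#' @examples
#' capen_config()
#' @export
capen_config <- function(params = capen_params(), band = c(1, 45), notch = 50,
                         reject_sd = 5, min_epochs = 10L, alpha = 0.05,
                         screen_p = 0.2, adjust = c("none", "BH"),
                         montage = build_default_montage()) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(params, "capen_params"), length(band) == 2L,
            band[1] > 0, band[2] > band[1], reject_sd > 0, min_epochs >= 1)
  structure(list(params = params, band = band, notch = notch,
                 reject_sd = reject_sd, min_epochs = as.integer(min_epochs),
                 alpha = alpha, screen_p = screen_p, adjust = adjust,
                 montage = montage),
            class = "capen_config")
}

#' @export
print.capen_config <- function(x, ...) {
  cat("capen run configuration\n")
  print(x$params)
  cat(sprintf("  band %g-%g Hz, notch %s Hz, reject at %g SD, min %d epochs\n",
              x$band[1], x$band[2], x$notch, x$reject_sd, x$min_epochs))
  cat(sprintf("  alpha = %g, screening p < %g, adjustment: %s\n",
              x$alpha, x$screen_p, x$adjust))
  invisible(x)
}

#' Serialize / restore a run configuration
#'
#' Configurations are written as YAML so that every output directory can
#' carry a verbatim copy of the settings that produced it. The montage is
#' stored as its electrode -> (region, hemisphere) mapping plus pair list,
#' so alternative networks round-trip too.
#'
#' @param config A `"capen_config"`.
#' @param path File to write to / read from.
#' @return `read_config()` returns the restored `"capen_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "capen_config"))
  x <- list(
    params = unclass(config$params),
    band = config$band, notch = config$notch,
    reject_sd = config$reject_sd, min_epochs = config$min_epochs,
    alpha = config$alpha, screen_p = config$screen_p, adjust = config$adjust,
    montage = list(sites = as.list(config$montage$sites),
                   pairs = as.list(config$montage$pairs)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  montage <- structure(
    list(sites = as.data.frame(x$montage$sites, stringsAsFactors = FALSE),
         pairs = as.data.frame(x$montage$pairs, stringsAsFactors = FALSE)),
    class = "capen_montage")
  capen_config(params = do.call(capen_params, x$params),
               band = as.numeric(x$band), notch = x$notch,
               reject_sd = x$reject_sd, min_epochs = x$min_epochs,
               alpha = x$alpha, screen_p = x$screen_p, adjust = x$adjust,
               montage = montage)
}
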