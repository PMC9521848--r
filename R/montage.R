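#' The 10-site speech-articulation montage
#'
#' Ten electrodes of the international 10-20 system covering five bilateral
#' nodes of the cortical speech-articulation network: DLPFC at F3/F4, IFG at
#' F7/F8 (F7/F8 placed over the inferior frontal gyri, at the crossing of
#' T3-Fz with F7-Cz and its right mirror — metadata only, computation is
#' unaffected), M1 at C3/C4, SPT at T5/T6, IPL at P3/P4. Recordings may carry
#' extra channels (a standard session records 16); only these ten are
#' analyzed.
#'
#' @return `build_default_montage()`: a list of class `"capen_montage"` with
#'   `sites` (data.frame: electrode, region, hemisphere) and `pairs`
#'   (data.frame: pair, el1, el2, category), where category is one of
#'   `"left-intra"`, `"right-intra"`, `"interhemispheric"`. The 21 pairs and
#'   their ordering are fixed: 8 left intra-hemispheric, 8 right
#'   intra-hemispheric (the left set mirrored), 5 homologous
#'   inter-hemispheric.
#' @examples
#' m <- build_default_montage()
#' m$sites
#' nrow(m$pairs)  # 21
#' @export
build_default_montage <- function() {
  sites <- data.frame(
    electrode  = c("F3", "F4", "F7", "F8", "C3", "C4", "T5", "T6", "P3", "P4"),
    region     = rep(c("DLPFC", "IFG", "M1", "SPT", "IPL"), each = 2L),
    hemisphere = rep(c("left", "right"), 5L),
    stringsAsFactors = FALSE)

  left <- rbind(
    c("F3", "F7"), c("F3", "P3"), c("F7", "C3"), c("P3", "F7"),
    c("P3", "C3"), c("T5", "C3"), c("T5", "P3"), c("T5", "F7"))
  mirror <- c(F3 = "F4", F7 = "F8", C3 = "C4", T5 = "T6", P3 = "P4")
  right <- matrix(mirror[left], ncol = 2L)
  # homologous block in fixed report order: F3-F4, F7-F8, C3-C4, P3-P4, T5-T6
  inter <- rbind(c("F3", "F4"), c("F7", "F8"), c("C3", "C4"),
                 c("P3", "P4"), c("T5", "T6"))
  els <- rbind(left, right, inter)
  pairs <- data.frame(
    pair = paste(els[, 1L], els[, 2L], sep = "-"),
    el1 = els[, 1L], el2 = els[, 2L],
    category = rep(c("left-intra", "right-intra", "interhemispheric"),
                   c(8L, 8L, 5L)),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(pairs$pair), all(pairs$el1 != pairs$el2))
  structure(list(sites = sites, pairs = pairs), class = "capen_montage")
}

#' @export
print.capen_montage <- function(x, ...) {
  cat("Speech-articulation montage:", nrow(x$sites), "sites,",
      nrow(x$pairs), "pairs\n")
  cat("  regions:", paste(unique(x$sites$region), collapse = ", "), "\n")
  cat("  pair categories:",
      paste(sprintf("%s (%d)", names(table(x$pairs$category)),
                    table(x$pairs$category)), collapse = ", "), "\n")
  invisible(x)
}

#' Cortical region and hemisphere of an electrode
#'
#' @param electrode A 10-20 electrode label present in the montage.
#' @param montage A `"capen_montage"`.
#' @return Named character vector with `region` and `hemisphere`.
#' @examples
#' region_of("C3")  # M1, left
#' @export
region_of <- function(electrode, montage = build_default_montage()) {
  i <- match(electrode, montage$sites$electrode)
  if (is.na(i)) stop("electrode not in montage: ", electrode)
  c(region = montage$sites$region[i],
    hemisphere = montage$sites$hemisphere[i])
}

#' Electrode pairs of one hemisphere category
#'
#' @param category One of `"left-intra"`, `"right-intra"`,
#'   `"interhemispheric"`.
#' @param montage A `"capen_montage"`.
#' @return The subset of the pair table, in stable (report) order.
#' @examples
#' pairs_for("interhemispheric")$pair
#' @export
pairs_for <- function(category, montage = build_default_montage()) {
  ok <- c("left-intra", "right-intra", "interhemispheric")
  if (!category %in% ok)
    stop("unknown category '", category, "'; expected one of: ",
         paste(ok, collapse = ", "))
  montage$pairs[montage$pairs$category == category, , drop = FALSE]
}
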