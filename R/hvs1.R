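#' HVS1 sequence-quality metrics
#'
#' Control-region (HVS1) datasets are screened for systematic sequencing
#' artefacts by splitting observed transitions into "speedy" sites (known
#' mutational hotspots, where recurrent hits are expected) and "weighty"
#' sites (slowly mutating positions, where an excess of hits signals
#' error), and pooling transversions with indels, which are rare genuine
#' events. The ratio of weighty transitions to transversions-plus-indels
#' (the WTTI ratio) is a scale-free quality indicator: published
#' good-quality datasets fall around 2.3-4.8, while artefact-ridden sets
#' reach values an order of magnitude higher.
#'
#' @param variants Data frame with columns `position`, `ref`, `alt` and
#'   optionally `haplotype` and `kind` (`kind` is derived from the bases
#'   when absent). One row per variant occurrence.
#' @param site_class_table Data frame with columns `position` and `class`
#'   (`"speedy"` or `"weighty"`) covering every HVS1 position in the
#'   window; see [synthetic_site_classes()] for a stand-in table and use
#'   the published hotspot classification for real data.
#' @param window Inclusive 1-based analysis window; variants outside it
#'   are dropped. Default 16090-16383.
#' @param distinct If `TRUE`, count distinct (position, ref, alt) variants
#'   instead of per-occurrence rows. Default counts occurrences.
#' @return List of class `quality_counts` with `speedy_transitions`,
#'   `weighty_transitions`, `tv_indels`, `n_in_window` and `wtti`.
#' @export
classify_hvs1_variants <- function(variants, site_class_table,
                                   window = c(16090L, 16383L),
                                   distinct = FALSE) {
  stopifnot(all(c("position", "ref", "alt") %in% names(variants)),
            all(c("position", "class") %in% names(site_class_table)),
            all(site_class_table$class %in% c("speedy", "weighty")))
  if (anyDuplicated(site_class_table$position))
    stop("site class table assigns multiple classes to one position")
  v <- variants[variants$position >= window[1] &
                variants$position <= window[2], , drop = FALSE]
  if (distinct)
    v <- unique(v[, c("position", "ref", "alt"), drop = FALSE])
  if (nrow(v) == 0L) {
    out <- list(speedy_transitions = 0L, weighty_transitions = 0L,
                tv_indels = 0L, n_in_window = 0L, wtti = NA_real_)
    class(out) <- "quality_counts"
    return(out)
  }
  kind <- if (!is.null(v$kind)) v$kind else substitution_kind(v$ref, v$alt)
  cls <- site_class_table$class[match(v$position, site_class_table$position)]
  ti <- kind == "transition"
  if (any(ti & is.na(cls))) {
    stop("transition at unclassified HVS1 position(s): ",
         paste(utils::head(sort(unique(v$position[ti & is.na(cls)])), 5),
               collapse = ", "))
  }
  counts <- list(
    speedy_transitions = sum(ti & cls == "speedy"),
    weighty_transitions = sum(ti & cls == "weighty"),
    tv_indels = sum(!ti),
    n_in_window = nrow(v)
  )
  counts$wtti <- wtti_ratio(counts)
  class(counts) <- "quality_counts"
  counts
}

#' @export
print.quality_counts <- function(x, ...) {
  cat(sprintf(
    "HVS1 quality: %d speedy, %d weighty transitions, %d tv+indels; WTTI = %s\n",
    x$speedy_transitions, x$weighty_transitions, x$tv_indels,
    format(x$wtti, digits = 3)))
  invisible(x)
}

#' WTTI ratio
#'
#' Weighty transitions over transversions-plus-indels. Zero weighty
#' transitions give 0; a positive weighty count with no transversions or
#' indels gives `Inf` (the denominator-free, formally perfect-quality
#' limit).
#'
#' @param counts A `quality_counts` object, or a list/vector with
#'   `weighty_transitions` and `tv_indels`.
#' @return The ratio (possibly `Inf`).
#' @examples
#' wtti_ratio(list(weighty_transitions = 75, tv_indels = 25))  # 3
#' @export
wtti_ratio <- function(counts) {
  w <- counts[["weighty_transitions"]]
  tvi <- counts[["tv_indels"]]
  if (tvi < 0 || w < 0) stop("counts must be non-negative")
  if (tvi == 0) {
    if (w == 0) return(NA_real_)
    return(Inf)
  }
  w / tvi
}

#' Synthetic HVS1 site-class table
#'
#' A deterministic stand-in for the published speedy/weighty hotspot
#' classification of HVS1 positions, for testing and simulation only: it
#' does not reproduce the empirically determined hotspot list, it merely
#' partitions the window with a realistic speedy fraction. Supply the
#' published table for real analyses.
#'
#' @param range Positions covered (default the full HVS1 span 16024-16383).
#' @param speedy_fraction Fraction of positions labelled speedy.
#' @return Data frame with columns `position` and `class`.
#' @export
synthetic_site_classes <- function(range = c(16024L, 16383L),
                                   speedy_fraction = 0.8) {
  pos <- seq.int(range[1], range[2])
  period <- max(2L, round(1 / (1 - speedy_fraction)))
  cls <- ifelse(pos %% period == 0L, "weighty", "speedy")
  data.frame(position = pos, class = cls, stringsAsFactors = FALSE)
}
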