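#' Molecular-clock calibrations
#'
#' A clock calibration carries a per-genome synonymous mutation rate
#' (mutations per lineage per year). The canonical way to obtain one is to
#' anchor it on a reference clade with a known (or previously estimated)
#' age: `rate = rho_ref / age_ref`. Literature per-site rates are accepted
#' only together with an explicit synonymous-site count that converts them
#' to the per-genome scale.
#'
#' @param rate Synonymous mutations per lineage per year (> 0).
#' @param source Short description of where the rate comes from.
#' @param site_count Optional effective synonymous site count; when given,
#'   a `per_site_rate = rate / site_count` is attached.
#' @return Object of class `clock_calibration`.
#' @export
clock_calibration <- function(rate, source = "fixed_literature",
                              site_count = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  structure(list(rate = rate, source = source,
                 per_site_rate = if (!is.null(site_count)) rate / site_count,
                 site_count = site_count),
            class = "clock_calibration")
}

#' @export
print.clock_calibration <- function(x, ...) {
  cat(sprintf("clock calibration (%s): %.4g syn mutations/lineage/year\n",
              x$source, x$rate))
  if (!is.null(x$per_site_rate))
    cat(sprintf("  per-site: %.4g /site/year over %.0f synonymous sites\n",
                x$per_site_rate, x$site_count))
  invisible(x)
}

#' The rho statistic
#'
#' The mean number of (synonymous) mutations separating a clade's tips
#' from the clade MRCA — the founder statistic of rho dating.
#'
#' @param profile A [distance_profile()] restricted to the clade, or a
#'   plain numeric vector of tip-to-MRCA counts.
#' @return Arithmetic mean distance.
#' @export
rho <- function(profile) {
  x <- if (is.data.frame(profile)) profile$count else profile
  if (length(x) < 1L) stop("need at least one tip")
  mean(x)
}

#' Anchor a clock on a reference clade
#'
#' @param rho_ref Mean tip-to-MRCA distance of the reference clade (> 0).
#' @param age_ref Age of the reference MRCA in years (> 0).
#' @param source Label recorded on the calibration.
#' @param site_count Optional synonymous-site count for a per-site form.
#' @return A [clock_calibration()] with `rate = rho_ref / age_ref`.
#' @examples
#' cal <- anchor_rate(8.26, 54500)  # anchored on the R super-haplogroup
#' date_clade(6.71, cal)$age        # ~44,270 years
#' @export
anchor_rate <- function(rho_ref, age_ref, source = "anchored",
                        site_count = NULL) {
  if (rho_ref <= 0 || age_ref <= 0)
    stop("rho_ref and age_ref must be positive")
  clock_calibration(rho_ref / age_ref, source = source,
                    site_count = site_count)
}

#' Recalibrate the clock for a slowly mutating clade
#'
#' For a clade whose lineage-wide mutation rate differs from the rest of
#' the phylogeny (e.g. a globally slowed clade), a clade-specific rate is
#' estimated from the mean distance between the clade's tips and the
#' super-lineage MRCA, divided by the independently estimated age of that
#' super-lineage MRCA. Dating the clade's sub-haplogroups with this rate
#' removes the bias a shared clock would introduce.
#'
#' @param clade_mean_from_superroot Mean distance from clade tips to the
#'   super-lineage MRCA (> 0).
#' @param superroot_age Age in years of the super-lineage MRCA (> 0).
#' @param source Label recorded on the calibration.
#' @param site_count Optional synonymous-site count for a per-site form.
#' @return A [clock_calibration()].
#' @examples
#' cal <- recalibrate_clade_rate(3.89, 54500)  # a slowed clade's own clock
#' date_clade(2.89, cal)$age                   # ~40,490 years
#' @export
recalibrate_clade_rate <- function(clade_mean_from_superroot, superroot_age,
                                   source = "recalibrated",
                                   site_count = NULL) {
  if (clade_mean_from_superroot <= 0 || superroot_age <= 0)
    stop("inputs must be positive")
  clock_calibration(clade_mean_from_superroot / superroot_age,
                    source = source, site_count = site_count)
}

#' Date a clade from its rho statistic
#'
#' `age = rho / rate`. The reported interval is the star-phylogeny
#' heuristic of [rho_sigma_heuristic()] when `n_tips` is supplied; it is a
#' heuristic, not the tree-topology-dependent error of the original
#' founder-analysis method.
#'
#' @param rho_value Mean tip-to-MRCA distance (>= 0).
#' @param calibration A [clock_calibration()].
#' @param clade Optional clade label.
#' @param n_tips Optional number of tips (enables the interval heuristic).
#' @return Data frame of class `dating_result` with columns `clade`, `n`,
#'   `rho`, `age` (years), `age_ky`, `interval` (years or NA),
#'   `interval_ky`, `calibration`.
#' @export
date_clade <- function(rho_value, calibration, clade = NA_character_,
                       n_tips = NA_integer_) {
  stopifnot(inherits(calibration, "clock_calibration"), rho_value >= 0)
  age <- rho_value / calibration$rate
  interval <- if (!is.na(n_tips))
    rho_sigma_heuristic(rho_value, n_tips, calibration) else NA_real_
  out <- data.frame(clade = clade, n = n_tips, rho = rho_value, age = age,
                    age_ky = round(age / 1000, 2),
                    interval = interval,
                    interval_ky = round(interval / 1000, 2),
                    calibration = calibration$source,
                    stringsAsFactors = FALSE)
  class(out) <- c("dating_result", "data.frame")
  out
}

#' Star-phylogeny heuristic for the rho dating error
#'
#' Under a star phylogeny the n tip-to-MRCA counts are independent
#' Poisson, so `Var(rho_hat) = rho / n` and the age standard error is
#' `sqrt(rho / n) / rate`. On structured trees shared internal branches
#' inflate the true variance; the exact founder-analysis variance
#' `sum_b (n_b / n)^2 * m_b` (over branches b with `n_b` subtended tips
#' and `m_b` mutations) is available via `rho_sigma_exact()` when branch
#' structure is supplied.
#'
#' @param rho_value Mean tip-to-MRCA distance.
#' @param n_tips Number of tips (>= 1).
#' @param calibration A [clock_calibration()].
#' @return Heuristic one-sigma age error in years.
#' @export
rho_sigma_heuristic <- function(rho_value, n_tips, calibration) {
  stopifnot(n_tips >= 1)
  sqrt(rho_value / n_tips) / calibration$rate
}

#' Exact founder-analysis variance of rho on a known tree
#'
#' @param tree A `haplotree`.
#' @param ancestor Clade MRCA (node id or clade label).
#' @param class_filter,annotation,reference Passed to the branch counts,
#'   see [distance_profile()].
#' @return `sqrt(sum_b (n_b/n)^2 m_b)`, the standard error of rho in
#'   mutation units (divide by the calibration rate for years).
#' @export
rho_sigma_exact <- function(tree, ancestor, class_filter = "synonymous",
                            annotation = NULL, reference = NULL) {
  ancestor <- resolve_node(tree, ancestor)
  tips <- subtree_tips(tree, ancestor)
  n <- length(tips)
  bc <- branch_filter_counts(tree, class_filter, annotation, reference)
  nodes <- setdiff(subtree_tips_closure(tree, ancestor), ancestor)
  v <- sum(vapply(nodes, function(b) {
    nb <- length(subtree_tips(tree, b))
    (nb / n)^2 * bc[[b]]
  }, double(1)))
  sqrt(v)
}

#' Dating table over a nested clade partition
#'
#' Produces one dated row per clade, mirroring the layout of a haplogroup
#' dating table: clade, n, rho, age and heuristic interval. Clades whose
#' synonymous/non-synonymous ratio is inverted (see [selection_flag()])
#' are reported as `"ND"` — their synonymous distances under-count real
#' mutation events, so no date is defensible.
#'
#' @param tree A `haplotree` with clade labels.
#' @param clades Character vector of clade labels (or node ids) to date.
#' @param calibrations Either one [clock_calibration()] applied to all
#'   clades or a named list keyed by clade label.
#' @param selection_flags Character vector of clade labels to flag as ND.
#' @param class_filter,annotation,reference,exclude_positions Passed to
#'   [distance_profile()].
#' @return Data frame with columns `clade`, `n`, `rho`, `age_ky`,
#'   `interval_ky`, `calibration`, `flag`.
#' @export
dating_table <- function(tree, clades, calibrations,
                         selection_flags = character(0),
                         class_filter = "synonymous",
                         annotation = NULL, reference = NULL,
                         exclude_positions = integer(0)) {
  one_cal <- inherits(calibrations, "clock_calibration")
  rows <- lapply(clades, function(cl) {
    prof <- distance_profile(tree, cl, class_filter,
                             annotation = annotation, reference = reference,
                             exclude_positions = exclude_positions)
    r <- rho(prof)
    n <- nrow(prof)
    cal <- if (one_cal) calibrations else calibrations[[cl]]
    if (is.null(cal)) stop("no calibration supplied for clade ", cl)
    if (cl %in% selection_flags) {
      data.frame(clade = cl, n = n, rho = r, age_ky = NA_real_,
                 interval_ky = NA_real_, calibration = cal$source,
                 flag = "ND", stringsAsFactors = FALSE)
    } else {
      d <- date_clade(r, cal, clade = cl, n_tips = n)
      data.frame(clade = cl, n = n, rho = r, age_ky = d$age_ky,
                 interval_ky = d$interval_ky, calibration = cal$source,
                 flag = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
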