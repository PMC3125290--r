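#' Kolmogorov-Smirnov test of Poisson mutation accumulation
#'
#' Under a constant molecular clock, the number of mutations a lineage
#' accumulates in a fixed time is Poisson. This test compares the
#' empirical distribution of per-haplotype mutation counts against a
#' Poisson law with the rate estimated by the sample mean. The default
#' procedure evaluates the classical sup-gap statistic
#' `d = sup |ECDF - CDF|` at the integer support points and converts it to
#' a p value with the asymptotic Kolmogorov distribution; because the rate
#' is estimated from the same data and the distribution is discrete, this
#' p value is conservative. A parametric-bootstrap variant
#' (`method = "bootstrap"`) re-simulates cohorts from the fitted Poisson,
#' re-estimating the rate each time, and is exact up to Monte-Carlo error.
#'
#' @param counts Non-negative integer mutation counts, `n >= 8`.
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param B Bootstrap replicates when `method = "bootstrap"`.
#' @return List with elements `d`, `p.value`, `lambda`, `n` and `method`.
#' @export
poisson_ks_test <- function(counts, method = c("asymptotic", "bootstrap"),
                            B = 2000L) {
  method <- match.arg(method)
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  if (n < 8L) stop("need at least 8 counts")
  lambda <- mean(counts)
  if (lambda == 0) stop("all counts are zero; Poisson rate degenerate")
  d <- ks_poisson_stat(counts, lambda)
  p <- switch(method,
    asymptotic = ks_asymptotic_p(d, n),
    bootstrap = {
      ref <- vapply(seq_len(B), function(i) {
        x <- stats::rpois(n, lambda)
        if (mean(x) == 0) return(0)
        ks_poisson_stat(x, mean(x))
      }, double(1))
      (1 + sum(ref >= d)) / (B + 1)
    })
  list(d = d, p.value = p, lambda = lambda, n = n, method = method)
}

# sup over the integer support of |ECDF(k) - F(k)| (both CDFs are step
# functions jumping only at integers, so the sup is attained there).
ks_poisson_stat <- function(counts, lambda) {
  ks <- 0:max(max(counts), stats::qpois(1 - 1e-12, lambda))
  ecdf_k <- vapply(ks, function(k) mean(counts <= k), double(1))
  max(abs(ecdf_k - stats::ppois(ks, lambda)))
}

# Asymptotic Kolmogorov tail probability Q(sqrt(n) d).
ks_asymptotic_p <- function(d, n) {
  t <- sqrt(n) * d
  if (t < 0.2) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(1, max(0, p))
}

#' Per-group summaries of a distance profile
#'
#' @param profile A [distance_profile()] (or any data frame with `tip` and
#'   `count` columns).
#' @param partition Named character vector mapping tips to group labels;
#'   tips missing from the partition are dropped with a warning.
#' @param global_label If non-NULL, adds a composite group of this name
#'   formed by the union of the groups in `global_groups`.
#' @param global_groups Groups pooled into the composite.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summaries <- function(profile, partition, global_label = NULL,
                            global_groups = NULL) {
  grp <- partition[profile$tip]
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " tip(s) missing from partition excluded")
    profile <- profile[!is.na(grp), , drop = FALSE]
    grp <- grp[!is.na(grp)]
  }
  summarize <- function(x, label) {
    data.frame(group = label, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }
  parts <- lapply(split(profile$count, grp), function(x) x)
  empty <- names(parts)[vapply(parts, length, 0L) == 0L]
  if (length(empty)) warning("empty group(s) excluded: ",
                             paste(empty, collapse = ", "))
  out <- do.call(rbind, Map(summarize, parts[lengths(parts) > 0], names(parts)[lengths(parts) > 0]))
  if (!is.null(global_label)) {
    if (is.null(global_groups)) stop("global_groups required with global_label")
    pooled <- profile$count[grp %in% global_groups]
    out <- rbind(out, summarize(pooled, global_label))
  }
  row.names(out) <- NULL
  out
}

#' Percentage of non-synonymous mutations
#'
#' From the mean total (synonymous + nonsynonymous) and mean synonymous
#' distances of a clade, the percentage of accumulated mutations that are
#' nonsynonymous: `100 * (total - syn) / total`. An inverted ratio (above
#' ~50% against a ~28% background) is the selection signature that makes
#' synonymous-distance dating of a clade unreliable.
#'
#' @param total_mean Mean count over all coding mutations (> 0).
#' @param syn_mean Mean synonymous count, `0 <= syn_mean <= total_mean`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' nonsyn_percentage(10.70, 4.28)  # 60
#' @export
nonsyn_percentage <- function(total_mean, syn_mean) {
  if (any(total_mean <= 0)) stop("total_mean must be positive")
  if (any(syn_mean < 0) || any(syn_mean > total_mean))
    stop("need 0 <= syn_mean <= total_mean")
  100 * (total_mean - syn_mean) / total_mean
}

#' Welch two-sample comparison of group mean distances
#'
#' @param a,b Numeric count vectors, each of length >= 2.
#' @return List with `statistic` (t), `p.value`, `df` and the group means.
#' @export
compare_group_means <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p.value = 1, df = NA_real_,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("both groups have zero variance but different means; ",
         "t statistic undefined")
  }
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Chi-square test of distance histograms across groups
#'
#' Builds a group-by-distance contingency table with unit-width bins from
#' 0 upward, pools the right tail until every expected cell count is at
#' least `min_expected`, and applies the contingency chi-square test (no
#' continuity correction). The degrees of freedom are data-dependent
#' through the pooling rule.
#'
#' @param counts_by_group Named list of non-negative integer count vectors,
#'   one per group (>= 2 groups).
#' @param min_expected Minimum expected count per cell after tail pooling.
#' @return List with `chi2`, `df`, `p.value` and the pooled `table`.
#' @export
chi2_histogram_test <- function(counts_by_group, min_expected = 1) {
  if (length(counts_by_group) < 2L)
    stop("need at least two groups")
  kmax <- max(unlist(counts_by_group))
  tab <- t(vapply(counts_by_group, function(x) {
    tabulate(factor(x, levels = 0:kmax), nbins = kmax + 1L)
  }, integer(kmax + 1L)))
  colnames(tab) <- as.character(0:kmax)
  # pool the right tail until all expected counts reach min_expected
  expected <- function(m) outer(rowSums(m), colSums(m)) / sum(m)
  while (ncol(tab) > 2L && min(expected(tab)) < min_expected) {
    nc <- ncol(tab)
    tab[, nc - 1L] <- tab[, nc - 1L] + tab[, nc]
    colnames(tab)[nc - 1L] <- paste0(">=", colnames(tab)[nc - 1L])
    tab <- tab[, -nc, drop = FALSE]
  }
  # drop all-zero leading/interior columns contribute 0; chisq.test handles
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  identical_hist <- {
    p <- sweep(tab, 1, rowSums(tab), "/")
    all(abs(sweep(p, 2, p[1, ], "-")) < 1e-12)
  }
  if (identical_hist) {
    return(list(chi2 = 0, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
                p.value = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab)
}

#' Paired test of per-set rate differences between two groups
#'
#' Given per-replicate-set mean distances (e.g. posterior mean root-to-tip
#' distances on independently re-sampled cohorts), tests whether the focal
#' group's mean differs from the reference group's by a paired t test on
#' the per-set differences. Both the 95% confidence interval and the
#' standard error of the mean difference are reported.
#'
#' @param focal,reference Numeric vectors of per-set group means, equal
#'   length >= 2, aligned by set.
#' @return List with `statistic`, `df`, `p.value`, `mean_difference`,
#'   `se`, `conf.int` (95%).
#' @export
paired_rate_test <- function(focal, reference) {
  stopifnot(length(focal) == length(reference))
  if (length(focal) < 2L) stop("need at least two replicate sets")
  d <- focal - reference
  if (stats::var(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, df = length(d) - 1L, p.value = 1,
                  mean_difference = 0, se = 0, conf.int = c(0, 0)))
    # constant nonzero offset: zero variance, t diverges
    return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                p.value = 0, mean_difference = mean(d), se = 0,
                conf.int = c(mean(d), mean(d))))
  }
  tt <- stats::t.test(focal, reference, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = mean(d),
       se = stats::sd(d) / sqrt(length(d)),
       conf.int = as.numeric(tt$conf.int))
}
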