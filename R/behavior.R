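# Scratch-bout analytics: binned counts, 45-min totals, the pre-injection
# duration reference limit, and cohort comparisons.

#' Bin bout counts over the observation window
#'
#' Bouts are assigned by onset to half-open bins `[start, end)`; a bout at
#' t = 0 falls in the first post-injection bin. Per-bin duration quantiles
#' (box-and-whisker statistics: 10/25/50/75/90%) are attached.
#'
#' @param bouts data.frame (onset_s, duration_s).
#' @param bin bin width, s (default 300 = 5 min).
#' @param window observation window, s, injection at 0.
#' @return data.frame per bin: start_s, end_s, count, duration quantiles.
#' @export
bin_bout_counts <- function(bouts, bin = 300, window = c(-900, 2700)) {
  starts <- seq(window[1], window[2] - bin, by = bin)
  idx <- findInterval(bouts$onset_s, c(starts, window[2]),
                      rightmost.closed = FALSE)
  idx[bouts$onset_s >= window[2] | bouts$onset_s < window[1]] <- NA
  out <- data.frame(start_s = starts, end_s = starts + bin,
                    count = tabulate(idx, nbins = length(starts)))
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  qmat <- matrix(NA_real_, length(starts), length(qs),
                 dimnames = list(NULL, paste0("dur_q", qs * 100)))
  for (b in seq_along(starts)) {
    d <- bouts$duration_s[!is.na(idx) & idx == b]
    if (length(d)) qmat[b, ] <- quantile(d, qs, type = 7)
  }
  cbind(out, qmat)
}

#' Total scratches after the injection
#'
#' Counts bouts with onset in `[0, 2700)` s (45 min), the behavior
#' covariate of the scratch-Fos correlation.
#'
#' @param bouts data.frame (onset_s, duration_s).
#' @param window counting window, s.
#' @return integer count.
#' @export
total_scratches <- function(bouts, window = c(0, 2700)) {
  sum(bouts$onset_s >= window[1] & bouts$onset_s < window[2])
}

#' Upper reference limit of pre-injection bout durations
#'
#' The dotted 0.3 s reference line of the duration plots is described as
#' the "10%-upper confidential limit" of pre-injection durations. The
#' default interpretation is the 90th percentile of the pooled
#' pre-injection durations (linear type-7 interpolation); an alternative
#' one-sided 90% upper confidence bound of the mean is available.
#'
#' @param bouts data.frame (onset_s, duration_s); only onsets < 0 are used.
#' @param method `"percentile"` (default) or `"mean_ucl"`.
#' @return duration threshold, s.
#' @export
pre_injection_upper_limit <- function(bouts,
                                      method = c("percentile", "mean_ucl")) {
  method <- match.arg(method)
  d <- bouts$duration_s[bouts$onset_s < 0]
  if (!length(d)) stop("no pre-injection bouts")
  if (method == "percentile")
    return(unname(quantile(d, 0.9, type = 7)))
  mean(d) + qt(0.9, length(d) - 1) * sd(d) / sqrt(length(d))
}

#' Cohort comparisons of scratching behavior
#'
#' Per 5-min bin: 2x2 factorial ANOVA of per-mouse bout counts (factors
#' injection and nails plus interaction). On 45-min totals: one-way ANOVA
#' across the four cohorts with Bonferroni-adjusted pairwise t tests. On
#' pooled bout durations: per-bin two-sided Mann-Whitney tests between
#' nail groups within each injection arm. No multiplicity correction is
#' applied across time bins.
#'
#' @param bouts data.frame (mouse, cohort, onset_s, duration_s).
#' @param bin,window as in [bin_bout_counts()].
#' @return list(per_bin_anova, totals_anova, totals_pairwise,
#'   duration_tests, totals).
#' @export
group_comparisons <- function(bouts, bin = 300, window = c(-900, 2700)) {
  stopifnot(all(c("mouse", "cohort", "onset_s", "duration_s") %in%
                  names(bouts)))
  bouts$injection <- ifelse(grepl("histamine", bouts$cohort),
                            "histamine", "saline")
  bouts$nails <- ifelse(grepl("clipped", bouts$cohort), "clipped", "intact")
  mice <- unique(bouts[c("mouse", "cohort", "injection", "nails")])
  if (any(table(mice$cohort) < 2))
    warning("cohorts with fewer than 2 mice are unreliable")
  starts <- seq(window[1], window[2] - bin, by = bin)
  # per-mouse per-bin counts
  cnt <- matrix(0L, nrow(mice), length(starts),
                dimnames = list(mice$mouse, NULL))
  for (i in seq_len(nrow(mice))) {
    b <- bouts[bouts$mouse == mice$mouse[i], ]
    cnt[i, ] <- bin_bout_counts(b, bin, window)$count
  }
  per_bin <- data.frame(start_s = starts, end_s = starts + bin,
                        p_injection = NA_real_, p_nails = NA_real_,
                        p_interaction = NA_real_)
  for (b in seq_along(starts)) {
    d <- data.frame(y = cnt[, b], injection = mice$injection,
                    nails = mice$nails)
    if (var(d$y) == 0) next
    a <- anova(aov(y ~ injection * nails, data = d))
    pr <- a[["Pr(>F)"]]
    per_bin[b, c("p_injection", "p_nails", "p_interaction")] <- pr[1:3]
  }
  # 45-min totals
  totals <- data.frame(
    mouse = mice$mouse, cohort = mice$cohort,
    total = vapply(mice$mouse, function(m)
      total_scratches(bouts[bouts$mouse == m, ]), integer(1)))
  tot_aov <- anova(aov(total ~ cohort, data = totals))
  pairs <- utils::combn(sort(unique(totals$cohort)), 2)
  pw <- data.frame(cohort_a = pairs[1, ], cohort_b = pairs[2, ],
                   p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    tt <- t.test(totals$total[totals$cohort == pairs[1, j]],
                 totals$total[totals$cohort == pairs[2, j]])
    pw$p[j] <- tt$p.value
  }
  pw$p_adj <- pmin(1, pw$p * ncol(pairs))
  # per-bin duration Mann-Whitney, intact vs clipped within injection arm
  dur <- expand.grid(start_s = starts, injection = c("saline", "histamine"),
                     stringsAsFactors = FALSE)
  dur$p <- NA_real_
  bidx <- findInterval(bouts$onset_s, c(starts, window[2]))
  for (r in seq_len(nrow(dur))) {
    sel <- !is.na(bidx) & bidx == match(dur$start_s[r], starts) &
      bouts$injection == dur$injection[r] &
      bouts$onset_s >= window[1] & bouts$onset_s < window[2]
    di <- bouts$duration_s[sel & bouts$nails == "intact"]
    dc <- bouts$duration_s[sel & bouts$nails == "clipped"]
    if (length(di) >= 2 && length(dc) >= 2)
      dur$p[r] <- wilcox.test(di, dc)$p.value
  }
  list(per_bin_anova = per_bin, totals_anova = tot_aov,
       totals_pairwise = pw, duration_tests = dur, totals = totals)
}

#' Scratch totals per mouse
#'
#' Convenience wrapper: 45-min post-injection totals for every mouse in a
#' bout table, the covariate used by [scratch_fos_correlation()].
#'
#' @param bouts data.frame (mouse, cohort, onset_s, duration_s).
#' @return data.frame (mouse, cohort, total).
#' @export
scratch_totals <- function(bouts) {
  mice <- unique(bouts[c("mouse", "cohort")])
  mice$total <- vapply(mice$mouse, function(m)
    total_scratches(bouts[bouts$mouse == m, ]), integer(1))
  rownames(mice) <- NULL
  mice
}
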