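# Comparative statistics across regions: t/FDR maps, response classes,
# receptor composition tests, and scratch-Fos correlation maps.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1. Regions are one family per comparison, spanning all three
#' planes.
#'
#' @param p p-values in \[0, 1\] (NA passed through).
#' @param m family size; defaults to the number of non-NA p-values.
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p, m = sum(!is.na(p))) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must be in [0, 1]")
  n <- length(pv)
  if (n == 0) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / seq(n, 1)))[ro]
  q
}

#' Per-region two-sample t map with FDR classes
#'
#' For every region with at least `min_cases` valid cases in both groups,
#' computes a two-sample t statistic (Welch by default) signed so that
#' positive t means a higher mean in `counts_b` (the second-listed
#' condition), BH-adjusts the p-values across all testable regions as one
#' family, and classifies regions at `q < q_threshold` as `increased`
#' (t > 0) or `decreased` (t < 0); everything else tested is `insensitive`.
#'
#' @param counts_a,counts_b region-count tables ([tabulate_regions()]) of
#'   the reference and comparison condition; case unit = section.
#' @param value column compared.
#' @param var_equal pooled-variance t instead of Welch.
#' @param q_threshold FDR threshold (default 0.1).
#' @param min_cases minimum cases per group per region.
#' @param regions region keys to evaluate.
#' @return data.frame (pzs_id, n_a, n_b, t, p, q, class); class is
#'   `not_testable` where a group has too few cases.
#' @export
region_t_map <- function(counts_a, counts_b, value = "fraction_fos",
                         var_equal = FALSE, q_threshold = 0.1,
                         min_cases = 2L, regions = enumerate_regions()) {
  counts_a <- counts_a[counts_a$valid, ]
  counts_b <- counts_b[counts_b$valid, ]
  out <- data.frame(pzs_id = regions$pzs_id, n_a = 0L, n_b = 0L,
                    t = NA_real_, p = NA_real_, q = NA_real_,
                    class = "not_testable", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    xa <- counts_a[[value]][counts_a$pzs_id == out$pzs_id[i]]
    xb <- counts_b[[value]][counts_b$pzs_id == out$pzs_id[i]]
    out$n_a[i] <- length(xa); out$n_b[i] <- length(xb)
    if (length(xa) < min_cases || length(xb) < min_cases) next
    if (var(xa) == 0 && var(xb) == 0) {
      # degenerate but testable: identical groups give t = 0, p = 1
      if (mean(xa) == mean(xb)) {
        out$t[i] <- 0; out$p[i] <- 1
      } else {
        out$t[i] <- sign(mean(xb) - mean(xa)) * Inf; out$p[i] <- 0
      }
      next
    }
    tt <- t.test(xb, xa, var.equal = var_equal)
    out$t[i] <- unname(tt$statistic)
    out$p[i] <- tt$p.value
  }
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out$class[tested] <- "insensitive"
  out$class[tested & out$q < q_threshold & out$t > 0] <- "increased"
  out$class[tested & out$q < q_threshold & out$t < 0] <- "decreased"
  out
}

#' Compare receptor-positive fractions between response classes
#'
#' With three or more non-empty classes: Kruskal-Wallis omnibus plus
#' Bonferroni-adjusted pairwise two-sided Mann-Whitney tests; with two:
#' the Mann-Whitney test alone. One observation = one region.
#'
#' @param fractions numeric vector (e.g. per-region Drd1-positive
#'   fraction).
#' @param class factor/character response class per region.
#' @return list with `omnibus` (method, statistic, p) and `pairwise`
#'   data.frame (class_a, class_b, statistic, p, p_adj).
#' @export
receptor_fraction_tests <- function(fractions, class) {
  keep <- !is.na(fractions) & !is.na(class)
  fractions <- fractions[keep]; class <- as.character(class)[keep]
  tab <- table(class)
  empty <- names(tab)[tab < 2]
  if (length(empty)) {
    warning("dropping classes with fewer than 2 regions: ",
            paste(empty, collapse = ", "))
    keep <- !(class %in% empty)
    fractions <- fractions[keep]; class <- class[keep]
  }
  lev <- sort(unique(class))
  if (length(lev) < 2) stop("need at least two classes with >= 2 regions")
  if (length(lev) >= 3) {
    kw <- kruskal.test(fractions, factor(class))
    omnibus <- list(method = "kruskal_wallis",
                    statistic = unname(kw$statistic), p = kw$p.value)
  } else {
    mw <- suppressWarnings(
      wilcox.test(fractions[class == lev[1]], fractions[class == lev[2]]))
    omnibus <- list(method = "mann_whitney",
                    statistic = unname(mw$statistic), p = mw$p.value)
  }
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  pw <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                   statistic = NA_real_, p = NA_real_)
  for (j in seq_len(n_pairs)) {
    # ties fall back on the normal approximation; routine for fractions
    mw <- suppressWarnings(wilcox.test(fractions[class == pairs[1, j]],
                                       fractions[class == pairs[2, j]]))
    pw$statistic[j] <- unname(mw$statistic)
    pw$p[j] <- mw$p.value
  }
  pw$p_adj <- pmin(1, pw$p * n_pairs)  # Bonferroni over class pairs
  list(omnibus = omnibus, pairwise = pw)
}

# Pearson chi-square statistic without continuity correction
.chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(stat = sum((tab - e)^2 / e), df = (nrow(tab) - 1) * (ncol(tab) - 1),
       expected = e)
}

#' Chi-square tests of Fos-positive receptor composition between classes
#'
#' Rows = response classes, columns = the four receptor co-expression
#' patterns of Fos-positive cells. Performs the omnibus Pearson chi-square
#' on the full table and Bonferroni-adjusted pairwise class-vs-class tests;
#' the conventional significance marker is P < 0.005.
#'
#' @param tab matrix of counts (classes x patterns).
#' @param alpha significance level for the `significant` flag.
#' @return list with `omnibus` and `pairwise`; a warning is attached when
#'   any expected count is below 1.
#' @export
composition_chisq <- function(tab, alpha = 0.005) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2) stop("need at least two classes")
  om <- .chisq_stat(tab)
  if (any(om$expected < 1))
    warning("expected counts below 1; chi-square approximation is weak")
  omnibus <- list(statistic = om$stat, df = om$df,
                  p = stats::pchisq(om$stat, om$df, lower.tail = FALSE))
  omnibus$significant <- omnibus$p < alpha
  rn <- rownames(tab)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(tab)))
  pairs <- utils::combn(seq_len(nrow(tab)), 2)
  pw <- data.frame(class_a = rn[pairs[1, ]], class_b = rn[pairs[2, ]],
                   statistic = NA_real_, df = NA_integer_, p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    st <- .chisq_stat(tab[pairs[, j], , drop = FALSE])
    pw$statistic[j] <- st$stat
    pw$df[j] <- st$df
    pw$p[j] <- stats::pchisq(st$stat, st$df, lower.tail = FALSE)
  }
  pw$p_adj <- pmin(1, pw$p * ncol(pairs))
  pw$significant <- pw$p_adj < alpha
  list(omnibus = omnibus, pairwise = pw)
}

# Spearman rho with average ranks; p two-sided via t approximation for
# n >= 10, exact permutation enumeration for smaller n.
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  } else {
    # exact: all permutations of one rank vector
    perms <- .all_perms(n)
    mx <- rx - mean(rx); my <- ry - mean(ry)
    denom <- sqrt(sum(mx^2) * sum(my^2))
    # correlation of every permutation of x-ranks against fixed y-ranks
    rhos <- (matrix(mx[perms], nrow(perms)) %*% my) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1))
}

# all permutations of 1..n as a matrix (n <= 9)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Scratch-Fos correlation map of one cohort
#'
#' Per region, the Spearman rank correlation between each mouse's total
#' post-injection scratches and its regional Fos-positive fraction (one
#' section per mouse per plane; sections of the same mouse are averaged if
#' several). Regions with fewer than `min_n` mice, or a constant vector,
#' are reported missing.
#'
#' @param counts region-count table with cohort labels.
#' @param totals data.frame (mouse, total) of 45-min scratch totals.
#' @param cohort cohort to map (NULL = all rows of `counts`).
#' @param alpha significance level (default 0.1).
#' @param min_n minimum mice per region.
#' @param regions region keys to evaluate.
#' @return data.frame (pzs_id, n, rho, p, significant).
#' @export
scratch_fos_correlation <- function(counts, totals, cohort = NULL,
                                    alpha = 0.1, min_n = 4L,
                                    regions = enumerate_regions()) {
  if (!is.null(cohort)) counts <- counts[counts$cohort %in% cohort, ]
  counts <- counts[counts$valid, ]
  out <- data.frame(pzs_id = regions$pzs_id, n = 0L, rho = NA_real_,
                    p = NA_real_, significant = NA)
  for (i in seq_len(nrow(out))) {
    sub <- counts[counts$pzs_id == out$pzs_id[i], ]
    if (!nrow(sub)) next
    frac <- tapply(sub$fraction_fos, sub$mouse, mean)
    m <- match(names(frac), totals$mouse)
    ok <- !is.na(m)
    x <- totals$total[m[ok]]; y <- as.numeric(frac[ok])
    out$n[i] <- length(x)
    if (length(x) < min_n) next
    st <- spearman_test(x, y)
    out$rho[i] <- st$rho
    out$p[i] <- st$p
    out$significant[i] <- !is.na(st$p) && st$p < alpha
  }
  out
}
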