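test_that("bh_fdr matches the step-up oracle and its defining properties", {
  expect_equal(bh_fdr(0.03), 0.03)                       # single p
  expect_equal(bh_fdr(c(0.05, 1.0)), c(0.10, 1.0))       # formula case
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  for (rep in 1:20) {
    p <- runif(sample(2:120, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))                     # q >= p
    expect_true(all(q <= 1))
    # monotone in the p ordering
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA passthrough
  expect_equal(bh_fdr(c(0.05, NA, 1.0)), c(0.10, NA, 1.0))
})

test_that("region_t_map: identical groups, sign convention, classes", {
  regions <- data.frame(pzs_id = c("211", "212", "213"))
  mk <- function(vals, coh) {
    do.call(rbind, lapply(seq_along(vals), function(i)
      data.frame(mouse = paste0(coh, "_m", i), section = paste0("s", i),
                 cohort = coh, pzs_id = c("211", "212", "213"),
                 n_dapi = 50, fraction_fos = vals[[i]], valid = TRUE)))
  }
  a <- mk(list(c(0.2, 0.3, 0.1), c(0.25, 0.35, 0.15), c(0.22, 0.28, 0.12)), "A")
  # identical groups -> t = 0, insensitive
  same <- region_t_map(a, a, regions = regions)
  expect_true(all(same$t == 0))
  expect_true(all(same$class == "insensitive"))
  # planted shift upward in B -> positive t; swapping groups negates t
  b <- mk(list(c(0.5, 0.3, 0.1), c(0.55, 0.35, 0.15), c(0.52, 0.28, 0.12)), "B")
  ab <- region_t_map(a, b, regions = regions)
  ba <- region_t_map(b, a, regions = regions)
  expect_gt(ab$t[ab$pzs_id == "211"], 0)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$q, ba$q)
  # class partition of testable regions
  expect_true(all(ab$class %in% c("increased", "decreased", "insensitive")))
  expect_true(all(ab$q >= ab$p - 1e-15))
  # fewer than 2 cases -> not testable
  a1 <- a[a$mouse == "A_m1", ]
  nt <- region_t_map(a1, b, regions = regions)
  expect_true(all(nt$class == "not_testable"))
  expect_true(all(is.na(nt$t)))
})

test_that("planted effect is classified 'increased' with high power", {
  # Delta = +0.15 on fractions with case-level sd ~0.05, n = 12 vs 12
  regions <- data.frame(pzs_id = sprintf("2%d%d", rep(1:4, each = 8), 1:8))
  hits <- 0; n_rep <- 20
  set.seed(99)
  for (r in seq_len(n_rep)) {
    mk <- function(mu, coh) do.call(rbind, lapply(1:12, function(i)
      data.frame(mouse = paste0(coh, i), section = paste0(coh, i),
                 cohort = coh, pzs_id = regions$pzs_id, n_dapi = 100,
                 fraction_fos = pmin(pmax(rnorm(32, mu, 0.05), 0), 1),
                 valid = TRUE)))
    a <- mk(0.3, "a"); b <- mk(0.3, "b")
    # plant the effect in region 211 only
    b$fraction_fos[b$pzs_id == "211"] <- b$fraction_fos[b$pzs_id == "211"] + 0.15
    cmp <- region_t_map(a, b, regions = regions)
    if (cmp$class[cmp$pzs_id == "211"] == "increased") hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("receptor fraction tests: omnibus choice and Bonferroni", {
  set.seed(43)
  # three identical groups -> H ~ 0, p ~ 1
  x <- rep(c(0.2, 0.3, 0.4, 0.5), 3)
  cls <- rep(c("increased", "decreased", "insensitive"), each = 4)
  res <- receptor_fraction_tests(x, cls)
  expect_equal(res$omnibus$method, "kruskal_wallis")
  expect_gt(res$omnibus$p, 0.9)
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p * 3))
  # exact Mann-Whitney: {1,2,3} vs {4,5,6} -> U = 0, two-sided p = 0.1
  res2 <- receptor_fraction_tests(c(1, 2, 3, 4, 5, 6),
                                  rep(c("a", "b"), each = 3))
  expect_equal(res2$omnibus$method, "mann_whitney")
  expect_equal(unname(res2$omnibus$statistic), 0)
  expect_equal(res2$omnibus$p, 0.1)
  # empty classes dropped with warning
  expect_warning(
    res3 <- receptor_fraction_tests(c(1, 2, 3, 4, 5),
                                    c("a", "a", "b", "b", "c")),
    "fewer than 2")
  expect_equal(res3$omnibus$method, "mann_whitney")
  expect_error(receptor_fraction_tests(1:2, c("a", "a")), "two classes")
})

test_that("composition chi-square equals the hand formula", {
  # proportional rows -> 0
  prop <- rbind(c(10, 20, 30, 40), c(5, 10, 15, 20))
  res <- composition_chisq(prop)
  expect_equal(res$omnibus$statistic, 0)
  expect_gt(res$omnibus$p, 0.999)
  # hand-computed 2x2
  tab <- rbind(c(10, 20), c(20, 10))
  expect_equal(composition_chisq(tab)$omnibus$statistic, 20 / 3,
               tolerance = 1e-9)
  expect_equal(composition_chisq(tab)$omnibus$statistic, oracle_chisq(tab),
               tolerance = 1e-12)
  # row swap invariance, random 2x4 and 3x4 tables vs oracle
  set.seed(44)
  for (r in 1:10) {
    t2 <- matrix(rpois(8, 30) + 1, 2)
    expect_equal(composition_chisq(t2)$omnibus$statistic, oracle_chisq(t2),
                 tolerance = 1e-9)
    expect_equal(composition_chisq(t2[2:1, ])$omnibus$statistic,
                 composition_chisq(t2)$omnibus$statistic)
    t3 <- matrix(rpois(12, 30) + 1, 3)
    res3 <- composition_chisq(t3)
    expect_equal(res3$omnibus$statistic, oracle_chisq(t3), tolerance = 1e-9)
    expect_equal(nrow(res3$pairwise), 3L)
    expect_equal(res3$pairwise$p_adj, pmin(1, res3$pairwise$p * 3))
  }
  expect_warning(composition_chisq(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))),
                 "expected counts")
})

test_that("Spearman: exact small-n values and the rank-formula oracle", {
  st <- enacmap:::spearman_test
  expect_equal(st(1:5, 1:5)$rho, 1)
  expect_equal(st(1:5, 5:1)$rho, -1)
  r <- st(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_equal(r$rho, oracle_spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  set.seed(45)
  for (n in c(5, 6, 8)) {
    x <- rnorm(n); y <- rnorm(n)  # continuous: no ties
    expect_equal(st(x, y)$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    # exact permutation p matches cor.test's exact p for untied data
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(st(x, y)$p, ct$p.value, tolerance = 1e-9)
  }
  # constant vector -> undefined
  expect_true(is.na(st(rep(1, 5), 1:5)$rho))
})

test_that("scratch_fos_correlation maps regions with enough mice", {
  set.seed(46)
  mice <- sprintf("m%02d", 1:10)
  totals <- data.frame(mouse = mice, total = c(5, 12, 20, 33, 41, 52, 60, 75, 81, 95))
  counts <- do.call(rbind, lapply(seq_along(mice), function(i)
    data.frame(mouse = mice[i], section = paste0(mice[i], "_s"),
               cohort = "saline_intact", pzs_id = c("211", "212"),
               n_dapi = 50,
               fraction_fos = c(totals$total[i] / 100,          # rho = 1
                                0.5 - totals$total[i] / 200),   # rho = -1
               valid = TRUE)))
  cm <- scratch_fos_correlation(counts, totals, "saline_intact",
                                regions = data.frame(pzs_id = c("211", "212", "213")))
  expect_equal(cm$rho[cm$pzs_id == "211"], 1)
  expect_equal(cm$rho[cm$pzs_id == "212"], -1)
  expect_true(cm$significant[cm$pzs_id == "211"])
  expect_true(is.na(cm$rho[cm$pzs_id == "213"]))  # no data -> missing
  # fewer than min_n mice -> missing
  cm4 <- scratch_fos_correlation(counts[counts$mouse %in% mice[1:3], ],
                                 totals, "saline_intact", min_n = 4,
                                 regions = data.frame(pzs_id = "211"))
  expect_true(is.na(cm4$rho))
  # constant fractions -> undefined, reported missing
  cc <- counts; cc$fraction_fos <- 0.3
  cmc <- scratch_fos_correlation(cc, totals, "saline_intact",
                                 regions = data.frame(pzs_id = "211"))
  expect_true(is.na(cmc$rho))
})

test_that("FDR is controlled on null data and planted signs are recovered", {
  # fast null check at the summary level (the full generator-level
  # calibration lives in the acceptance suite)
  set.seed(47)
  regions <- data.frame(pzs_id = sprintf("2%d%d", rep(1:4, each = 8), 1:8))
  fdp <- replicate(60, {
    mk <- function(coh) do.call(rbind, lapply(1:12, function(i)
      data.frame(mouse = paste0(coh, i), section = paste0(coh, i),
                 cohort = coh, pzs_id = regions$pzs_id, n_dapi = 100,
                 fraction_fos = rnorm(32, 0.3, 0.05), valid = TRUE)))
    cmp <- region_t_map(mk("a"), mk("b"), regions = regions)
    mean(cmp$q < 0.1, na.rm = TRUE)
  })
  expect_lte(mean(fdp), 0.1 + 2 * sd(fdp) / sqrt(length(fdp)))
  # planted signs: significant regions carry the planted direction
  mk2 <- function(coh, shift) do.call(rbind, lapply(1:12, function(i)
    data.frame(mouse = paste0(coh, i), section = paste0(coh, i),
               cohort = coh, pzs_id = regions$pzs_id, n_dapi = 100,
               fraction_fos = rnorm(32, 0.3, 0.05) +
                 shift * (regions$pzs_id %in% c("211", "212")) -
                 shift * (regions$pzs_id %in% c("241", "242")),
               valid = TRUE)))
  cmp <- region_t_map(mk2("a", 0), mk2("b", 0.2), regions = regions)
  # planted-sign recovery: planted regions that reach q < 0.1 carry the
  # planted direction, and the strong effects are in fact detected
  expect_true(all(cmp$class[cmp$pzs_id %in% c("211", "212")] == "increased"))
  expect_true(all(cmp$class[cmp$pzs_id %in% c("241", "242")] == "decreased"))
  expect_true(all(cmp$t[cmp$class == "increased"] > 0))
  expect_true(all(cmp$t[cmp$class == "decreased"] < 0))
})
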