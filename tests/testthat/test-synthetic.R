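test_that("effect maps validate partitions and plant archetype structure", {
  grid <- enumerate_regions(parcellation_config(excluded_regions = character(0)))
  # uniform single archetype
  uni <- build_effect_map(list(list(
    name = "all", regions = grid$pzs_id,
    probs = c(saline_intact = 0.3, saline_clipped = 0.3,
              histamine_intact = 0.3, histamine_clipped = 0.3))))
  expect_equal(nrow(uni), 96 * 4)
  expect_true(all(uni$p == 0.3))
  # default 5 archetypes partition the grid; planted identity by construction
  em <- build_effect_map(default_archetypes())
  expect_equal(sort(unique(em$pzs_id)), grid$pzs_id)
  expect_equal(length(unique(em$archetype)), 5L)
  per_region <- tapply(em$archetype, em$pzs_id, function(x) unique(x))
  expect_true(all(lengths(per_region) == 1))
  # qualitative ordering mirrors the described clusters: gamma low under
  # every condition, epsilon/delta high under saline-intact
  probs <- do.call(rbind, tapply(em$p, em$archetype, range))
  expect_lt(max(em$p[em$archetype == "gamma"]), 0.15)
  expect_gt(min(em$p[em$archetype == "delta" &
                       em$cohort == "saline_intact"]), 0.4)
  # overlapping and incomplete sets are rejected with regions named
  arch <- default_archetypes()
  arch[[1]]$regions <- c(arch[[1]]$regions, arch[[2]]$regions[1])
  expect_error(build_effect_map(arch), arch[[2]]$regions[1])
  arch2 <- default_archetypes()
  dropped <- arch2[[1]]$regions[1]
  arch2[[1]]$regions <- arch2[[1]]$regions[-1]
  expect_error(build_effect_map(arch2), dropped)
})

test_that("simulate_cells: determinism, empty cases, planted fractions", {
  cfg <- calib_config()
  a <- simulate_cells(cfg, "intermed", "histamine_intact", seed = 3)
  b <- simulate_cells(cfg, "intermed", "histamine_intact", seed = 3)
  expect_identical(a, b)
  c2 <- simulate_cells(cfg, "intermed", "histamine_intact", seed = 4)
  expect_false(identical(a, c2))
  # zero density -> empty with warning
  cfg0 <- calib_config(density = 0)
  expect_warning(e <- simulate_cells(cfg0, "intermed", "saline_intact"),
                 "zero")
  expect_equal(nrow(e), 0L)
  # constant p = 1 -> all positive
  grid <- enumerate_regions(parcellation_config(excluded_regions = character(0)))
  em1 <- build_effect_map(list(list(
    name = "all", regions = grid$pzs_id,
    probs = setNames(rep(1, 4), c("saline_intact", "saline_clipped",
                                  "histamine_intact", "histamine_clipped")))))
  all_pos <- simulate_cells(calib_config(effect_map = em1), "intermed",
                            "saline_intact", seed = 1)
  expect_true(all(all_pos$true_fos))
  # p = 0.3 at ~10000 cells: observed fraction within 3 binomial SE
  cfg3 <- sim_config(planes = "intermed", nuclei_density = 11,
                     baseline_fos_p = 0.3)
  big <- simulate_cells(cfg3, "intermed", "saline_intact", seed = 9)
  expect_gt(nrow(big), 8000)
  se <- sqrt(0.3 * 0.7 / nrow(big))
  expect_lt(abs(mean(big$true_fos) - 0.3), 3 * se)
  # overlaps respect the margin around the calling thresholds
  thr <- positivity_thresholds()
  expect_true(all(big$overlap_fos[big$true_fos] >= thr$fos + 0.1))
  expect_true(all(big$overlap_fos[!big$true_fos] <= thr$fos - 0.1))
})

test_that("planted per-region fractions are recovered within 4 binomial SE", {
  em <- build_effect_map(default_archetypes())
  cfg <- sim_config(nuclei_density = 8, effect_map = em)
  for (pl in c("rostral", "caudal")) {
    cells <- simulate_cells(cfg, pl, "histamine_clipped", seed = 21)
    cells <- cells[!is.na(cells$true_pzs), ]
    n <- table(cells$true_pzs)
    frac <- tapply(cells$true_fos, cells$true_pzs, mean)
    planted <- em$p[em$cohort == "histamine_clipped"][
      match(names(frac), em$pzs_id[em$cohort == "histamine_clipped"])]
    big <- n >= 100
    se <- sqrt(planted * (1 - planted) / as.numeric(n))
    expect_true(all(abs(frac[big] - planted[big]) <= 4 * se[big]))
  }
})

test_that("receptor pattern composition converges to receptor_probs", {
  cfg <- sim_config(planes = "intermed", nuclei_density = 8,
                    receptor_probs = c(d1 = 0.4, d2 = 0.4, both = 0.1,
                                       neither = 0.1))
  cells <- do.call(rbind, lapply(1:7, function(s)
    simulate_cells(cfg, "intermed", "saline_intact", seed = s)))
  expect_gt(nrow(cells), 50000)
  obs <- c(d1 = sum(cells$true_drd1 & !cells$true_drd2),
           d2 = sum(!cells$true_drd1 & cells$true_drd2),
           both = sum(cells$true_drd1 & cells$true_drd2),
           neither = sum(!cells$true_drd1 & !cells$true_drd2))
  gof <- chisq.test(obs, p = c(0.4, 0.4, 0.1, 0.1))
  expect_gt(gof$p.value, 0.001)
})

test_that("render_section draws disks, truth labels, and clips with warning", {
  # one nucleus, no noise -> exactly one bright component
  one <- data.frame(x = 20, y = 20, overlap_fos = 0.5, overlap_drd1 = 0,
                    overlap_drd2 = 0)
  r1 <- render_section(one, shape = c(41, 41), nucleus_radius = 5)
  comp <- enacmap:::cpp_label_components(r1$image$dapi > 0)
  expect_equal(max(comp), 1L)
  expect_equal(sort(unique(as.vector(r1$labels))), c(0L, 1L))
  # fos coverage equals the requested overlap fraction
  npix <- sum(r1$labels == 1)
  expect_equal(sum(r1$image$fos > 0) / npix, 0.5, tolerance = 0.02)
  # two nuclei 1.5 radii apart: one DAPI blob, two truth labels
  two <- data.frame(x = c(20, 27.5), y = c(20, 20),
                    overlap_fos = 0, overlap_drd1 = 0, overlap_drd2 = 0)
  r2 <- render_section(two, shape = c(41, 48), nucleus_radius = 5)
  expect_equal(max(enacmap:::cpp_label_components(r2$image$dapi > 0)), 1L)
  expect_equal(sort(unique(as.vector(r2$labels))), c(0L, 1L, 2L))
  # nucleus at the border -> clipped with warning
  expect_warning(render_section(data.frame(x = 1, y = 1, overlap_fos = 0,
                                           overlap_drd1 = 0, overlap_drd2 = 0),
                                shape = c(20, 20), nucleus_radius = 5),
                 "clipped")
  # determinism of the noise
  r3 <- render_section(one, shape = c(41, 41), noise_sd = 500, seed = 2)
  r4 <- render_section(one, shape = c(41, 41), noise_sd = 500, seed = 2)
  expect_identical(r3$image$dapi, r4$image$dapi)
})

test_that("simulate_scratches: determinism, Poisson mean, rate multipliers", {
  expect_identical(simulate_scratches("saline_intact", seed = 5),
                   simulate_scratches("saline_intact", seed = 5))
  expect_error(scratch_params(base_rate = -1), "non-negative")
  # all multipliers 1: total count mean ~ lambda * T over many seeds
  p1 <- scratch_params(base_rate = 2, histamine_mult = 1, clip_mult = 1)
  counts <- vapply(1:300, function(s)
    nrow(simulate_scratches("saline_intact", p1, seed = s)), numeric(1))
  lamT <- 2 * 60  # 2/min over the 60-min window
  expect_lt(abs(mean(counts) - lamT), 4 * sqrt(lamT / 300))
  # histamine multiplier 4 vs 1 (no decay): post totals differ by ~4x
  p4 <- scratch_params(base_rate = 2, histamine_mult = 4, clip_mult = 1,
                       decay_halflife_min = Inf)
  post <- function(co, s) total_scratches(simulate_scratches(co, p4, seed = s))
  m_hist <- mean(vapply(1:200, function(s) post("histamine_intact", s),
                        numeric(1)))
  m_sal <- mean(vapply(1:200, function(s) post("saline_intact", 1000 + s),
                       numeric(1)))
  expect_equal(m_hist / m_sal, 4, tolerance = 0.1)
  # durations shift upward under histamine + clipped
  dh <- simulate_scratches("histamine_clipped", seed = 8)
  ds <- simulate_scratches("saline_intact", seed = 8)
  expect_gt(median(dh$duration_s[dh$onset_s > 0]),
            median(ds$duration_s[ds$onset_s > 0]))
})

test_that("simulate_study is a pure function of (config, seed)", {
  cfg <- sim_config(n_mice_per_cohort = c(saline_intact = 2L,
                                          saline_clipped = 2L,
                                          histamine_intact = 2L,
                                          histamine_clipped = 2L),
                    planes = "intermed", nuclei_density = 1)
  s1 <- simulate_study(cfg, seed = 10)
  s2 <- simulate_study(cfg, seed = 10)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$bouts, s2$bouts)
  expect_equal(length(unique(s1$cells$mouse)), 8L)
  expect_true(all(table(s1$bouts$mouse) > 0))
})
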