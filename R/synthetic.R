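# Ground-truthed synthetic data: cell tables, rendered section images, and
# scratch-bout series with the statistical structure the analysis assumes.

COHORTS <- c("saline_intact", "saline_clipped",
             "histamine_intact", "histamine_clipped")

# run code under a temporary RNG state so generators are pure in (config, seed)
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Scratch-bout generator parameters
#'
#' Pre-injection bouts are homogeneous Poisson at `base_rate`. After the
#' injection the rate is `base_rate * M` with
#' `M = histamine_mult^[histamine] * clip_mult^[clipped]`, and the excess
#' over baseline decays exponentially with half-life `decay_halflife_min`
#' (the observed time course peaks early and relaxes over tens of minutes;
#' the time course has no canonical functional form, so exponential decay of the excess is
#' the package's choice). Durations are log-normal; the post-injection
#' mean-log is shifted upward under histamine, more so with clipped nails.
#' The baseline duration parameters are chosen so the 90th percentile of
#' pre-injection durations is close to the 0.3 s reference limit.
#'
#' @param base_rate spontaneous bout rate, bouts/min.
#' @param histamine_mult,clip_mult post-injection rate multipliers.
#' @param decay_halflife_min half-life (min) of the excess rate; `Inf`
#'   keeps the post-injection rate constant.
#' @param duration_meanlog,duration_sdlog log-normal bout duration (s).
#' @param hist_duration_shift,clip_duration_shift additive mean-log shifts
#'   applied to post-injection durations (histamine; histamine + clipped).
#' @export
scratch_params <- function(base_rate = 1, histamine_mult = 4,
                           clip_mult = 1.5, decay_halflife_min = 20,
                           duration_meanlog = log(0.16),
                           duration_sdlog = 0.5,
                           hist_duration_shift = 0.4,
                           clip_duration_shift = 0.25) {
  if (base_rate < 0 || histamine_mult < 0 || clip_mult < 0)
    stop("rates and multipliers must be non-negative")
  structure(list(base_rate = base_rate, histamine_mult = histamine_mult,
                 clip_mult = clip_mult,
                 decay_halflife_min = decay_halflife_min,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 hist_duration_shift = hist_duration_shift,
                 clip_duration_shift = clip_duration_shift),
            class = "scratch_params")
}

#' Simulation configuration
#'
#' The defaults are the study's stated conditions: cohort sizes 12/11/12/13
#' (saline-intact / saline-clipped / histamine-intact / histamine-clipped),
#' three planes with the reference mean circle radii, one section per mouse
#' per plane. Nuclei density and baseline positivity have no reference values and
#' are documented guesses (see the methods vignette).
#'
#' @param n_mice_per_cohort named integer vector over the four cohorts.
#' @param planes plane labels simulated for each mouse.
#' @param circle_radii_px named list of five increasing radii per plane.
#' @param nuclei_density nuclei per 1e4 px^2 of annulus between circles 1
#'   and 5.
#' @param baseline_fos_p default Fos positivity probability where the
#'   effect map gives none.
#' @param receptor_probs probabilities of (D1+D2-, D1-D2+, D1+D2+, D1-D2-),
#'   summing to 1.
#' @param effect_map per-(region, cohort) Fos probabilities from
#'   [build_effect_map()]; `NULL` = flat `baseline_fos_p`.
#' @param scratch a [scratch_params()].
#' @param min_center_sep hard-core minimum nucleus center separation, px
#'   (0 = off).
#' @param overlap_margin how far the simulated overlap fractions stay away
#'   from the calling thresholds on either side.
#' @param seed base seed.
#' @export
sim_config <- function(n_mice_per_cohort = c(saline_intact = 12L,
                                             saline_clipped = 11L,
                                             histamine_intact = 12L,
                                             histamine_clipped = 13L),
                       planes = names(PLANE_CODES),
                       circle_radii_px = DEFAULT_RADII,
                       nuclei_density = 8,
                       baseline_fos_p = 0.3,
                       receptor_probs = c(d1 = 0.40, d2 = 0.40,
                                          both = 0.10, neither = 0.10),
                       effect_map = NULL,
                       scratch = scratch_params(),
                       min_center_sep = 0,
                       overlap_margin = 0.1,
                       seed = 1L) {
  stopifnot(all(COHORTS %in% names(n_mice_per_cohort)))
  if (abs(sum(receptor_probs) - 1) > 1e-9)
    stop("receptor_probs must sum to 1")
  if (any(receptor_probs < 0) || baseline_fos_p < 0 || baseline_fos_p > 1)
    stop("probabilities must be in [0, 1]")
  for (pl in planes)
    if (any(diff(circle_radii_px[[pl]]) <= 0))
      stop("circle radii must be strictly increasing: ", pl)
  structure(list(n_mice_per_cohort = n_mice_per_cohort, planes = planes,
                 circle_radii_px = circle_radii_px,
                 nuclei_density = nuclei_density,
                 baseline_fos_p = baseline_fos_p,
                 receptor_probs = receptor_probs,
                 effect_map = effect_map, scratch = scratch,
                 min_center_sep = min_center_sep,
                 overlap_margin = overlap_margin, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a per-(region, cohort) Fos-probability map from archetypes
#'
#' Archetypes are region sets sharing one per-cohort probability profile —
#' the planted analogue of the response clusters. The sets must partition
#' the region grid exactly.
#'
#' @param archetypes list of `list(name=, regions=<pzs ids>, probs=)` where
#'   `probs` is a named numeric over the four cohorts.
#' @param regions data.frame of region keys (default: full 96-key grid).
#' @return data.frame (pzs_id, cohort, p, archetype).
#' @export
build_effect_map <- function(archetypes,
                             regions = enumerate_regions(
                               parcellation_config(excluded_regions = character(0)))) {
  all_ids <- sort(unlist(lapply(archetypes, `[[`, "regions")))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    stop("regions in more than one archetype: ", paste(dup, collapse = ", "))
  missing <- setdiff(regions$pzs_id, all_ids)
  if (length(missing))
    stop("regions not covered by any archetype: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(all_ids, regions$pzs_id)
  if (length(extra))
    stop("archetype regions outside the grid: ", paste(extra, collapse = ", "))
  out <- do.call(rbind, lapply(archetypes, function(a) {
    if (!all(COHORTS %in% names(a$probs)))
      stop("archetype '", a$name, "' lacks probabilities for all cohorts")
    if (any(a$probs < 0 | a$probs > 1))
      stop("archetype '", a$name, "' has probabilities outside [0, 1]")
    expand <- expand.grid(pzs_id = a$regions, cohort = COHORTS,
                          stringsAsFactors = FALSE)
    expand$p <- as.numeric(a$probs[expand$cohort])
    expand$archetype <- a$name
    expand
  }))
  rownames(out) <- NULL
  out
}

#' Default planted archetypes
#'
#' Five response profiles mirroring, qualitatively, the reference cluster
#' descriptions: one set high under all conditions except when spontaneous
#' scratching is blunted, one consistently low, one low and nail-dependent,
#' one high mainly when nails are intact, and one enhanced by histamine but
#' suppressed by clipping. Region sets are contiguous plane/zone blocks of
#' the grid (geography is synthetic).
#'
#' @return archetype list for [build_effect_map()].
#' @export
default_archetypes <- function() {
  grid <- enumerate_regions(parcellation_config(excluded_regions = character(0)))
  sel <- function(plane, zones)
    grid$pzs_id[grid$plane == plane & grid$zone %in% zones]
  list(
    list(name = "alpha", regions = sel("intermed", 1:2),
         probs = c(saline_intact = 0.20, saline_clipped = 0.10,
                   histamine_intact = 0.22, histamine_clipped = 0.12)),
    list(name = "beta", regions = sel("intermed", 3:4),
         probs = c(saline_intact = 0.25, saline_clipped = 0.15,
                   histamine_intact = 0.45, histamine_clipped = 0.30)),
    list(name = "gamma", regions = sel("caudal", 3:4),
         probs = c(saline_intact = 0.10, saline_clipped = 0.10,
                   histamine_intact = 0.10, histamine_clipped = 0.10)),
    list(name = "delta", regions = sel("rostral", 1:4),
         probs = c(saline_intact = 0.45, saline_clipped = 0.25,
                   histamine_intact = 0.45, histamine_clipped = 0.45)),
    list(name = "epsilon", regions = sel("caudal", 1:2),
         probs = c(saline_intact = 0.50, saline_clipped = 0.35,
                   histamine_intact = 0.55, histamine_clipped = 0.40))
  )
}

# Beta-distributed overlap fractions kept `margin` away from the threshold:
# positives in [thr + margin, 1], negatives in [0, thr - margin].
.sim_overlap <- function(positive, thr, margin) {
  n <- length(positive)
  b <- rbeta(n, 2, 2)
  lo_pos <- thr + margin
  hi_neg <- max(thr - margin, 0.001)
  ifelse(positive, lo_pos + (1 - lo_pos) * b, hi_neg * b)
}

#' Simulate the cell table of one section
#'
#' Nuclei are placed uniformly in the annulus between circles 1 and 5 (with
#' an optional hard-core minimum separation); Fos positivity is Bernoulli
#' with the probability of the cell's true region under the section's
#' cohort; the receptor pattern is drawn independently from
#' `receptor_probs`; overlap fractions land on the correct side of the
#' calling thresholds with margin `overlap_margin`.
#'
#' @param config a [sim_config()].
#' @param plane plane label.
#' @param cohort cohort label.
#' @param mouse mouse id (character).
#' @param seed integer seed; the generator is a pure function of
#'   (config, section, seed).
#' @param draw_overlaps if `FALSE`, overlap fractions are set to fixed
#'   margin-respecting values instead of Beta draws (fast path for
#'   large statistical simulations).
#' @return data.frame with positions (image px), true labels and overlaps;
#'   attribute `geometry` carries the section geometry.
#' @export
simulate_cells <- function(config, plane, cohort, mouse = "m1",
                           seed = config$seed, draw_overlaps = TRUE) {
  stopifnot(cohort %in% COHORTS, plane %in% config$planes)
  radii <- config$circle_radii_px[[plane]]
  center <- rep(ceiling(radii[5] + 20), 2)
  geometry <- aco_geometry(plane, center, radii)
  empty <- data.frame(mouse = character(0), cohort = character(0),
                      plane = character(0), x = numeric(0), y = numeric(0),
                      true_pzs = character(0), true_fos = logical(0),
                      true_drd1 = logical(0), true_drd2 = logical(0),
                      overlap_fos = numeric(0), overlap_drd1 = numeric(0),
                      overlap_drd2 = numeric(0))
  area <- pi * (radii[5]^2 - radii[1]^2)
  if (config$nuclei_density <= 0) {
    warning("nuclei density is zero: empty section")
    attr(empty, "geometry") <- geometry
    return(empty)
  }
  with_seed(seed, {
    n <- rpois(1, config$nuclei_density * area / 1e4)
    if (n == 0) {
      warning("no nuclei drawn for section")
      attr(empty, "geometry") <- geometry
      return(empty)
    }
    if (config$min_center_sep > 0) {
      # dart throwing for a hard-core process
      xs <- ys <- numeric(0)
      tries <- 0L
      while (length(xs) < n && tries < 50L * n) {
        r <- sqrt(runif(1, radii[1]^2, radii[5]^2))
        th <- runif(1, 0, 2 * pi)
        x <- r * cos(th); y <- r * sin(th)
        if (length(xs) == 0 ||
            min((xs - x)^2 + (ys - y)^2) >= config$min_center_sep^2) {
          xs <- c(xs, x); ys <- c(ys, y)
        }
        tries <- tries + 1L
      }
      dx <- xs; dy <- ys; n <- length(xs)
    } else {
      r <- sqrt(runif(n, radii[1]^2, radii[5]^2))
      th <- runif(n, 0, 2 * pi)
      dx <- r * cos(th); dy <- r * sin(th)
    }
    cells <- data.frame(
      mouse = mouse, cohort = cohort, plane = plane,
      x = center[1] + dx, y = center[2] - dy)  # anatomical -> image frame
    rr <- sqrt(dx^2 + dy^2)
    zone <- assign_zone(rr, geometry)
    sector <- assign_sector(dx, dy)
    in_grid <- zone %in% 1:4
    cells$true_pzs <- NA_character_
    cells$true_pzs[in_grid] <- pzs_encode(plane, zone[in_grid], sector[in_grid])
    p <- rep(config$baseline_fos_p, n)
    if (!is.null(config$effect_map)) {
      em <- config$effect_map
      em <- em[em$cohort == cohort, ]
      m <- match(cells$true_pzs, em$pzs_id)
      p[!is.na(m)] <- em$p[m[!is.na(m)]]
    }
    cells$true_fos <- rbinom(n, 1, p) == 1
    pat <- sample(c("d1", "d2", "both", "neither"), n, replace = TRUE,
                  prob = config$receptor_probs[c("d1", "d2", "both", "neither")])
    cells$true_drd1 <- pat %in% c("d1", "both")
    cells$true_drd2 <- pat %in% c("d2", "both")
    thr <- positivity_thresholds()
    mg <- config$overlap_margin
    if (draw_overlaps) {
      cells$overlap_fos <- .sim_overlap(cells$true_fos, thr$fos, mg)
      cells$overlap_drd1 <- .sim_overlap(cells$true_drd1, thr$drd1, mg)
      cells$overlap_drd2 <- .sim_overlap(cells$true_drd2, thr$drd2, mg)
    } else {
      cells$overlap_fos <- ifelse(cells$true_fos, thr$fos + mg,
                                  max(thr$fos - mg, 0) / 2)
      cells$overlap_drd1 <- ifelse(cells$true_drd1, thr$drd1 + mg,
                                   max(thr$drd1 - mg, 0) / 2)
      cells$overlap_drd2 <- ifelse(cells$true_drd2, thr$drd2 + mg,
                                   max(thr$drd2 - mg, 0) / 2)
    }
    attr(cells, "geometry") <- geometry
    cells
  })
}

#' Render a cell table into a multichannel section image
#'
#' The DAPI channel gets one bright disk per nucleus plus Gaussian noise;
#' each signal channel gets a coherent sub-region of every positive nucleus
#' covering that cell's overlap fraction (a chord cut of the disk). The
#' returned label mask is the ground truth per-pixel cell id.
#'
#' @param cells a cell table from [simulate_cells()] (needs x, y and
#'   overlap columns).
#' @param shape image (rows, cols); default fits all nuclei.
#' @param nucleus_radius disk radius, px.
#' @param intensity foreground intensity (all channels).
#' @param noise_sd Gaussian noise SD added to every channel.
#' @param seed seed for the noise.
#' @return list(image = [multichannel_image()], labels = truth mask).
#' @export
render_section <- function(cells, shape = NULL, nucleus_radius = 5,
                           intensity = 20000, noise_sd = 0, seed = 1L) {
  rad <- nucleus_radius
  if (is.null(shape)) {
    shape <- c(ceiling(max(cells$y, 0)) + rad + 10,
               ceiling(max(cells$x, 0)) + rad + 10)
  }
  nr <- shape[1]; nc <- shape[2]
  chans <- list(dapi = matrix(0, nr, nc), fos = matrix(0, nr, nc),
                drd1 = matrix(0, nr, nc), drd2 = matrix(0, nr, nc))
  labels <- matrix(0L, nr, nc)
  clipped <- FALSE
  for (i in seq_len(nrow(cells))) {
    # pixel-center coordinates: pixel (r, c) covers point (c-1, r-1)
    cx <- cells$x[i]; cy <- cells$y[i]
    rs <- max(1, floor(cy - rad) + 1):min(nr, ceiling(cy + rad) + 1)
    cs <- max(1, floor(cx - rad) + 1):min(nc, ceiling(cx + rad) + 1)
    if (cy - rad < 0 || cy + rad > nr - 1 || cx - rad < 0 || cx + rad > nc - 1)
      clipped <- TRUE
    if (!length(rs) || !length(cs)) next
    dy <- (rs - 1) - cy; dx <- (cs - 1) - cx
    disk <- outer(dy^2, dx^2, "+") <= rad^2
    if (!any(disk)) next
    sub <- which(disk, arr.ind = TRUE)
    rows <- rs[sub[, 1]]; cols <- cs[sub[, 2]]
    idx <- rows + (cols - 1) * nr
    chans$dapi[idx] <- intensity
    labels[idx] <- i
    # signal channels: chord cut covering the cell's overlap fraction
    ord <- order(cols, rows)
    for (nm in c("fos", "drd1", "drd2")) {
      f <- cells[[paste0("overlap_", nm)]][i]
      k <- round(f * length(idx))
      if (k > 0) chans[[nm]][idx[ord][seq_len(k)]] <- intensity
    }
  }
  if (clipped) warning("some nuclei extend beyond the canvas; clipped")
  with_seed(seed, {
    for (nm in names(chans)) {
      if (noise_sd > 0)
        chans[[nm]] <- chans[[nm]] + rnorm(nr * nc, 0, noise_sd)
      chans[[nm]][] <- pmin(pmax(round(chans[[nm]]), 0), 65535)
    }
    list(image = multichannel_image(chans$dapi, chans$fos, chans$drd1,
                                    chans$drd2),
         labels = labels)
  })
}

#' Simulate the scratch-bout series of one mouse
#'
#' @param cohort cohort label.
#' @param params a [scratch_params()].
#' @param seed integer seed.
#' @param window observation window in s around the injection (t = 0).
#' @return data.frame (onset_s, duration_s), onsets sorted.
#' @export
simulate_scratches <- function(cohort, params = scratch_params(),
                               seed = 1L, window = c(-900, 2700)) {
  stopifnot(cohort %in% COHORTS, window[1] <= 0, window[2] > 0)
  hist <- grepl("histamine", cohort)
  clip <- grepl("clipped", cohort)
  M <- (if (hist) params$histamine_mult else 1) *
    (if (clip) params$clip_mult else 1)
  base_s <- params$base_rate / 60   # bouts per second
  h_s <- params$decay_halflife_min * 60
  with_seed(seed, {
    # pre-injection: homogeneous Poisson
    n_pre <- rpois(1, base_s * (0 - window[1]))
    t_pre <- sort(runif(n_pre, window[1], 0))
    # post-injection: thinning under rate(t) = base*(1 + (M-1)*2^(-t/h))
    lam_max <- base_s * max(M, 1)
    n_cand <- rpois(1, lam_max * window[2])
    t_cand <- sort(runif(n_cand, 0, window[2]))
    rate <- if (is.finite(h_s)) {
      base_s * (1 + (M - 1) * 2^(-t_cand / h_s))
    } else rep(base_s * M, n_cand)
    t_post <- t_cand[runif(n_cand) < rate / lam_max]
    ml <- params$duration_meanlog
    ml_post <- ml + (if (hist) params$hist_duration_shift else 0) +
      (if (hist && clip) params$clip_duration_shift else 0)
    dur <- c(rlnorm(length(t_pre), ml, params$duration_sdlog),
             rlnorm(length(t_post), ml_post, params$duration_sdlog))
    data.frame(onset_s = c(t_pre, t_post), duration_s = dur)
  })
}

#' Simulate a full study
#'
#' One section per mouse per plane, plus one bout series per mouse; returns
#' cell tables, bout table, the effect map used, and per-plane geometry.
#' Everything is a pure function of (config, seed): per-section and
#' per-mouse sub-seeds are drawn once from the base seed.
#'
#' @param config a [sim_config()]; if it has no effect map, the default
#'   archetypes are used.
#' @param seed overrides `config$seed`.
#' @return list(cells, bouts, effect_map, geometry, config).
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  if (is.null(config$effect_map))
    config$effect_map <- build_effect_map(default_archetypes())
  mice <- data.frame(
    mouse = character(0), cohort = character(0), stringsAsFactors = FALSE)
  for (co in COHORTS) {
    n <- config$n_mice_per_cohort[[co]]
    if (n > 0)
      mice <- rbind(mice, data.frame(
        mouse = sprintf("%s_m%02d", co, seq_len(n)), cohort = co))
  }
  n_sections <- nrow(mice) * length(config$planes)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    n_sections + nrow(mice)))
  cells <- vector("list", n_sections)
  geometry <- list()
  k <- 0L
  for (i in seq_len(nrow(mice))) {
    for (pl in config$planes) {
      k <- k + 1L
      tab <- simulate_cells(config, pl, mice$cohort[i], mice$mouse[i],
                            seed = sub[k])
      tab$section <- paste0(mice$mouse[i], "_", pl)
      geometry[[pl]] <- attr(tab, "geometry")
      cells[[k]] <- tab
    }
  }
  bouts <- vector("list", nrow(mice))
  for (i in seq_len(nrow(mice))) {
    b <- simulate_scratches(mice$cohort[i], config$scratch,
                            seed = sub[n_sections + i])
    if (nrow(b)) {
      b$mouse <- mice$mouse[i]
      b$cohort <- mice$cohort[i]
    } else {
      b$mouse <- character(0); b$cohort <- character(0)
    }
    bouts[[i]] <- b
  }
  list(cells = do.call(rbind, cells), bouts = do.call(rbind, bouts),
       effect_map = config$effect_map, geometry = geometry, config = config)
}
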