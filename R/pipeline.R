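# Configuration, delimited-text readers/writers with a format-version
# field, run manifests, and end-to-end orchestration of the stages.

TABLE_FORMAT_VERSION <- 1L

#' Write / read a delimited table with a format-version header
#'
#' Tab-separated, a single comment line `# enacmap_table_version=<v>`
#' before the column header. Output is byte-deterministic for identical
#' input.
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_versioned <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# enacmap_table_version=%d", TABLE_FORMAT_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_versioned
#' @export
read_table_versioned <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# enacmap_table_version=", first))
    stop("missing format-version field: ", path)
  read.delim(path, skip = 1, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the simulation configuration, segmentation and positivity
#' parameters, parcellation options and statistics options. Statistics
#' defaults follow the reference analysis design: FDR threshold Q < 0.1, Spearman
#' significance P < 0.1, composition chi-square marker P < 0.005, five
#' clusters.
#'
#' @param sim a [sim_config()].
#' @param segmentation a [segmentation_params()].
#' @param thresholds a [positivity_thresholds()].
#' @param parcellation a [parcellation_config()].
#' @param q_threshold,spearman_alpha,chisq_alpha,cluster_k statistics
#'   options.
#' @param var_equal pooled-variance t tests instead of Welch.
#' @param render_demo if `TRUE`, the segment stage renders and re-segments
#'   one small synthetic section to exercise the imaging stack; the main
#'   quantification always runs on the simulated cell tables.
#' @param seed base seed.
#' @export
pipeline_config <- function(sim = sim_config(),
                            segmentation = segmentation_params(),
                            thresholds = positivity_thresholds(),
                            parcellation = parcellation_config(),
                            q_threshold = 0.1, spearman_alpha = 0.1,
                            chisq_alpha = 0.005, cluster_k = 5,
                            var_equal = FALSE, render_demo = FALSE,
                            seed = 1L) {
  stopifnot(q_threshold > 0, q_threshold < 1,
            spearman_alpha > 0, spearman_alpha < 1,
            chisq_alpha > 0, chisq_alpha < 1, cluster_k >= 1)
  structure(list(sim = sim, segmentation = segmentation,
                 thresholds = thresholds, parcellation = parcellation,
                 q_threshold = q_threshold, spearman_alpha = spearman_alpha,
                 chisq_alpha = chisq_alpha, cluster_k = cluster_k,
                 var_equal = var_equal, render_demo = render_demo,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# flatten a config into plain lists for the JSON manifest
.config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), .config_as_list) else x
}

.require_stage_input <- function(path, stage, producer) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs '", basename(path),
         "'; run stage '", producer, "' first", call. = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: `simulate` (cell tables + bout series), `segment` (optional
#' small rendered-image demo of the imaging stack), `quantify` (positivity
#' calls and per-region tabulation), `stats` (the four cohort comparisons
#' with FDR classes, receptor tests, composition tests), `correlate`
#' (scratch-Fos maps per cohort), `cluster` (fraction- and rho-mode
#' hierarchical clustering), `behavior` (bin summaries and cohort
#' comparisons). Every run writes a manifest with the config and seed;
#' rerunning with the same config and seed reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param stages subset of stages to run (`"all"` = everything); later
#'   stages read their inputs from `out_dir`.
#' @return (invisibly) list of in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = "all") {
  all_stages <- c("simulate", "segment", "quantify", "stats", "correlate",
                  "cluster", "behavior")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  pth <- function(f) file.path(out_dir, f)

  if ("simulate" %in% stages) {
    study <- simulate_study(config$sim, seed = config$seed)
    write_table_versioned(study$cells, pth("cells.tsv"))
    write_table_versioned(study$bouts, pth("bouts.tsv"))
    write_table_versioned(study$effect_map, pth("effect_map.tsv"))
    for (pl in names(study$geometry))
      write_geometry(study$geometry[[pl]],
                     pth(sprintf("geometry_%s.json", pl)))
    res$study <- study
  }

  if ("segment" %in% stages && config$render_demo) {
    # small-scale exercise of the imaging stack: render one section with
    # reduced geometry and re-segment it
    demo_cfg <- config$sim
    demo_cfg$circle_radii_px <- list(intermed = c(40, 85, 125, 180, 235))
    demo_cfg$nuclei_density <- 2
    demo_cfg$min_center_sep <- 16
    cells <- simulate_cells(demo_cfg, "intermed", "saline_intact",
                            seed = config$seed + 1L)
    rend <- render_section(cells, nucleus_radius = 5, noise_sd = 1500,
                           seed = config$seed + 2L)
    write_section_tiff(rend$image, pth("demo_section.tif"))
    seg <- segment_section(rend$image, config$segmentation)
    write_tiff16(matrix(as.integer(seg$labels), nrow(seg$labels)),
                 pth("demo_labels.tif"))
    write_table_versioned(seg$rois, pth("demo_rois.tsv"))
    res$segment_demo <- seg
  }

  if ("quantify" %in% stages) {
    cells <- res$study$cells
    if (is.null(cells))
      cells <- read_table_versioned(
        .require_stage_input(pth("cells.tsv"), "quantify", "simulate"))
    # parcellate from coordinates and geometry (not from the truth labels)
    parts <- lapply(split(cells, cells$plane), function(part) {
      pl <- part$plane[1]
      geom <- if (!is.null(res$study)) res$study$geometry[[pl]] else
        read_geometry(.require_stage_input(
          pth(sprintf("geometry_%s.json", pl)), "quantify", "simulate"))
      assign_cells_to_regions(part, geom, config$parcellation)
    })
    cells <- do.call(rbind, parts)
    rownames(cells) <- NULL
    called <- call_positivity(cells, config$thresholds)
    counts <- tabulate_regions(called, config$parcellation)
    write_table_versioned(counts, pth("region_counts.tsv"))
    res$counts <- counts
    layers <- lapply(setNames(COHORTS, COHORTS), function(co)
      aggregate_condition(counts, co,
                          regions = enumerate_regions(config$parcellation)))
    for (co in COHORTS)
      write_table_versioned(layers[[co]],
                            pth(sprintf("mean_fraction_%s.tsv", co)))
    jsonlite::write_json(
      lapply(layers, function(l) setNames(as.list(l$mean_value), l$pzs_id)),
      pth("zone_sector_maps.json"), auto_unbox = TRUE, digits = NA)
    res$layers <- layers
  }

  get_counts <- function(stage) {
    if (!is.null(res$counts)) return(res$counts)
    read_table_versioned(
      .require_stage_input(pth("region_counts.tsv"), stage, "quantify"))
  }

  comparisons <- list(
    histamine_vs_saline_intact = c("saline_intact", "histamine_intact"),
    histamine_vs_saline_clipped = c("saline_clipped", "histamine_clipped"),
    clipped_vs_intact_saline = c("saline_intact", "saline_clipped"),
    clipped_vs_intact_histamine = c("histamine_intact", "histamine_clipped"))

  if ("stats" %in% stages) {
    counts <- get_counts("stats")
    regions <- enumerate_regions(config$parcellation)
    res$comparisons <- list()
    for (nm in names(comparisons)) {
      co <- comparisons[[nm]]
      cmp <- region_t_map(counts[counts$cohort == co[1], ],
                          counts[counts$cohort == co[2], ],
                          var_equal = config$var_equal,
                          q_threshold = config$q_threshold,
                          regions = regions)
      write_table_versioned(cmp, pth(sprintf("t_map_%s.tsv", nm)))
      res$comparisons[[nm]] <- cmp
      # receptor fractions and composition by response class, within the
      # second-listed (treatment) cohort
      sub <- counts[counts$cohort == co[2] & counts$valid, ]
      cls <- cmp$class[match(sub$pzs_id, cmp$pzs_id)]
      keep <- cls %in% c("increased", "decreased", "insensitive")
      if (length(unique(cls[keep])) >= 2) {
        per_region_d1 <- tapply(sub$fraction_drd1[keep], sub$pzs_id[keep], mean)
        per_region_cls <- tapply(cls[keep], sub$pzs_id[keep], function(x) x[1])
        rec <- try(receptor_fraction_tests(as.numeric(per_region_d1),
                                           as.character(per_region_cls)),
                   silent = TRUE)
        if (!inherits(rec, "try-error"))
          jsonlite::write_json(rec, pth(sprintf("receptor_tests_%s.json", nm)),
                               auto_unbox = TRUE, digits = NA, force = TRUE)
        pat_cols <- paste0("n_fos_", c("D1pD2p", "D1pD2n", "D1nD2p", "D1nD2n"))
        tab <- rowsum(as.matrix(sub[keep, pat_cols]), cls[keep])
        if (nrow(tab) >= 2 && all(rowSums(tab) > 0)) {
          comp <- composition_chisq(tab, config$chisq_alpha)
          jsonlite::write_json(comp, pth(sprintf("composition_%s.json", nm)),
                               auto_unbox = TRUE, digits = NA, force = TRUE)
        }
      }
    }
  }

  if ("correlate" %in% stages) {
    counts <- get_counts("correlate")
    bouts <- res$study$bouts
    if (is.null(bouts))
      bouts <- read_table_versioned(
        .require_stage_input(pth("bouts.tsv"), "correlate", "simulate"))
    totals <- scratch_totals(bouts)
    write_table_versioned(totals, pth("scratch_totals.tsv"))
    res$correlations <- list()
    for (co in COHORTS) {
      cm <- scratch_fos_correlation(
        counts, totals, cohort = co, alpha = config$spearman_alpha,
        regions = enumerate_regions(config$parcellation))
      write_table_versioned(cm, pth(sprintf("correlation_%s.tsv", co)))
      res$correlations[[co]] <- cm
    }
  }

  if ("cluster" %in% stages) {
    if (is.null(res$layers)) {
      layers <- lapply(setNames(COHORTS, COHORTS), function(co) {
        f <- .require_stage_input(pth(sprintf("mean_fraction_%s.tsv", co)),
                                  "cluster", "quantify")
        read_table_versioned(f)
      })
    } else layers <- res$layers
    modes <- list(fraction = layers)
    if (!is.null(res$correlations)) {
      rho_layers <- lapply(res$correlations, function(cm)
        setNames(cm$rho, cm$pzs_id))
      modes$rho <- rho_layers
    }
    res$clustering <- list()
    for (mode in names(modes)) {
      m <- build_feature_matrix(modes[[mode]], mode = mode)
      hc <- hierarchical_cluster(m)
      cl <- cut_dendrogram(hc, k = config$cluster_k)
      prof <- cluster_profiles(cl, m)
      write_table_versioned(
        data.frame(pzs_id = names(cl), cluster = as.integer(cl)),
        pth(sprintf("clusters_%s.tsv", mode)))
      write_table_versioned(
        data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                   height = hc$height),
        pth(sprintf("cluster_merges_%s.tsv", mode)))
      write_table_versioned(
        data.frame(cluster = rownames(prof), prof, row.names = NULL),
        pth(sprintf("cluster_profiles_%s.tsv", mode)))
      res$clustering[[mode]] <- list(matrix = m, hclust = hc,
                                     assignment = cl, profiles = prof)
    }
  }

  if ("behavior" %in% stages) {
    bouts <- res$study$bouts
    if (is.null(bouts))
      bouts <- read_table_versioned(
        .require_stage_input(pth("bouts.tsv"), "behavior", "simulate"))
    res$behavior <- group_comparisons(bouts)
    write_table_versioned(res$behavior$totals, pth("behavior_totals.tsv"))
    write_table_versioned(res$behavior$per_bin_anova,
                          pth("behavior_per_bin.tsv"))
    write_table_versioned(res$behavior$duration_tests,
                          pth("behavior_durations.tsv"))
  }

  manifest <- list(
    package = "enacmap",
    version = as.character(utils::packageVersion("enacmap")),
    seed = config$seed,
    stages = stages,
    config = .config_as_list(config),
    files = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
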