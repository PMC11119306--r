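# Per-cell positivity calling, co-expression patterns, and per-region
# count/fraction tables.

RECEPTOR_PATTERNS <- c("D1+D2+", "D1+D2-", "D1-D2+", "D1-D2-")

#' Positivity thresholds on overlap fractions
#'
#' A cell is called positive for a channel when its binarized-signal
#' overlap with the DAPI ROI is at least the threshold (inclusive — "15%
#' or more"): Drd1 >= 0.15, Fos >= 0.20, Drd2 >= 0.30.
#'
#' @param drd1,fos,drd2 thresholds in (0, 1].
#' @export
positivity_thresholds <- function(drd1 = 0.15, fos = 0.20, drd2 = 0.30) {
  v <- c(drd1 = drd1, fos = fos, drd2 = drd2)
  if (any(v <= 0 | v > 1)) stop("thresholds must be in (0, 1]")
  structure(as.list(v), class = "positivity_thresholds")
}

#' Call per-cell positivity and co-expression pattern
#'
#' Adds boolean calls for Fos/Drd1/Drd2, the receptor pattern of every cell
#' (one of `D1+D2+`, `D1+D2-`, `D1-D2+`, `D1-D2-`), and `fos_pattern`: the
#' receptor pattern of Fos-positive cells (NA for Fos-negative cells).
#'
#' @param cells data.frame with `overlap_fos`, `overlap_drd1`,
#'   `overlap_drd2` in \[0, 1\].
#' @param thresholds a [positivity_thresholds()].
#' @return `cells` with call columns added.
#' @export
call_positivity <- function(cells, thresholds = positivity_thresholds()) {
  ov <- cells[c("overlap_fos", "overlap_drd1", "overlap_drd2")]
  if (any(unlist(ov) < 0 | unlist(ov) > 1, na.rm = TRUE))
    stop("overlap fractions must be in [0, 1]")
  cells$fos_pos <- cells$overlap_fos >= thresholds$fos
  cells$drd1_pos <- cells$overlap_drd1 >= thresholds$drd1
  cells$drd2_pos <- cells$overlap_drd2 >= thresholds$drd2
  cells$receptor_pattern <- paste0(
    ifelse(cells$drd1_pos, "D1+", "D1-"),
    ifelse(cells$drd2_pos, "D2+", "D2-"))
  cells$fos_pattern <- ifelse(cells$fos_pos, cells$receptor_pattern,
                              NA_character_)
  cells
}

#' Tabulate per-region counts and fractions
#'
#' One row per (mouse, section, region): DAPI count, per-channel positive
#' counts, the four receptor-pattern counts over all cells and over
#' Fos-positive cells, `fraction_fos = n_fos / n_dapi`, and a validity flag
#' from the DAPI count.
#'
#' @param cells called cells with a `pzs_id` column (from
#'   [assign_cells_to_regions()]) or a `true_pzs` column; out-of-analysis
#'   cells (NA region) are ignored.
#' @param config a [parcellation_config()] (for the validity threshold).
#' @return data.frame of region counts.
#' @export
tabulate_regions <- function(cells, config = parcellation_config()) {
  if (!"pzs_id" %in% names(cells) && "true_pzs" %in% names(cells))
    cells$pzs_id <- cells$true_pzs
  if (!"section" %in% names(cells)) cells$section <- "s1"
  if (!"mouse" %in% names(cells)) cells$mouse <- "m1"
  if (!"cohort" %in% names(cells)) cells$cohort <- NA_character_
  cells <- cells[!is.na(cells$pzs_id) &
                   !(cells$pzs_id %in% config$excluded_regions), ]
  if (nrow(cells) == 0)
    return(data.frame(mouse = character(0), section = character(0),
                      cohort = character(0), pzs_id = character(0),
                      n_dapi = integer(0), n_fos = integer(0),
                      n_drd1 = integer(0), n_drd2 = integer(0),
                      fraction_fos = numeric(0), valid = logical(0)))
  cells$cohort[is.na(cells$cohort)] <- "none"
  key <- paste(cells$mouse, cells$section, cells$cohort, cells$pzs_id,
               sep = "\r")
  agg <- function(x) {
    s <- rowsum(as.numeric(x), key)   # rows sorted by key
    as.vector(s)
  }
  meta <- cells[!duplicated(key), c("mouse", "section", "cohort", "pzs_id")]
  meta <- meta[order(key[!duplicated(key)]), ]
  out <- data.frame(
    meta,
    n_dapi = agg(rep(1, nrow(cells))),
    n_fos = agg(cells$fos_pos),
    n_drd1 = agg(cells$drd1_pos),
    n_drd2 = agg(cells$drd2_pos),
    row.names = NULL)
  for (pat in RECEPTOR_PATTERNS) {
    nm <- gsub("[+]", "p", gsub("-", "n", pat))
    out[[paste0("n_all_", nm)]] <- agg(cells$receptor_pattern == pat)
    out[[paste0("n_fos_", nm)]] <-
      agg(cells$fos_pos & cells$receptor_pattern == pat)
  }
  out$fraction_fos <- out$n_fos / out$n_dapi
  out$fraction_drd1 <- out$n_drd1 / out$n_dapi
  out$fraction_drd2 <- out$n_drd2 / out$n_dapi
  out$valid <- region_validity(out$n_dapi, config)
  out
}

#' Mean regional Fos fraction over the cases of one cohort
#'
#' The case unit is one section; the mean is unweighted over cases ("mean
#' of the fraction"), with a cell-weighted pooled alternative behind
#' `weighted = TRUE`. Invalid regions (too few DAPI ROIs) are dropped
#' before averaging; a region missing in every case yields NA.
#'
#' @param counts region-count table from [tabulate_regions()].
#' @param cohort cohort label to aggregate (NULL = all rows).
#' @param value column to average.
#' @param weighted cell-count weighting flag.
#' @param regions region keys defining the output rows.
#' @return data.frame (pzs_id, mean_value, n_cases).
#' @export
aggregate_condition <- function(counts, cohort = NULL,
                                value = "fraction_fos", weighted = FALSE,
                                regions = enumerate_regions()) {
  if (!is.null(cohort)) counts <- counts[counts$cohort %in% cohort, ]
  counts <- counts[counts$valid, ]
  out <- data.frame(pzs_id = regions$pzs_id, mean_value = NA_real_,
                    n_cases = 0L, stringsAsFactors = FALSE)
  if (nrow(counts)) {
    if (weighted) {
      num <- tapply(counts[[value]] * counts$n_dapi, counts$pzs_id, sum)
      den <- tapply(counts$n_dapi, counts$pzs_id, sum)
      mv <- num / den
    } else {
      mv <- tapply(counts[[value]], counts$pzs_id, mean)
    }
    nc <- tapply(counts[[value]], counts$pzs_id, length)
    m <- match(out$pzs_id, names(mv))
    out$mean_value <- as.numeric(mv[m])
    out$n_cases <- ifelse(is.na(m), 0L, as.integer(nc[m]))
  }
  out
}
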