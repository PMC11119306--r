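# Hierarchical clustering of regions by their 4-condition response
# profiles (mean Fos fractions or scratch-Fos correlations).

#' Assemble the region-by-condition feature matrix
#'
#' Rows are regions, columns the four cohort conditions in fixed order
#' (saline-intact, saline-clipped, histamine-intact, histamine-clipped)
#' regardless of input order. Rows with any missing value are dropped and
#' reported via the `"dropped"` attribute — with the default grid and one
#' unusable region this reproduces the 95 complete rows used in the
#' 95-region reference clustering.
#'
#' @param layers named list of the four per-cohort layers, each a
#'   data.frame (pzs_id, mean_value) as returned by
#'   [aggregate_condition()] or a named numeric vector keyed by pzs_id.
#' @param mode `"fraction"` (values in \[0, 1\]) or `"rho"` (\[-1, 1\]);
#'   used for validation only.
#' @param drop_incomplete drop rows with missing values (default) instead
#'   of erroring.
#' @return numeric matrix with rownames = pzs_id.
#' @export
build_feature_matrix <- function(layers, mode = c("fraction", "rho"),
                                 drop_incomplete = TRUE) {
  mode <- match.arg(mode)
  if (!all(COHORTS %in% names(layers)))
    stop("layers must be named by the four cohorts")
  as_vec <- function(l) {
    if (is.data.frame(l)) {
      v <- l[[if ("mean_value" %in% names(l)) "mean_value" else "rho"]]
      names(v) <- l$pzs_id
      v
    } else l
  }
  vecs <- lapply(layers[COHORTS], as_vec)
  ids <- sort(unique(unlist(lapply(vecs, names))))
  m <- sapply(vecs, function(v) as.numeric(v[ids]))
  rownames(m) <- ids
  lims <- if (mode == "fraction") c(0, 1) else c(-1, 1)
  if (any(m < lims[1] - 1e-9 | m > lims[2] + 1e-9, na.rm = TRUE))
    stop("values outside the valid range for mode '", mode, "'")
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    if (!drop_incomplete) stop("missing values in the feature matrix")
    dropped <- rownames(m)[!complete]
    m <- m[complete, , drop = FALSE]
    attr(m, "dropped") <- dropped
  }
  if (nrow(m) < 2) stop("fewer than 2 complete regions")
  m
}

#' Agglomerative clustering of the feature matrix
#'
#' Euclidean distance (Minkowski order 2) with complete linkage; merge
#' heights are non-decreasing. Ties are resolved by the deterministic
#' lowest-index convention of the underlying agglomeration.
#'
#' @param m feature matrix from [build_feature_matrix()].
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(m) {
  if (anyNA(m)) stop("feature matrix contains missing values")
  hclust(dist(m, method = "euclidean"), method = "complete")
}

#' Cut the dendrogram into clusters
#'
#' @param hc an `hclust` from [hierarchical_cluster()].
#' @param k number of clusters (default 5, the number of response
#'   archetypes reported); alternatively cut at height `h`.
#' @return named integer vector region -> cluster label.
#' @export
cut_dendrogram <- function(hc, k = 5, h = NULL) {
  if (!is.null(h)) return(cutree(hc, h = h))
  n <- length(hc$order)
  cutree(hc, k = min(k, n))
}

#' Per-cluster mean response profiles
#'
#' @param assignment named cluster labels from [cut_dendrogram()].
#' @param m the clustered feature matrix.
#' @return matrix clusters x conditions of unweighted member means.
#' @export
cluster_profiles <- function(assignment, m) {
  stopifnot(all(names(assignment) %in% rownames(m)))
  mm <- m[names(assignment), , drop = FALSE]
  prof <- rowsum(mm, assignment) / as.vector(table(assignment))
  prof
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
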