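#' Multichannel section image container
#'
#' Four single-channel intensity matrices with 16-bit semantics (values in
#' \[0, 65535\]), all the same shape. Matrix rows are image y (downward),
#' columns are image x.
#'
#' @param dapi,fos,drd1,drd2 numeric matrices of identical dimension.
#' @param pixel_size_um micrometres per pixel.
#' @export
multichannel_image <- function(dapi, fos, drd1, drd2, pixel_size_um = 0.585) {
  ch <- list(dapi = dapi, fos = fos, drd1 = drd1, drd2 = drd2)
  dims <- vapply(ch, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all channels must have the same shape")
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    stop("intensities must be non-negative")
  structure(c(ch, list(pixel_size_um = pixel_size_um)),
            class = "multichannel_image")
}

#' Segmentation parameters
#'
#' Particle filters mirror the interactive size/circularity cursors of the
#' original ROI selection; no canonical values exist for them, so the
#' defaults here are explicit and logged in every run manifest.
#'
#' @param dapi_method auto-threshold method for the nuclear channel.
#' @param signal_method auto-threshold method for Fos/Drd1/Drd2.
#' @param min_area,max_area particle area filter, px^2.
#' @param min_circularity particle circularity filter (4*pi*A/P^2).
#' @param renyi_alpha order of the Renyi-entropy criterion.
#' @param min_peak_sep minimum separation (px) of watershed seed maxima;
#'   `NULL` = estimate one nucleus radius from the median blob area.
#' @param exclusion_polygons list of data.frames (columns x, y) outlining
#'   manually flagged artifacts; ROIs whose centroid falls inside are
#'   flagged, not deleted.
#' @export
segmentation_params <- function(dapi_method = "huang",
                                signal_method = "renyi_entropy",
                                min_area = 30, max_area = 500,
                                min_circularity = 0.3,
                                renyi_alpha = 2,
                                min_peak_sep = NULL,
                                exclusion_polygons = list()) {
  stopifnot(min_area > 0, max_area > min_area,
            min_circularity >= 0, min_circularity <= 1, renyi_alpha > 0)
  structure(list(dapi_method = dapi_method, signal_method = signal_method,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 renyi_alpha = renyi_alpha, min_peak_sep = min_peak_sep,
                 exclusion_polygons = exclusion_polygons),
            class = "segmentation_params")
}

# 256-bin histogram over [min, max]; returns bin centers and counts.
# Binning to 256 grey levels mirrors how ImageJ-style auto-thresholders
# treat 16-bit images.
.grey_hist <- function(channel, n_bins = 256L) {
  lo <- min(channel); hi <- max(channel)
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((channel - lo) / width), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  list(centers = centers, counts = counts, lo = lo, hi = hi)
}

# Huang-Wang fuzziness for every candidate threshold; returns the vector of
# fuzziness values (index t = foreground strictly above bin t).
.huang_criterion <- function(centers, counts) {
  L <- length(centers)
  w <- counts
  cw <- cumsum(w); cwx <- cumsum(w * centers)
  n <- cw[L]; total <- cwx[L]
  C <- centers[L] - centers[1]
  crit <- rep(NA_real_, L - 1)
  for (t in seq_len(L - 1)) {
    n0 <- cw[t]; n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cwx[t] / n0
    mu1 <- (total - cwx[t]) / n1
    mu <- ifelse(seq_len(L) <= t,
                 1 / (1 + abs(centers - mu0) / C),
                 1 / (1 + abs(centers - mu1) / C))
    # Shannon entropy of fuzzy membership; mu in [0.5, 1] so 1-mu safe via
    # the x*log(x) convention 0*log(0) = 0
    h <- -mu * log(mu) - ifelse(mu < 1, (1 - mu) * log(1 - mu), 0)
    crit[t] <- sum(w * h)
  }
  crit
}

# Renyi entropy sum H_alpha(background) + H_alpha(foreground) per candidate
# threshold (Sahoo-style criterion, single configurable order).
.renyi_criterion <- function(centers, counts, alpha = 2) {
  L <- length(centers)
  p <- counts / sum(counts)
  cp <- cumsum(p)
  crit <- rep(NA_real_, L - 1)
  for (t in seq_len(L - 1)) {
    P0 <- cp[t]; P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    if (abs(alpha - 1) < 1e-9) {
      q0 <- p[1:t] / P0; q0 <- q0[q0 > 0]
      q1 <- p[(t + 1):L] / P1; q1 <- q1[q1 > 0]
      crit[t] <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    } else {
      h0 <- log(sum((p[1:t] / P0)^alpha)) / (1 - alpha)
      h1 <- log(sum((p[(t + 1):L] / P1)^alpha)) / (1 - alpha)
      crit[t] <- h0 + h1
    }
  }
  crit
}

#' Automatic intensity threshold
#'
#' Computes a global threshold on a 256-bin grey histogram. `"huang"`
#' minimizes the Huang-Wang fuzziness measure (Shannon entropy of the fuzzy
#' membership to the two class means); `"renyi_entropy"` maximizes the sum
#' of Renyi entropies of the background and foreground distributions
#' (order `alpha`, default 2). Pixels strictly above the returned intensity
#' are foreground.
#'
#' @param channel numeric matrix of intensities.
#' @param method `"huang"` or `"renyi_entropy"`.
#' @param alpha Renyi order (ignored for Huang).
#' @param n_bins histogram bins.
#' @param name channel name used in error messages.
#' @return threshold intensity (scalar).
#' @export
auto_threshold <- function(channel, method = c("huang", "renyi_entropy"),
                           alpha = 2, n_bins = 256L, name = "channel") {
  method <- match.arg(method)
  if (length(unique(as.vector(channel))) < 2L)
    stop("cannot threshold constant image: ", name)
  h <- .grey_hist(channel, n_bins)
  crit <- switch(method,
    huang = .huang_criterion(h$centers, h$counts),
    renyi_entropy = .renyi_criterion(h$centers, h$counts, alpha))
  t_idx <- if (method == "huang") which.min(crit) else which.max(crit)
  # threshold at the upper edge of bin t_idx: pixels > threshold are fg
  h$lo + t_idx * (h$hi - h$lo) / length(h$centers)
}

#' Split touching nuclei by distance-transform watershed
#'
#' Each connected foreground component is split at necks between local
#' maxima of the Euclidean distance transform; maxima closer together than
#' `min_peak_sep` are merged (greedy suppression, highest peak wins) so
#' single bumpy nuclei are not over-segmented.
#'
#' @param mask logical matrix, foreground `TRUE`.
#' @param min_peak_sep minimum seed separation in px; `NULL` = radius of
#'   the median-area blob, `sqrt(median_area / pi)`.
#' @return integer label matrix (0 = background).
#' @export
split_touching <- function(mask, min_peak_sep = NULL) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  comp <- cpp_label_components(mask)
  edt <- cpp_edt(mask)
  if (is.null(min_peak_sep)) {
    areas <- tabulate(comp[comp > 0])
    min_peak_sep <- max(2, sqrt(median(areas) / pi))
  }
  # local maxima of the EDT (8-neighborhood, plateaus included)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- ifelse(mask, edt, -Inf)
  nmax <- pad[2:(nr + 1), 2:(nc + 1)]
  is_max <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max &
      nmax >= pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  cand <- which(is_max)
  ord <- order(-edt[cand], cand)
  cand <- cand[ord]
  cy <- (cand - 1) %% nr; cx <- (cand - 1) %/% nr
  keep <- logical(length(cand))
  kx <- ky <- numeric(0)
  for (i in seq_along(cand)) {
    if (length(kx) == 0 ||
        min((kx - cx[i])^2 + (ky - cy[i])^2) >= min_peak_sep^2) {
      keep[i] <- TRUE
      kx <- c(kx, cx[i]); ky <- c(ky, cy[i])
    }
  }
  seeds <- matrix(0L, nr, nc)
  seeds[cand[keep]] <- seq_len(sum(keep))
  cpp_watershed(edt, seeds, mask)
}

# point-in-polygon (even-odd ray casting), vectorized over points
.in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]; xj <- poly$x[j]; yj <- poly$y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Particle analysis of a label mask
#'
#' Measures per-label area, chain-code perimeter, centroid (0-based,
#' pixel-center coordinates) and circularity `4*pi*A/P^2` (capped at 1,
#' as is conventional, since the digital perimeter of small particles can
#' push the raw value above 1). Records failing the size or circularity
#' filters are flagged `excluded`; records whose centroid falls inside an
#' exclusion polygon are flagged `artifact`. Nothing is deleted.
#'
#' @param labels integer label matrix.
#' @param params a [segmentation_params()].
#' @return data.frame of ROI records.
#' @export
particle_analysis <- function(labels, params = segmentation_params()) {
  nlab <- max(labels)
  if (nlab == 0)
    return(data.frame(roi_id = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), excluded = logical(0),
                      artifact = logical(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  nr <- nrow(labels)
  px_x <- (idx - 1) %/% nr   # 0-based column = image x
  px_y <- (idx - 1) %% nr    # 0-based row    = image y
  area <- tabulate(lab, nbins = nlab)
  cx <- as.vector(rowsum(px_x, lab)) / area
  cy <- as.vector(rowsum(px_y, lab)) / area
  per <- cpp_perimeters(labels, nlab, 1, sqrt(2))
  circ <- pmin(4 * pi * area / per^2, 1)
  excluded <- area < params$min_area | area > params$max_area |
    circ < params$min_circularity
  artifact <- rep(FALSE, nlab)
  for (poly in params$exclusion_polygons)
    artifact <- artifact | .in_polygon(cx, cy, poly)
  data.frame(roi_id = seq_len(nlab), x = cx, y = cy, area = area,
             perimeter = per, circularity = circ,
             excluded = excluded, artifact = artifact)
}

#' Per-ROI overlap with binarized signal channels
#'
#' The overlap fraction of an ROI with a channel is the share of its pixels
#' that are signal-positive after binarization — the quantity the
#' positivity thresholds (15/20/30%) are applied to.
#'
#' @param labels integer label matrix of the ROIs.
#' @param signal_masks named list of logical matrices (same shape).
#' @return data.frame with `roi_id` and one `overlap_<name>` column per
#'   channel.
#' @export
measure_overlaps <- function(labels, signal_masks) {
  nlab <- max(labels)
  if (nlab == 0) stop("no ROIs to measure")
  idx <- which(labels > 0)
  lab <- labels[idx]
  out <- data.frame(roi_id = seq_len(nlab))
  for (nm in names(signal_masks)) {
    m <- signal_masks[[nm]]
    if (!all(dim(m) == dim(labels)))
      stop("signal mask shape mismatch: ", nm)
    s <- rowsum(as.numeric(m[idx]), lab)
    out[[paste0("overlap_", nm)]] <- as.vector(s) / tabulate(lab, nbins = nlab)
  }
  out
}

#' Segment one multichannel section
#'
#' Runs the full image-to-ROI stack: Huang threshold on DAPI, watershed
#' splitting, particle analysis, Renyi-entropy binarization of the three
#' signal channels, and per-ROI overlap measurement.
#'
#' @param image a [multichannel_image()].
#' @param params a [segmentation_params()].
#' @return list with `rois` (ROI table joined with overlap fractions),
#'   `labels` (label matrix), and `thresholds`.
#' @export
segment_section <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "multichannel_image"))
  thr_dapi <- auto_threshold(image$dapi, params$dapi_method, name = "dapi")
  labels <- split_touching(image$dapi > thr_dapi, params$min_peak_sep)
  rois <- particle_analysis(labels, params)
  thr <- c(dapi = thr_dapi)
  masks <- list()
  for (nm in c("fos", "drd1", "drd2")) {
    t_nm <- auto_threshold(image[[nm]], params$signal_method,
                           alpha = params$renyi_alpha, name = nm)
    thr[nm] <- t_nm
    masks[[nm]] <- image[[nm]] > t_nm
  }
  if (nrow(rois) > 0) {
    ov <- measure_overlaps(labels, masks)
    rois <- merge(rois, ov, by = "roi_id", sort = TRUE)
  } else {
    rois$overlap_fos <- rois$overlap_drd1 <- rois$overlap_drd2 <- numeric(0)
  }
  list(rois = rois, labels = labels, thresholds = thr)
}
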