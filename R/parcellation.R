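#' @useDynLib enacmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate aov chisq.test cutree dist hclust kruskal.test
#'   median pt quantile rbeta rbinom rlnorm rnorm rpois runif sd setNames
#'   t.test var wilcox.test complete.cases qt
#' @importFrom utils head read.delim write.table packageVersion
"_PACKAGE"

# Plane labels and their leading digit in the three-digit region code.
PLANE_CODES <- c(rostral = 1L, intermed = 2L, caudal = 3L)

# Per-plane means of the five concentric circle radii (px at 0.585 um/px)
# used for the zone boundaries around the anterior commissure (aco).
DEFAULT_RADII <- list(
  rostral  = c(280, 591, 887, 1310, 1662),
  intermed = c(293, 618, 915, 1324, 1732),
  caudal   = c(287, 570, 836, 1147, 1648)
)

#' Circle geometry of one section
#'
#' Describes the polar coordinate frame of one coronal section: the pixel
#' position of the aco center and the five strictly increasing circle radii
#' that bound zones 1-4 (zone 0 = inside circle 1, zone 5 = outside circle
#' 5; both are excluded from analysis).
#'
#' @param plane one of `"rostral"`, `"intermed"`, `"caudal"`.
#' @param center numeric length-2, aco center (x, y) in image pixels
#'   (0-based, x right, y down).
#' @param radii five strictly increasing radii in px; defaults to the
#'   per-plane mean radii.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @return an object of class `aco_geometry`.
#' @export
aco_geometry <- function(plane, center = c(0, 0), radii = NULL,
                         pixel_size_um = 0.585) {
  plane <- match.arg(plane, names(PLANE_CODES))
  if (is.null(radii)) radii <- DEFAULT_RADII[[plane]]
  radii <- as.numeric(radii)
  if (length(radii) != 5L || any(diff(radii) <= 0) || radii[1] <= 0)
    stop("'radii' must be five strictly increasing positive values")
  structure(list(plane = plane, center = as.numeric(center),
                 radii = radii, pixel_size_um = pixel_size_um),
            class = "aco_geometry")
}

#' Parcellation options
#'
#' @param zones zones included in the analysis (zones 0 and 5 never are).
#' @param excluded_regions character vector of PZS IDs dropped from the
#'   default grid; the default drops zone 4, sector 5 in the rostral plane,
#'   the region with insufficient image coverage.
#' @param min_dapi_per_region minimum DAPI-positive ROI count for a region
#'   of one section to be treated as valid.
#' @export
parcellation_config <- function(zones = 1:4, excluded_regions = "145",
                                min_dapi_per_region = 10L) {
  stopifnot(all(zones %in% 1:4), min_dapi_per_region >= 0)
  grid <- pzs_grid()
  bad <- setdiff(excluded_regions, grid$pzs_id)
  if (length(bad))
    stop("excluded regions not in the grid: ", paste(bad, collapse = ", "))
  structure(list(zones = as.integer(zones),
                 excluded_regions = as.character(excluded_regions),
                 min_dapi_per_region = as.integer(min_dapi_per_region)),
            class = "parcellation_config")
}

#' Radial zone of a point
#'
#' Zones are half-open annuli `(R_k, R_{k+1}]`: radius exactly on a circle
#' belongs to the inner zone. `r <= R1` is zone 0 (inside the aco),
#' `r > R5` is zone 5; both are outside the analysis grid.
#'
#' @param r radial distance(s) from the aco center, px, `>= 0`.
#' @param geometry an [aco_geometry()].
#' @return integer zone(s) in 0..5.
#' @export
assign_zone <- function(r, geometry) {
  stopifnot(inherits(geometry, "aco_geometry"), all(r >= 0))
  # findInterval with left-open intervals gives (R_k, R_{k+1}]
  findInterval(r, geometry$radii, left.open = TRUE)
}

#' Angular sector of a point
#'
#' The offsets are in the anatomical frame: +x medial, +y dorsal. Sector 1
#' spans \[0, 45) degrees immediately above the medial horizontal;
#' numbering proceeds counter-clockwise through dorsal (3), lateral (4-5),
#' and ventral (6-7) back to just below medial (8).
#'
#' @param dx,dy offsets from the aco center in the anatomical frame, px.
#' @return integer sector(s) in 1..8.
#' @export
assign_sector <- function(dx, dy) {
  if (any(dx == 0 & dy == 0)) stop("sector undefined at the aco center")
  theta <- atan2(dy, dx) %% (2 * pi)
  s <- floor(theta / (pi / 4)) + 1L
  as.integer(pmin(s, 8L))  # guard theta == 2*pi after rounding
}

#' Encode / decode three-digit plane-zone-sector region IDs
#'
#' The first digit encodes the plane (1 rostral, 2 intermed, 3 caudal), the
#' second the zone (1-4), the third the sector (1-8), e.g. `"212"` is the
#' intermed-plane region in zone 1, sector 2.
#'
#' @param plane plane label(s).
#' @param zone zone(s) in 1..4.
#' @param sector sector(s) in 1..8.
#' @return `pzs_encode`: character ID(s); `pzs_decode`: data.frame with
#'   columns plane, zone, sector.
#' @export
pzs_encode <- function(plane, zone, sector) {
  p <- PLANE_CODES[as.character(plane)]
  if (any(is.na(p))) stop("unknown plane label")
  zone <- as.integer(zone); sector <- as.integer(sector)
  if (any(zone < 1L | zone > 4L)) stop("zone must be in 1..4")
  if (any(sector < 1L | sector > 8L)) stop("sector must be in 1..8")
  sprintf("%d%d%d", p, zone, sector)
}

#' @rdname pzs_encode
#' @param pzs_id three-digit ID(s), character or numeric.
#' @export
pzs_decode <- function(pzs_id) {
  id <- suppressWarnings(as.integer(as.character(pzs_id)))
  if (any(is.na(id)) || any(id < 100L | id > 999L))
    stop("malformed PZS ID")
  p <- id %/% 100L; z <- (id %/% 10L) %% 10L; s <- id %% 10L
  if (any(p < 1L | p > 3L)) stop("plane digit out of range")
  if (any(z < 1L | z > 4L)) stop("zone digit out of range")
  if (any(s < 1L | s > 8L)) stop("sector digit out of range")
  data.frame(pzs_id = sprintf("%03d", id),
             plane = names(PLANE_CODES)[p], zone = z, sector = s,
             stringsAsFactors = FALSE)
}

# Full 96-key grid (3 planes x 4 zones x 8 sectors), codec ordering.
pzs_grid <- function() {
  g <- expand.grid(sector = 1:8, zone = 1:4, plane = names(PLANE_CODES),
                   stringsAsFactors = FALSE)[, c("plane", "zone", "sector")]
  g$pzs_id <- pzs_encode(g$plane, g$zone, g$sector)
  g[order(g$pzs_id), ]
}

#' Enumerate analysis regions
#'
#' The full grid has 96 regions (4 zones x 8 sectors x 3 planes); the
#' default configuration drops zone 4, sector 5 in the rostral plane,
#' leaving the 95 regions used in clustering.
#'
#' @param config a [parcellation_config()].
#' @return data.frame of region keys with `pzs_id`.
#' @export
enumerate_regions <- function(config = parcellation_config()) {
  g <- pzs_grid()
  g <- g[g$zone %in% config$zones & !(g$pzs_id %in% config$excluded_regions), ]
  rownames(g) <- NULL
  g
}

#' Assign cells to regions
#'
#' Converts image coordinates to the anatomical frame (x medial, y dorsal;
#' the image y axis grows downward and is negated), computes radial zone
#' and angular sector, and flags cells in zones 0/5 or excluded regions as
#' out of analysis.
#'
#' @param cells data.frame with columns `x`, `y` (image px).
#' @param geometry an [aco_geometry()] for the section's plane.
#' @param config a [parcellation_config()].
#' @return `cells` with added columns `zone`, `sector`, `pzs_id` (NA when
#'   out of grid) and logical `in_analysis`.
#' @export
assign_cells_to_regions <- function(cells, geometry,
                                    config = parcellation_config()) {
  if (!inherits(geometry, "aco_geometry")) stop("missing or invalid geometry")
  dx <- cells$x - geometry$center[1]
  dy <- geometry$center[2] - cells$y   # image y down -> anatomical y up
  r <- sqrt(dx^2 + dy^2)
  zone <- assign_zone(r, geometry)
  sector <- rep(NA_integer_, nrow(cells))
  ok <- r > 0
  sector[ok] <- assign_sector(dx[ok], dy[ok])
  cells$zone <- zone
  cells$sector <- sector
  cells$pzs_id <- NA_character_
  grid_ok <- zone %in% config$zones & !is.na(sector)
  cells$pzs_id[grid_ok] <-
    pzs_encode(geometry$plane, zone[grid_ok], sector[grid_ok])
  cells$pzs_id[cells$pzs_id %in% config$excluded_regions] <- NA_character_
  cells$in_analysis <- !is.na(cells$pzs_id)
  cells
}

#' Region validity from DAPI counts
#'
#' A region of one section is valid when it contains at least
#' `min_dapi_per_region` DAPI-positive ROIs (the count equal to the
#' threshold is valid).
#'
#' @param n_dapi integer DAPI counts.
#' @param config a [parcellation_config()].
#' @return logical vector, `TRUE` = valid.
#' @export
region_validity <- function(n_dapi, config = parcellation_config()) {
  n_dapi >= config$min_dapi_per_region
}

#' Read / write section geometry sidecar JSON
#'
#' @param path JSON file with fields plane, center_x, center_y, radii (5),
#'   pixel_size_um.
#' @return an [aco_geometry()].
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  aco_geometry(j$plane, c(j$center_x, j$center_y), j$radii,
               if (is.null(j$pixel_size_um)) 0.585 else j$pixel_size_um)
}

#' @rdname read_geometry
#' @param geometry an [aco_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(
    list(plane = geometry$plane, center_x = geometry$center[1],
         center_y = geometry$center[2], radii = geometry$radii,
         pixel_size_um = geometry$pixel_size_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
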