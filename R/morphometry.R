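# Eighteen per-cell morphometric parameters: area/perimeter descriptors of
# the cell, its convex hull and its soma; solidity, convexity and
# circularity; skeleton length, branch and endpoints; process count; and
# Sholl-analysis statistics (branching index, critical radius, dendritic
# maximum, Schoenen ramification index).

#' Canonical morphometric parameter names
#'
#' The 18 per-cell parameters in their fixed order. The Schoenen
#' ramification index (`sri`) is undefined for cells without processes and
#' is excluded from nearest-centroid analyses; [nc_parameters()] returns
#' the remaining 17.
#' @return character vector of length 18.
#' @export
morphometry_parameters <- function() {
  c("cell_area_um2", "cell_perimeter_um", "convex_hull_area_um2",
    "convex_hull_perimeter_um", "cell_solidity", "cell_convexity",
    "cell_circularity", "soma_area_um2", "soma_perimeter_um",
    "soma_circularity", "skeleton_length_um", "skeleton_branch_points",
    "skeleton_endpoints", "n_processes", "branching_index",
    "critical_radius_um", "dendritic_maximum", "sri")
}

#' @rdname morphometry_parameters
#' @export
nc_parameters <- function() {
  setdiff(morphometry_parameters(), "sri")
}

#' Circularity of a shape from its area and perimeter
#'
#' `4 * pi * area / perimeter^2`; equals 1 for a perfect circle and
#' decreases as the shape deviates from a circle.
#'
#' @param area shape area.
#' @param perimeter shape perimeter (same length unit).
#' @return circularity (unitless).
#' @export
circularity <- function(area, perimeter) {
  4 * pi * area / perimeter^2
}

# marching-squares boundary polygons of a mask (sub-pixel vertices at
# level 0.5); returns list of closed polygons as (row, col) matrices
mask_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  cl <- contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L), z = pad,
                     levels = 0.5)
  lapply(cl, function(p) cbind(p$x, p$y))
}

# light corner-average smoothing of a closed polygon; suppresses the
# 1-pixel staircase of marching squares (which otherwise inflates a
# disc's perimeter by ~6%) while genuine corners of large shapes lose
# only O(1 px) of length
smooth_closed_polygon <- function(p, passes = 2L) {
  n <- nrow(p)
  if (n < 5L) return(p)
  if (all(p[1L, ] == p[n, ])) { p <- p[-n, , drop = FALSE]; n <- n - 1L }
  for (k in seq_len(passes))
    p <- (p[c(n, 1:(n - 1L)), , drop = FALSE] + p +
            p[c(2:n, 1L), , drop = FALSE]) / 3
  p
}

poly_length <- function(p, closed = TRUE) {
  if (nrow(p) < 2L) return(0)
  d <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
  s <- sum(d)
  if (closed && any(p[1L, ] != p[nrow(p), ]))
    s <- s + sqrt(sum((p[1L, ] - p[nrow(p), ])^2))
  s
}

poly_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

#' Region shape descriptors of a binary mask
#'
#' Area from the pixel count; perimeter from the marching-squares
#' polygonal boundary after two corner-average smoothing passes (so an
#' ideal disc's circularity approaches 1 instead of inheriting the ~6%
#' staircase inflation); convex hull over the sub-pixel boundary
#' vertices. Solidity and
#' convexity are clamped at 1 (rasterization can push the pixel-count
#' area a fraction of a pixel beyond the polygonal hull for convex
#' shapes).
#'
#' @param mask non-empty binary mask (one connected component).
#' @param pixel_size_um physical pixel size.
#' @return named list: `area_um2`, `perimeter_um`, `hull_area_um2`,
#'   `hull_perimeter_um`, `solidity`, `convexity`, `circularity`.
#' @export
region_metrics <- function(mask, pixel_size_um = 0.122) {
  mask <- as_mask(mask)
  if (sum(mask) == 0L) stop("region_metrics: empty mask")
  s <- pixel_size_um
  area <- sum(mask) * s^2
  raw_contours <- mask_contours(mask)
  contours <- lapply(raw_contours, smooth_closed_polygon)
  perimeter <- sum(vapply(contours, poly_length, numeric(1))) * s
  # hull over the raw (unsmoothed) boundary vertices: smoothing shaves
  # convex corner tips and would bias the hull of spiky shapes low
  verts <- do.call(rbind, raw_contours)
  h <- chull(verts)
  hull <- verts[h, , drop = FALSE]
  hull_area <- poly_area(hull) * s^2
  hull_perimeter <- poly_length(hull) * s
  list(area_um2 = area,
       perimeter_um = perimeter,
       hull_area_um2 = hull_area,
       hull_perimeter_um = hull_perimeter,
       solidity = min(1, area / hull_area),
       convexity = min(1, hull_perimeter / perimeter),
       circularity = circularity(area, perimeter))
}

#' Skeleton length, branch points and endpoints
#'
#' Length sums the inter-pixel steps of the thinned skeleton (1 for
#' axial, sqrt(2) for diagonal neighbours). An endpoint has exactly one
#' 8-neighbour; a branch point has three or more. An isolated pixel has
#' zero neighbours and counts as neither.
#'
#' @param skeleton thinned binary mask.
#' @param pixel_size_um physical pixel size.
#' @return list: `length_um`, `branch_points`, `endpoints`.
#' @export
skeleton_metrics <- function(skeleton, pixel_size_um = 0.122) {
  skeleton <- as_mask(skeleton)
  if (sum(skeleton) == 0L)
    return(list(length_um = 0, branch_points = 0L, endpoints = 0L))
  nb <- cpp_neighbor_count(skeleton)
  nbv <- nb[!is.na(nb)]
  list(length_um = cpp_skeleton_length(skeleton) * pixel_size_um,
       branch_points = sum(nbv >= 3L),
       endpoints = sum(nbv == 1L))
}

#' Number of cell processes
#'
#' Counts the 8-connected components of the cell mask after subtracting
#' the 3-pixel-dilated soma; processes shorter than the dilation collar
#' vanish and are not counted.
#'
#' @param cell_mask,soma_mask crop-local binary masks (soma inside cell).
#' @return integer process count.
#' @export
count_processes <- function(cell_mask, soma_mask) {
  dil <- binary_dilation(soma_mask, 3)
  rest <- as_mask(as_mask(cell_mask) & !dil)
  max(label_components(rest))
}

#' Sholl profile of a cell skeleton
#'
#' Counts process crossings on concentric rings around the soma centroid.
#' A crossing at radius r is one 8-connected component of the skeleton
#' intersected with the 1-pixel-wide ring at r. Rings start one step
#' beyond the soma-equivalent radius `sqrt(soma_area / pi)` and extend to
#' the cell's maximal radial extent.
#'
#' @param skeleton thinned process skeleton (crop-local).
#' @param soma_centroid (row, col) of the soma centroid, crop-local.
#' @param soma_area_um2 soma area used for the innermost ring radius.
#' @param step_um ring spacing in micrometres.
#' @param pixel_size_um physical pixel size.
#' @return list of class `sholl_profile`: `radii_um` (strictly
#'   increasing), `crossings`, `center`.
#' @export
sholl_profile <- function(skeleton, soma_centroid, soma_area_um2,
                          step_um = 2, pixel_size_um = 0.122) {
  skeleton <- as_mask(skeleton)
  r0_um <- sqrt(soma_area_um2 / pi) + step_um
  idx <- which(skeleton == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(structure(list(radii_um = r0_um, crossings = 0L,
                          center = soma_centroid),
                     class = "sholl_profile"))
  }
  d_px <- sqrt((idx[, 1L] - soma_centroid[1L])^2 +
               (idx[, 2L] - soma_centroid[2L])^2)
  rmax_um <- max(d_px) * pixel_size_um + step_um
  radii <- seq(r0_um, rmax_um, by = step_um)
  dmat <- matrix(0, nrow(skeleton), ncol(skeleton))
  dmat[idx] <- d_px
  crossings <- vapply(radii, function(r_um) {
    r_px <- r_um / pixel_size_um
    ring <- matrix(0L, nrow(skeleton), ncol(skeleton))
    sel <- abs(d_px - r_px) <= 0.5
    if (!any(sel)) return(0L)
    ring[idx[sel, , drop = FALSE]] <- 1L
    max(label_components(ring))
  }, integer(1))
  structure(list(radii_um = radii, crossings = crossings,
                 center = soma_centroid),
            class = "sholl_profile")
}

#' Sholl-derived statistics
#'
#' Dendritic maximum (peak crossing count), critical radius (smallest
#' radius attaining the peak), branching index (sum of positive
#' ring-to-ring crossing increments weighted by the ring radius, with a
#' zero-crossing baseline before the first ring) and the Schoenen
#' ramification index (peak crossings divided by the number of primary
#' processes; undefined (`NA`) for cells without processes).
#'
#' @param profile a [sholl_profile()].
#' @param n_processes number of primary processes.
#' @return list: `branching_index`, `critical_radius_um`,
#'   `dendritic_maximum`, `sri`.
#' @export
sholl_derived <- function(profile, n_processes) {
  cr <- profile$crossings
  radii <- profile$radii_um
  dmax <- if (length(cr)) max(cr) else 0L
  crit <- radii[which.max(cr)]
  inc <- diff(c(0L, cr))
  bi <- sum(pmax(inc, 0) * radii)
  sri <- if (n_processes > 0) dmax / n_processes else NA_real_
  list(branching_index = bi, critical_radius_um = crit,
       dendritic_maximum = as.integer(dmax), sri = sri)
}

#' Full morphometric record of one extracted cell
#'
#' @param cell a `cell_extract` from [extract_cells()].
#' @param step_um Sholl ring spacing.
#' @return one-row data.frame with `cell_id` and the 18 parameters of
#'   [morphometry_parameters()].
#' @export
cell_morphometry <- function(cell, step_um = 2) {
  stopifnot(inherits(cell, "cell_extract"))
  s <- cell$pixel_size_um
  cm <- region_metrics(cell$cell_mask, s)
  so <- region_metrics(cell$soma_mask, s)
  sk <- skeleton_metrics(cell$skeleton, s)
  np <- count_processes(cell$cell_mask, cell$soma_mask)
  sidx <- which(cell$soma_mask == 1L, arr.ind = TRUE)
  centroid_local <- colMeans(sidx)
  prof <- sholl_profile(cell$skeleton, centroid_local, so$area_um2,
                        step_um, s)
  sh <- sholl_derived(prof, np)
  data.frame(cell_id = cell$cell_id,
             cell_area_um2 = cm$area_um2,
             cell_perimeter_um = cm$perimeter_um,
             convex_hull_area_um2 = cm$hull_area_um2,
             convex_hull_perimeter_um = cm$hull_perimeter_um,
             cell_solidity = cm$solidity,
             cell_convexity = cm$convexity,
             cell_circularity = cm$circularity,
             soma_area_um2 = so$area_um2,
             soma_perimeter_um = so$perimeter_um,
             soma_circularity = so$circularity,
             skeleton_length_um = sk$length_um,
             skeleton_branch_points = sk$branch_points,
             skeleton_endpoints = sk$endpoints,
             n_processes = np,
             branching_index = sh$branching_index,
             critical_radius_um = sh$critical_radius_um,
             dendritic_maximum = sh$dendritic_maximum,
             sri = sh$sri)
}

#' Morphometry table for a list of cells
#' @param cells list of `cell_extract` objects.
#' @param step_um Sholl ring spacing.
#' @return data.frame, one row per cell.
#' @export
morphometry_table <- function(cells, step_um = 2) {
  do.call(rbind, lapply(cells, cell_morphometry, step_um = step_um))
}

#' Per-image metrics: segmented area percentage and cell density
#'
#' @param labels label image from [separate_cells()].
#' @param segmented_mask binary mask of all segmented pixels before cell
#'   detection (the merged soma/process mask).
#' @param pixel_size_um physical pixel size.
#' @return list: `segmented_area_pct`, `cell_density_per_mm2`.
#' @export
image_metrics <- function(labels, segmented_mask, pixel_size_um = 0.122) {
  total_px <- length(labels)
  if (total_px == 0L) stop("zero-area image")
  area_mm2 <- total_px * (pixel_size_um * 1e-3)^2
  list(segmented_area_pct = 100 * sum(as_mask(segmented_mask)) / total_px,
       cell_density_per_mm2 = max(labels) / area_mm2)
}
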