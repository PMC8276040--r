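# Hybrid soma/process segmentation: contrast-normalized, inverted images
# are split into a soma channel (top-hat + Gaussian + Otsu + size filter +
# closing) and a process channel (local adaptive segmentation of the image
# and of its ridge-filtered version), merged, repaired by endpoint
# bridging, cleared of orphans and border cells, and finally separated
# into uniquely labeled single cells by parallel flood fill seeded at the
# soma regions.

#' Segmentation configuration
#'
#' Numeric constants of the segmentation pipeline. The defaults encode the
#' published working point: a 1,500-pixel soma size threshold, 7.5-pixel
#' closing radius, 5-pixel adaptive segmentation radius, ridge filter
#' scale 5, 50-pixel endpoint bridging radius and 0.122 um/px pixel size.
#'
#' @param clahe_clip_limit CLAHE clip limit (multiple of the uniform bin
#'   count).
#' @param clahe_tile_grid CLAHE tiles per image side.
#' @param tophat_radius_px disc radius of the white top-hat used for soma
#'   enhancement; must exceed the radius of the largest expected soma so
#'   that the morphological opening removes every soma.
#' @param gaussian_sigma_px Gaussian blur applied after the top-hat.
#' @param soma_min_area_px smallest surviving soma component, in pixels.
#' @param closing_radius_px disc radius of the soma reconstruction closing.
#' @param adaptive_radius_px neighbourhood radius of the local adaptive
#'   segmentation.
#' @param adaptive_offset additive offset of the adaptive threshold, in
#'   intensity units; keeps background noise below the percolation regime.
#' @param ridge_sigma_px scale of the Hessian ridge filter.
#' @param bridge_max_dist_px maximum endpoint-to-soma bridging distance.
#' @param bridge_line_width_px width of the drawn bridge line.
#' @param bridge_min_orphan_px smallest orphan component considered a
#'   detached process and eligible for bridging; smaller components are
#'   treated as noise and fall to the orphan-clearing rule.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(clahe_clip_limit = 2,
                                clahe_tile_grid = 8L,
                                tophat_radius_px = 40,
                                gaussian_sigma_px = 5,
                                soma_min_area_px = 1500L,
                                closing_radius_px = 7.5,
                                adaptive_radius_px = 5,
                                adaptive_offset = 0.15,
                                ridge_sigma_px = 5,
                                bridge_max_dist_px = 50,
                                bridge_line_width_px = 3,
                                bridge_min_orphan_px = 30L,
                                pixel_size_um = 0.122) {
  cfg <- list(clahe_clip_limit = clahe_clip_limit,
              clahe_tile_grid = as.integer(clahe_tile_grid),
              tophat_radius_px = tophat_radius_px,
              gaussian_sigma_px = gaussian_sigma_px,
              soma_min_area_px = as.integer(soma_min_area_px),
              closing_radius_px = closing_radius_px,
              adaptive_radius_px = adaptive_radius_px,
              adaptive_offset = adaptive_offset,
              ridge_sigma_px = ridge_sigma_px,
              bridge_max_dist_px = bridge_max_dist_px,
              bridge_line_width_px = bridge_line_width_px,
              bridge_min_orphan_px = as.integer(bridge_min_orphan_px),
              pixel_size_um = pixel_size_um)
  stopifnot(cfg$tophat_radius_px > 0, cfg$gaussian_sigma_px > 0,
            cfg$soma_min_area_px >= 1L, cfg$closing_radius_px > 0,
            cfg$adaptive_radius_px > 0, cfg$ridge_sigma_px > 0,
            cfg$bridge_max_dist_px >= 0, cfg$pixel_size_um > 0)
  structure(cfg, class = "segmentation_config")
}

#' Preprocess a tissue image: CLAHE then intensity inversion
#'
#' Dark stained cells become bright foreground; a constant image is
#' returned as its constant complement.
#'
#' @param image grayscale matrix in \[0, 1\] (convert RGB input with
#'   [rgb_to_gray()] first).
#' @param cfg a [segmentation_config()].
#' @return preprocessed grayscale matrix in \[0, 1\].
#' @export
preprocess <- function(image, cfg = segmentation_config()) {
  image <- as_gray_image(image)
  eq <- clahe(image, cfg$clahe_clip_limit, cfg$clahe_tile_grid)
  1 - eq
}

#' Soma size filter
#'
#' Removes 8-connected components with strictly fewer than `min_area`
#' pixels; a component of exactly `min_area` pixels survives.
#'
#' @param mask binary mask.
#' @param min_area pixel-count threshold.
#' @return filtered mask.
#' @export
soma_size_filter <- function(mask, min_area = 1500L) {
  remove_small_components(mask, min_area)
}

#' Detect cell somata
#'
#' White top-hat (suppressing the smooth background), Gaussian blur
#' (suppressing thin processes), Otsu binarization, size filtering at
#' `soma_min_area_px` and morphological closing.
#'
#' @param inv preprocessed (inverted, bright-cell) image.
#' @param cfg a [segmentation_config()].
#' @return binary soma mask (possibly empty; an empty mask is valid).
#' @export
detect_somata <- function(inv, cfg = segmentation_config()) {
  th <- white_tophat(inv, cfg$tophat_radius_px)
  sm <- gaussian_blur(th, cfg$gaussian_sigma_px)
  if (max(sm) - min(sm) < 1e-6) return(matrix(0L, nrow(inv), ncol(inv)))
  thr <- otsu_threshold(sm)
  bin <- as_mask(sm > thr)
  bin <- soma_size_filter(bin, cfg$soma_min_area_px)
  if (sum(bin) == 0L) return(bin)
  binary_closing(bin, cfg$closing_radius_px)
}

#' Detect stained cells and processes
#'
#' Union of the local adaptive segmentation of the preprocessed image and
#' of its ridge-filtered version (the ridge filter amplifies thin
#' curvilinear processes before re-segmentation).
#'
#' @param inv preprocessed (inverted) image.
#' @param cfg a [segmentation_config()].
#' @return binary mask of all stained structures.
#' @export
detect_processes <- function(inv, cfg = segmentation_config()) {
  seg1 <- adaptive_threshold(inv, cfg$adaptive_radius_px,
                             cfg$adaptive_offset)
  rg <- ridge_filter(inv, cfg$ridge_sigma_px)
  if (max(rg) > 0) rg <- rg / max(rg)
  seg2 <- adaptive_threshold(rg, cfg$adaptive_radius_px,
                             cfg$adaptive_offset)
  as_mask(seg1 | seg2)
}

# endpoints (exactly one 8-neighbour) of a thinned mask
skeleton_endpoints_idx <- function(skel) {
  nb <- cpp_neighbor_count(skel)
  which(!is.na(nb) & nb == 1L, arr.ind = TRUE)
}

#' Merge soma and process masks and repair connectivity
#'
#' Takes the union of the two masks; every connected component without a
#' soma pixel is bridged, from its skeleton endpoint nearest to any soma
#' boundary pixel, by a straight drawn line to that soma pixel, provided
#' the Euclidean distance does not exceed `bridge_max_dist_px`. Components
#' still lacking a soma after bridging are deleted, as is every component
#' touching the image border.
#'
#' @param somata binary soma mask from [detect_somata()].
#' @param processes binary mask from [detect_processes()].
#' @param cfg a [segmentation_config()].
#' @return repaired binary mask of whole cells.
#' @export
merge_and_reconstruct <- function(somata, processes,
                                  cfg = segmentation_config()) {
  stopifnot(all(dim(somata) == dim(processes)))
  merged <- as_mask(somata | processes)
  soma_b <- soma_boundary_idx(somata)
  if (nrow(soma_b) > 0L) {
    lab <- label_components(merged)
    nlab <- max(lab)
    if (nlab > 0L) {
      has_soma <- rep(FALSE, nlab)
      soma_ids <- lab[somata == 1L]
      has_soma[unique(soma_ids[soma_ids > 0L])] <- TRUE
      sizes <- component_pixel_counts(lab)
      for (id in which(!has_soma & sizes >= cfg$bridge_min_orphan_px)) {
        cidx <- which(lab == id, arr.ind = TRUE)
        bb <- c(min(cidx[, 1L]), min(cidx[, 2L]),
                max(cidx[, 1L]), max(cidx[, 2L]))
        comp <- as_mask(lab[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE] == id)
        ep <- skeleton_endpoints_idx(thin_mask(comp))
        if (nrow(ep) == 0L) ep <- which(comp == 1L, arr.ind = TRUE)
        ep[, 1L] <- ep[, 1L] + bb[1] - 1L
        ep[, 2L] <- ep[, 2L] + bb[2] - 1L
        # nearest (endpoint, soma-boundary) pair; ties by lowest (row, col)
        d2 <- outer(ep[, 1L], soma_b[, 1L], "-")^2 +
              outer(ep[, 2L], soma_b[, 2L], "-")^2
        dmin <- min(d2)
        if (sqrt(dmin) <= cfg$bridge_max_dist_px) {
          hit <- which(d2 == dmin, arr.ind = TRUE)
          ord <- order(ep[hit[, 1L], 1L], ep[hit[, 1L], 2L],
                       soma_b[hit[, 2L], 1L], soma_b[hit[, 2L], 2L])
          e <- ep[hit[ord[1L], 1L], ]
          s <- soma_b[hit[ord[1L], 2L], ]
          merged <- cpp_draw_line(merged, e[1L] - 1L, e[2L] - 1L,
                                  s[1L] - 1L, s[2L] - 1L,
                                  cfg$bridge_line_width_px / 2)
        }
      }
    }
  }
  # clear components without soma, then border-touching components
  lab <- label_components(merged)
  nlab <- max(lab)
  if (nlab == 0L) return(merged)
  keep <- rep(FALSE, nlab)
  soma_ids <- lab[somata == 1L]
  keep[unique(soma_ids[soma_ids > 0L])] <- TRUE
  border_ids <- unique(c(lab[1L, ], lab[nrow(lab), ],
                         lab[, 1L], lab[, ncol(lab)]))
  keep[border_ids[border_ids > 0L]] <- FALSE
  as_mask(matrix(lab %in% which(keep), nrow(lab), ncol(lab)))
}

# boundary pixels of the soma mask (soma pixels with a non-soma 4-neighbour)
soma_boundary_idx <- function(somata) {
  s <- as_mask(somata)
  if (sum(s) == 0L) return(matrix(0L, 0L, 2L))
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- s
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
              pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(s == 1L & !interior, arr.ind = TRUE)
}

#' Separate touching cells by parallel flood fill
#'
#' Soma connected components are the seeds; labels grow simultaneously
#' (breadth-first, so by geodesic distance inside the mask) until they
#' meet the cell borders or each other. Ties at equal distance go to the
#' lower label id.
#'
#' @param mask repaired cell mask from [merge_and_reconstruct()].
#' @param somata binary soma mask.
#' @return label image; label count equals the number of soma components
#'   inside the mask.
#' @export
separate_cells <- function(mask, somata) {
  stopifnot(all(dim(mask) == dim(somata)))
  mask <- as_mask(mask)
  seeds_src <- as_mask(somata) * mask # somata restricted to the mask
  seeds <- label_components(seeds_src)
  cpp_floodfill_multi(mask, seeds)
}

#' Extract per-cell masks, skeletons and crops
#'
#' @param labels label image from [separate_cells()].
#' @param somata binary soma mask.
#' @param gray grayscale image to crop (typically the equalized image).
#' @param pixel_size_um pixel size carried into each extract.
#' @return list of `cell_extract` objects, each with `cell_id`, `bbox`
#'   (r0, c0, r1, c1; 1-based inclusive), crop-local `cell_mask`,
#'   `soma_mask`, `process_mask`, `skeleton` (thinned process medial
#'   axis), `gray_crop`, full-image `soma_centroid` (row, col) and
#'   `pixel_size_um`.
#' @export
extract_cells <- function(labels, somata, gray,
                          pixel_size_um = 0.122) {
  stopifnot(all(dim(labels) == dim(somata)),
            all(dim(labels) == dim(gray)))
  n <- max(labels)
  out <- vector("list", n)
  for (id in seq_len(n)) {
    idx <- which(labels == id, arr.ind = TRUE)
    bb <- c(min(idx[, 1L]), min(idx[, 2L]), max(idx[, 1L]), max(idx[, 2L]))
    sub <- labels[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE]
    cell <- as_mask(sub == id)
    soma <- as_mask(somata[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE] * cell)
    if (sum(soma) == 0L)
      stop("label ", id, " contains no soma pixel; pipeline contract violated")
    proc <- as_mask(cell & !soma)
    skel <- thin_mask(proc)
    sidx <- which(soma == 1L, arr.ind = TRUE)
    centroid <- round(colMeans(sidx)) + c(bb[1], bb[2]) - 1
    out[[id]] <- structure(
      list(cell_id = id, bbox = bb, cell_mask = cell, soma_mask = soma,
           process_mask = proc, skeleton = skel,
           gray_crop = gray[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE],
           soma_centroid = as.numeric(centroid),
           pixel_size_um = pixel_size_um),
      class = "cell_extract")
  }
  out
}

#' Run the full segmentation on one image
#'
#' Convenience wrapper chaining [preprocess()], [detect_somata()],
#' [detect_processes()], [merge_and_reconstruct()], [separate_cells()]
#' and [extract_cells()].
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param cfg a [segmentation_config()].
#' @return list with `preprocessed`, `somata`, `processes`, `merged`,
#'   `labels`, `cells` (list of `cell_extract`) and `stage_counts`
#'   (structured per-stage tallies for logging).
#' @export
segment_image <- function(image, cfg = segmentation_config()) {
  inv <- preprocess(image, cfg)
  somata <- detect_somata(inv, cfg)
  processes <- detect_processes(inv, cfg)
  merged <- merge_and_reconstruct(somata, processes, cfg)
  somata_kept <- as_mask(somata * merged)
  labels <- separate_cells(merged, somata_kept)
  cells <- extract_cells(labels, somata_kept, 1 - inv, cfg$pixel_size_um)
  counts <- list(
    somata_detected = max(label_components(somata)),
    somata_kept = max(label_components(somata_kept)),
    cells_extracted = length(cells),
    foreground_px = sum(merged))
  list(preprocessed = inv, somata = somata_kept, processes = processes,
       merged = merged, labels = labels, cells = cells,
       stage_counts = counts)
}
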