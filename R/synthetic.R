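# Ground-truthed synthetic microglia. Somata are (possibly elongated)
# ellipses; processes are biased random walks grown from the soma boundary
# with per-step branching. Geometry is calibrated to the pipeline's
# published working scale (0.122 um/px; somata >= 1,500 px) so synthetic
# cells exercise the same size filters as the real tissue images.

#' Default generator parameters for a phenotype
#'
#' Returns the parameter ranges describing one of the four archetypes:
#' \describe{
#'   \item{amoeboid}{large round soma, no processes;}
#'   \item{activated}{enlarged soma, few short thick processes;}
#'   \item{rod_like}{elongated soma, sparse processes aligned with the
#'     long axis;}
#'   \item{ramified}{small soma, many long fine branched processes.}
#' }
#' Soma size is parameterized by the equivalent radius (the radius of the
#' disc with the same area), so the expected soma area is ordered
#' amoeboid > activated > rod_like > ramified and every soma exceeds the
#' 1,500-pixel detection threshold at the default scale.
#'
#' @param phenotype one of `phenotype_classes()`.
#' @return list of class `phenotype_params`.
#' @export
phenotype_params <- function(phenotype = phenotype_classes()) {
  phenotype <- match.arg(phenotype)
  base <- switch(phenotype,
    amoeboid = list(
      soma_radius_px = c(31, 38), soma_elongation = c(1, 1.2),
      n_processes = c(0L, 0L), process_length_px = c(0, 0),
      branch_probability_per_step = 0, tortuosity = 0.3,
      process_thickness_px = c(0, 0), angular_spread = 2 * pi),
    activated = list(
      soma_radius_px = c(27.5, 31), soma_elongation = c(1, 1.3),
      n_processes = c(2L, 4L), process_length_px = c(15, 35),
      branch_probability_per_step = 0.02, tortuosity = 0.35,
      process_thickness_px = c(3, 5), angular_spread = 2 * pi),
    rod_like = list(
      soma_radius_px = c(24.5, 27.5), soma_elongation = c(2.5, 4),
      n_processes = c(2L, 3L), process_length_px = c(40, 70),
      branch_probability_per_step = 0.02, tortuosity = 0.25,
      process_thickness_px = c(2, 3), angular_spread = 0.6),
    ramified = list(
      soma_radius_px = c(22, 24.5), soma_elongation = c(1, 1.2),
      n_processes = c(4L, 7L), process_length_px = c(60, 120),
      branch_probability_per_step = 0.08, tortuosity = 0.3,
      process_thickness_px = c(2, 3), angular_spread = 2 * pi)
  )
  structure(c(list(phenotype = phenotype), base),
            class = "phenotype_params")
}

validate_phenotype_params <- function(p) {
  stopifnot(inherits(p, "phenotype_params"))
  if (any(p$soma_radius_px <= 0)) stop("soma radius must be positive")
  if (any(p$soma_elongation < 1)) stop("elongation must be >= 1")
  if (any(p$n_processes < 0)) stop("n_processes must be >= 0")
  if (p$branch_probability_per_step < 0 || p$branch_probability_per_step > 1)
    stop("branch probability must be in [0, 1]")
  if (max(p$n_processes) > 0 && max(p$process_length_px) <= 0)
    stop("processes requested but maximum process length is 0")
  invisible(p)
}

# run expr with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

runif1 <- function(rng) if (rng[1] == rng[2]) rng[1] else runif(1, rng[1], rng[2])

# stamp a filled ellipse into a mask (center cr/cc, semiaxes a/b, angle th)
stamp_ellipse <- function(mask, cr, cc, a, b, th) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- pmax(1L, floor(cr - a)):pmin(nr, ceiling(cr + a))
  cc2 <- pmax(1L, floor(cc - a)):pmin(nc, ceiling(cc + a))
  co <- cos(th); si <- sin(th)
  for (r in rr) {
    dy <- r - cr
    dx <- cc2 - cc
    u <- dx * co + dy * si
    v <- -dx * si + dy * co
    inside <- (u / a)^2 + (v / b)^2 <= 1
    mask[r, cc2[inside]] <- 1L
  }
  mask
}

# grow one biased random walk; returns list(path = n x 2 matrix of pixel
# coords, branches = list of walks) stamped later by the caller
grow_walk <- function(start, angle, length_px, tortuosity, branch_prob,
                      depth = 0L) {
  step <- 1.5
  n_steps <- max(1L, as.integer(round(length_px / step)))
  pos <- start
  dir <- angle
  path <- matrix(0, n_steps + 1L, 2L)
  path[1L, ] <- pos
  branches <- list()
  for (i in seq_len(n_steps)) {
    # AR(1) heading noise pulled back toward the launch direction keeps
    # walks mostly radial so sibling processes rarely collide
    dir <- dir + rnorm(1L, 0, tortuosity) - 0.15 * (dir - angle)
    pos <- pos + step * c(sin(dir), cos(dir))
    path[i + 1L, ] <- pos
    if (depth < 2L && runif(1L) < branch_prob && i > 2L) {
      rem <- (n_steps - i) * step * runif(1L, 0.4, 0.9)
      if (rem > 3) {
        bang <- dir + sample(c(-1, 1), 1L) * runif(1L, 0.5, 1.1)
        branches <- c(branches,
                      list(grow_walk(pos, bang, rem, tortuosity,
                                     branch_prob, depth + 1L)))
      }
    }
  }
  list(path = path, branches = branches)
}

collect_paths <- function(walk) {
  out <- list(walk$path)
  for (b in walk$branches) out <- c(out, collect_paths(b))
  out
}

stamp_path <- function(mask, path, halfwidth) {
  nr <- nrow(mask); nc <- ncol(mask)
  hw <- max(0L, as.integer(ceiling(halfwidth)))
  off <- expand.grid(dr = -hw:hw, dc = -hw:hw)
  off <- off[off$dr^2 + off$dc^2 <= halfwidth^2 + 1e-9, , drop = FALSE]
  pr <- round(path[, 1L]); pc <- round(path[, 2L])
  for (k in seq_along(pr)) {
    r2 <- pr[k] + off$dr; c2 <- pc[k] + off$dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    mask[cbind(r2[ok], c2[ok])] <- 1L
  }
  mask
}

stamp_skeleton <- function(mask, path) {
  nr <- nrow(mask); nc <- ncol(mask)
  pr <- round(path[, 1L]); pc <- round(path[, 2L])
  ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
  mask[cbind(pr[ok], pc[ok])] <- 1L
  mask
}

#' Generate one synthetic microglial cell
#'
#' Draws the soma as a filled (possibly elongated, randomly oriented)
#' ellipse and grows `n_processes` biased random walks from the soma
#' boundary, each stamped with a disc brush of the configured thickness.
#' Deterministic for a given `(params, seed)` pair.
#'
#' @param params a `phenotype_params` object.
#' @param seed integer seed.
#' @return list of class `synthetic_cell` with elements `cell_mask`,
#'   `soma_mask`, `skeleton_truth` (binary matrices of identical size),
#'   `label`, `seed`, `n_processes_drawn`, `soma_theta`.
#' @export
generate_cell <- function(params, seed) {
  validate_phenotype_params(params)
  with_seed(seed, {
    r_eq <- runif1(params$soma_radius_px)
    elong <- runif1(params$soma_elongation)
    a <- r_eq * sqrt(elong)
    b <- r_eq / sqrt(elong)
    theta <- runif(1L, 0, pi)
    n_proc <- if (params$n_processes[1] == params$n_processes[2])
      as.integer(params$n_processes[1])
    else sample(params$n_processes[1]:params$n_processes[2], 1L)
    lmax <- max(params$process_length_px)
    side <- 2L * as.integer(ceiling(a + lmax * 1.3 + 10)) + 1L
    ctr <- (side + 1) / 2
    soma <- matrix(0L, side, side)
    soma <- stamp_ellipse(soma, ctr, ctr, a, b, theta)
    proc <- matrix(0L, side, side)
    skel <- matrix(0L, side, side)
    if (n_proc > 0L) {
      # launch angles: jittered equal spacing inside the allowed spread
      if (params$angular_spread >= 2 * pi - 1e-9) {
        base <- runif(1L, 0, 2 * pi) + 2 * pi * seq_len(n_proc) / n_proc
        ang <- base + rnorm(n_proc, 0, 0.25)
      } else {
        # axis-aligned (rod-like): alternate between the two pole caps
        pole <- theta + pi / 2 + pi * (seq_len(n_proc) %% 2L)
        ang <- pole + runif(n_proc, -params$angular_spread / 2,
                            params$angular_spread / 2)
      }
      for (i in seq_len(n_proc)) {
        phi <- ang[i]
        # boundary point of the ellipse along direction phi (polar form)
        co <- cos(phi - theta); si <- sin(phi - theta)
        rad <- 1 / sqrt((co / a)^2 + (si / b)^2)
        start <- c(ctr + 0.9 * rad * sin(phi), ctr + 0.9 * rad * cos(phi))
        len <- runif1(params$process_length_px)
        walk <- grow_walk(start, phi, len, params$tortuosity,
                          params$branch_probability_per_step)
        thick <- runif1(params$process_thickness_px)
        for (p in collect_paths(walk)) {
          proc <- stamp_path(proc, p, thick / 2)
          skel <- stamp_skeleton(skel, p)
        }
      }
    }
    cell <- as_mask(soma | proc)
    skel[soma == 1L] <- 0L
    skel[cell == 0L] <- 0L
    # defensive: keep the component containing the soma (stray rounding
    # islands are possible for extreme parameter choices)
    lab <- label_components(cell)
    soma_id <- lab[which(soma == 1L)[1L]]
    cell <- as_mask(lab == soma_id)
    skel[cell == 0L] <- 0L
    structure(list(cell_mask = cell, soma_mask = soma,
                   skeleton_truth = skel, label = params$phenotype,
                   seed = seed, n_processes_drawn = n_proc,
                   soma_theta = theta),
              class = "synthetic_cell")
  })
}

#' Construct a tile scene
#'
#' A scene is a canvas description plus cell placements; call
#' [render_tile()] to rasterize it.
#'
#' @param height,width canvas size in pixels.
#' @param background_mean background intensity in \[0, 1\].
#' @param background_noise_sd additive Gaussian noise sd.
#' @param background_gradient peak-to-peak amplitude of a low-frequency
#'   background modulation (exercises the contrast normalization stage).
#' @param pixel_size_um physical pixel size (default 0.122 um/px).
#' @return list of class `tile_scene` with an empty placement list.
#' @export
tile_scene <- function(height, width, background_mean = 0.85,
                       background_noise_sd = 0.03,
                       background_gradient = 0.04,
                       pixel_size_um = 0.122) {
  structure(list(height = as.integer(height), width = as.integer(width),
                 placements = list(), background_mean = background_mean,
                 background_noise_sd = background_noise_sd,
                 background_gradient = background_gradient,
                 pixel_size_um = pixel_size_um),
            class = "tile_scene")
}

#' Add a cell placement to a scene
#'
#' @param scene a `tile_scene`.
#' @param cell a `synthetic_cell`.
#' @param offset (row, col) of the cell canvas top-left corner, 1-based.
#' @param border_test allow the cell to intersect the canvas border.
#' @return the updated scene.
#' @export
place_cell <- function(scene, cell, offset, border_test = FALSE) {
  stopifnot(inherits(scene, "tile_scene"), inherits(cell, "synthetic_cell"))
  bb <- mask_bbox(cell$cell_mask)
  r0 <- offset[1] + bb[1] - 1L; c0 <- offset[2] + bb[2] - 1L
  r1 <- offset[1] + bb[3] - 1L; c1 <- offset[2] + bb[4] - 1L
  if (!border_test &&
      (r0 < 1L || c0 < 1L || r1 > scene$height || c1 > scene$width))
    stop("cell placed outside canvas; set border_test = TRUE to allow")
  scene$placements <- c(scene$placements,
                        list(list(cell = cell,
                                  offset = as.integer(offset),
                                  border_test = border_test)))
  scene
}

# bounding box (r0, c0, r1, c1) of a mask's foreground, 1-based inclusive
mask_bbox <- function(mask) {
  idx <- which(mask != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box")
  c(min(idx[, 1L]), min(idx[, 2L]), max(idx[, 1L]), max(idx[, 2L]))
}

#' Render a scene to a grayscale tile plus ground truth
#'
#' Cells are rendered dark on a light background (matching chromogen
#' staining polarity): soma pixels darkest, process pixels intermediate.
#' Additive Gaussian noise and an optional smooth background gradient are
#' applied on top.
#'
#' @param scene a `tile_scene` with placements.
#' @param seed integer seed for the noise.
#' @return list with `image` (grayscale matrix), `truth_labels` (one
#'   unique positive id per placed cell), `truth_soma` (binary mask of all
#'   soma pixels) and the scene's `pixel_size_um`.
#' @export
render_tile <- function(scene, seed = 1L) {
  stopifnot(inherits(scene, "tile_scene"))
  h <- scene$height; w <- scene$width
  labels <- matrix(0L, h, w)
  soma_all <- matrix(0L, h, w)
  depth <- matrix(0, h, w) # 0 bg, 1 process, 2 soma
  for (i in seq_along(scene$placements)) {
    pl <- scene$placements[[i]]
    m <- pl$cell$cell_mask
    sm <- pl$cell$soma_mask
    idx <- which(m != 0L, arr.ind = TRUE)
    rr <- idx[, 1L] + pl$offset[1] - 1L
    cc <- idx[, 2L] + pl$offset[2] - 1L
    keep <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    if (!pl$border_test && !all(keep))
      stop("placement ", i, " leaves the canvas")
    if (!pl$border_test && i > 1L &&
        any(labels[cbind(rr[keep], cc[keep])] > 0L))
      stop("placement ", i, " overlaps an earlier cell")
    labels[cbind(rr[keep], cc[keep])] <- i
    is_soma <- sm[idx] != 0L
    depth[cbind(rr[keep], cc[keep])] <- ifelse(is_soma[keep], 2, 1)
    soma_idx <- cbind(rr[keep & is_soma], cc[keep & is_soma])
    if (nrow(soma_idx)) soma_all[soma_idx] <- 1L
  }
  with_seed(seed, {
    img <- matrix(scene$background_mean, h, w)
    if (scene$background_gradient > 0) {
      gr <- outer(sin(seq(0, pi, length.out = h)),
                  cos(seq(0, 2 * pi, length.out = w))) / 2
      img <- img + scene$background_gradient * gr
    }
    img[depth == 1] <- scene$background_mean - 0.45
    img[depth == 2] <- scene$background_mean - 0.55
    if (scene$background_noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, scene$background_noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, truth_labels = labels, truth_soma = soma_all,
         pixel_size_um = scene$pixel_size_um)
  })
}

#' Random non-overlapping scene of synthetic cells
#'
#' Convenience builder used throughout the test-suite: draws phenotypes,
#' generates cells, and places them on a grid with jitter so that
#' bounding boxes never overlap and no cell touches the border.
#'
#' @param n_cells number of cells to place (placement stops early if the
#'   canvas is full; the returned scene records what was placed).
#' @param size canvas side in pixels.
#' @param seed integer seed.
#' @param phenotypes phenotype names to cycle through.
#' @param ... passed to [tile_scene()].
#' @return a `tile_scene`.
#' @export
random_tile_scene <- function(n_cells, size = 768L, seed = 1L,
                              phenotypes = phenotype_classes(), ...) {
  scene <- tile_scene(size, size, ...)
  with_seed(seed, {
    phen <- rep(phenotypes, length.out = n_cells)
    cells <- lapply(seq_len(n_cells), function(i)
      generate_cell(phenotype_params(phen[i]),
                    seed = (seed * 7919L + i) %% 2147483647L))
    occupied <- matrix(FALSE, size, size)
    margin <- 12L
    for (cl in cells) {
      bb <- mask_bbox(cl$cell_mask)
      bh <- bb[3] - bb[1] + 1L; bw <- bb[4] - bb[2] + 1L
      placed <- FALSE
      for (try in 1:200) {
        r0 <- sample.int(max(1L, size - bh - 2L * margin), 1L) + margin
        c0 <- sample.int(max(1L, size - bw - 2L * margin), 1L) + margin
        if (r0 + bh - 1L > size - margin || c0 + bw - 1L > size - margin)
          next
        block <- occupied[r0:(r0 + bh - 1L), c0:(c0 + bw - 1L)]
        if (any(block)) next
        occupied[max(1L, r0 - margin):min(size, r0 + bh - 1L + margin),
                 max(1L, c0 - margin):min(size, c0 + bw - 1L + margin)] <- TRUE
        scene <- place_cell(scene, cl, c(r0 - bb[1] + 1L, c0 - bb[2] + 1L))
        placed <- TRUE
        break
      }
      if (!placed) break
    }
  })
  scene
}

# tri-level rendering of a cell (background 0, processes 0.5, soma 1)
# cropped to its bounding box, padded square, rescaled to side x side
cell_to_trilevel <- function(cell, side = 64L,
                             process_level = 0.5, soma_level = 1) {
  bb <- mask_bbox(cell$cell_mask)
  cm <- cell$cell_mask[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE] + 0
  sm <- cell$soma_mask[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE] + 0
  cmr <- cpp_rescale(pad_square(cm), side, side) >= 0.5
  smr <- cpp_rescale(pad_square(sm), side, side) >= 0.5
  img <- matrix(0, side, side)
  img[cmr] <- process_level
  img[smr] <- soma_level
  img
}

#' Generate a labelled synthetic phenotype image dataset
#'
#' Produces `n_per_class` tri-level cell images (background 0, processes
#' mid-level, soma max-level) per phenotype, the convention used by the
#' classifier, together with per-cell ground-truth measurements.
#'
#' @param n_per_class images per phenotype.
#' @param image_size square image side in pixels.
#' @param seed integer seed; the run is fully reproducible.
#' @return list with `images` (array `image_size` x `image_size` x 4n),
#'   `labels` (factor in the fixed class order) and `meta` (data.frame
#'   with phenotype, per-cell seed, soma area, process count and true
#'   skeleton length in pixels).
#' @export
generate_dataset <- function(n_per_class, image_size = 64L, seed = 1L) {
  stopifnot(n_per_class >= 1)
  classes <- phenotype_classes()
  n_total <- 4L * n_per_class
  images <- array(0, c(image_size, image_size, n_total))
  meta <- data.frame(phenotype = character(n_total), seed = integer(n_total),
                     soma_area_px = numeric(n_total),
                     n_processes = integer(n_total),
                     skeleton_length_px = numeric(n_total),
                     stringsAsFactors = FALSE)
  k <- 0L
  for (cls in classes) {
    par <- phenotype_params(cls)
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      cell_seed <- as.integer((as.numeric(seed) * 7919 + k * 104729) %%
                                2147483647)
      cell <- generate_cell(par, cell_seed)
      images[, , k] <- cell_to_trilevel(cell, image_size)
      meta$phenotype[k] <- cls
      meta$seed[k] <- cell_seed
      meta$soma_area_px[k] <- sum(cell$soma_mask)
      meta$n_processes[k] <- cell$n_processes_drawn
      meta$skeleton_length_px[k] <- cpp_skeleton_length(cell$skeleton_truth)
    }
  }
  list(images = images,
       labels = factor(meta$phenotype, levels = classes),
       meta = meta)
}
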