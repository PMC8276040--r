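# Shared fixtures (memoized: segmentation of a tile costs seconds) and
# independent oracles used to cross-check the package's own routines.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# rendered 5-cell tile plus its segmentation, reused across files
fixture_tile <- function() {
  memo("tile5", {
    scene <- random_tile_scene(5, 768, seed = 3)
    tile <- render_tile(scene, seed = 3)
    tile$scene <- scene
    tile
  })
}

fixture_segmentation <- function() {
  memo("seg5", segment_image(fixture_tile()$image))
}

# ---- independent oracles -------------------------------------------------

# plain-R BFS connected component count (8-connectivity)
oracle_count_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# exhaustive convex hull oracle: a point lies on the hull boundary iff
# some directed edge through it keeps all points on one side (O(n^3));
# hull vertices are then angularly sorted around the centroid. Collinear
# boundary points are retained - harmless for area and perimeter.
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || on_hull[i]) next
    d <- pts[j, ] - pts[i, ]
    cr <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) on_hull[i] <- TRUE
  }
  hp <- pts[on_hull, , drop = FALSE]
  ctr <- colMeans(hp)
  ang <- atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1])
  rad <- sqrt(rowSums(sweep(hp, 2, ctr)^2))
  hp[order(ang, rad), , drop = FALSE]
}

oracle_poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]; n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

oracle_poly_perimeter <- function(p) {
  n <- nrow(p)
  sum(sqrt(rowSums((p - p[c(2:n, 1), , drop = FALSE])^2)))
}

# two-source BFS geodesic (chessboard) distances inside a mask
oracle_geodesic_dist <- function(mask, seeds) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  queue <- seeds
  for (k in seq_len(nrow(seeds))) dist[seeds[k, 1], seeds[k, 2]] <- 0
  while (nrow(queue)) {
    nxt <- NULL
    for (k in seq_len(nrow(queue))) {
      p <- queue[k, ]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] != 0 &&
            dist[r, c] > dist[p[1], p[2]] + 1) {
          dist[r, c] <- dist[p[1], p[2]] + 1
          nxt <- rbind(nxt, c(r, c))
        }
      }
    }
    queue <- if (is.null(nxt)) matrix(0, 0, 2) else unique(nxt)
  }
  dist
}

# rank-then-Pearson Spearman oracle
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# draw a filled disc mask of an exact pixel count by growing the radius
disc_of_area <- function(npx, side = 101L) {
  ctr <- (side + 1) / 2
  d2 <- outer(seq_len(side), seq_len(side),
              function(i, j) (i - ctr)^2 + (j - ctr)^2)
  ord <- order(d2)
  m <- matrix(0L, side, side)
  m[ord[seq_len(npx)]] <- 1L
  m
}

# deterministic cross-shaped cell: square soma + four straight arms
cross_cell <- function(soma_half = 10L, arm_len = 25L, arm_half = 1L,
                       side = 101L) {
  ctr <- (side + 1L) %/% 2L
  soma <- matrix(0L, side, side)
  soma[(ctr - soma_half):(ctr + soma_half),
       (ctr - soma_half):(ctr + soma_half)] <- 1L
  cell <- soma
  a0 <- soma_half
  cell[(ctr - arm_half):(ctr + arm_half),
       (ctr + a0):(ctr + a0 + arm_len)] <- 1L
  cell[(ctr - arm_half):(ctr + arm_half),
       (ctr - a0 - arm_len):(ctr - a0)] <- 1L
  cell[(ctr + a0):(ctr + a0 + arm_len),
       (ctr - arm_half):(ctr + arm_half)] <- 1L
  cell[(ctr - a0 - arm_len):(ctr - a0),
       (ctr - arm_half):(ctr + arm_half)] <- 1L
  list(cell = cell, soma = soma, center = c(ctr, ctr))
}

# wrap crop-local masks into a cell_extract without running segmentation
make_extract <- function(cell, soma, gray = NULL, pixel_size_um = 0.122,
                         id = 1L) {
  proc <- as_mask(cell & !soma)
  structure(list(cell_id = id,
                 bbox = c(1L, 1L, nrow(cell), ncol(cell)),
                 cell_mask = as_mask(cell), soma_mask = as_mask(soma),
                 process_mask = proc, skeleton = thin_mask(proc),
                 gray_crop = gray %||%
                   matrix(0.5, nrow(cell), ncol(cell)),
                 soma_centroid = as.numeric(
                   round(colMeans(which(soma == 1, arr.ind = TRUE)))),
                 pixel_size_um = pixel_size_um),
            class = "cell_extract")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small trained classifier shared by pipeline tests (100 cells/class,
# early-stopped; ~1.5 min once per run)
fixture_model <- function() {
  memo("model100", {
    ds <- generate_dataset(100, 64, seed = 13)
    sp <- split_dataset(ds$labels, seed = 1)
    fit <- train_cnn(build_model(model_spec("reduced"), seed = 1),
                     ds$images[, , sp$train], ds$labels[sp$train],
                     ds$images[, , sp$val], ds$labels[sp$val],
                     train_config(epochs = 6, seed = 1))
    fit$model
  })
}

# half-and-half "stroke-like" scene: left activated/rod-like, right
# ramified; deterministic grid placement
fixture_stroke_tile <- function() {
  memo("stroke_tile", {
    sc <- tile_scene(1100, 1500)
    k <- 0
    for (i in 0:4) for (j in 0:1) {
      k <- k + 1
      cls <- if (k %% 2 == 0) "activated" else "rod_like"
      cell <- generate_cell(phenotype_params(cls), seed = 100 + k)
      bb <- microgliamorph:::mask_bbox(cell$cell_mask)
      sc <- place_cell(sc, cell, c(40 + i * 205 - bb[1] + 1,
                                   40 + j * 330 - bb[2] + 1))
    }
    for (i in 0:2) for (j in 0:1) {
      cell <- generate_cell(phenotype_params("ramified"),
                            seed = 200 + i * 2 + j)
      bb <- microgliamorph:::mask_bbox(cell$cell_mask)
      sc <- place_cell(sc, cell, c(40 + i * 350 - bb[1] + 1,
                                   800 + j * 340 - bb[2] + 1))
    }
    tile <- render_tile(sc, seed = 1)
    tile$scene <- sc
    tile
  })
}
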