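test_that("preprocess inverts, normalizes contrast, keeps flat images flat", {
  cfg <- segmentation_config()
  # constant image -> constant complement (CLAHE identity on flat tiles)
  flat <- matrix(0.3, 64, 64)
  expect_equal(preprocess(flat, cfg), matrix(0.7, 64, 64))

  # cells brighter than background after preprocessing (noise-free tile)
  sc <- tile_scene(256, 256, background_noise_sd = 0)
  cell <- generate_cell(phenotype_params("activated"), seed = 2)
  sc <- place_cell(sc, cell, c(40L, 40L))
  out <- render_tile(sc, seed = 1)
  inv <- preprocess(out$image, cfg)
  expect_gt(median(inv[out$truth_labels == 1L]),
            median(inv[out$truth_labels == 0L]))

  # global brightness offsets are compressed by contrast normalization
  img_a <- out$image * 0.8
  img_b <- pmin(img_a + 0.1, 1)
  d_raw <- mean(abs(img_b - img_a))
  d_pre <- mean(abs(preprocess(img_b, cfg) - preprocess(img_a, cfg)))
  expect_lt(d_pre, d_raw)

  expect_error(preprocess(array(0.5, c(4, 4, 3)), cfg), "matrix")
})

test_that("detect_somata applies the size threshold and closing", {
  cfg <- segmentation_config()
  # blank image -> empty mask, not an error
  expect_equal(sum(detect_somata(matrix(0.2, 128, 128), cfg)), 0)

  # 1,400 px blob removed, 1,600 px blob kept (published 1,500-px rule)
  img <- matrix(0.9, 300, 560)
  b1 <- disc_of_area(1400); b2 <- disc_of_area(1600)
  img[40:140, 40:140][b1[1:101, 1:101] == 1L] <- 0.3
  img[40:140, 320:420][b2[1:101, 1:101] == 1L] <- 0.3
  inv <- preprocess(img, cfg)
  somata <- detect_somata(inv, cfg)
  lab <- label_components(somata)
  expect_equal(max(lab), 1L)
  idx <- which(lab == 1L, arr.ind = TRUE)
  expect_gt(mean(idx[, 2]), 250) # the survivor is the right-hand blob

  # three well-separated somata -> exactly three components
  seg <- fixture_segmentation()
  expect_equal(max(label_components(seg$somata)),
               length(fixture_tile()$scene$placements))
})

test_that("soma_size_filter boundary is exact at the pixel count", {
  ladder <- c(1400, 1450, 1499, 1500, 1501, 1600)
  m <- matrix(0L, 101, length(ladder) * 110)
  for (i in seq_along(ladder)) {
    blob <- disc_of_area(ladder[i])
    m[1:101, (i - 1L) * 110 + (1:101)] <- blob
  }
  kept <- soma_size_filter(m, 1500L)
  sizes <- component_sizes <- tabulate(label_components(kept))
  expect_equal(sort(sizes), c(1500, 1501, 1600))
  expect_equal(min(sizes), 1500) # exactly 1,500 survives
})

test_that("detect_processes covers thin curves and satisfies the union", {
  cfg <- segmentation_config()
  expect_equal(sum(detect_processes(matrix(0.2, 96, 96), cfg)), 0)

  # single 2-px-wide bright curve on flat background: >= 90% coverage
  img <- matrix(0.1, 128, 128)
  truth <- matrix(0L, 128, 128)
  for (t in seq(0, 1, length.out = 400)) {
    r <- round(20 + 88 * t)
    c <- round(64 + 30 * sin(2 * pi * t))
    img[r, c + 0:1] <- 0.8
    truth[r, c + 0:1] <- 1L
  }
  mask <- detect_processes(img, cfg)
  expect_gte(sum(mask & truth) / sum(truth), 0.9)

  # union property: output contains the plain adaptive segmentation
  inv <- fixture_segmentation()$preprocessed
  seg1 <- adaptive_threshold(inv, cfg$adaptive_radius_px,
                             cfg$adaptive_offset)
  both <- detect_processes(inv, cfg)
  expect_true(all(both[seg1 == 1L] == 1L))
})

test_that("merge_and_reconstruct bridges orphans within 50 px and clears", {
  cfg <- segmentation_config()
  somata <- matrix(0L, 200, 260)
  somata[80:120, 40:80] <- 1L
  # orphan process 30 px away: bridged into the soma's component
  near <- matrix(0L, 200, 260)
  near[98:102, 111:160] <- 1L # nearest point 30 px from soma edge
  merged <- merge_and_reconstruct(somata, near, cfg)
  expect_equal(max(label_components(merged)), 1L)
  expect_true(all(merged[somata == 1L] == 1L))
  expect_gt(sum(merged[near == 1L]), 0)

  # orphan at 60 px: deleted
  far <- matrix(0L, 200, 260)
  far[98:102, 141:190] <- 1L
  merged2 <- merge_and_reconstruct(somata, far, cfg)
  expect_equal(sum(merged2[far == 1L]), 0)
  expect_true(all(merged2[somata == 1L] == 1L))

  # component touching the border: removed entirely
  border_somata <- matrix(0L, 120, 120)
  border_somata[1:40, 30:70] <- 1L
  merged3 <- merge_and_reconstruct(border_somata,
                                   matrix(0L, 120, 120), cfg)
  expect_equal(sum(merged3), 0)
})

test_that("separate_cells partitions by geodesic distance with low-id ties", {
  # single soma, single component -> one label covering the component
  one <- matrix(0L, 60, 60); one[20:40, 20:40] <- 1L
  lab1 <- separate_cells(one, one)
  expect_equal(max(lab1), 1L)
  expect_equal(sum(lab1 == 1L), sum(one))

  # two somata joined by a touching corridor: partition boundary at equal
  # geodesic distance (+-1 px) from the two soma regions (BFS oracle)
  mask <- matrix(0L, 80, 200)
  mask[30:50, 20:60] <- 1L; mask[30:50, 140:180] <- 1L
  mask[38:42, 60:140] <- 1L
  somata <- matrix(0L, 80, 200)
  somata[30:50, 20:60] <- 1L; somata[30:50, 140:180] <- 1L
  lab <- separate_cells(mask, somata)
  expect_equal(max(lab), 2L)
  # pixel conservation
  expect_equal(sum(lab > 0L), sum(mask))
  d1 <- oracle_geodesic_dist(mask, which(somata == 1L & lab == 1L,
                                         arr.ind = TRUE))
  d2 <- oracle_geodesic_dist(mask, which(somata == 1L & lab == 2L,
                                         arr.ind = TRUE))
  corridor <- which(mask == 1L & somata == 0L, arr.ind = TRUE)
  for (k in seq_len(nrow(corridor))) {
    r <- corridor[k, 1]; c <- corridor[k, 2]
    if (lab[r, c] == 1L) expect_lte(d1[r, c], d2[r, c] + 1)
    else expect_lte(d2[r, c], d1[r, c] + 1)
  }

  # label count equals soma count on the synthetic tile fixture
  seg <- fixture_segmentation()
  expect_equal(max(seg$labels), max(label_components(seg$somata)))
})

test_that("extract_cells returns consistent extracts and recovers cells", {
  tile <- fixture_tile()
  seg <- fixture_segmentation()
  expect_equal(length(seg$cells), max(tile$truth_labels))

  h <- nrow(tile$image); w <- ncol(tile$image)
  for (cl in seg$cells) {
    # invariants
    expect_true(all(cl$cell_mask[cl$soma_mask == 1L] == 1L))
    expect_identical(cl$process_mask,
                     as_mask(cl$cell_mask & !cl$soma_mask))
    expect_true(all(cl$cell_mask[cl$skeleton == 1L] == 1L))
    expect_equal(max(label_components(cl$cell_mask)), 1L)
    # border rule: no bbox touches the image border
    expect_true(cl$bbox[1] > 1 && cl$bbox[2] > 1 &&
                  cl$bbox[3] < h && cl$bbox[4] < w)
  }

  # recovery: each truth cell matched by exactly one extract, Jaccard > 0.5
  for (id in seq_len(max(tile$truth_labels))) {
    tm <- tile$truth_labels == id
    jacc <- vapply(seg$cells, function(cl) {
      full <- matrix(FALSE, h, w)
      full[cl$bbox[1]:cl$bbox[3], cl$bbox[2]:cl$bbox[4]] <-
        cl$cell_mask == 1L
      sum(full & tm) / sum(full | tm)
    }, numeric(1))
    expect_equal(sum(jacc > 0.5), 1L)
  }

  # pixel conservation: sum of label areas = foreground of separated mask
  expect_equal(sum(vapply(seg$cells, function(cl) sum(cl$cell_mask),
                          numeric(1))),
               sum(seg$labels > 0L))

  # label without a soma pixel is a hard error
  labs <- matrix(0L, 30, 30); labs[10:20, 10:20] <- 1L
  expect_error(extract_cells(labs, matrix(0L, 30, 30),
                             matrix(0.5, 30, 30)),
               "soma")

  # amoeboid-only tile: empty process mask
  sc <- tile_scene(220, 220, background_noise_sd = 0.02)
  am <- generate_cell(phenotype_params("amoeboid"), seed = 8)
  sc <- place_cell(sc, am, c(60L, 60L))
  out <- render_tile(sc, seed = 2)
  seg_am <- segment_image(out$image)
  expect_equal(length(seg_am$cells), 1L)
  expect_lt(sum(seg_am$cells[[1]]$process_mask),
            0.1 * sum(seg_am$cells[[1]]$cell_mask))
})
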