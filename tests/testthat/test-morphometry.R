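test_that("region metrics match analytic shapes within tolerance", {
  eps <- 0.05
  # rasterized disc: circularity ~ 1, solidity/convexity ~ 1
  r <- 50; n <- 111
  disc <- outer(1:n, 1:n,
                function(i, j) as.integer((i - 56)^2 + (j - 56)^2 <= r^2))
  rm <- region_metrics(disc, 1)
  expect_equal(rm$area_um2, sum(disc))
  expect_lt(abs(rm$circularity - 1), eps)
  expect_lt(abs(rm$perimeter_um - 2 * pi * r) / (2 * pi * r), eps)
  expect_gt(rm$solidity, 1 - eps)
  expect_gt(rm$convexity, 1 - eps)
  expect_lte(rm$solidity, 1)
  expect_lte(rm$convexity, 1)

  # filled axis-aligned square in the continuous limit: circ -> pi/4
  sq <- matrix(0L, 111, 111); sq[6:106, 6:106] <- 1L
  rs <- region_metrics(sq, 1)
  expect_equal(rs$solidity, 1)
  expect_equal(rs$convexity, 1)
  expect_lt(abs(rs$circularity - pi / 4), eps)

  # unit scaling: areas ~ s^2, perimeters ~ s, ratios invariant
  rm2 <- region_metrics(disc, 0.122)
  expect_equal(rm2$area_um2, rm$area_um2 * 0.122^2)
  expect_equal(rm2$perimeter_um, rm$perimeter_um * 0.122)
  expect_equal(rm2$circularity, rm$circularity)
  expect_equal(rm2$solidity, rm$solidity)

  expect_error(region_metrics(matrix(0L, 5, 5)), "empty")
})

test_that("hull metrics agree with the exhaustive pairwise hull oracle", {
  # plus-sign of two crossed 3 x 31 bars (strongly non-convex)
  plus <- matrix(0L, 41, 41)
  plus[20:22, 5:35] <- 1L
  plus[5:35, 20:22] <- 1L
  rm <- region_metrics(plus, 1)
  verts <- do.call(rbind, microgliamorph:::mask_contours(plus))
  hull <- oracle_hull(verts)
  expect_equal(rm$hull_area_um2, oracle_poly_area(hull), tolerance = 1e-8)
  expect_equal(rm$hull_perimeter_um, oracle_poly_perimeter(hull),
               tolerance = 1e-8)
  expect_equal(rm$solidity, sum(plus) / oracle_poly_area(hull),
               tolerance = 1e-8)
  expect_lt(rm$solidity, 0.5) # plus sign fills < half its hull

  # rotation robustness of the unitless descriptors
  disc <- outer(1:61, 1:61,
                function(i, j) as.integer((i - 31)^2 + (j - 31)^2 <= 25^2))
  base <- region_metrics(disc, 1)
  for (tr in list(t(disc), disc[61:1, ], disc[, 61:1])) {
    m2 <- region_metrics(tr, 1)
    expect_lt(abs(m2$solidity - base$solidity), 0.05)
    expect_lt(abs(m2$convexity - base$convexity), 0.05)
    expect_lt(abs(m2$circularity - base$circularity), 0.05)
  }
})

test_that("skeleton metrics follow the step and neighbour-count rules", {
  # horizontal 101-px line at 0.122 um/px -> 12.2 um, 2 endpoints
  line <- matrix(0L, 5, 105); line[3, 3:103] <- 1L
  sk <- skeleton_metrics(line, 0.122)
  expect_equal(sk$length_um, 100 * 0.122)
  expect_equal(sk$endpoints, 2L)
  expect_equal(sk$branch_points, 0L)

  # isolated pixel: zero everything (0 neighbours is not an endpoint)
  px <- matrix(0L, 9, 9); px[5, 5] <- 1L
  sk2 <- skeleton_metrics(px, 1)
  expect_equal(unlist(sk2), c(length_um = 0, branch_points = 0,
                              endpoints = 0))

  # Y-shape: three 20-px arms from one junction
  y <- matrix(0L, 61, 61)
  y[31:51, 31] <- 1L                       # downward arm
  for (k in 0:20) { y[31 - k, 31 - k] <- 1L; y[31 - k, 31 + k] <- 1L }
  y[31, 31] <- 1L
  sk3 <- skeleton_metrics(y, 1)
  expect_equal(sk3$endpoints, 3L)
  expect_equal(sk3$branch_points, 1L)
  # brute-force path sum: 20 axial + 2 * 20 diagonal steps
  expect_lt(abs(sk3$length_um - (20 + 40 * sqrt(2))), sqrt(2) + 1e-9)

  expect_equal(skeleton_metrics(matrix(0L, 4, 4), 1)$length_um, 0)
})

test_that("count_processes subtracts the 3-px dilated soma", {
  cc <- cross_cell()
  expect_equal(count_processes(cc$cell, cc$soma), 4L)

  # amoeboid: zero processes
  am <- generate_cell(phenotype_params("amoeboid"), seed = 2)
  expect_equal(count_processes(am$cell_mask, am$soma_mask), 0L)

  # a 2-px stub vanishes inside the dilation collar
  stub <- cc$soma
  ctr <- cc$center
  stub2 <- stub
  stub2[ctr[1], (ctr[2] + 10 + 1):(ctr[2] + 10 + 2)] <- 1L
  expect_equal(count_processes(stub2, cc$soma), 0L)
})

test_that("sholl profile counts ring crossings geometrically", {
  # no processes -> all-zero profile
  p0 <- sholl_profile(matrix(0L, 41, 41), c(21, 21), soma_area_um2 = 100,
                      step_um = 2, pixel_size_um = 1)
  expect_true(all(p0$crossings == 0L))

  # one straight radial process: one crossing at every ring it spans
  sk <- matrix(0L, 121, 121)
  sk[61, 75:115] <- 1L # radial arm from r=14 to r=54 px
  prof <- sholl_profile(sk, c(61, 61), soma_area_um2 = pi * 10^2,
                        step_um = 2, pixel_size_um = 1)
  spanned <- prof$radii_um > 14 & prof$radii_um < 54
  expect_true(all(prof$crossings[spanned] == 1L))
  expect_true(all(diff(prof$radii_um) > 0))

  # symmetric Y branching: 1 crossing inside, 2 beyond the fork; the
  # two arms run vertically from the fork so every ring they span is
  # met (radial increment per arm pixel < 1)
  yk <- matrix(0L, 161, 161)
  yk[81, 95:115] <- 1L                 # trunk: radius 14..34
  yk[41:121, 115] <- 1L                # both arms: radius 34..sqrt(34^2+40^2)
  profy <- sholl_profile(yk, c(81, 81), soma_area_um2 = pi * 10^2,
                         step_um = 2, pixel_size_um = 1)
  inner <- profy$radii_um > 16 & profy$radii_um < 32
  outer_r <- profy$radii_um > 36 & profy$radii_um < 50
  expect_true(all(profy$crossings[inner] == 1L))
  expect_true(all(profy$crossings[outer_r] == 2L))
})

test_that("sholl-derived statistics follow the increment formula", {
  # all-zero profile with zero processes: SRI undefined, never 0
  p0 <- structure(list(radii_um = c(2, 4, 6), crossings = c(0L, 0L, 0L),
                       center = c(0, 0)), class = "sholl_profile")
  d0 <- sholl_derived(p0, 0L)
  expect_equal(d0$dendritic_maximum, 0L)
  expect_equal(d0$critical_radius_um, 2)
  expect_equal(d0$branching_index, 0)
  expect_true(is.na(d0$sri))

  # single straight process: BI = 1 * r1 (the single 0 -> 1 increment)
  p1 <- structure(list(radii_um = c(3, 5, 7), crossings = c(1L, 1L, 1L),
                       center = c(0, 0)), class = "sholl_profile")
  d1 <- sholl_derived(p1, 1L)
  expect_equal(d1$branching_index, 3)
  expect_equal(d1$dendritic_maximum, 1L)
  expect_equal(d1$sri, 1)

  # Y cell: one primary process, max crossings 2 -> SRI 2; only positive
  # increments contribute, weighted by the ring radius
  p2 <- structure(list(radii_um = c(2, 4, 6, 8),
                       crossings = c(1L, 2L, 2L, 0L), center = c(0, 0)),
                  class = "sholl_profile")
  d2 <- sholl_derived(p2, 1L)
  expect_equal(d2$sri, 2)
  expect_equal(d2$branching_index, 1 * 2 + 1 * 4) # 0->1 at r=2, 1->2 at r=4
  expect_equal(d2$critical_radius_um, 4) # smallest radius attaining max
})

test_that("image metrics scale with canvas and pixel size", {
  lab <- matrix(0L, 1000, 1000)
  lab[100:150, 100:150] <- 1L
  seg_mask <- lab
  im <- image_metrics(lab, seg_mask, 0.122)
  expect_equal(im$cell_density_per_mm2, 1 / (1000 * 0.122e-3)^2)
  expect_equal(im$segmented_area_pct, 100 * sum(seg_mask) / 1e6)

  # doubling the canvas with the same cells halves the percentage
  lab2 <- matrix(0L, 1000, 2000)
  lab2[100:150, 100:150] <- 1L
  im2 <- image_metrics(lab2, lab2, 0.122)
  expect_equal(im2$segmented_area_pct, im$segmented_area_pct / 2)

  empty <- matrix(0L, 100, 100)
  im0 <- image_metrics(empty, empty, 0.122)
  expect_equal(im0$segmented_area_pct, 0)
  expect_equal(im0$cell_density_per_mm2, 0)
})

test_that("morphometry recovers the synthetic class ordering", {
  # qualitative contrasts on 40 cells/class (scaled down for runtime)
  stats <- memo("morph_by_class", {
    out <- list()
    for (cls in c("amoeboid", "activated", "ramified")) {
      rows <- lapply(1:40, function(i) {
        cl <- generate_cell(phenotype_params(cls), seed = 2000 + i)
        ex <- make_extract(cl$cell_mask, cl$soma_mask)
        cell_morphometry(ex)
      })
      out[[cls]] <- do.call(rbind, rows)
    }
    out
  })
  expect_gt(median(stats$ramified$skeleton_length_um),
            median(stats$activated$skeleton_length_um))
  expect_equal(median(stats$amoeboid$skeleton_length_um), 0)
  expect_gt(median(stats$amoeboid$soma_area_um2),
            median(stats$ramified$soma_area_um2))
  # record-level invariants over all computed cells
  all_rows <- do.call(rbind, stats)
  expect_true(all(all_rows$cell_solidity > 0 &
                    all_rows$cell_solidity <= 1))
  expect_true(all(all_rows$cell_convexity > 0 &
                    all_rows$cell_convexity <= 1))
  expect_true(all(all_rows$soma_circularity <= 1.05))
  expect_true(all(all_rows$soma_area_um2 <= all_rows$cell_area_um2))
  expect_true(all(is.na(all_rows$sri) == (all_rows$n_processes == 0)))
})
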