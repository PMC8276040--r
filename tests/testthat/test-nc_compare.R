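# toy feature table with one cell per centroid corner
toy_table <- function(values) {
  data.frame(a = values[, 1], b = values[, 2])
}

test_that("centroids are componentwise medians with midpoint rule", {
  tab <- data.frame(
    p = c(1, 2, 10, 5, 5, 5, 7, 7, 7, 1, 2, 3, 4),
    q = 1,
    class = factor(c(rep("amoeboid", 3), rep("activated", 3),
                     rep("rod_like", 3), rep("ramified", 4)),
                   levels = phenotype_classes()))
  cent <- compute_centroids(tab, c("p", "q"))
  expect_equal(cent$centroids["amoeboid", "p"], 2)   # odd-count median
  expect_equal(cent$centroids["ramified", "p"], 2.5) # midpoint rule
  # one cell per class: centroids equal those cells' values
  tab1 <- tab[c(1, 4, 7, 10), ]
  cent1 <- compute_centroids(tab1, c("p", "q"))
  expect_equal(as.numeric(cent1$centroids[, "p"]), c(1, 5, 7, 1))
  expect_error(compute_centroids(tab[1:6, ], c("p", "q")), "class")
  expect_error(compute_centroids(tab, c("p", "missing")), "missing")
})

test_that("nc_classify picks the nearest centroid, ties by class order", {
  cent <- structure(list(
    centroids = matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE,
                       dimnames = list(phenotype_classes(), c("a", "b"))),
    subset = c("a", "b"), scaling = "raw",
    scale_center = c(0, 0), scale_sd = c(1, 1)),
    class = "class_centroids")
  # brute-force distance over the four centroids
  pts <- rbind(c(1, 1), c(9, 1), c(1, 9), c(9, 9), c(0, 0))
  pred <- nc_classify(toy_table(pts), cent)
  brute <- apply(pts, 1, function(p) {
    d <- sqrt(rowSums(sweep(cent$centroids, 2, p)^2))
    phenotype_classes()[which.min(d)]
  })
  expect_equal(as.character(pred), brute)
  # cell exactly at a centroid
  expect_equal(as.character(pred[5]), "amoeboid")
  # equidistant cell: first class in fixed order wins
  tie <- nc_classify(toy_table(rbind(c(5, 5))), cent)
  expect_equal(as.character(tie), "amoeboid")
  # zscore-mode invariance to affine rescaling of a column
  set.seed(1)
  tab <- data.frame(a = rnorm(40, rep(c(0, 10), 20)),
                    b = rnorm(40),
                    class = factor(rep(phenotype_classes(), 10),
                                   levels = phenotype_classes()))
  cz <- compute_centroids(tab, c("a", "b"), scaling = "zscore")
  p1 <- nc_classify(tab, cz)
  tab2 <- tab; tab2$a <- tab2$a * 1000 + 5
  cz2 <- compute_centroids(tab2, c("a", "b"), scaling = "zscore")
  expect_equal(nc_classify(tab2, cz2), p1)
})

test_that("conformity is trace over total and permutation invariant", {
  # identical labels -> conformity 1, diagonal matrix
  lab <- factor(rep(phenotype_classes(), each = 5),
                levels = phenotype_classes())
  cf1 <- conformity(lab, lab)
  expect_equal(cf1$conformity, 1.0)
  expect_true(all(cf1$matrix[upper.tri(cf1$matrix)] == 0))

  # constructed 40/50 case
  cnn <- factor(c(rep("amoeboid", 10), rep("activated", 15),
                  rep("rod_like", 15), rep("ramified", 10)),
                levels = phenotype_classes())
  nc <- cnn
  nc[11:15] <- "rod_like"  # 5 activated -> rod_like
  nc[26:30] <- "activated" # 5 rod_like -> activated
  cf2 <- conformity(cnn, nc)
  expect_equal(cf2$conformity, 40 / 50)
  expect_equal(cf2$matrix["activated", "rod_like"], 5L)

  # permuting the cell order leaves the result unchanged
  perm <- sample(length(cnn))
  cf3 <- conformity(cnn[perm], nc[perm])
  expect_equal(cf3$matrix, cf2$matrix)
  expect_error(conformity(factor(character(0)), factor(character(0))),
               "empty")
})

test_that("exact symmetry test matches the closed-form binomial", {
  # perfectly symmetric matrix -> p = 1
  m <- matrix(c(5, 2, 1, 0,  2, 5, 3, 1,  1, 3, 5, 2,  0, 1, 2, 5), 4, 4)
  expect_equal(exact_symmetry_test(m)$p_value, 1)

  # single discordant pair 10 vs 0: p = 2 * (1/2)^10
  m2 <- diag(4) * 10
  m2[1, 2] <- 10; m2[2, 1] <- 0
  st <- exact_symmetry_test(m2)
  pair <- st$pairs[st$pairs$i == 1 & st$pairs$j == 2, ]
  expect_equal(pair$p, 2 * 0.5^10)
  expect_equal(pair$p, 0.001953125)

  # balanced 1-1 pair: p = 1; all-zero off-diagonals: p = 1
  m3 <- diag(4); m3[1, 2] <- 1; m3[2, 1] <- 1
  expect_equal(exact_symmetry_test(m3)$p_value, 1)
  expect_equal(exact_symmetry_test(diag(4) * 3)$p_value, 1)
})

test_that("subset enumeration matches the closed-form counts", {
  # 4 parameters, sizes 2..4: C(4,2)+C(4,3)+C(4,4) = 11
  s4 <- enumerate_subsets(letters[1:4], 2, 4)
  expect_equal(length(s4), 11L)
  expect_equal(length(unique(vapply(s4, paste, "", collapse = ""))), 11L)
  # k = n..n: exactly one subset
  expect_equal(length(enumerate_subsets(letters[1:5], 5, 5)), 1L)
  expect_error(enumerate_subsets(letters[1:4], 3, 2), "bounds")
  expect_error(enumerate_subsets(letters[1:4], 0, 2), "bounds")
})

test_that("sweep matches direct conformity and flags noise parameters", {
  set.seed(42)
  n <- 30
  cls <- factor(rep(phenotype_classes(), each = n),
                levels = phenotype_classes())
  centers <- c(amoeboid = 0, activated = 3, rod_like = 6, ramified = 9)
  tab <- data.frame(
    sig1 = rnorm(4 * n, centers[as.character(cls)], 0.8),
    sig2 = rnorm(4 * n, centers[as.character(cls)] * 2, 1.5),
    noise = rnorm(4 * n, 0, 1))
  sw <- sweep_subsets(tab, cls, parameters = names(tab), k_min = 2,
                      k_max = 3)
  expect_equal(nrow(sw$results), 4L) # C(3,2) + C(3,3)
  expect_true(all(sw$results$conformity >= 0 &
                    sw$results$conformity <= 1))
  # full-subset sweep row equals a direct conformity call
  training <- tab; training$class <- cls
  cent <- compute_centroids(training, names(tab))
  direct <- conformity(cls, nc_classify(tab, cent))$conformity
  expect_equal(sw$results$conformity[sw$results$k == 3], direct)
  # the pure-noise parameter cannot help: the informative pair beats the
  # pairs that swap an informative parameter for noise
  conf <- setNames(sw$results$conformity, sw$results$subset)
  expect_gte(conf[["sig1+sig2"]], conf[["sig1+noise"]])
  expect_gte(conf[["sig1+sig2"]], conf[["sig2+noise"]])
})

test_that("correlation analysis reproduces rank-based oracles", {
  set.seed(7)
  x <- rnorm(25)
  tab <- data.frame(a = x, b = x^3, c = rnorm(25), d = rnorm(25))
  cls <- factor(rep(phenotype_classes(), length.out = 25),
                levels = phenotype_classes())
  ca <- correlation_analysis(tab, cls, parameters = names(tab))
  # monotone transform pair: rho = 1 (rank invariance)
  expect_equal(ca$rho["a", "b"], 1)
  expect_equal(diag(ca$rho), rep(1, 4), ignore_attr = TRUE)
  # brute-force rank-then-Pearson oracle on every pair
  for (i in seq_len(nrow(ca$pairs))) {
    p1 <- ca$pairs$p1[i]; p2 <- ca$pairs$p2[i]
    expect_equal(ca$pairs$rho[i], oracle_spearman(tab[[p1]], tab[[p2]]),
                 tolerance = 1e-12)
  }
  expect_true(is.numeric(ca$correlation))
  expect_error(correlation_analysis(tab[1:2, ], cls[1:2],
                                    parameters = names(tab)),
               "3 cells")
})

test_that("conformity drops for strongly correlated parameter pairs", {
  # directional property: pairs with |rho| > 0.8 conform less on average
  # than pairs with |rho| < 0.2 (four informative but partly redundant
  # parameters plus independent ones)
  set.seed(11)
  n <- 40
  cls <- factor(rep(phenotype_classes(), each = n),
                levels = phenotype_classes())
  # mu2 is chosen with zero covariance against mu1 across classes, so
  # pairs mixing the two signal axes are weakly correlated but jointly
  # informative; r1/r2 (and i1 with either of them) share one axis and
  # are strongly correlated, i.e. redundant
  mu1 <- c(amoeboid = 0, activated = 2, rod_like = 4, ramified = 6)
  mu2 <- c(amoeboid = 4, activated = 0, rod_like = 6, ramified = 2)
  base <- rnorm(4 * n, mu1[as.character(cls)], 1)
  tab <- data.frame(
    r1 = base + rnorm(4 * n, 0, 0.1),
    r2 = base + rnorm(4 * n, 0, 0.1),
    i1 = rnorm(4 * n, mu1[as.character(cls)], 1),
    i2 = rnorm(4 * n, mu2[as.character(cls)], 1))
  ca <- correlation_analysis(tab, cls, parameters = names(tab))
  strong <- ca$pairs[abs(ca$pairs$rho) > 0.8, ]
  weak <- ca$pairs[abs(ca$pairs$rho) < 0.2, ]
  expect_gt(nrow(strong), 0)
  expect_gt(nrow(weak), 0)
  expect_lt(mean(strong$conformity), mean(weak$conformity))
})

test_that("feature_table extracts the 17 NC parameters and checks NA", {
  cc <- cross_cell()
  morph <- morphometry_table(list(make_extract(cc$cell, cc$soma)))
  ft <- feature_table(morph)
  expect_equal(setdiff(names(ft), "cell_id"), nc_parameters())
  expect_equal(length(nc_parameters()), 17L)
  expect_false("sri" %in% names(ft))
  # a cell with undefined SRI still yields a complete feature row
  am <- generate_cell(phenotype_params("amoeboid"), seed = 5)
  morph2 <- morphometry_table(list(make_extract(am$cell_mask,
                                                am$soma_mask)))
  expect_true(is.na(morph2$sri))
  expect_false(anyNA(feature_table(morph2)[, nc_parameters()]))
})
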