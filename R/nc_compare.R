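# Nearest-centroid (NC) classification over morphometric parameter
# subsets and its comparison with the CNN classification: per-class
# median centroids, Euclidean nearest-centroid assignment, degree of
# conformity (trace over total of the cross-tabulation), an exact
# symmetry test for paired contingency tables, exhaustive subset sweeps
# and Spearman correlation analysis.

#' Per-class median centroids
#'
#' Class centroids are the componentwise medians of the selected
#' parameters over each class's training cells (midpoint interpolation
#' for even counts). With `scaling = "zscore"` the pooled mean and
#' standard deviation of each parameter are stored and applied before
#' distance computations.
#'
#' @param table data.frame of cells; must contain the columns in
#'   `subset` and a `class` column (or pass `classes`).
#' @param subset character vector of parameter names (2 to 17 of
#'   [nc_parameters()], or any numeric columns).
#' @param classes class labels per row; defaults to `table$class`.
#' @param scaling `"raw"` or `"zscore"`.
#' @return list of class `class_centroids`: `centroids` (4 x k matrix),
#'   `subset`, `scaling`, `scale_center`, `scale_sd`.
#' @export
compute_centroids <- function(table, subset, classes = table$class,
                              scaling = c("raw", "zscore")) {
  scaling <- match.arg(scaling)
  missing_cols <- setdiff(subset, names(table))
  if (length(missing_cols))
    stop("missing parameter columns: ", paste(missing_cols, collapse = ", "))
  classes <- factor(classes, levels = phenotype_classes())
  if (any(tabulate(classes, 4L) == 0L))
    stop("every class needs at least one training cell")
  m <- as.matrix(table[, subset, drop = FALSE])
  if (anyNA(m)) stop("missing values in parameter columns")
  ctr <- rep(0, length(subset)); sdv <- rep(1, length(subset))
  if (scaling == "zscore") {
    ctr <- colMeans(m)
    sdv <- apply(m, 2L, sd)
    sdv[sdv == 0] <- 1
    m <- sweep(sweep(m, 2L, ctr), 2L, sdv, "/")
  }
  cent <- t(vapply(phenotype_classes(), function(cl)
    apply(m[classes == cl, , drop = FALSE], 2L, median),
    numeric(length(subset))))
  structure(list(centroids = cent, subset = subset, scaling = scaling,
                 scale_center = ctr, scale_sd = sdv),
            class = "class_centroids")
}

#' Nearest-centroid classification
#'
#' Assigns each cell the class of the nearest centroid (Euclidean
#' distance in the, possibly z-scored, parameter subspace). Ties are
#' broken by the fixed class order.
#'
#' @param table data.frame containing the centroid's parameter columns.
#' @param centroids a [compute_centroids()] result.
#' @return factor of assigned classes.
#' @export
nc_classify <- function(table, centroids) {
  missing_cols <- setdiff(centroids$subset, names(table))
  if (length(missing_cols))
    stop("missing parameter columns: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(table[, centroids$subset, drop = FALSE])
  m <- sweep(sweep(m, 2L, centroids$scale_center), 2L,
             centroids$scale_sd, "/")
  d2 <- vapply(seq_len(nrow(centroids$centroids)), function(k)
    rowSums(sweep(m, 2L, centroids$centroids[k, ])^2),
    numeric(nrow(m)))
  if (nrow(m) == 1L) d2 <- matrix(d2, 1L)
  idx <- apply(d2, 1L, which.min) # which.min takes the first on ties
  factor(phenotype_classes()[idx], levels = phenotype_classes())
}

#' Degree of conformity between two classifications
#'
#' Cross-tabulates CNN against NC labels (rows = CNN class, columns = NC
#' class); the degree of conformity is the sum of the diagonal divided by
#' the total count. The matrix symmetry is assessed with
#' [exact_symmetry_test()].
#'
#' @param cnn_labels,nc_labels equal-length label vectors over the four
#'   classes.
#' @return list of class `conformity_result`: `matrix` (4 x 4),
#'   `conformity`, `symmetry_p`, `symmetry` (full test result).
#' @export
conformity <- function(cnn_labels, nc_labels) {
  if (length(cnn_labels) == 0L) stop("empty input")
  if (length(cnn_labels) != length(nc_labels))
    stop("label vectors differ in length")
  cnn_labels <- factor(cnn_labels, levels = phenotype_classes())
  nc_labels <- factor(nc_labels, levels = phenotype_classes())
  m <- matrix(as.integer(table(cnn_labels, nc_labels)), 4, 4,
              dimnames = list(cnn = phenotype_classes(),
                              nc = phenotype_classes()))
  sym <- exact_symmetry_test(m)
  structure(list(matrix = m, conformity = sum(diag(m)) / sum(m),
                 symmetry_p = sym$p_value, symmetry = sym),
            class = "conformity_result")
}

#' Exact symmetry test for paired contingency tables
#'
#' For each off-diagonal pair (i, j), an exact two-sided binomial test of
#' `n_ij` successes in `n_ij + n_ji` trials at p = 1/2 (the McNemar-type
#' exact test); pairwise p-values are multiplicity-adjusted (FDR by
#' default) and the global p-value is the minimum adjusted pairwise p.
#' With no discordant pairs the p-value is 1.
#'
#' @param m square count matrix.
#' @param method multiplicity adjustment passed to [stats::p.adjust()].
#' @return list: `p_value` (global), `pairs` (data.frame with i, j,
#'   n_ij, n_ji, p, p_adj).
#' @export
exact_symmetry_test <- function(m, method = "fdr") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  k <- nrow(m)
  rows <- list()
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k) {
      nij <- m[i, j]; nji <- m[j, i]
      n <- nij + nji
      p <- if (n == 0) 1 else min(1, 2 * pbinom(min(nij, nji), n, 0.5))
      rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = j, n_ij = nij, n_ji = nji, p = p)
    }
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- p.adjust(pairs$p, method = method)
  list(p_value = min(pairs$p_adj), pairs = pairs)
}

#' Enumerate parameter subsets
#'
#' Lexicographic, duplicate-free enumeration of all subsets of
#' `parameters` with sizes `k_min` to `k_max`. Over the 17
#' nearest-centroid parameters and sizes 2-17 this yields 131,054
#' subsets.
#'
#' @param parameters character vector of parameter names.
#' @param k_min,k_max subset size bounds.
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(parameters = nc_parameters(), k_min = 2L,
                              k_max = length(parameters)) {
  n <- length(parameters)
  if (k_min < 1L || k_min > k_max || k_max > n)
    stop("invalid subset size bounds")
  out <- vector("list", sum(choose(n, k_min:k_max)))
  pos <- 0L
  for (k in k_min:k_max) {
    cmb <- combn(n, k)
    for (c_i in seq_len(ncol(cmb))) {
      pos <- pos + 1L
      out[[pos]] <- parameters[cmb[, c_i]]
    }
  }
  out
}

#' Conformity sweep over parameter subsets
#'
#' Runs nearest-centroid classification and the conformity analysis for
#' every subset in the given size range.
#'
#' @param table feature table of the cells to classify.
#' @param cnn_labels reference (CNN) labels for `table` rows.
#' @param training_table feature table used for centroids; must have a
#'   `class` column. Defaults to `table` with `cnn_labels` as classes.
#' @param parameters candidate parameters.
#' @param k_min,k_max subset sizes.
#' @param scaling passed to [compute_centroids()].
#' @return list of class `sweep_result`: `results` (data.frame subset,
#'   k, conformity, symmetry_p), `per_k` (data.frame k, min, median,
#'   max conformity).
#' @export
sweep_subsets <- function(table, cnn_labels, training_table = NULL,
                          parameters = nc_parameters(), k_min = 2L,
                          k_max = length(parameters),
                          scaling = "raw") {
  if (is.null(training_table)) {
    training_table <- table
    training_table$class <- cnn_labels
  }
  subsets <- enumerate_subsets(parameters, k_min, k_max)
  res <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    k = vapply(subsets, length, integer(1)),
    conformity = NA_real_, symmetry_p = NA_real_)
  for (i in seq_along(subsets)) {
    cent <- compute_centroids(training_table, subsets[[i]],
                              scaling = scaling)
    nc <- nc_classify(table, cent)
    cf <- conformity(cnn_labels, nc)
    res$conformity[i] <- cf$conformity
    res$symmetry_p[i] <- cf$symmetry_p
  }
  per_k <- do.call(rbind, lapply(split(res$conformity, res$k), function(v)
    data.frame(min = min(v), median = median(v), max = max(v))))
  per_k$k <- as.integer(rownames(per_k))
  structure(list(results = res, per_k = per_k[, c("k", "min", "median",
                                                  "max")]),
            class = "sweep_result")
}

#' Spearman correlation and conformity-versus-correlation analysis
#'
#' Computes Spearman's rank correlation for all parameter pairs, the
#' two-parameter nearest-centroid conformity for each pair, and the
#' least-squares regression of conformity against the absolute
#' correlation coefficient.
#'
#' @param table feature table of classified cells.
#' @param cnn_labels reference labels.
#' @param parameters parameters to analyse.
#' @param scaling passed to [compute_centroids()].
#' @return list: `rho` (pairwise Spearman matrix), `pairs` (data.frame
#'   p1, p2, rho, conformity), `regression` (intercept, slope),
#'   `correlation` (Pearson r between conformity and |rho|).
#' @export
correlation_analysis <- function(table, cnn_labels,
                                 parameters = nc_parameters(),
                                 scaling = "raw") {
  if (nrow(table) < 3L) stop("need at least 3 cells")
  m <- as.matrix(table[, parameters, drop = FALSE])
  rho <- suppressWarnings(cor(m, method = "spearman"))
  training <- table
  training$class <- cnn_labels
  pairs <- t(combn(parameters, 2L))
  out <- data.frame(p1 = pairs[, 1L], p2 = pairs[, 2L],
                    rho = NA_real_, conformity = NA_real_)
  for (i in seq_len(nrow(out))) {
    sub <- c(out$p1[i], out$p2[i])
    out$rho[i] <- rho[sub[1L], sub[2L]]
    cent <- compute_centroids(training, sub, scaling = scaling)
    nc <- nc_classify(table, cent)
    out$conformity[i] <- conformity(cnn_labels, nc)$conformity
  }
  ok <- is.finite(out$rho)
  fit <- lm(conformity ~ abs_rho,
            data = data.frame(conformity = out$conformity[ok],
                              abs_rho = abs(out$rho[ok])))
  list(rho = rho, pairs = out,
       regression = coef(fit),
       correlation = cor(out$conformity[ok], abs(out$rho[ok])))
}

#' Assemble a feature table from morphometry output
#'
#' Keeps the 17 nearest-centroid parameters (the ramification index is
#' excluded because it is undefined for cells without processes) plus
#' `cell_id`, and verifies completeness.
#'
#' @param morph data.frame from [morphometry_table()].
#' @param cnn_labels optional CNN labels to attach as `class`.
#' @return data.frame feature table.
#' @export
feature_table <- function(morph, cnn_labels = NULL) {
  cols <- c("cell_id", nc_parameters())
  missing_cols <- setdiff(cols, names(morph))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  out <- morph[, cols]
  if (anyNA(out[, nc_parameters()]))
    stop("missing values in nearest-centroid parameters")
  if (!is.null(cnn_labels))
    out$class <- factor(cnn_labels, levels = phenotype_classes())
  out
}
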