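# Grayscale images are numeric matrices in [0, 1] (rows = y, top-left
# origin); binary masks are integer matrices in {0, 1}; label images are
# integer matrices with consecutive positive ids and 0 background.

#' Validate and coerce a grayscale image
#'
#' @param img numeric matrix; values must be finite and in \[0, 1\].
#' @return the validated matrix.
#' @export
as_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("grayscale image must be a 2D numeric matrix")
  if (any(!is.finite(img)))
    stop("grayscale image contains non-finite values")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("grayscale image values must lie in [0, 1]")
  pmin(pmax(img, 0), 1)
}

#' Coerce to a binary mask
#' @param mask matrix (logical or numeric); nonzero means foreground.
#' @return integer matrix in \{0, 1\}.
#' @export
as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}

#' Convert an RGB array to grayscale by luminance
#' @param arr array (H, W, 3) in \[0, 1\].
#' @return grayscale matrix.
#' @export
rgb_to_gray <- function(arr) {
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    stop("expected an (H, W, 3) array")
  0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
}

gaussian_kernel <- function(sigma, order = 0L) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma^2 * g)
  if (order == 2L) return((x^2 - sigma^2) / sigma^4 * g)
  stop("order must be 0, 1 or 2")
}

#' Gaussian blur
#' @param img grayscale matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  g <- gaussian_kernel(sigma)
  cpp_sep_conv(img, g, g)
}

#' Contrast limited adaptive histogram equalization
#'
#' Tile-based CLAHE with bilinear interpolation between tile mappings.
#' Tiles with zero intensity range are mapped identically, so a constant
#' image is returned unchanged.
#'
#' @param img grayscale matrix in \[0, 1\].
#' @param clip_limit histogram clip limit as a multiple of the uniform bin
#'   count (2 means no bin may hold more than twice the average count).
#' @param tile_grid number of tiles per image side.
#' @param nbins histogram bins.
#' @return equalized matrix in \[0, 1\].
#' @export
clahe <- function(img, clip_limit = 2, tile_grid = 8L, nbins = 256L) {
  img <- as_gray_image(img)
  cpp_clahe(img, as.integer(tile_grid), clip_limit, as.integer(nbins))
}

#' White top-hat transform with a disc structuring element
#'
#' Image minus its morphological opening; retains structures narrower than
#' the disc (somata, processes) and removes the smooth background.
#'
#' @param img grayscale matrix.
#' @param radius disc radius in pixels (fractional radii allowed; the
#'   structuring element is the set of offsets with distance `<= radius`).
#' @return top-hat filtered matrix (non-negative).
#' @export
white_tophat <- function(img, radius) {
  opened <- cpp_disc_dilate(cpp_disc_erode(img, radius), radius)
  out <- img - opened
  out[out < 0] <- 0
  out
}

#' Otsu threshold
#'
#' Global threshold maximizing between-class variance of the histogram.
#'
#' @param img grayscale matrix.
#' @param nbins number of histogram bins.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(
    tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins))
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- length(v)
  mt <- m[nbins]
  w0 <- w[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-nbins] / w0
  mu1 <- (mt - m[-nbins]) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv)
  breaks[k + 1L]
}

#' Local adaptive mean segmentation
#'
#' Marks pixels whose intensity exceeds the mean of their disc
#' neighbourhood by more than `offset`.
#'
#' @param img grayscale matrix.
#' @param radius neighbourhood disc radius in pixels.
#' @param offset additive threshold offset in intensity units.
#' @return binary mask.
#' @export
adaptive_threshold <- function(img, radius = 5, offset = 0) {
  mu <- cpp_disc_mean(img, radius)
  as_mask(img > mu + offset)
}

#' Hessian ridge filter
#'
#' Positive part of the negated smallest eigenvalue of the Hessian of the
#' Gaussian-smoothed image; amplifies thin bright curvilinear structures
#' such as cell processes.
#'
#' @param img grayscale matrix (bright structures on dark background).
#' @param sigma Gaussian scale in pixels.
#' @return non-negative ridge response matrix.
#' @export
ridge_filter <- function(img, sigma = 5) {
  g0 <- gaussian_kernel(sigma, 0L)
  g1 <- gaussian_kernel(sigma, 1L)
  g2 <- gaussian_kernel(sigma, 2L)
  ixx <- cpp_sep_conv(img, g0, g2)
  iyy <- cpp_sep_conv(img, g2, g0)
  ixy <- cpp_sep_conv(img, g1, g1)
  lam_min <- (ixx + iyy) / 2 - sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  out <- -lam_min
  out[out < 0] <- 0
  out
}

#' Connected component labelling
#' @param mask binary mask.
#' @param connectivity 8 (default) or 4.
#' @return label image with consecutive ids from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  cpp_label(as_mask(mask), as.integer(connectivity))
}

#' Binary morphological closing with a disc
#' @param mask binary mask.
#' @param radius disc radius in pixels (fractional allowed).
#' @return closed binary mask.
#' @export
binary_closing <- function(mask, radius) {
  m <- cpp_disc_erode(cpp_disc_dilate(as_mask(mask) + 0, radius), radius)
  as_mask(m > 0.5)
}

#' Binary morphological dilation with a disc
#' @param mask binary mask.
#' @param radius disc radius in pixels.
#' @return dilated binary mask.
#' @export
binary_dilation <- function(mask, radius) {
  as_mask(cpp_disc_dilate(as_mask(mask) + 0, radius) > 0.5)
}

#' Morphological thinning (skeletonization)
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected medial axis.
#'
#' @param mask binary mask.
#' @return skeleton mask.
#' @export
thin_mask <- function(mask) {
  cpp_thin(as_mask(mask))
}

#' Remove labelled components below a pixel-count threshold
#' @param mask binary mask.
#' @param min_area smallest surviving component area in pixels; components
#'   with strictly fewer pixels are removed.
#' @param connectivity component connectivity.
#' @return filtered binary mask.
#' @export
remove_small_components <- function(mask, min_area, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(as_mask(lab))
  sizes <- tabulate(lab[lab > 0L], max(lab))
  keep <- which(sizes >= min_area)
  as_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)))
}

component_pixel_counts <- function(lab) {
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L], max(lab))
}
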