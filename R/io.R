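# Plain-text raster I/O. Portable graymap (PGM, "P2") is used for
# grayscale images and 16-bit label images, portable pixmap (PPM, "P3")
# for color overlays. Both are text formats readable by standard viewers.

#' Write a grayscale image or label image as plain (ASCII) PGM
#'
#' @param img numeric matrix in \[0, 1\] (scaled to `maxval`) or integer
#'   matrix of labels (written verbatim when `labels = TRUE`).
#' @param path output file.
#' @param maxval maximum sample value (255 for 8-bit, 65535 for 16-bit).
#' @param labels if `TRUE`, `img` holds integer ids written unscaled.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L, labels = FALSE) {
  if (labels) {
    vals <- as.integer(t(img))
    maxval <- max(1L, max(vals))
  } else {
    vals <- as.integer(round(pmin(pmax(t(img), 0), 1) * maxval))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read a plain (ASCII) PGM image
#'
#' @param path PGM file (magic "P2").
#' @param labels if `TRUE`, return integer values verbatim instead of
#'   rescaling to \[0, 1\].
#' @return numeric matrix in \[0, 1\], or integer matrix when `labels`.
#' @export
read_pgm <- function(path, labels = FALSE) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain PGM (P2) is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong sample count")
  m <- t(matrix(vals, nrow = w, ncol = h))
  if (labels) matrix(as.integer(m), h, w) else m / maxval
}

#' Write an RGB overlay as plain (ASCII) PPM
#'
#' @param arr array (H, W, 3) with values in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(arr, path) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  r <- as.integer(round(pmin(pmax(t(arr[, , 1]), 0), 1) * 255))
  g <- as.integer(round(pmin(pmax(t(arr[, , 2]), 0), 1) * 255))
  b <- as.integer(round(pmin(pmax(t(arr[, , 3]), 0), 1) * 255))
  inter <- as.vector(rbind(r, g, b))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(inter, collapse = " "), con)
  invisible(path)
}

#' Read a grayscale image from PGM or CSV
#'
#' CSV files are read as numeric matrices (no header) and rescaled to
#' \[0, 1\] if their maximum exceeds 1.
#'
#' @param path input file; format chosen by extension.
#' @return grayscale matrix in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext %in% c("csv", "txt")) {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    if (max(m) > 1) m <- m / max(m)
    return(as_gray_image(m))
  }
  stop("unsupported image format: ", ext)
}
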