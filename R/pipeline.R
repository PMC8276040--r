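# Orchestration: segmentation -> morphometry -> classification ->
# summaries and color-coded overlays, over a batch of images.

#' Default overlay palette
#'
#' Ramified microglia blue, rod-like orange, activated red, amoeboid
#' gray.
#' @return named list of RGB triples in \[0, 1\].
#' @export
default_palette <- function() {
  list(amoeboid = c(0.5, 0.5, 0.5),
       activated = c(0.85, 0.1, 0.1),
       rod_like = c(1.0, 0.55, 0.0),
       ramified = c(0.1, 0.3, 0.9))
}

#' Pipeline configuration
#'
#' @param inputs character vector of image paths (PGM or CSV) or a named
#'   list of in-memory grayscale matrices.
#' @param segmentation a [segmentation_config()].
#' @param classifier optional trained `cnn_model` (or a path to a JSON
#'   checkpoint from [save_model()]); when absent, cells are left
#'   unclassified.
#' @param input_mode classifier input representation, `"mask"` or
#'   `"gray"`.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param palette overlay palette.
#' @param step_um Sholl ring spacing for morphometry.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, segmentation = segmentation_config(),
                            classifier = NULL, input_mode = "mask",
                            out_dir = tempfile("microglia_out_"),
                            seed = 1L, palette = default_palette(),
                            step_um = 2) {
  structure(list(inputs = inputs, segmentation = segmentation,
                 classifier = classifier, input_mode = input_mode,
                 out_dir = out_dir, seed = as.integer(seed),
                 palette = palette, step_um = step_um),
            class = "pipeline_config")
}

#' Run the full pipeline over a batch of images
#'
#' For each input image: segmentation into labeled cells, per-cell
#' morphometry, optional CNN classification, per-image metrics, a
#' color-coded overlay, and CSV/JSON outputs on disk. Per-image failures
#' are logged in the manifest and skipped; they do not abort the batch.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list with per-image records and output paths),
#'   invisibly; all artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$classifier
  if (is.character(model)) model <- load_model(model)
  inputs <- config$inputs
  if (length(inputs) == 0L) {
    warning("empty input set; writing empty manifest")
    manifest <- list(images = list(), n_images = 0L)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  names(inputs) <- names(inputs) %||%
    vapply(seq_along(inputs), function(i)
      if (is.character(inputs)) basename(inputs[i]) else
        sprintf("image_%03d", i), character(1))
  records <- list()
  all_morph <- list()
  for (nm in names(inputs)) {
    rec <- tryCatch({
      img <- inputs[[nm]]
      if (is.character(img)) img <- read_gray_image(img)
      seg <- segment_image(img, config$segmentation)
      pre_mask <- as_mask(seg$somata | seg$processes)
      im <- image_metrics(seg$labels, pre_mask,
                          config$segmentation$pixel_size_um)
      morph <- if (length(seg$cells))
        morphometry_table(seg$cells, config$step_um) else NULL
      labels_by_cell <- NULL
      if (!is.null(model) && length(seg$cells)) {
        side <- model$spec$input_side
        stack <- array(0, c(side, side, length(seg$cells)))
        for (i in seq_along(seg$cells))
          stack[, , i] <- prepare_input(seg$cells[[i]],
                                        config$input_mode, side)
        pr <- predict_cnn(model, stack)
        labels_by_cell <- pr$labels
        morph$class <- as.character(labels_by_cell)
        probs <- as.data.frame(pr$probs)
        names(probs) <- paste0("p_", phenotype_classes())
        morph <- cbind(morph, probs)
        ov <- render_overlay(seg$labels,
                             setNames(as.character(labels_by_cell),
                                      seq_along(seg$cells)),
                             config$palette)
        write_ppm(ov, file.path(config$out_dir,
                                paste0(nm, "_overlay.ppm")))
      }
      if (!is.null(morph)) {
        morph$source_image <- nm
        all_morph[[nm]] <- morph
        write.csv(morph, file.path(config$out_dir,
                                   paste0(nm, "_cells.csv")),
                  row.names = FALSE)
      }
      write_pgm(seg$labels, file.path(config$out_dir,
                                      paste0(nm, "_labels.pgm")),
                labels = TRUE)
      list(image = nm, status = "ok",
           n_cells = length(seg$cells),
           stage_counts = seg$stage_counts,
           segmented_area_pct = im$segmented_area_pct,
           cell_density_per_mm2 = im$cell_density_per_mm2,
           classes = if (!is.null(labels_by_cell))
             as.list(table(labels_by_cell)) else NULL)
    }, error = function(e)
      list(image = nm, status = "error", message = conditionMessage(e)))
    records[[nm]] <- rec
  }
  if (length(all_morph)) {
    combined <- do.call(rbind, all_morph)
    rownames(combined) <- NULL
    write.csv(combined, file.path(config$out_dir, "all_cells.csv"),
              row.names = FALSE)
  }
  manifest <- list(images = records, n_images = length(inputs),
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-group class counts and percentages
#'
#' @param labels_by_group named list (or factor-splittable structure) of
#'   label vectors, one entry per group (e.g. per region of interest).
#' @return data.frame with one row per group and class: counts and
#'   percentages (percentages sum to 100 per group); empty groups are
#'   flagged with `NA` percentages.
#' @export
class_percentages <- function(labels_by_group) {
  rows <- lapply(names(labels_by_group), function(g) {
    lab <- factor(labels_by_group[[g]], levels = phenotype_classes())
    counts <- as.integer(table(lab))
    pct <- if (length(lab) == 0L) rep(NA_real_, 4L)
           else 100 * counts / length(lab)
    data.frame(group = g, class = phenotype_classes(), count = counts,
               percentage = pct)
  })
  do.call(rbind, rows)
}

#' Render a class-colored overlay of a label image
#'
#' Background stays white; each cell's pixels are tinted with its class
#' color.
#'
#' @param labels label image.
#' @param class_by_cell named character vector mapping label id (as
#'   character) to class name; every id present in `labels` must be
#'   covered.
#' @param palette named list of RGB triples.
#' @return array (H, W, 3) in \[0, 1\].
#' @export
render_overlay <- function(labels, class_by_cell,
                           palette = default_palette()) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing_ids <- setdiff(as.character(ids), names(class_by_cell))
  if (length(missing_ids))
    stop("no class assigned to label(s): ",
         paste(missing_ids, collapse = ", "))
  h <- nrow(labels); w <- ncol(labels)
  out <- array(1, c(h, w, 3L))
  for (id in ids) {
    cls <- class_by_cell[[as.character(id)]]
    col <- palette[[cls]]
    if (is.null(col)) stop("palette has no color for class ", cls)
    sel <- labels == id
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- col[ch]
      out[, , ch] <- plane
    }
  }
  out
}
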