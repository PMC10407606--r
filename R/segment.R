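# Rule-based two-stage segmentation of root scenes.
#
# Stage 1 separates the scene into background (top/bottom felt zones), plant,
# ruler and label; stage 2 partitions the plant region into leaf, stem and
# root tissue. Both stages classify pixels by nearest palette colour within a
# tolerance; the interface is mask-level so a learned segmenter could be
# dropped in for real photographs.

SCENE_MASK_CLASSES <- c("background_top", "background_bottom", "plant",
                        "ruler", "label")
TISSUE_CLASSES <- c("none", "leaf", "stem", "root")

.colour_dists <- function(img, colour) {
  sqrt((img[, , 1] - colour[1])^2 + (img[, , 2] - colour[2])^2 +
         (img[, , 3] - colour[3])^2)
}

#' Rotate an image (and masks) to landscape orientation
#'
#' Images are standardised to landscape before processing; a portrait image
#' is rotated 90 degrees clockwise.
#' @param img H x W x 3 array.
#' @return possibly rotated array.
#' @export
to_landscape <- function(img) {
  if (dim(img)[1] <= dim(img)[2]) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- array(0, c(W, H, dim(img)[3]))
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- t(img[H:1, , ch])
  out
}

.clean_small_components <- function(lab, min_px, protect = integer(0)) {
  # merge components smaller than min_px into their majority neighbour label
  H <- nrow(lab); W <- ncol(lab)
  for (cl in setdiff(sort(unique(as.vector(lab))), protect)) {
    comp <- label_components(lab == cl, 8)
    tab <- tabulate(comp[comp > 0])
    small <- which(tab > 0 & tab < min_px)
    for (s in small) {
      px <- which(comp == s)
      rr <- ((px - 1L) %% H) + 1L; cc <- ((px - 1L) %/% H) + 1L
      nb_lab <- integer(0)
      sh <- .octile_shifts()
      for (k in seq_len(nrow(sh))) {
        r2 <- rr + sh$dr[k]; c2 <- cc + sh$dc[k]
        ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
        v <- lab[cbind(r2[ok], c2[ok])]
        nb_lab <- c(nb_lab, v[v != cl])
      }
      if (length(nb_lab))
        lab[px] <- as.integer(names(which.max(table(nb_lab))))
    }
  }
  lab
}

#' Segment a scene into background zones, plant, ruler and label
#'
#' Each pixel is assigned to the nearest palette colour within `tol`
#' (Euclidean distance in RGB); the three tissue colours collapse to a single
#' `plant` class. Pixels matching no palette colour fall back to the
#' background zone they sit in, where the zone boundary is estimated from the
#' pixels that did match a background colour. Components smaller than
#' `min_component_px` are merged into their surrounding label.
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @param palette named list of class colours, see [default_palette()].
#' @param tol per-pixel colour tolerance; palette colours must be separated
#'   by more than `2 * tol`.
#' @param min_component_px small-component cleanup threshold.
#' @return object of class `scene_mask`: list with `labels` (integer matrix
#'   indexing `SCENE_MASK_CLASSES`), `classes`, `flags`, `zone_split_est`.
#' @export
segment_scene <- function(img, palette = default_palette(), tol = 0.15,
                          min_component_px = 10) {
  stopifnot(length(dim(img)) == 3)
  if (palette_separation(palette) <= 2 * tol)
    stop("palette colours must be separated by more than 2 * tol")
  img <- to_landscape(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  # order must match SCENE_CLASSES; plant = min over leaf/stem/root
  d <- vapply(SCENE_CLASSES, function(cl) .colour_dists(img, palette[[cl]]),
              matrix(0, H, W))
  dim(d) <- c(H * W, length(SCENE_CLASSES))
  best <- max.col(-d, ties.method = "first")
  bestd <- d[cbind(seq_len(H * W), best)]
  scene_code <- c(1L, 2L, 4L, 5L, 3L, 3L, 3L)  # -> SCENE_MASK_CLASSES index
  lab <- matrix(scene_code[best], H, W)
  unmatched <- matrix(bestd > tol, H, W)
  # zone boundary estimate from matched background pixels
  rows_top <- row(lab)[lab == 1L & !unmatched]
  rows_bot <- row(lab)[lab == 2L & !unmatched]
  split_est <- if (length(rows_top) && length(rows_bot))
    (max(rows_top) + min(rows_bot)) / 2 else H / 2
  if (any(unmatched)) {
    fr <- row(lab)[unmatched]
    lab[unmatched] <- ifelse(fr <= split_est, 1L, 2L)
  }
  lab <- .clean_small_components(lab, min_component_px)
  flags <- character(0)
  if (!any(lab == 4L)) flags <- c(flags, "no-ruler")
  structure(list(labels = lab, classes = SCENE_MASK_CLASSES, flags = flags,
                 zone_split_est = split_est, tol = tol, palette = palette),
            class = "scene_mask")
}

#' Segment the plant region into leaf, stem and root tissue
#'
#' Within the `plant` region of a [segment_scene()] mask, pixels are assigned
#' to the nearest of the leaf/stem/root palette colours. The background zone
#' partition (top vs bottom felt) is carried over from the scene mask so that
#' roots can later be classified by the felt colour they lie over.
#'
#' @param img H x W x 3 RGB array (landscape).
#' @param scene_mask result of [segment_scene()].
#' @param palette,min_component_px as in [segment_scene()].
#' @return object of class `tissue_mask`: list with `labels` (integer matrix
#'   indexing `TISSUE_CLASSES`, 1 = none outside the plant), `scene`
#'   (the scene mask), `flags`.
#' @export
segment_tissue <- function(img, scene_mask, palette = default_palette(),
                           min_component_px = 10) {
  stopifnot(inherits(scene_mask, "scene_mask"))
  img <- to_landscape(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  plant <- scene_mask$labels == 3L
  lab <- matrix(1L, H, W)                    # none
  if (any(plant)) {
    dl <- .colour_dists(img, palette$leaf)
    ds <- .colour_dists(img, palette$stem)
    dr <- .colour_dists(img, palette$root)
    pick <- max.col(-cbind(dl[plant], ds[plant], dr[plant]),
                    ties.method = "first")
    lab[plant] <- pick + 1L
    lab <- .clean_small_components(lab, min_component_px, protect = 1L)
    lab[!plant] <- 1L
  }
  flags <- character(0)
  if (!any(lab == 4L)) flags <- c(flags, "empty-root")
  if (!any(plant)) flags <- c(flags, "no-plant")
  structure(list(labels = lab, classes = TISSUE_CLASSES, scene = scene_mask,
                 flags = flags), class = "tissue_mask")
}

#' Render a mask back to an RGB image using the palette
#'
#' Useful for visual QC and for the idempotence property that re-segmenting a
#' rendered mask reproduces the mask.
#'
#' @param scene_mask a `scene_mask`.
#' @param tissue_mask optional `tissue_mask` to paint tissue classes inside
#'   the plant region.
#' @param palette named list of class colours.
#' @return H x W x 3 array.
#' @export
render_mask <- function(scene_mask, tissue_mask = NULL,
                        palette = default_palette()) {
  lab <- scene_mask$labels
  H <- nrow(lab); W <- ncol(lab)
  cols <- list(palette$background_top, palette$background_bottom,
               palette$stem, palette$ruler, palette$label)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- matrix(0, H, W)
    for (k in 1:5) m[lab == k] <- cols[[k]][ch]
    img[, , ch] <- m
  }
  if (!is.null(tissue_mask)) {
    tl <- tissue_mask$labels
    tis <- list(palette$leaf, palette$stem, palette$root)
    for (ch in 1:3) {
      m <- img[, , ch]
      for (k in 2:4) m[tl == k] <- tis[[k - 1]][ch]
      img[, , ch] <- m
    }
  }
  img
}

#' Collapse a ground-truth class map to scene-mask classes
#' @param class_map integer matrix from the scene generator truth.
#' @return integer matrix coded as `SCENE_MASK_CLASSES`.
#' @export
truth_to_scene_classes <- function(class_map) {
  map <- c(1L, 2L, 4L, 5L, 3L, 3L, 3L)
  matrix(map[class_map], nrow(class_map), ncol(class_map))
}

#' Collapse a ground-truth class map to tissue classes
#' @param class_map integer matrix from the scene generator truth.
#' @return integer matrix coded as `TISSUE_CLASSES`.
#' @export
truth_to_tissue_classes <- function(class_map) {
  map <- c(1L, 1L, 1L, 1L, 2L, 3L, 4L)
  matrix(map[class_map], nrow(class_map), ncol(class_map))
}

#' Write a mask as an indexed PNG plus JSON legend
#' @param mask a `scene_mask` or `tissue_mask`.
#' @param png_path output path.
#' @export
write_mask <- function(mask, png_path) {
  lab <- mask$labels
  png::writePNG((lab - 1) / max(1, length(mask$classes) - 1), png_path)
  jsonlite::write_json(
    list(classes = mask$classes, levels = seq_along(mask$classes),
         flags = mask$flags),
    sub("\\.png$", ".json", png_path), auto_unbox = TRUE)
  invisible(png_path)
}
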