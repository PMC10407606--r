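# Synthetic root-scene generator with exact ground truth.
#
# A scene emulates the imaging convention of the rooting assay: a cutting is
# laid flat with basal adventitious roots arranged downward over a blue felt
# zone at the bottom of the frame and lateral adventitious roots to the side
# over a grey felt zone, with a ruler and a label in frame for metric
# calibration and identification.

SCENE_CLASSES <- c("background_top", "background_bottom", "ruler", "label",
                   "leaf", "stem", "root")

#' Default scene palette
#'
#' RGB triples in \[0, 1\] for each scene class. The two felt backgrounds are
#' deliberately far apart in colour space (blue bottom zone for basal roots,
#' grey top/side zone for lateral roots) because the background colour under
#' a root is what drives its basal/lateral classification downstream.
#'
#' @return named list of length-3 numeric vectors.
#' @export
default_palette <- function() {
  list(
    background_top    = c(0.60, 0.60, 0.60),
    background_bottom = c(0.10, 0.20, 0.70),
    ruler             = c(0.95, 0.85, 0.10),
    label             = c(0.95, 0.95, 0.95),
    leaf              = c(0.10, 0.50, 0.15),
    stem              = c(0.55, 0.35, 0.15),
    root              = c(0.85, 0.80, 0.55)
  )
}

#' Minimum pairwise Euclidean distance between palette colours
#' @keywords internal
palette_separation <- function(palette) {
  cols <- do.call(rbind, palette)
  min(stats::dist(cols))
}

#' Build a scene specification
#'
#' @param width,height canvas size in pixels.
#' @param zone_split last image row of the top (grey) background zone; rows
#'   below it are the bottom (blue) zone.
#' @param palette named list of RGB triples, see [default_palette()].
#' @param ruler_mm physical ruler length in mm.
#' @param ruler_px drawn ruler length in pixels.
#' @param roots list of root specs, each a list with `class` ("basal" or
#'   "lateral"), `points` (n x 2 matrix of (row, col) control points) and
#'   `thickness` (pixels).
#' @param stem integer vector c(row0, row1, col0, col1) of the stem rectangle.
#' @param ruler_rect,label_rect rectangles c(row0, row1, col0, col1).
#' @param leaves list of leaf ellipses, each list(center = c(row, col),
#'   semi = c(a_row, a_col)).
#' @param noise_sd per-channel Gaussian jitter SD added at render time.
#' @param min_palette_sep required minimum pairwise palette distance.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 400, height = 300, zone_split = 160,
                       palette = default_palette(),
                       ruler_mm = 150, ruler_px = 300,
                       roots = list(),
                       stem = c(40, 172, 188, 216),
                       ruler_rect = c(8, 20, 20, 20 + 300 - 1),
                       label_rect = c(8, 46, 345, 392),
                       leaves = list(
                         list(center = c(58, 164), semi = c(12, 16)),
                         list(center = c(52, 238), semi = c(10, 14))
                       ),
                       noise_sd = 0.02, min_palette_sep = 0.3) {
  ruler_rect[4] <- ruler_rect[3] + ruler_px - 1
  spec <- list(width = as.integer(width), height = as.integer(height),
               zone_split = as.integer(zone_split), palette = palette,
               ruler_mm = ruler_mm, ruler_px = as.integer(ruler_px),
               roots = roots, stem = as.integer(stem),
               ruler_rect = as.integer(ruler_rect),
               label_rect = as.integer(label_rect),
               leaves = leaves, noise_sd = noise_sd,
               min_palette_sep = min_palette_sep)
  class(spec) <- "scene_spec"
  spec
}

.rect_pixels <- function(rect, dim) {
  r <- max(1L, rect[1]):min(dim[1], rect[2])
  c <- max(1L, rect[3]):min(dim[2], rect[4])
  as.matrix(expand.grid(row = r, col = c))
}

#' Render a synthetic root scene
#'
#' Draws the backgrounds, ruler, label, stem, leaves and thickened-polyline
#' roots of a [scene_spec()], adds per-channel Gaussian noise, and returns the
#' RGB image together with exact ground truth (per-pixel class map, per-root
#' records, true mm-per-px). The spec is validated first: root polylines must
#' lie entirely inside the background zone matching their class, basal roots
#' must attach at the stem base and lateral roots at the stem flank, objects
#' must not overlap, and palette colours must be separated by at least the
#' configured minimum.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed controlling the rendering noise.
#' @return list with `image` (H x W x 3 array in \[0,1\]), `truth` (list with
#'   `class_map` factor-coded integer matrix, `root_map` integer matrix of
#'   root ids, `roots` data.frame, `mm_per_px`), and `spec`.
#' @export
generate_root_scene <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width; dm <- c(H, W)
  if (H <= 0 || W <= 0) stop("canvas dimensions must be positive")
  if (palette_separation(spec$palette) < spec$min_palette_sep)
    stop("palette colours closer than the configured minimum separation")

  class_map <- matrix(1L, H, W)              # background_top
  if (spec$zone_split < H)
    class_map[(spec$zone_split + 1L):H, ] <- 2L   # background_bottom
  occupied <- matrix(0L, H, W)               # object id map for overlap checks

  put <- function(px, code, what) {
    lin <- .px_lin(px, H)
    if (any(occupied[lin] != 0L))
      stop("overlapping placement: ", what, " collides with another object")
    occupied[lin] <<- code
    class_map[lin] <<- code
  }
  put(.rect_pixels(spec$ruler_rect, dm), 3L, "ruler")
  put(.rect_pixels(spec$label_rect, dm), 4L, "label")
  put(.rect_pixels(spec$stem, dm), 6L, "stem")
  for (lf in spec$leaves)
    put(stamp_ellipse(lf$center, lf$semi, dm), 5L, "leaf")

  root_map <- matrix(0L, H, W)
  root_rec <- list()
  if (length(spec$roots)) {
    stem_px <- .rect_pixels(spec$stem, dm)
    for (i in seq_along(spec$roots)) {
      rt <- spec$roots[[i]]
      stopifnot(rt$class %in% c("basal", "lateral"))
      px <- stamp_polyline(rt$points, rt$thickness, dm)
      zone_ok <- if (rt$class == "basal") all(px[, 1] > spec$zone_split)
                 else all(px[, 1] <= spec$zone_split)
      if (!zone_ok)
        stop("root ", i, " (", rt$class, ") crosses the background zone boundary")
      # attachment: first control point within reach of the stem rectangle
      p0 <- rt$points[1, ]
      dmin <- min(abs(p0[1] - stem_px[, 1]) + abs(p0[2] - stem_px[, 2]))
      if (dmin > rt$thickness + 2)
        stop("root ", i, " does not attach to the stem")
      lin <- .px_lin(px, H)
      clash <- occupied[lin] != 0L & occupied[lin] != 6L
      if (any(clash))
        stop("root ", i, " overlaps a non-stem object")
      keep <- occupied[lin] == 0L            # stem keeps priority at the joint
      lin <- lin[keep]; px <- px[keep, , drop = FALSE]
      occupied[lin] <- 7L
      class_map[lin] <- 7L
      root_map[lin] <- i
      root_rec[[i]] <- data.frame(
        root_id = i, class = rt$class,
        polyline_len_px = polyline_length(rt$points),
        area_px = nrow(px),
        attach_row = round(p0[1]), attach_col = round(p0[2]))
    }
  }
  roots <- if (length(root_rec)) do.call(rbind, root_rec) else
    data.frame(root_id = integer(0), class = character(0),
               polyline_len_px = numeric(0), area_px = integer(0),
               attach_row = integer(0), attach_col = integer(0))

  pal <- do.call(rbind, spec$palette[SCENE_CLASSES])
  img <- array(0, c(H, W, 3))
  set.seed(as.integer(seed))
  for (ch in 1:3) {
    base <- matrix(pal[class_map, ch], H, W)
    img[, , ch] <- pmin(1, pmax(0, base + stats::rnorm(H * W, 0, spec$noise_sd)))
  }
  truth <- list(class_map = class_map, root_map = root_map, roots = roots,
                mm_per_px = spec$ruler_mm / spec$ruler_px,
                zone_split = spec$zone_split)
  list(image = img, truth = truth, spec = spec)
}

#' Randomly populate a scene spec with roots
#'
#' Draws a random number of basal and lateral roots as gently curving
#' polylines attached to the stem, each confined to its background zone.
#' A small fraction of plants are non-rooters (no roots at all), mirroring
#' the zero-inflation seen in rooting assays.
#'
#' @param base a [scene_spec()] providing canvas, palette and fixed objects.
#' @param p_no_roots probability of a rootless plant.
#' @param n_basal,n_lateral ranges (inclusive) for per-class root counts.
#' @param len_range root length range in px.
#' @param thickness_range integer range of root thickness in px.
#' @return a `scene_spec` with `roots` filled in.
#' @export
random_scene_spec <- function(base = scene_spec(), p_no_roots = 0.08,
                              n_basal = c(1, 3), n_lateral = c(1, 3),
                              len_range = c(50, 140),
                              thickness_range = c(2, 4)) {
  H <- base$height; W <- base$width; split <- base$zone_split
  stem <- base$stem
  roots <- list()
  if (stats::runif(1) >= p_no_roots) {
    nb <- sample(n_basal[1]:n_basal[2], 1)
    nl <- sample(n_lateral[1]:n_lateral[2], 1)
    mask <- matrix(FALSE, H, W)   # already-claimed root pixels
    mk_polyline <- function(start, heading0, len, lims) {
      nseg <- 4L
      pts <- matrix(start, 1, 2)
      hd <- heading0
      for (s in seq_len(nseg)) {
        hd <- hd + stats::runif(1, -20, 20) * pi / 180
        step <- len / nseg
        nxt <- pts[nrow(pts), ] + step * c(sin(hd), cos(hd))
        nxt[1] <- min(max(nxt[1], lims[1]), lims[2])
        nxt[2] <- min(max(nxt[2], lims[3]), lims[4])
        pts <- rbind(pts, nxt)
      }
      pts
    }
    try_place <- function(class, tries = 40) {
      for (t in seq_len(tries)) {
        th <- sample(thickness_range[1]:thickness_range[2], 1)
        len <- stats::runif(1, len_range[1], len_range[2])
        m <- ceiling(th / 2) + 2
        if (class == "basal") {
          start <- c(stem[2] + 1, stats::runif(1, stem[3] + 1, stem[4] - 1))
          # heading pi/2 points straight down (row-step = sin, col-step = cos)
          pts <- mk_polyline(start, pi / 2 + stats::runif(1, -0.45, 0.45),
                             len, c(split + 1 + m, H - m, 1 + m, W - m))
        } else {
          side <- sample(c(-1, 1), 1)
          start <- c(stats::runif(1, 85, min(150, split - 10)),
                     if (side < 0) stem[3] - 1 else stem[4] + 1)
          hd0 <- if (side < 0) pi else 0      # cos(hd)=dc: left or right
          pts <- mk_polyline(start, hd0 + stats::runif(1, -0.35, 0.35),
                             len, c(80, split - m, 1 + m, W - m))
        }
        px <- stamp_polyline(pts, th, c(H, W))
        zone_ok <- if (class == "basal") all(px[, 1] > split)
                   else all(px[, 1] <= split)
        if (!zone_ok) next
        lin <- .px_lin(px, H)
        # buffered footprint: roots must not touch, so that each stays its
        # own connected component with well-defined ground truth
        buf <- stamp_polyline(pts, th + 5, c(H, W))
        if (any(mask[.px_lin(buf, H)])) next
        # avoid fixed objects except the stem it attaches to
        cm <- matrix(FALSE, H, W)
        cm[.px_lin(.rect_pixels(base$ruler_rect, c(H, W)), H)] <- TRUE
        cm[.px_lin(.rect_pixels(base$label_rect, c(H, W)), H)] <- TRUE
        for (lf in base$leaves) cm[.px_lin(stamp_ellipse(lf$center, lf$semi, c(H, W)), H)] <- TRUE
        if (any(cm[lin])) next
        mask[lin] <<- TRUE
        return(list(class = class, points = pts, thickness = th))
      }
      NULL
    }
    for (i in seq_len(nb)) {
      r <- try_place("basal"); if (!is.null(r)) roots[[length(roots) + 1L]] <- r
    }
    for (i in seq_len(nl)) {
      r <- try_place("lateral"); if (!is.null(r)) roots[[length(roots) + 1L]] <- r
    }
  }
  base$roots <- roots
  base
}

# NOTE on basal headings above: mk_polyline takes heading in radians with
# row-step = sin(h), col-step = cos(h); pi/2 points straight down the image.

#' Simulate a batch of random scenes
#'
#' @param n number of scenes.
#' @param seed master seed; scene i uses `seed` for spec randomisation and
#'   rendering jointly, so the batch is fully reproducible.
#' @param base base [scene_spec()].
#' @param ... passed to [random_scene_spec()].
#' @return list of [generate_root_scene()] results.
#' @export
simulate_scenes <- function(n, seed = 1, base = scene_spec(), ...) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + i)
    sp <- random_scene_spec(base, ...)
    out[[i]] <- generate_root_scene(sp, seed = as.integer(seed) + i)
  }
  out
}

#' Write a scene to PNG with a JSON ground-truth sidecar
#'
#' @param scene result of [generate_root_scene()].
#' @param png_path output PNG path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
write_scene <- function(scene, png_path) {
  png::writePNG(scene$image, png_path)
  side <- sub("\\.png$", ".json", png_path)
  tr <- scene$truth
  jsonlite::write_json(
    list(mm_per_px = tr$mm_per_px, zone_split = tr$zone_split,
         roots = tr$roots, class_counts = as.list(table(tr$class_map))),
    side, auto_unbox = TRUE, digits = NA)
  invisible(png_path)
}

#' Read a scene PNG
#' @param png_path path written by [write_scene()] or any RGB PNG.
#' @return H x W x 3 array.
#' @export
read_scene_png <- function(png_path) {
  img <- png::readPNG(png_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
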