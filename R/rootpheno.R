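# Per-root and per-plant measurement from tissue masks: instance extraction,
# origin/tip detection, geodesic length, area, basal/lateral classification,
# ruler calibration and stem diameter.

#' Metric calibration from the ruler component
#'
#' The pixel width of the ruler is its extent along its principal axis; the
#' scale is `ruler_mm / ruler_px_width`.
#'
#' @param scene_mask a `scene_mask` from [segment_scene()].
#' @param ruler_mm physical ruler length in mm.
#' @return mm-per-px (numeric scalar).
#' @export
calibrate_scale <- function(scene_mask, ruler_mm = 150) {
  lab <- scene_mask$labels
  if (!any(lab == 4L)) stop("no ruler component found; cannot calibrate")
  comp <- label_components(lab == 4L, 8)
  tab <- tabulate(comp[comp > 0])
  px <- which(comp == which.max(tab))
  H <- nrow(lab)
  coords <- cbind(((px - 1L) %% H) + 1L, ((px - 1L) %/% H) + 1L)
  if (nrow(coords) < 3) stop("ruler component is degenerate (< 3 px)")
  cc <- scale(coords, scale = FALSE)
  v <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% v
  width_px <- diff(range(proj)) + 1
  if (width_px < 3) stop("ruler component is degenerate")
  ruler_mm / width_px
}

#' Extract root instances from a tissue mask
#'
#' Each 8-connected root component touching the stem yields one instance per
#' distinct (8-connected) run of stem-contact pixels; a multi-contact
#' component is partitioned by geodesic proximity to the contact runs.
#' Components touching another root but not the stem become child instances
#' of that root; components touching neither are flagged orphans and excluded
#' from summaries.
#'
#' @param tissue_mask result of [segment_tissue()] (or any object with a
#'   `labels` matrix coded as `TISSUE_CLASSES`).
#' @return list with `instances` (list of `root_instance`: pixels, origin,
#'   parent, class = NA) and `orphans` (list of pixel matrices), plus flags.
#' @export
extract_root_instances <- function(tissue_mask) {
  lab <- tissue_mask$labels
  H <- nrow(lab); W <- ncol(lab)
  rootm <- lab == 4L; stemm <- lab == 3L
  out <- list(instances = list(), orphans = list(), flags = character(0))
  if (!any(rootm)) return(out)
  comp <- label_components(rootm, 8)
  ncomp <- max(comp)
  sh <- .octile_shifts()
  touches <- function(px, target) {
    # which of px have an 8-neighbour inside logical matrix `target`
    hit <- logical(nrow(px))
    for (s in seq_len(nrow(sh))) {
      r2 <- px[, 1] + sh$dr[s]; c2 <- px[, 2] + sh$dc[s]
      ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
      hit[ok] <- hit[ok] | target[cbind(r2[ok], c2[ok])]
    }
    hit
  }
  comp_px <- lapply(seq_len(ncomp), function(k) {
    px <- which(comp == k)
    cbind(row = ((px - 1L) %% H) + 1L, col = ((px - 1L) %/% H) + 1L)
  })
  assigned <- rep(FALSE, ncomp)
  instances <- list()
  inst_of_comp <- vector("list", ncomp)   # instance ids carved from comp k

  new_instance <- function(pixels, origin, parent) {
    id <- length(instances) + 1L
    instances[[id]] <<- structure(
      list(id = id, pixels = pixels, origin = origin, parent = parent,
           class = NA_character_), class = "root_instance")
    id
  }
  run_origin <- function(run_px) {
    ctr <- colMeans(run_px)
    run_px[which.min((run_px[, 1] - ctr[1])^2 + (run_px[, 2] - ctr[2])^2), ]
  }
  carve <- function(px, parent_label) {
    # split a component's pixels into instances by its contact runs
    contact <- touches(px, parent_label)
    cm <- matrix(FALSE, H, W); cm[px[contact, , drop = FALSE]] <- TRUE
    runs <- label_components(cm, 8)
    nrun <- max(runs)
    origins <- lapply(seq_len(nrun), function(r) {
      rp <- which(runs == r)
      run_origin(cbind(((rp - 1L) %% H) + 1L, ((rp - 1L) %/% H) + 1L))
    })
    if (nrun == 1L) return(list(list(pixels = px, origin = origins[[1]])))
    pg <- pixel_graph(px, c(H, W))
    key <- paste(px[, 1], px[, 2])
    ovid <- vapply(origins, function(o) match(paste(o[1], o[2]), key), 0L)
    D <- igraph::distances(pg$graph, v = ovid)
    nearest <- apply(D, 2, which.min)       # ties -> lower run id
    lapply(seq_len(nrun), function(r)
      list(pixels = px[nearest == r, , drop = FALSE], origin = origins[[r]]))
  }

  # pass 1: components in contact with the stem
  for (k in seq_len(ncomp)) {
    px <- comp_px[[k]]
    if (any(touches(px, stemm))) {
      parts <- carve(px, stemm)
      ids <- vapply(parts, function(p)
        new_instance(p$pixels, p$origin, parent = "stem"), 0L)
      inst_of_comp[[k]] <- ids
      assigned[k] <- TRUE
    }
  }
  # pass 2: components attached to an already-assigned root component
  repeat {
    progressed <- FALSE
    placed <- matrix(FALSE, H, W)
    for (k in which(assigned)) placed[comp_px[[k]]] <- TRUE
    for (k in which(!assigned)) {
      px <- comp_px[[k]]
      if (any(touches(px, placed))) {
        # parent = instance owning the touched pixel(s)
        contact <- touches(px, placed)
        o <- run_origin(px[contact, , drop = FALSE])
        parent_id <- NA_integer_
        for (s in seq_len(nrow(sh))) {
          r2 <- o[1] + sh$dr[s]; c2 <- o[2] + sh$dc[s]
          if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W && placed[r2, c2]) {
            pk <- comp[r2, c2]
            cand <- inst_of_comp[[pk]]
            parent_id <- cand[1]
            if (length(cand) > 1L) {
              # nearest instance of the parent component by origin distance
              d <- vapply(cand, function(ii) {
                oo <- instances[[ii]]$origin
                (oo[1] - o[1])^2 + (oo[2] - o[2])^2
              }, 0)
              parent_id <- cand[which.min(d)]
            }
            break
          }
        }
        ids <- new_instance(px, o, parent = parent_id)
        inst_of_comp[[k]] <- ids
        assigned[k] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  orphans <- comp_px[!assigned]
  flags <- character(0)
  if (length(orphans)) flags <- c(flags, "orphan-root")
  list(instances = instances, orphans = orphans, flags = flags)
}

#' Measure one root instance: geodesic length and area
#'
#' Builds the weighted pixel graph over the instance (8-connectivity, axial
#' cost 1, diagonal cost sqrt(2)), takes the tip as the pixel with maximal
#' shortest-path (octile geodesic) distance from the origin, and reports both
#' that octile distance and a rasterisation-corrected length: the shortest
#' pixel path is simplified (Ramer-Douglas-Peucker, eps = 1 px) and its
#' Euclidean arc length summed. The corrected length is the primary length
#' used in summaries; the raw octile distance systematically overestimates
#' Euclidean length for headings between the grid axes.
#'
#' @param instance a `root_instance`.
#' @param dim c(H, W) of the mask the pixels came from.
#' @return the instance with `tip`, `length_px` (corrected),
#'   `length_geodesic_px` (octile), `area_px` filled in.
#' @export
measure_root <- function(instance, dim) {
  px <- instance$pixels
  key <- paste(px[, 1], px[, 2])
  ov <- match(paste(instance$origin[1], instance$origin[2]), key)
  if (is.na(ov)) stop("origin pixel is not part of the instance pixel set")
  if (nrow(px) == 1L) {
    instance$tip <- instance$origin
    instance$length_px <- 0
    instance$length_geodesic_px <- 0
    instance$area_px <- 1L
    return(instance)
  }
  pg <- pixel_graph(px, dim)
  d <- igraph::distances(pg$graph, v = ov)[1, ]
  tip_v <- which.max(ifelse(is.finite(d), d, -Inf))
  path <- igraph::shortest_paths(pg$graph, from = ov, to = tip_v)$vpath[[1]]
  pts <- px[as.integer(path), , drop = FALSE]
  instance$tip <- px[tip_v, ]
  instance$length_geodesic_px <- unname(d[tip_v])
  instance$length_px <- polyline_length(rdp_simplify(pts, eps = 1))
  instance$area_px <- nrow(px)
  instance
}

#' Classify a root instance as basal or lateral
#'
#' Each pixel votes for the background zone whose felt it is nearest to
#' (Euclidean distance map to the segmented background classes); the majority
#' zone decides the class, with ties broken to basal. Roots over the bottom
#' (blue) felt are basal, roots over the top/side (grey) felt are lateral.
#'
#' @param instance a `root_instance`.
#' @param zone_maps result of [zone_distance_maps()].
#' @return the instance with `class` set.
#' @export
classify_root_type <- function(instance, zone_maps) {
  px <- instance$pixels
  d_top <- zone_maps$top[px]
  d_bot <- zone_maps$bottom[px]
  n_bot <- sum(d_bot <= d_top)
  instance$class <- if (n_bot >= nrow(px) - n_bot) "basal" else "lateral"
  instance
}

#' Distance maps to the two background zones
#'
#' @param scene_mask a `scene_mask`.
#' @return list of two H x W matrices: distance of every pixel to the nearest
#'   `background_top` / `background_bottom` pixel.
#' @export
zone_distance_maps <- function(scene_mask) {
  lab <- scene_mask$labels
  dist_to <- function(code) {
    m <- matrix(1, nrow(lab), ncol(lab))
    m[lab == code] <- 0
    if (all(m == 1)) return(matrix(Inf, nrow(lab), ncol(lab)))
    EBImage::distmap(m, metric = "euclidean")
  }
  list(top = dist_to(1L), bottom = dist_to(2L))
}

#' Stem diameter in pixels
#'
#' Median run-length of stem pixels perpendicular to the stem's principal
#' axis.
#' @param tissue_mask a `tissue_mask`.
#' @return numeric scalar (px); NA if no stem.
#' @export
stem_diameter_px <- function(tissue_mask) {
  lab <- tissue_mask$labels
  px <- which(lab == 3L)
  if (length(px) < 3) return(NA_real_)
  H <- nrow(lab)
  coords <- cbind(((px - 1L) %% H) + 1L, ((px - 1L) %/% H) + 1L)
  cc <- scale(coords, scale = FALSE)
  ev <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  along <- cc %*% ev[, 1]
  perp <- cc %*% ev[, 2]
  bins <- round(along)
  widths <- tapply(perp, bins, function(z) diff(range(z)) + 1)
  stats::median(widths)
}

#' Summarise a plant: per-class totals, longest root lengths, stem diameter
#'
#' Per root class (basal, lateral) and overall: total root area and longest
#' root length (LRL), converted to mm / mm^2 via the calibration. Overall
#' area is basal + lateral; overall LRL is the larger class LRL. With no
#' calibration available, values stay in pixel units and a flag is raised.
#'
#' @param instances list of measured, classified `root_instance`s.
#' @param mm_per_px calibration, or NA.
#' @param tissue_mask the `tissue_mask` (for stem diameter).
#' @param extra_flags character vector of upstream QC flags to carry.
#' @return one-row data.frame (a `PlantMeasurement`).
#' @export
summarize_plant <- function(instances, mm_per_px, tissue_mask,
                            extra_flags = character(0)) {
  flags <- extra_flags
  if (is.na(mm_per_px)) {
    flags <- c(flags, "uncalibrated-px-units")
    s <- 1
  } else s <- mm_per_px
  cls <- vapply(instances, function(i) i$class, "")
  len <- vapply(instances, function(i) i$length_px, 0)
  area <- vapply(instances, function(i) as.numeric(i$area_px), 0)
  agg <- function(which_cls) {
    sel <- cls == which_cls
    c(area = sum(area[sel]) * s^2,
      lrl = if (any(sel)) max(len[sel]) * s else 0)
  }
  b <- agg("basal"); l <- agg("lateral")
  if (!length(instances)) flags <- c(flags, "no-roots-found")
  data.frame(
    lateral_area = unname(l["area"]), basal_area = unname(b["area"]),
    total_area = unname(b["area"] + l["area"]),
    lateral_lrl = unname(l["lrl"]), basal_lrl = unname(b["lrl"]),
    overall_lrl = unname(max(b["lrl"], l["lrl"])),
    stem_diam = stem_diameter_px(tissue_mask) * s,
    mm_per_px = mm_per_px, n_roots = length(instances),
    flags = paste(flags, collapse = ";"))
}

#' Measure a rendered scene end to end
#'
#' Convenience wrapper: scene segmentation, tissue segmentation, calibration,
#' instance extraction, measurement, classification and plant summary.
#'
#' @param img RGB array.
#' @param palette scene palette.
#' @param ruler_mm physical ruler length.
#' @param tol colour tolerance.
#' @return list with `summary` (one-row data.frame), `instances`, `scene_mask`,
#'   `tissue_mask`, `mm_per_px`.
#' @export
measure_scene <- function(img, palette = default_palette(), ruler_mm = 150,
                          tol = 0.15) {
  sm <- segment_scene(img, palette, tol)
  tm <- segment_tissue(img, sm, palette)
  mmpp <- if ("no-ruler" %in% sm$flags) NA_real_ else
    tryCatch(calibrate_scale(sm, ruler_mm), error = function(e) NA_real_)
  ex <- extract_root_instances(tm)
  zm <- zone_distance_maps(sm)
  dm <- dim(tm$labels)
  inst <- lapply(ex$instances, function(i)
    classify_root_type(measure_root(i, dm), zm))
  summ <- summarize_plant(inst, mmpp, tm,
                          extra_flags = c(sm$flags, tm$flags, ex$flags))
  list(summary = summ, instances = inst, orphans = ex$orphans,
       scene_mask = sm, tissue_mask = tm, mm_per_px = mmpp)
}
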