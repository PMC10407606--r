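# Shared pixel-grid helpers. Pixels are (row, col) pairs on an H x W grid,
# row 1 at the top; linear indices are column-major (R matrix convention).

.octile_shifts <- function() {
  # 8-neighbourhood offsets with step costs: axial 1, diagonal sqrt(2)
  data.frame(
    dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
    dc = c(0, 0, -1, 1, -1, 1, -1, 1),
    w  = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  )
}

#' 8- or 4-connected component labelling of a logical mask
#'
#' Labels each connected set of TRUE pixels with an integer starting at 1.
#' Built on igraph components; diagonal adjacency counts as connected when
#' `connectivity = 8`.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same dimension; 0 where `mask` is FALSE.
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  vid <- integer(H * W)           # map linear pixel index -> vertex id
  vid[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  sh <- .octile_shifts()
  if (connectivity == 4) sh <- sh[sh$w == 1, ]
  from <- integer(0); to <- integer(0)
  for (s in seq_len(nrow(sh))) {
    r2 <- rr + sh$dr[s]; c2 <- cc + sh$dc[s]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- vid[nb] > 0L
    if (!any(hit)) next
    from <- c(from, vid[idx[ok]][hit])
    to <- c(to, vid[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

#' Weighted pixel graph over a set of pixels
#'
#' Vertices are the supplied pixels; edges join 8-neighbours with axial cost 1
#' and diagonal cost sqrt(2).
#'
#' @param pixels two-column integer matrix (row, col).
#' @param dim c(H, W) of the underlying image.
#' @return list with the igraph object and the pixel order used for vertices.
#' @keywords internal
pixel_graph <- function(pixels, dim) {
  H <- dim[1]; W <- dim[2]
  idx <- (pixels[, 2] - 1L) * H + pixels[, 1]
  vid <- integer(H * W)
  vid[idx] <- seq_along(idx)
  sh <- .octile_shifts()
  from <- integer(0); to <- integer(0); wts <- numeric(0)
  for (s in seq_len(nrow(sh))) {
    r2 <- pixels[, 1] + sh$dr[s]; c2 <- pixels[, 2] + sh$dc[s]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- vid[nb] > 0L
    if (!any(hit)) next
    a <- vid[idx[ok]][hit]; b <- vid[nb][hit]
    keep <- a < b                 # each undirected edge once
    from <- c(from, a[keep]); to <- c(to, b[keep])
    wts <- c(wts, rep(sh$w[s], sum(keep)))
  }
  g <- igraph::make_empty_graph(n = nrow(pixels), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- wts
  }
  list(graph = g, pixels = pixels)
}

#' Ramer-Douglas-Peucker polyline simplification
#' @param pts n x 2 numeric matrix of ordered points.
#' @param eps tolerance in pixels.
#' @keywords internal
rdp_simplify <- function(pts, eps = 1) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; len2 <- sum(ab^2)
    mid <- (i + 1L):(j - 1L)
    if (len2 == 0) {
      d <- sqrt(rowSums((pts[mid, , drop = FALSE] -
                           matrix(a, length(mid), 2, byrow = TRUE))^2))
    } else {
      ap <- pts[mid, , drop = FALSE] - matrix(a, length(mid), 2, byrow = TRUE)
      cross <- abs(ap[, 1] * ab[2] - ap[, 2] * ab[1])
      d <- cross / sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- mid[k]; keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, m)
      stack[[length(stack) + 1L]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

#' Arc length of a polyline
#' @keywords internal
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Pixels covered by a thickened polyline (disk stamping)
#'
#' Samples the polyline densely and stamps a disk of diameter `thickness`
#' at each sample.
#'
#' @return two-column integer matrix of unique (row, col) pixels.
#' @keywords internal
stamp_polyline <- function(pts, thickness, dim) {
  H <- dim[1]; W <- dim[2]
  r <- thickness / 2
  # dense samples along the polyline
  samp <- pts[1, , drop = FALSE]
  if (nrow(pts) >= 2L) {
    for (i in seq_len(nrow(pts) - 1L)) {
      a <- pts[i, ]; b <- pts[i + 1L, ]
      L <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(L / 0.3) + 1L))
      samp <- rbind(samp, cbind(a[1] + t * (b[1] - a[1]),
                                a[2] + t * (b[2] - a[2])))
    }
  }
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  rr <- as.vector(outer(round(samp[, 1]), off$dr, `+`))
  cc <- as.vector(outer(round(samp[, 2]), off$dc, `+`))
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  px <- unique(cbind(as.integer(rr[ok]), as.integer(cc[ok])))
  colnames(px) <- c("row", "col")
  px
}

#' Pixels of a filled axis-aligned ellipse
#' @keywords internal
stamp_ellipse <- function(center, semi, dim) {
  H <- dim[1]; W <- dim[2]
  r0 <- max(1L, floor(center[1] - semi[1])); r1 <- min(H, ceiling(center[1] + semi[1]))
  c0 <- max(1L, floor(center[2] - semi[2])); c1 <- min(W, ceiling(center[2] + semi[2]))
  gr <- expand.grid(row = r0:r1, col = c0:c1)
  inside <- ((gr$row - center[1]) / semi[1])^2 + ((gr$col - center[2]) / semi[2])^2 <= 1
  as.matrix(gr[inside, , drop = FALSE])
}

# linear indices for a pixel matrix
.px_lin <- function(px, H) (px[, 2] - 1L) * H + px[, 1]
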