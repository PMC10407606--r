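# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (flood fill, dense shortest path, O(n^2) scans) and
# kept separate from the package implementations they check.

fx_panel <- function(n = 120, m = 300, seed = 42, ...) {
  arch <- genetic_architecture(n = n, m = m, ...)
  list(arch = arch, G = simulate_genotypes(arch, seed = seed))
}

# recursive flood fill (stack-based) over a logical mask, 8-connectivity
oracle_flood_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[i] != 0L) next
      lab[i] <- nxt
      r <- ((i - 1L) %% H) + 1L; c <- ((i - 1L) %/% H) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if ((dr != 0L || dc != 0L) && r2 >= 1L && r2 <= H &&
            c2 >= 1L && c2 <= W && mask[r2, c2] && lab[r2, c2] == 0L)
          stack <- c(stack, (c2 - 1L) * H + r2)
      }
    }
  }
  lab
}

# dense Dijkstra-by-relaxation over a pixel set (octile metric); returns
# distances from the origin index
oracle_pixel_distances <- function(pixels, origin_idx) {
  n <- nrow(pixels)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(pixels[i, 1] - pixels[j, 1])
    dc <- abs(pixels[i, 2] - pixels[j, 2])
    if (i == j) D[i, j] <- 0
    else if (dr <= 1 && dc <= 1)
      D[i, j] <- if (dr + dc == 2) sqrt(2) else 1
  }
  d <- rep(Inf, n); d[origin_idx] <- 0
  repeat {
    d_new <- pmin(d, apply(D + matrix(d, n, n, byrow = FALSE), 2, min))
    if (all(d_new == d)) break
    d <- d_new
  }
  d
}

# build a tissue_mask-like object from a character matrix with entries in
# {".", "L", "S", "R"} (none, leaf, stem, root); background zones split at
# `zone_split` for the embedded scene mask
fx_tissue_mask <- function(chars, zone_split = floor(nrow(chars) / 2)) {
  code <- matrix(1L, nrow(chars), ncol(chars))
  code[chars == "L"] <- 2L
  code[chars == "S"] <- 3L
  code[chars == "R"] <- 4L
  scene <- matrix(1L, nrow(chars), ncol(chars))
  if (zone_split < nrow(chars))
    scene[(zone_split + 1):nrow(chars), ] <- 2L
  scene[code > 1L] <- 3L
  sm <- structure(list(labels = scene,
                       classes = c("background_top", "background_bottom",
                                   "plant", "ruler", "label"),
                       flags = character(0), zone_split_est = zone_split),
                  class = "scene_mask")
  structure(list(labels = code,
                 classes = c("none", "leaf", "stem", "root"),
                 scene = sm, flags = character(0)),
            class = "tissue_mask")
}

# covariates for a simulated panel, matching the pipeline convention
fx_covariates <- function(ph, trait_table) {
  assoc_covariates(trait_table, ph)
}
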