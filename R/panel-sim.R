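# Simulated genotype panels and replicate-level phenotypes with known
# architecture: realistic MAF spectrum, missingness, LD blocks from founder
# haplotypes, optional population structure, planted causal windows, a
# polygenic background, batch effects and clonal replicate noise.

#' Describe a simulated genetic architecture
#'
#' @param n number of genotypes (individuals).
#' @param m number of variants.
#' @param maf_shape1,maf_shape2 Beta parameters for the MAF spectrum; draws
#'   are scaled to (0, 0.5] and floored at `maf_min_sim`.
#' @param maf_min_sim smallest simulated allele frequency.
#' @param maf_point optional fixed MAF for all variants (overrides the Beta).
#' @param missing_rate per-entry missing probability.
#' @param bp_per_snp mean spacing between variants (bp).
#' @param ld_block_bp LD block length; genotypes are drawn by copying founder
#'   haplotypes block-wise, so variants within a block are correlated.
#'   Use a value below the variant spacing for independent variants.
#' @param n_founder_hap founder haplotypes per block (smaller = stronger LD).
#' @param n_subpop number of subpopulations (1 = unstructured).
#' @param fst Balding-Nichols divergence when `n_subpop > 1`.
#' @param h2 target narrow-sense heritability of the simulated traits
#'   (single-measurement scale, batch excluded via covariates).
#' @param causal data.frame with columns chrom, start, end, prop_var: planted
#'   causal windows and their phenotypic variance share (counted inside h2).
#' @param batch_var,stem_var variance shares of the batch effect and the
#'   stem-diameter covariate effect.
#' @param n_rep clonal replicates per genotype.
#' @param weeks time points (weeks after the assay start).
#' @param n_batch number of assay batches; both replicates of a genotype
#'   share a batch.
#' @param shared_gen fraction of genetic variance shared between the lateral
#'   and basal root trait families.
#' @param zero_floor floor measurements at zero (areas and lengths cannot be
#'   negative), producing a small zero-inflated fraction.
#' @param chrom chromosome name.
#' @return object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(n = 200, m = 5000,
                                 maf_shape1 = 0.4, maf_shape2 = 1.6,
                                 maf_min_sim = 0.005, maf_point = NULL,
                                 missing_rate = 0.02,
                                 bp_per_snp = 100, ld_block_bp = 1000,
                                 n_founder_hap = 24,
                                 n_subpop = 1, fst = 0.1,
                                 h2 = 0.4,
                                 causal = NULL,
                                 batch_var = 0.05, stem_var = 0.02,
                                 n_rep = 2, weeks = 2:5, n_batch = 8,
                                 shared_gen = 0.7, zero_floor = TRUE,
                                 chrom = "Chr01") {
  if (is.null(causal))
    causal <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), prop_var = numeric(0))
  stopifnot(h2 > 0, h2 < 1, sum(causal$prop_var) <= h2,
            h2 + batch_var + stem_var < 1)
  arch <- as.list(environment())
  class(arch) <- "genetic_architecture"
  arch
}

#' Simulate a genotype panel
#'
#' Variant positions are uniform draws over `m * bp_per_snp` bp; within each
#' LD block every individual copies two haplotypes from a small founder pool,
#' inducing block-wise LD; missing calls are dropped at random. With
#' `n_subpop > 1`, subpopulation allele frequencies follow a Balding-Nichols
#' model and founder pools are subpopulation-specific.
#'
#' @param arch a [genetic_architecture()].
#' @param seed integer seed.
#' @return object of class `genotype_matrix`: list with `G` (n x m integer
#'   dosage matrix in 0/1/2 with NA for missing), `variants` (chrom, pos, id,
#'   ref, alt, maf, missing_frac), `samples`, `subpop`.
#' @export
simulate_genotypes <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "genetic_architecture"))
  n <- arch$n; m <- arch$m
  if (n < 2 || m < 2) stop("need at least 2 genotypes and 2 variants")
  set.seed(as.integer(seed))
  pos <- sort(sample.int(m * arch$bp_per_snp, m))
  maf <- if (!is.null(arch$maf_point)) rep(arch$maf_point, m) else
    pmax(arch$maf_min_sim, 0.5 * stats::rbeta(m, arch$maf_shape1, arch$maf_shape2))
  subpop <- rep(seq_len(arch$n_subpop), length.out = n)
  # per-subpopulation allele frequencies (Balding-Nichols)
  freq <- matrix(maf, arch$n_subpop, m, byrow = TRUE)
  if (arch$n_subpop > 1) {
    F <- arch$fst
    for (k in seq_len(arch$n_subpop))
      freq[k, ] <- stats::rbeta(m, maf * (1 - F) / F, (1 - maf) * (1 - F) / F)
  }
  block <- (pos - 1L) %/% max(1L, as.integer(arch$ld_block_bp))
  ublock <- unique(block)
  G <- matrix(0L, n, m)
  nh <- arch$n_founder_hap
  for (b in ublock) {
    j <- which(block == b)
    for (k in seq_len(arch$n_subpop)) {
      rows <- which(subpop == k)
      # founder haplotype pool for this block and subpopulation
      hap <- matrix(stats::rbinom(nh * length(j), 1L, rep(freq[k, j], each = nh)),
                    nh, length(j))
      a1 <- sample.int(nh, length(rows), replace = TRUE)
      a2 <- sample.int(nh, length(rows), replace = TRUE)
      G[rows, j] <- hap[a1, , drop = FALSE] + hap[a2, , drop = FALSE]
    }
  }
  if (arch$missing_rate > 0) {
    miss <- stats::runif(n * m) < arch$missing_rate
    G[miss] <- NA_integer_
  }
  af <- colMeans(G, na.rm = TRUE) / 2
  maf_real <- pmin(af, 1 - af)
  variants <- data.frame(
    chrom = arch$chrom, pos = pos,
    id = sprintf("%s_%d", arch$chrom, pos),
    ref = "A", alt = "T",
    maf = ifelse(is.nan(maf_real), NA_real_, maf_real),
    missing_frac = colMeans(is.na(G)))
  structure(list(G = G, variants = variants,
                 samples = sprintf("G%04d", seq_len(n)), subpop = subpop),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

# standardized dosages: mean-imputed, centered, unit variance (0 for
# monomorphic columns)
.std_dosage <- function(G) {
  X <- G
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- mu[j]
    X[, j] <- xj
  }
  X <- sweep(X, 2, mu)
  sdv <- sqrt(colMeans(X^2))
  sdv[sdv < 1e-12] <- Inf
  sweep(X, 2, sdv, "/")
}

#' Simulate replicate-level phenotype measurements
#'
#' Generates per genotype x replicate x week measurements for the six base
#' trait families (lateral/basal/total root area, lateral/basal/overall
#' longest root length), plus a stem-diameter covariate and batch label per
#' plant. The additive model is: planted causal-window effects + a polygenic
#' term spread over all variants + batch effect + a stem-diameter
#' contribution + replicate measurement noise, with variance shares set by
#' the architecture. Total area is the sum of the lateral and basal areas
#' and overall LRL the maximum of the class LRLs, as in the measurement
#' pipeline. Values are floored at zero when `zero_floor` is set.
#'
#' @param G a `genotype_matrix`.
#' @param arch the [genetic_architecture()] used to build it.
#' @param seed integer seed.
#' @return data.frame with columns genotype_id, replicate, batch, week,
#'   stem_diam, lateral_area, basal_area, total_area, lateral_lrl, basal_lrl,
#'   overall_lrl. Attributes: `realized_h2` (per family, single-measurement
#'   scale, pre-floor), `genetic_values`, `causal_values`.
#' @export
simulate_phenotypes <- function(G, arch, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$G)
  set.seed(as.integer(seed) + 77L)
  X <- .std_dosage(G$G)
  v <- G$variants
  causal <- arch$causal
  if (nrow(causal) > 0 &&
      any(causal$start > max(v$pos) | causal$end < min(v$pos)))
    stop("a causal window lies outside the simulated coordinate range")
  unit_var <- function(x) if (stats::sd(x) < 1e-12) rep(0, length(x)) else
    (x - mean(x)) / stats::sd(x)
  # causal component: variance-component architecture with Beta(1,25) MAF
  # weighting, i.e. rarer variants carry larger per-allele effects, the
  # generative model the windowed kernel test is designed for
  c_val <- rep(0, n); pv_causal <- 0
  if (nrow(causal) > 0) {
    mu_d <- colMeans(G$G, na.rm = TRUE); mu_d[is.nan(mu_d)] <- 0
    for (w in seq_len(nrow(causal))) {
      j <- which(v$chrom == causal$chrom[w] & v$pos >= causal$start[w] &
                   v$pos <= causal$end[w])
      if (!length(j)) stop("causal window ", w, " contains no variants")
      D <- G$G[, j, drop = FALSE]
      for (jj in seq_along(j)) D[is.na(D[, jj]), jj] <- mu_d[j[jj]]
      af <- colMeans(D) / 2
      wts <- skat_beta_weights(pmin(af, 1 - af))
      beta <- stats::rnorm(length(j)) * wts
      c_val <- c_val + sqrt(causal$prop_var[w]) *
        unit_var(D %*% beta)
    }
    pv_causal <- sum(causal$prop_var)
  }
  pv_poly <- arch$h2 - pv_causal
  poly_draw <- function() {
    u <- unit_var(X %*% stats::rnorm(ncol(X)))
    sqrt(pv_poly) * u
  }
  poly_shared <- poly_draw()
  fam_gen <- function() {
    # causal windows act on every family at full strength; the polygenic
    # background is split into a shared trunk and a family-private part
    c_val + sqrt(arch$shared_gen) * poly_shared +
      sqrt(1 - arch$shared_gen) * poly_draw()
  }
  g_lat_area <- fam_gen(); g_bas_area <- fam_gen()
  g_lat_lrl <- fam_gen(); g_bas_lrl <- fam_gen()

  batch <- rep(rep(seq_len(arch$n_batch), length.out = n), times = arch$n_rep)
  b_eff <- stats::rnorm(arch$n_batch, 0, sqrt(arch$batch_var))
  week_scale <- stats::approx(c(2, 5), c(1, 2.6), xout = arch$weeks)$y
  rows <- list()
  v_rep <- 1 - arch$h2 - arch$batch_var - arch$stem_var
  realized <- c()
  for (r in seq_len(arch$n_rep)) {
    stem_d <- stats::rnorm(n, 20, 1.5)
    stem_z <- unit_var(stem_d)
    for (wk in seq_along(arch$weeks)) {
      s <- week_scale[wk]
      mk <- function(g) {
        y <- 1.1 + g + b_eff[batch[seq_len(n) + (r - 1) * n]] +
          sqrt(arch$stem_var) * stem_z + stats::rnorm(n, 0, sqrt(v_rep))
        s * y
      }
      la <- mk(g_lat_area); ba <- mk(g_bas_area)
      ll <- mk(g_lat_lrl); bl <- mk(g_bas_lrl)
      if (arch$zero_floor) {
        la <- pmax(0, la); ba <- pmax(0, ba)
        ll <- pmax(0, ll); bl <- pmax(0, bl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genotype_id = G$samples, replicate = r,
        batch = batch[seq_len(n) + (r - 1) * n],
        week = arch$weeks[wk], stem_diam = stem_d,
        lateral_area = la, basal_area = ba, total_area = la + ba,
        lateral_lrl = ll, basal_lrl = bl, overall_lrl = pmax(ll, bl))
    }
  }
  out <- do.call(rbind, rows)
  gen_list <- list(lateral_area = g_lat_area, basal_area = g_bas_area,
                   lateral_lrl = g_lat_lrl, basal_lrl = g_bas_lrl)
  realized_h2 <- vapply(gen_list, function(g)
    stats::var(g) / (stats::var(g) + arch$batch_var + arch$stem_var + v_rep),
    0)
  attr(out, "realized_h2") <- realized_h2
  attr(out, "genetic_values") <- gen_list
  attr(out, "causal_values") <- c_val
  out
}
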