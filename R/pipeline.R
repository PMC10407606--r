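# Convenience wiring of the full association pipeline on simulated panels.

#' Covariate matrix for association scans
#'
#' Intercept, standardized stem diameter, batch indicator columns and
#' (optionally) genotype principal components, in genotype-table row order.
#'
#' @param trait_table genotype-level table (one row per genotype).
#' @param measurements replicate-level measurement table carrying stem_diam
#'   and batch per genotype.
#' @param pcs optional n x k genotype PC matrix.
#' @return numeric covariate matrix with an intercept column.
#' @export
assoc_covariates <- function(trait_table, measurements, pcs = NULL) {
  gmeta <- measurements[!duplicated(measurements$genotype_id), ]
  gmeta <- gmeta[match(trait_table$genotype_id, gmeta$genotype_id), ]
  stem <- tapply(measurements$stem_diam, measurements$genotype_id, mean)
  stem <- as.numeric(stem[trait_table$genotype_id])
  W <- cbind(intercept = 1, stem_diam = as.numeric(scale(stem)))
  if (length(unique(gmeta$batch)) > 1)
    W <- cbind(W, stats::model.matrix(~ factor(gmeta$batch))[, -1, drop = FALSE])
  if (!is.null(pcs)) W <- cbind(W, pcs)
  W
}

#' Windowed kernel-association scan of one simulated panel
#'
#' End-to-end convenience: filters variants for the SKAT set (missingness
#' only, rare variants kept), computes genotype PCs on the common-variant
#' set, builds staggered windows, scans the requested trait and calls QTL
#' peaks.
#'
#' @param G a `genotype_matrix`.
#' @param measurements output of [simulate_phenotypes()] (or the measurement
#'   pipeline).
#' @param trait trait column of the prepared table to scan (default the
#'   overall-development PC, `all_pc1`).
#' @param missing_max SKAT-set missingness bound (default 0.15).
#' @param n_pcs genotype PCs used as covariates (default 6).
#' @param window_size,window_step window tiling in bp.
#' @param empirical_below,B_max,seed resampling controls, see [skat_scan()].
#' @return list with `scan` (window results with trait/pos columns),
#'   `peaks`, `windows`, `trait_table`, `covariates`.
#' @export
run_window_gwas <- function(G, measurements, trait = "all_pc1",
                            missing_max = 0.15, n_pcs = 6,
                            window_size = 3000, window_step = 1000,
                            empirical_below = NULL, B_max = 1e5, seed = 1) {
  tt <- add_growth_traits(add_pc_traits(build_trait_table(measurements)))
  if (!trait %in% names(tt)) stop("unknown trait: ", trait)
  Gs <- filter_variants(G, maf_min = 0, missing_max = missing_max)
  pcs <- genotype_pcs(filter_variants(G, maf_min = 0.05,
                                      missing_max = missing_max), k = n_pcs)
  W <- assoc_covariates(tt, measurements, pcs)
  win <- build_windows(Gs$variants, size = window_size, step = window_step)
  sc <- skat_scan(tt[[trait]], W, Gs, win, empirical_below = empirical_below,
                  B_max = B_max, seed = seed)
  sc$trait <- trait
  sc$pos <- sc$center
  pk <- call_peaks(sc)
  list(scan = sc, peaks = pk, windows = win, trait_table = tt,
       covariates = W)
}
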