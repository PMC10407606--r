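# Genotype preparation for association mapping: variant filters, centered
# kinship, genotype principal components, and staggered SNP windows.

#' Filter variants by MAF and missingness
#'
#' MAF and missing fraction are recomputed on non-missing calls before
#' filtering, so the result does not depend on the order the two bounds are
#' applied in. Variants not mapped to chromosome scaffolds (empty or NA
#' chromosome) are dropped first.
#'
#' @param G a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param missing_max maximum missing fraction (inclusive).
#' @return filtered `genotype_matrix`; the number removed is recorded in
#'   attribute `n_removed`.
#' @export
filter_variants <- function(G, maf_min = 0.01, missing_max = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  mapped <- !is.na(G$variants$chrom) & G$variants$chrom != ""
  af <- colMeans(G$G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  missf <- colMeans(is.na(G$G))
  keep <- mapped & !is.na(maf) & maf >= maf_min & missf <= missing_max
  if (!any(keep)) stop("no variants survive the filters")
  out <- G
  out$G <- G$G[, keep, drop = FALSE]
  out$variants <- G$variants[keep, , drop = FALSE]
  out$variants$maf <- maf[keep]
  out$variants$missing_frac <- missf[keep]
  rownames(out$variants) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Centered relatedness (kinship) matrix
#'
#' GEMMA-style centered kinship: missing dosages are mean-imputed per
#' variant, columns centered, and K = X Xt / m. The matrix is reported
#' unscaled together with its mean diagonal; model fitting rescales to mean
#' diagonal 1.
#'
#' @param G a `genotype_matrix`.
#' @return object of class `kinship_matrix`: the n x n matrix with
#'   attributes `mean_diag` and `m_variants`.
#' @export
compute_kinship <- function(G) {
  stopifnot(ncol(G$G) >= 2)
  X <- G$G
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- is.na(X)
  if (any(na)) X[na] <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)[na]
  Xc <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Xc) / ncol(Xc)
  structure(K, mean_diag = mean(diag(K)), m_variants = ncol(Xc),
            class = c("kinship_matrix", "matrix", "array"))
}

#' Scale a kinship matrix to mean diagonal 1
#' @keywords internal
scale_kinship <- function(K) {
  md <- mean(diag(K))
  if (md <= 0) stop("kinship has non-positive mean diagonal")
  K / md
}

#' Genotype principal components
#'
#' Top-k eigenvectors of the standardized-genotype covariance, unit norm,
#' with a deterministic sign convention (the largest-magnitude loading of
#' each component is positive). Intended to be run on common variants
#' (MAF >= 0.05), which the caller selects via [filter_variants()].
#'
#' @param G a `genotype_matrix`, already filtered to common variants.
#' @param k number of components (default 6).
#' @return n x k matrix of PCs with attribute `var_explained`.
#' @export
genotype_pcs <- function(G, k = 6) {
  n <- nrow(G$G)
  if (k > n) stop("k must not exceed the number of individuals")
  if (k == 0) return(matrix(0, n, 0))
  X <- .std_dosage(G$G)
  sv <- svd(X, nu = k, nv = k)
  U <- sv$u
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("PC", seq_len(k))
  attr(U, "var_explained") <- (sv$d^2 / sum(svd(X, nu = 0, nv = 0)$d^2))[seq_len(k)]
  U
}

#' Tile staggered SNP windows along each chromosome
#'
#' Windows of `size` bp advance by `step` bp (default 3 kb windows with 1 kb
#' stagger, so each variant belongs to up to size/step windows). Tiling is
#' anchored on the step grid containing the first variant of the chromosome;
#' windows holding no variant are dropped.
#'
#' @param variants data.frame with chrom and pos (1-based), sorted by
#'   position within chromosome.
#' @param size window size in bp.
#' @param step stagger in bp.
#' @return data.frame with chrom, start, end, center, n_variants and a list
#'   column `members` of variant row indices.
#' @export
build_windows <- function(variants, size = 3000, step = 1000) {
  stopifnot(size >= step)
  out <- list()
  for (ch in unique(variants$chrom)) {
    rows <- which(variants$chrom == ch)
    pos <- variants$pos[rows]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome")
    # all windows on the genome-wide step grid (anchored at coordinate 1)
    # that overlap the variant span; empty ones are dropped below
    s0 <- ((max(1, min(pos) - size + 1) - 1) %/% step) * step + 1
    starts <- seq(s0, max(pos), by = step)
    for (s in starts) {
      j <- rows[pos >= s & pos <= s + size - 1]
      if (!length(j)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + size - 1,
        center = s + (size - 1) / 2, n_variants = length(j))
      attr(out[[length(out)]], "members") <- j
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), center = numeric(0),
                      n_variants = integer(0)))
  members <- lapply(out, attr, "members")
  res <- do.call(rbind, out)
  res$members <- members
  rownames(res) <- NULL
  res
}
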