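# Variant filtering, kinship, genotype PCs and window tiling.

test_that("filtering matches a hand-filtered toy matrix", {
  G <- structure(list(
    G = rbind(c(0L, 1L, 0L, 2L, NA),
              c(0L, 1L, 1L, 2L, 0L),
              c(0L, 2L, 0L, 2L, 0L),
              c(0L, 0L, 1L, 2L, 0L)),
    variants = data.frame(chrom = "Chr01", pos = 1:5 * 100,
                          id = paste0("v", 1:5), ref = "A", alt = "T",
                          maf = NA, missing_frac = NA),
    samples = paste0("s", 1:4), subpop = rep(1L, 4)),
    class = "genotype_matrix")
  # by hand: v1 monomorphic (maf 0), v2 maf 0.5, v3 maf 0.25,
  # v4 monomorphic (maf 0 after folding), v5 maf 0 + 25% missing
  f <- filter_variants(G, maf_min = 0.01, missing_max = 1)
  expect_equal(f$variants$id, c("v2", "v3"))
  # missing bound alone
  f2 <- filter_variants(G, maf_min = 0, missing_max = 0)
  expect_false("v5" %in% f2$variants$id)
  # identity filter keeps everything with defined MAF
  f3 <- filter_variants(G, maf_min = 0, missing_max = 1)
  expect_equal(nrow(f3$variants), 5)
  # filtering order invariance: thresholds computed on non-missing calls
  f4 <- filter_variants(filter_variants(G, 0, 0.3), 0.01, 1)
  f5 <- filter_variants(filter_variants(G, 0.01, 1), 0, 0.3)
  expect_equal(f4$variants$id, f5$variants$id)
  # all-monomorphic input cannot survive a MAF floor
  Gmono <- G
  Gmono$G <- G$G[, c(1, 4)]
  Gmono$variants <- G$variants[c(1, 4), ]
  expect_error(filter_variants(Gmono, 0.01, 1), "survive")
})

test_that("kinship reflects duplicates, centering and independence", {
  p <- fx_panel(n = 60, m = 500, seed = 13, missing_rate = 0.05)
  G <- p$G
  G$G[2, ] <- G$G[1, ]                 # clone individual 1
  K <- compute_kinship(G)
  expect_equal(K[1, 2], K[1, 1])
  expect_true(isSymmetric(unclass(K)))
  expect_equal(unname(rowSums(K)), rep(0, 60), tolerance = 1e-8)
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # independent individuals: off-diagonal O(1/sqrt(m)) of the diagonal
  p2 <- fx_panel(n = 20, m = 5000, seed = 14, ld_block_bp = 1,
                 n_founder_hap = 1000, missing_rate = 0)
  K2 <- compute_kinship(p2$G)
  off <- K2[upper.tri(K2)]
  expect_lt(mean(abs(off)) / mean(diag(K2)), 4 / sqrt(5000) + 0.05)
})

test_that("genotype PCs are orthonormal, signed deterministically, separate subpopulations", {
  p <- fx_panel(n = 100, m = 800, seed = 15, n_subpop = 2, fst = 0.1,
                missing_rate = 0.02)
  Gc <- filter_variants(p$G, maf_min = 0.05, missing_max = 0.1)
  U <- genotype_pcs(Gc, k = 6)
  expect_equal(crossprod(U), diag(6), tolerance = 1e-8, ignore_attr = TRUE)
  r <- cor(U[, 1], as.numeric(p$G$subpop == 1))
  expect_gt(abs(r), 0.9)
  expect_equal(ncol(genotype_pcs(Gc, k = 0)), 0)
  expect_error(genotype_pcs(Gc, k = 101), "exceed")
})

test_that("window tiling matches the enumeration oracle", {
  v <- data.frame(chrom = "Chr01", pos = seq(100, 10000, by = 100))
  win <- build_windows(v, size = 3000, step = 1000)
  # step-grid starts covering the 10-kb span: 1, 1001, ..., 9001, the first
  # eight of which lie fully inside the span
  expect_equal(win$start, seq(1, 9001, by = 1000))
  expect_equal(win$end, win$start + 2999)
  # enumeration oracle: each variant in every window covering it
  for (i in seq_len(nrow(win))) {
    expect_equal(sort(win$members[[i]]),
                 which(v$pos >= win$start[i] & v$pos <= win$end[i]))
  }
  # each variant belongs to at most size/step windows
  counts <- table(unlist(win$members))
  expect_lte(max(counts), 3)
  # a lone variant is covered by exactly the (<= 3) windows containing it
  win1 <- build_windows(data.frame(chrom = "Chr01", pos = 5500))
  expect_equal(nrow(win1), 3)
  expect_true(all(win1$start <= 5500 & win1$end >= 5500))
  # dense genome: about one window per step
  v2 <- data.frame(chrom = "Chr01", pos = 1:20000)
  expect_equal(nrow(build_windows(v2)), 20)
})
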