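# Threshold machinery, the 30-kb peak rule against a brute-force oracle,
# and nearest-gene annotation.

test_that("Bonferroni cuts and BH flags match hand computation", {
  p <- c(0.001, 0.02, 0.03, 0.9)
  fl <- significance_thresholds(p, n_tests_snp = 100, alpha_fdr = 0.10)
  cuts <- attr(fl, "cuts")
  expect_equal(cuts$bonferroni, 0.05 / 100)
  expect_equal(fl$bonferroni, p <= 5e-4)
  # BH step-up by hand: largest i with p(i) <= alpha * i / n
  ps <- sort(p); n <- 4
  thresh <- 0.10 * seq_len(n) / n
  k <- max(which(ps <= thresh))
  expect_equal(fl$fdr, p <= ps[k])
  expect_equal(fl$fdr, c(TRUE, TRUE, TRUE, FALSE))
  # BH flags are monotone in p
  set.seed(1)
  p2 <- runif(20)
  fl2 <- significance_thresholds(p2, n_tests_snp = 20)
  for (i in 1:20) for (j in 1:20)
    if (p2[i] <= p2[j] && fl2$fdr[j]) expect_true(fl2$fdr[i])
})

test_that("ART results are judged against the ART-Bonferroni cut", {
  p <- c(1e-9, 1e-8)
  fl <- significance_thresholds(p, n_tests_snp = 1e7, n_tests_art = 4e5,
                                is_art = c(FALSE, TRUE))
  expect_false(fl$bonferroni[2])
  expect_true(fl$art_bonferroni[2])
  expect_true(fl$bonferroni[1])
  expect_false(fl$art_bonferroni[1])
})

test_that("peak calling matches the O(n^2) oracle and ignores input order", {
  set.seed(2)
  res <- data.frame(chrom = sample(c("Chr01", "Chr02"), 100, TRUE),
                    pos = sample.int(2e5, 100), p = runif(100)^3,
                    trait = sample(c("t1", "t2"), 100, TRUE),
                    method = "m")
  pk <- call_peaks(res, 30000)
  oracle <- vapply(seq_len(nrow(res)), function(i) {
    grp <- res$trait == res$trait[i] & res$chrom == res$chrom[i]
    rivals <- grp & abs(res$pos - res$pos[i]) <= 30000 &
      (res$p < res$p[i] | (res$p == res$p[i] & res$pos < res$pos[i]))
    !any(rivals)
  }, TRUE)
  expect_setequal(paste(pk$trait, pk$chrom, pk$pos),
                  paste(res$trait, res$chrom, res$pos)[oracle])
  # permutation invariance
  pk2 <- call_peaks(res[sample(nrow(res)), ], 30000)
  expect_setequal(paste(pk2$trait, pk2$chrom, pk2$pos),
                  paste(pk$trait, pk$chrom, pk$pos))
  # trivial pairs
  two <- data.frame(chrom = "Chr01", pos = c(1e5, 1e5 + 1e4),
                    p = c(1e-9, 1e-8))
  expect_equal(nrow(call_peaks(two)), 1)
  two$pos[2] <- two$pos[1] + 35000
  expect_equal(nrow(call_peaks(two)), 2)
})

test_that("every non-peak has a smaller-p result within the radius", {
  set.seed(3)
  res <- data.frame(chrom = "Chr01", pos = sample.int(3e5, 150),
                    p = runif(150))
  pk <- call_peaks(res, 30000)
  non <- res[!paste(res$chrom, res$pos) %in% paste(pk$chrom, pk$pos), ]
  for (i in seq_len(nrow(non))) {
    expect_true(any(abs(res$pos - non$pos[i]) <= 30000 &
                      (res$p < non$p[i] |
                         (res$p == non$p[i] & res$pos < non$pos[i]))))
  }
})

test_that("annotation distances, classes and the 5-kb rule", {
  genes <- structure(list(
    genes = data.frame(gene_id = c("gPlus", "gMinus"),
                       chrom = "Chr01", strand = c("+", "-"),
                       start = c(50000, 200000), end = c(56000, 204000)),
    exons = data.frame(gene_id = c("gPlus", "gPlus", "gMinus"),
                       start = c(50000, 54000, 200000),
                       end = c(51000, 56000, 204000))),
    class = "gene_models")
  pk <- data.frame(chrom = "Chr01",
                   pos = c(50500,      # inside exon 1
                           52000,      # intron
                           50000 - 3775, # upstream of + strand
                           56000 + 1200, # downstream of + strand
                           204000 + 6000, # upstream of - strand, > 5 kb
                           200000 - 8000), # downstream of - strand
                   p = 1e-9)
  an <- annotate_peaks(pk, genes, near = 5000)
  expect_equal(an$location_class,
               c("exonic", "intragenic_nonexonic", "five_prime",
                 "three_prime", "five_prime", "three_prime"))
  expect_equal(an$distance, c(0, 0, 3775, 1200, 6000, 8000))
  expect_equal(an$within_near, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(an$nearest_gene,
               c("gPlus", "gPlus", "gPlus", "gPlus", "gMinus", "gMinus"))
})

test_that("annotation matches a brute-force nearest-gene oracle", {
  gm <- simulate_gene_models(40, genome_bp = 3e5, seed = 7)
  set.seed(8)
  pk <- data.frame(chrom = "Chr01", pos = sample.int(3e5, 60), p = 1e-8)
  an <- annotate_peaks(pk, gm)
  g <- gm$genes
  for (i in seq_len(nrow(pk))) {
    d_all <- pmax(0, g$start - pk$pos[i], pk$pos[i] - g$end)
    expect_equal(an$distance[i], min(d_all))
    expect_true(an$nearest_gene[i] %in% g$gene_id[d_all == min(d_all)])
  }
})

test_that("annotation is strand-symmetric under coordinate mirroring", {
  gm <- simulate_gene_models(15, genome_bp = 1e5, seed = 9)
  set.seed(10)
  pk <- data.frame(chrom = "Chr01", pos = sample.int(1e5, 30), p = 1e-8)
  an <- annotate_peaks(pk, gm)
  Lg <- 1e5 + 1
  gm2 <- gm
  gm2$genes$start <- Lg - gm$genes$end
  gm2$genes$end <- Lg - gm$genes$start
  gm2$genes$strand <- ifelse(gm$genes$strand == "+", "-", "+")
  gm2$exons$start2 <- Lg - gm$exons$end
  gm2$exons$end <- Lg - gm$exons$start
  gm2$exons$start <- gm2$exons$start2; gm2$exons$start2 <- NULL
  ord <- order(gm2$genes$start)
  gm2$genes <- gm2$genes[ord, ]
  pk2 <- data.frame(chrom = "Chr01", pos = Lg - pk$pos, p = 1e-8)
  an2 <- annotate_peaks(pk2, gm2)
  expect_equal(an2$location_class, an$location_class)
  expect_equal(an2$distance, an$distance)
})

test_that("an empty gene list leaves peaks unassigned", {
  gm <- structure(list(genes = data.frame(), exons = data.frame()),
                  class = "gene_models")
  an <- annotate_peaks(data.frame(chrom = "Chr01", pos = 5, p = 0.1), gm)
  expect_equal(an$location_class, "unassigned")
})
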