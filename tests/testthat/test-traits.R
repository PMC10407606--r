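# Trait table construction, growth and PC traits, normality assessment,
# transformations and binarization.

fx_meas <- function() {
  p <- fx_panel(n = 80, m = 120, seed = 11)
  simulate_phenotypes(p$G, p$arch, seed = 11)
}

test_that("replicate means, single-replicate flags and duplicate errors", {
  m <- data.frame(genotype_id = c("a", "a", "b"), replicate = c(1, 2, 1),
                  week = 2, lateral_area = c(4, 6, 3))
  tt <- build_trait_table(m)
  expect_equal(tt$lateral_area_wk2, c(5, 3))
  expect_equal(attr(tt, "single_replicate")$lateral_area_wk2, "b")
  m2 <- rbind(m, m[1, ])
  expect_error(build_trait_table(m2), "duplicate")
})

test_that("the table is invariant to input row order", {
  ph <- fx_meas()
  tt1 <- build_trait_table(ph)
  set.seed(1)
  tt2 <- build_trait_table(ph[sample(nrow(ph)), ])
  expect_equal(tt1, tt2, ignore_attr = TRUE)
})

test_that("growth traits are week-5 minus week-2 with missing propagation", {
  m <- expand.grid(genotype_id = c("a", "b"), replicate = 1, week = c(2, 5))
  m$lateral_area <- c(10, 0, 25, 0)
  m$basal_area <- c(1, 1, 2, 1)
  m$total_area <- m$lateral_area + m$basal_area
  tt <- add_growth_traits(build_trait_table(m))
  expect_equal(tt$lateral_area_growth, c(15, 0))
  expect_equal(tt$basal_area_growth, c(1, 0))
  m2 <- m[!(m$genotype_id == "a" & m$week == 5), ]
  tt2 <- add_growth_traits(build_trait_table(m2))
  expect_true(is.na(tt2$lateral_area_growth[tt2$genotype_id == "a"]))
})

test_that("PC traits: eigenstructure, orthogonality and sign invariance", {
  set.seed(4)
  n <- 150
  base <- data.frame(genotype_id = sprintf("g%03d", 1:n))
  # two perfectly correlated columns in the area group, the rest noise
  shared <- rnorm(n)
  for (w in 2:5) {
    base[[paste0("lateral_area_wk", w)]] <- if (w <= 3) shared else rnorm(n)
    base[[paste0("basal_area_wk", w)]] <- rnorm(n)
    base[[paste0("lateral_lrl_wk", w)]] <- rnorm(n)
    base[[paste0("basal_lrl_wk", w)]] <- rnorm(n)
  }
  tt <- add_pc_traits(base)
  info <- attr(tt, "pca")
  # variance-explained fractions sum to one per group
  for (g in names(info)) expect_equal(sum(info[[g]]$var_explained), 1)
  # the duplicated-column pair dominates PC1 of its group:
  # eigenvalue of the 2-block is (1 + r) with r = 1, i.e. 2/8 of the total
  expect_gt(info$area$var_explained[1], 1.9 / 8)
  # scores orthogonal
  expect_lt(abs(cor(tt$area_pc1, tt$area_pc2)), 1e-8)
  # a global sign flip of a column block leaves |scores| unchanged
  flip <- base
  for (cl in grep("wk", names(flip), value = TRUE)) flip[[cl]] <- -flip[[cl]]
  tt2 <- add_pc_traits(flip)
  expect_equal(abs(tt2$all_pc1), abs(tt$all_pc1), tolerance = 1e-8)
})

test_that("PCA drops constant columns with a warning", {
  ph <- fx_meas()
  tt0 <- build_trait_table(ph)
  tt0$basal_area_wk2 <- 1
  # the column sits in two PCA groups, so two warnings are raised
  w <- capture_warnings(tt1 <- add_pc_traits(tt0))
  expect_true(all(grepl("constant", w)))
  expect_length(w, 2)
  expect_false(anyNA(tt1$area_pc1))
})

test_that("normality assessment separates normal from skewed samples", {
  set.seed(6)
  ok <- 0
  for (s in 1:10) {
    r <- assess_normality(rnorm(1000))
    ok <- ok + (r$shapiro_p > 0.05)
  }
  expect_gte(ok, 9)
  r_exp <- assess_normality(rexp(1000))
  expect_lt(r_exp$shapiro_p, 1e-3)
  expect_gt(r_exp$qq_cor, 0.8)
  expect_lt(r_exp$qq_cor, assess_normality(rnorm(1000))$qq_cor)
  r_const <- assess_normality(rep(3, 10))
  expect_true("degenerate-constant" %in% r_const$flags)
  expect_error(assess_normality(c(1, 2)), "at least 3")
})

test_that("Box-Cox recovers the log transform for log-normal data", {
  set.seed(7)
  x <- exp(rnorm(2000, 1, 1))
  tr <- transform_trait(x, "boxcox")
  expect_lt(abs(tr$provenance$lambda), 0.06)
  expect_error(transform_trait(c(-1, 2, 3), "boxcox"), "positive")
  # square-root-ish data
  y <- (rnorm(2000, 10, 1))^2
  tr2 <- transform_trait(y, "boxcox")
  expect_lt(abs(tr2$provenance$lambda - 0.5), 0.15)
})

test_that("rank-based inverse normal has the right shape and handles ties", {
  set.seed(8)
  x <- rgamma(1000, 1.2)
  tr <- transform_trait(x, "rbinv")
  z <- tr$values
  expect_lt(abs(mean(z)), 0.02)
  expect_gt(cor(sort(z), qnorm(((1:1000) - 3 / 8) / (1000 + 1 / 4))), 0.999)
  # empirical CDF close to standard normal
  expect_lt(suppressWarnings(ks.test(z, "pnorm"))$statistic, 0.05)
  # rank preservation
  expect_equal(order(z), order(x))
  # ties share averaged ranks, output monotone in the input
  xt <- c(1, 2, 2, 3)
  zt <- transform_trait(xt, "rbinv")$values
  expect_equal(zt[2], zt[3])
  expect_true(all(diff(zt[order(xt)]) >= 0))
})

test_that("zero and outlier removal are recorded in provenance", {
  x <- c(0, 0, 1, 2, 3, 4, 5, 1000)
  tr <- transform_trait(x, "none", remove_zeros = TRUE, outlier_k = 3)
  expect_equal(tr$provenance$zeros_removed, 2L)
  expect_equal(tr$provenance$outliers_removed, 1L)
  expect_true(all(is.na(tr$values[c(1, 2, 8)])))
  expect_equal(tr$values[3:7], x[3:7])
})

test_that("binarization rules and uninformative flags", {
  b <- binarize_trait(c(0, 0, 3.2, 7))
  expect_equal(b$values, c(0, 0, 1, 1))
  expect_length(b$flags, 0)
  b2 <- binarize_trait(c(1, 2, 3))
  expect_true("uninformative-binarization" %in% b2$flags)
  b3 <- binarize_trait(c(1, 2, 3, 4), rule = "median_split")
  expect_equal(b3$values, c(0, 0, 1, 1))
})
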