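# SKAT window tests: single-variant reduction, null calibration, shift
# invariance, agreement between asymptotic and empirical p-values, and the
# adaptive empirical p-value machinery.

fx_skat_panel <- function() {
  p <- fx_panel(n = 300, m = 2000, seed = 41, ld_block_bp = 1,
                bp_per_snp = 1000, missing_rate = 0.02)
  p
}

test_that("zero weights give Q = 0, p = 1; empty windows error", {
  p <- fx_skat_panel()
  set.seed(1)
  null <- fit_null_skat(rnorm(300), NULL)
  res <- skat_window_test(null, p$G$G[, 1:4], weights = rep(0, 4))
  expect_equal(res$Q, 0)
  expect_equal(res$p, 1)
  expect_error(skat_window_test(null, p$G$G[, integer(0)]), "empty")
})

test_that("a single-variant window reduces to the marginal score test", {
  p <- fx_skat_panel()
  set.seed(2)
  y <- rnorm(300)
  W <- cbind(1, rnorm(300))
  null <- fit_null_skat(y, W)
  for (j in which(p$G$variants$maf > 0.05)[1:5]) {
    x <- p$G$G[, j]; x[is.na(x)] <- mean(x, na.rm = TRUE)
    res <- skat_window_test(null, matrix(x), weights = 1)
    x0 <- qr.resid(null$qrW, x)
    T <- sum(x * null$resid)^2 / (null$sigma2 * sum(x0^2))
    expect_equal(res$p, pchisq(T, 1, lower.tail = FALSE), tolerance = 1e-6)
  }
})

test_that("null traits give approximately uniform asymptotic p-values", {
  p <- fx_skat_panel()
  # monomorphic variants are untestable (their windows pin p at 1) and are
  # removed by the SKAT-set filter in the pipeline; non-overlapping tiles
  # avoid re-testing identical variant sets in sparse regions
  Gs <- filter_variants(p$G, maf_min = 1 / 600, missing_max = 0.15)
  win <- build_windows(Gs$variants, size = 3000, step = 3000)
  set.seed(3)
  pv <- c()
  for (s in 1:3) {
    y <- rnorm(300)
    sc <- skat_scan(y, NULL, Gs, win, empirical_below = NULL)
    pv <- c(pv, sc$p)
  }
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  expect_gt(mean(pv < 0.05), 0.035)
  expect_lt(mean(pv < 0.05), 0.065)
})

test_that("Q is invariant to adding a constant to the trait", {
  p <- fx_skat_panel()
  set.seed(4)
  y <- rnorm(300)
  n1 <- fit_null_skat(y, NULL)
  n2 <- fit_null_skat(y + 100, NULL)
  r1 <- skat_window_test(n1, p$G$G[, 1:6])
  r2 <- skat_window_test(n2, p$G$G[, 1:6])
  expect_equal(r1$Q, r2$Q, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("asymptotic and empirical p-values agree for moderate p", {
  p <- fx_panel(n = 200, m = 50, seed = 43, ld_block_bp = 1,
                missing_rate = 0)
  set.seed(5)
  done <- 0
  for (try in 1:20) {
    y <- rnorm(200)
    null <- fit_null_skat(y, NULL)
    Gwin <- p$G$G[, 1:8]
    res <- skat_window_test(null, Gwin)
    if (res$p < 0.01 || res$p > 0.5) next
    done <- done + 1
    af <- colMeans(Gwin) / 2
    Gw <- sweep(Gwin, 2, skat_beta_weights(pmin(af, 1 - af)), "*")
    r0 <- null$resid
    B <- 4000
    qs <- vapply(seq_len(B), function(b)
      sum(crossprod(Gw, r0[sample.int(200)])^2), 0)
    p_emp <- mean(qs >= res$Q)
    se <- sqrt(p_emp * (1 - p_emp) / B)
    expect_lt(abs(res$p - p_emp), 3 * se + 1e-12)
    if (done >= 3) break
  }
  expect_gte(done, 3)
})

test_that("adaptive empirical p-values stop early and respect the floor", {
  # statistic at the null median: ~0.5 after the first batch
  set.seed(6)
  e <- empirical_p(qnorm(0.5), function(b) rnorm(b), B_max = 1e6)
  expect_equal(e$B, 1000)
  expect_gt(e$p, 0.4); expect_lt(e$p, 0.6)
  # never-exceeded statistic at the full default budget: exactly 1e-7
  e2 <- empirical_p(1, function(b) numeric(b), B_max = 1e7)
  expect_identical(e2$p, 1e-7)
  expect_equal(e2$B, 1e7)
  expect_error(empirical_p(1, function(b) numeric(b), B_max = 0), "B_max")
})

test_that("empirical p is monotone in the observed statistic and covers", {
  set.seed(7)
  obs <- c(0.1, 0.5, 1, 1.5, 2)
  ps <- vapply(obs, function(o) {
    set.seed(99)
    empirical_p(o, function(b) rnorm(b), B_max = 1e4)$p
  }, 0)
  expect_true(all(diff(ps) <= 0))
  # binomial coverage at B_max = 100 for a known continuous null
  p_true <- pnorm(1.2, lower.tail = FALSE)
  hits <- 0
  for (s in 1:200) {
    set.seed(500 + s)
    e <- empirical_p(1.2, function(b) rnorm(b), B_max = 100)
    ci <- qbinom(c(0.005, 0.995), 100, p_true) / 100
    hits <- hits + (e$p >= ci[1] && e$p <= ci[2])
  }
  expect_gte(hits / 200, 0.9)
})

test_that("the Liu tail approximation is exact for chi-square cases", {
  # single eigenvalue: exact chi-square(1)
  expect_equal(pchisq_weighted(3.84, 2), pchisq(3.84 / 2, 1, lower.tail = FALSE))
  # equal eigenvalues: sum of k chi-squares
  expect_equal(pchisq_weighted(7, rep(1, 4)),
               pchisq(7, 4, lower.tail = FALSE), tolerance = 1e-6)
})
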