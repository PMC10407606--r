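# Linear mixed model y = W a + u + e with u ~ N(0, sg2 K), e ~ N(0, se2 I),
# fitted by REML through the eigen-decomposition of K and one-dimensional
# optimisation of the variance ratio delta = se2 / sg2 (the EMMA device).
# The per-variant scan holds delta at its null-model estimate and tests each
# variant by a generalized-least-squares Wald statistic.

# REML log-likelihood profile in delta for rotated data.
# d: eigenvalues of K; yt, Wt: rotated response and covariates.
.reml_loglik <- function(log_delta, d, yt, Wt) {
  delta <- exp(log_delta)
  v <- d + delta
  q <- ncol(Wt)
  n <- length(yt)
  WtV <- Wt / v
  A <- crossprod(Wt, WtV)
  Ai <- solve(A)
  b <- crossprod(WtV, yt)
  alpha <- Ai %*% b
  r <- yt - Wt %*% alpha
  rss <- sum(r^2 / v)
  -0.5 * ((n - q) * log(rss / (n - q)) + sum(log(v)) +
            determinant(A, logarithm = TRUE)$modulus + (n - q))
}

#' Fit the null linear mixed model
#'
#' @param y numeric response (NAs dropped with matching covariate/K rows).
#' @param W covariate matrix including an intercept; if NULL, an intercept
#'   only. Columns must not be collinear.
#' @param K kinship matrix (will be rescaled to mean diagonal 1).
#' @param delta_range search range for delta = se2/sg2.
#' @return object of class `null_lmm`: eigen cache, delta, variance
#'   components, PVE, covariate estimates, the analysis row subset.
#' @export
fit_null_lmm <- function(y, W = NULL, K, delta_range = c(1e-5, 1e5)) {
  n_all <- length(y)
  if (is.null(W)) W <- matrix(1, n_all, 1, dimnames = list(NULL, "intercept"))
  W <- as.matrix(W)
  keep <- which(!is.na(y) & stats::complete.cases(W))
  y <- y[keep]; W <- W[keep, , drop = FALSE]
  K <- scale_kinship(unclass(K)[keep, keep, drop = FALSE])
  n <- length(y)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("collinear covariate columns: ", paste(bad, collapse = ", "))
  }
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("kinship matrix is not positive semi-definite")
  d <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  yt <- drop(Ut %*% y)
  Wt <- Ut %*% W
  # bracket on a log grid, then refine
  grid <- seq(log(delta_range[1]), log(delta_range[2]), length.out = 41)
  ll <- vapply(grid, .reml_loglik, 0, d = d, yt = yt, Wt = Wt)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(.reml_loglik, c(lo, hi), d = d, yt = yt, Wt = Wt,
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  v <- d + delta
  WtV <- Wt / v
  A <- crossprod(Wt, WtV)
  alpha <- solve(A, crossprod(WtV, yt))
  r <- yt - Wt %*% alpha
  sg2 <- sum(r^2 / v) / (n - ncol(W))
  se2 <- sg2 * delta
  flags <- character(0)
  if (stats::sd(d) < 1e-10) flags <- c(flags, "pve-unidentifiable")
  structure(list(delta = delta, sigma_g2 = sg2, sigma_e2 = se2,
                 pve = 1 / (1 + delta), alpha = drop(alpha),
                 d = d, Ut = Ut, yt = yt, Wt = Wt, keep = keep,
                 n = n, q = ncol(W), flags = flags,
                 reml = opt$objective),
            class = "null_lmm")
}

#' SNP heritability (PVE) under the null mixed model
#'
#' Fits the null model and reports PVE = sg2 / (sg2 + se2), the fraction of
#' trait variance attributed to the kinship random effect, together with the
#' gate decision at the given threshold. For an identity-proportional
#' kinship the two components are not separately identifiable and the
#' estimate is flagged.
#'
#' @param y trait values.
#' @param W covariates (intercept added if NULL).
#' @param K kinship matrix.
#' @param gate_threshold heritability gate (default 0.10); traits at or
#'   below it are conventionally excluded from association scans.
#' @return list with `pve`, `sigma_g2`, `sigma_e2`, `gate`, `flags`.
#' @export
estimate_h2 <- function(y, W = NULL, K, gate_threshold = 0.10) {
  fit <- fit_null_lmm(y, W, K)
  pve <- fit$pve
  if ("pve-unidentifiable" %in% fit$flags) pve <- NA_real_
  list(pve = pve, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
       gate = isTRUE(pve > gate_threshold), flags = fit$flags)
}

#' Mixed-model Wald scan over variants
#'
#' For each variant, dosages are mean-imputed, rotated by the null model's
#' eigenvectors, and tested by a GLS Wald statistic (beta/se)^2 against
#' chi-square with 1 df, holding the variance ratio at its null estimate.
#' Variants whose squared multiple correlation with the covariate span
#' exceeds `r2_max` are skipped (p = NA, flagged), mirroring the customary
#' collinearity guard of mixed-model GWAS software.
#'
#' @param null a `null_lmm` from [fit_null_lmm()].
#' @param G a `genotype_matrix` (rows matching the y passed to the null fit).
#' @param r2_max collinearity threshold (default 0.9999).
#' @return data.frame: id, chrom, pos, beta, se, stat, p, skipped.
#' @export
lmm_wald_scan <- function(null, G, r2_max = 0.9999) {
  X <- G$G[null$keep, , drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE); mu[is.nan(mu)] <- 0
  na <- is.na(X)
  if (any(na)) X[na] <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)[na]
  v <- null$d + null$delta
  Xt <- null$Ut %*% X
  Wt <- null$Wt; yt <- null$yt
  WtV <- Wt / v
  A <- crossprod(Wt, WtV)
  Ai <- solve(A)
  # residualize x and y against covariates under the GLS inner product
  proj <- function(Z) Z - Wt %*% (Ai %*% crossprod(WtV, Z))
  Xr <- proj(Xt)
  yr <- drop(proj(matrix(yt)))
  xx <- colSums(Xr^2 / v)
  xy <- colSums(Xr * yr / v)
  yy <- sum(yr^2 / v)
  # collinearity guard: plain R^2 of raw dosages on the covariate span
  Wraw <- t(null$Ut) %*% null$Wt
  Q <- qr.Q(qr(Wraw))
  xc <- X - Q %*% crossprod(Q, X)
  ss_tot <- colSums(scale(X, scale = FALSE)^2)
  r2 <- 1 - colSums(xc^2) / pmax(ss_tot, 1e-300)
  skip <- r2 > r2_max | xx < 1e-12
  beta <- xy / xx
  df <- null$n - null$q - 1
  sigma2 <- (yy - beta^2 * xx) / df
  se <- sqrt(sigma2 / xx)
  stat <- (beta / se)^2
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  beta[skip] <- NA; se[skip] <- NA; stat[skip] <- NA; p[skip] <- NA
  data.frame(id = G$variants$id, chrom = G$variants$chrom,
             pos = G$variants$pos, beta = beta, se = se, stat = stat,
             p = p, skipped = skip, method = "lmm_wald")
}
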