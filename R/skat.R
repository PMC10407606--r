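# Windowed SNP-set kernel association test (SKAT) on untransformed traits:
# variance-component score statistic Q = r' Gw Gw' r with Beta(1,25)
# MAF-based variant weights, asymptotic p-value from the weighted chi-square
# null via four-moment matching, and adaptive Monte-Carlo empirical p-values
# by residual permutation for top windows.

#' Four-moment (Liu) approximation to a weighted sum of chi-squares
#'
#' P(sum_i lambda_i chi2_1 > q) approximated by a (non-central) chi-square
#' matched on four cumulants. Exact for a single eigenvalue.
#'
#' @param q observed statistic.
#' @param lambda eigenvalue weights (non-negative).
#' @return upper-tail probability.
#' @export
pchisq_weighted <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda, 0)]
  if (!length(lambda)) return(1)
  if (length(lambda) == 1L)
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    ncp <- 0
    df <- 1 / s2
  }
  mu_q <- c1; sd_q <- sqrt(2 * c2)
  mu_x <- df + ncp; sd_x <- sqrt(2 * (df + 2 * ncp))
  tstar <- (q - mu_q) / sd_q
  stats::pchisq(tstar * sd_x + mu_x, df = df, ncp = ncp, lower.tail = FALSE)
}

#' SKAT default variant weights
#'
#' Beta(1, 25) density evaluated at the MAF, the customary up-weighting of
#' rare variants.
#' @param maf minor allele frequencies.
#' @export
skat_beta_weights <- function(maf) stats::dbeta(pmin(pmax(maf, 0), 1), 1, 25)

#' Fit the SKAT linear null model
#'
#' Ordinary least squares of the (untransformed) trait on the covariates;
#' caches residuals, the hat-matrix complement and the error variance.
#'
#' @param y trait values.
#' @param W covariates including intercept (NULL = intercept only).
#' @return object of class `null_skat`.
#' @export
fit_null_skat <- function(y, W = NULL) {
  if (is.null(W)) W <- matrix(1, length(y), 1)
  W <- as.matrix(W)
  keep <- which(!is.na(y) & stats::complete.cases(W))
  y <- y[keep]; W <- W[keep, , drop = FALSE]
  qrW <- qr(W)
  r <- qr.resid(qrW, y)
  n <- length(y); q <- qrW$rank
  structure(list(resid = r, qrW = qrW, sigma2 = sum(r^2) / (n - q),
                 keep = keep, n = n, q = q),
            class = "null_skat")
}

#' SKAT test of one SNP window
#'
#' Q = r' Gw Gw' r where Gw holds the window's mean-imputed dosages scaled
#' by the variant weights and r the covariate-adjusted residuals. The
#' asymptotic null is the weighted chi-square with weights
#' sigma2 * eig(Gw' P0 Gw) where P0 projects off the covariates.
#'
#' @param null a `null_skat` fit.
#' @param Gwin n x L matrix of window dosages (may contain NAs).
#' @param weights per-variant weights (default Beta(1,25) on the realized
#'   MAF).
#' @return list with `Q`, `p`, `lambda`, `L`.
#' @export
skat_window_test <- function(null, Gwin, weights = NULL) {
  Gwin <- as.matrix(Gwin)[null$keep, , drop = FALSE]
  if (ncol(Gwin) == 0) stop("empty window")
  mu <- colMeans(Gwin, na.rm = TRUE); mu[is.nan(mu)] <- 0
  na <- is.na(Gwin)
  if (any(na)) Gwin[na] <- matrix(mu, nrow(Gwin), ncol(Gwin), byrow = TRUE)[na]
  if (is.null(weights)) {
    af <- colMeans(Gwin) / 2
    weights <- skat_beta_weights(pmin(af, 1 - af))
  }
  Gw <- sweep(Gwin, 2, weights, "*")
  s <- drop(crossprod(Gw, null$resid))
  Q <- sum(s^2)
  if (all(weights == 0)) return(list(Q = 0, p = 1, lambda = numeric(0),
                                     L = ncol(Gwin)))
  G0 <- qr.resid(null$qrW, Gw)
  lam <- eigen(crossprod(G0), symmetric = TRUE, only.values = TRUE)$values
  lam <- null$sigma2 * pmax(lam, 0)
  list(Q = Q, p = pchisq_weighted(Q, lam), lambda = lam, L = ncol(Gwin))
}

#' Adaptive Monte-Carlo empirical p-value
#'
#' Draws null statistics in growing batches (by default 1e3, 1e4, 1e5, 1e6,
#' then chunks up to `B_max`), stopping early once at least `r_min` null
#' draws reach the observed statistic. The estimate is r/B, floored at
#' 1/B_max when no exceedance is seen, so the smallest attainable value at
#' the full default budget of 1e7 is exactly 1e-7.
#'
#' @param observed observed statistic.
#' @param resampler function(b) returning b null statistics.
#' @param B_max total resampling budget (>= 1).
#' @param batch_sizes escalation schedule.
#' @param r_min early-stopping exceedance count.
#' @return list with `p`, `B`, `exceedances`.
#' @export
empirical_p <- function(observed, resampler, B_max = 1e7,
                        batch_sizes = c(1e3, 1e4, 1e5, 1e6), r_min = 10) {
  if (B_max < 1) stop("B_max must be at least 1")
  B <- 0; r <- 0
  sched <- batch_sizes[batch_sizes <= B_max]
  if (!length(sched)) sched <- B_max
  k <- 1
  while (B < B_max && r < r_min) {
    b <- if (k <= length(sched)) sched[k] else 1e6
    b <- min(b, B_max - B)
    stats <- resampler(b)
    r <- r + sum(stats >= observed)
    B <- B + b
    k <- k + 1
  }
  p <- if (r > 0) r / B else 1 / B_max
  list(p = p, B = B, exceedances = r)
}

#' Scan SNP windows with SKAT, optionally resampling top windows
#'
#' Tests every window of [build_windows()] against the linear null model and
#' replaces the asymptotic p-value by an adaptive permutation-based
#' empirical p-value (permuting the null-model residuals) for windows whose
#' asymptotic p falls below `empirical_below`.
#'
#' @param y untransformed trait values.
#' @param W covariates (intercept + stem diameter + batch + genotype PCs in
#'   typical use).
#' @param G a `genotype_matrix`.
#' @param windows data.frame from [build_windows()].
#' @param empirical_below asymptotic-p threshold triggering resampling
#'   (NULL disables resampling).
#' @param B_max resampling budget per window.
#' @param seed seed for the permutation stream.
#' @return data.frame: chrom, start, end, center, L, Q, p, method, B_used.
#' @export
skat_scan <- function(y, W = NULL, G, windows,
                      empirical_below = 1e-4, B_max = 1e6, seed = 1) {
  null <- fit_null_skat(y, W)
  m <- nrow(windows)
  Q <- p <- numeric(m); L <- integer(m); B_used <- rep(NA_real_, m)
  method <- rep("skat_asym", m)
  lam_cache <- vector("list", m)
  for (i in seq_len(m)) {
    res <- skat_window_test(null, G$G[, windows$members[[i]], drop = FALSE])
    Q[i] <- res$Q; p[i] <- res$p; L[i] <- res$L
    lam_cache[[i]] <- res$lambda
  }
  if (!is.null(empirical_below)) {
    set.seed(as.integer(seed))
    r0 <- null$resid
    for (i in which(p < empirical_below)) {
      Gwin <- G$G[null$keep, windows$members[[i]], drop = FALSE]
      mu <- colMeans(Gwin, na.rm = TRUE); mu[is.nan(mu)] <- 0
      na <- is.na(Gwin)
      if (any(na))
        Gwin[na] <- matrix(mu, nrow(Gwin), ncol(Gwin), byrow = TRUE)[na]
      af <- colMeans(Gwin) / 2
      Gw <- sweep(Gwin, 2, skat_beta_weights(pmin(af, 1 - af)), "*")
      resampler <- function(b) {
        out <- numeric(b)
        done <- 0
        while (done < b) {
          nb <- min(b - done, 2000L)
          P <- replicate(nb, sample.int(length(r0)))
          R <- matrix(r0[P], nrow = length(r0))
          out[done + seq_len(nb)] <- colSums(crossprod(Gw, R)^2)
          done <- done + nb
        }
        out
      }
      emp <- empirical_p(Q[i], resampler, B_max = B_max)
      p[i] <- emp$p; B_used[i] <- emp$B; method[i] <- "skat_empirical"
    }
  }
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, center = windows$center, L = L,
             Q = Q, p = p, method = method, B_used = B_used)
}
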