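# Logistic mixed model for binarized traits, fitted by penalized
# quasi-likelihood (iterated working-response LMM with the kinship as the
# random-effect covariance), followed by per-variant score tests. The score
# test needs no per-variant model fit, so variants with complete separation
# still yield finite p-values.

#' Fit the null logistic mixed model by PQL
#'
#' Iterates: given the current linear predictor, form the working response
#' z = eta + (y - mu)/(mu(1-mu)) and weights w = mu(1-mu); estimate sg2 by
#' REML on the working model z = W a + u + e with Var = sg2 K + diag(1/w);
#' update the fixed effects and BLUP. Convergence when successive sg2
#' estimates differ by less than `tol`.
#'
#' @param y binary response (0/1), both classes present.
#' @param W covariates including intercept (NULL = intercept only).
#' @param K kinship matrix.
#' @param tol convergence tolerance on sg2.
#' @param max_iter maximum PQL iterations.
#' @param fixed_sigma_g2 optional fixed value for sg2 (skips the REML step);
#'   with 0 the model collapses to ordinary logistic regression and the
#'   score test to the plain GLM score test.
#' @return object of class `null_glmm` with the projection matrix pieces
#'   needed by [glmm_score_scan()].
#' @export
fit_null_glmm <- function(y, W = NULL, K, tol = 1e-6, max_iter = 100,
                          fixed_sigma_g2 = NULL) {
  if (is.null(W)) W <- matrix(1, length(y), 1)
  W <- as.matrix(W)
  keep <- which(!is.na(y) & stats::complete.cases(W))
  y <- y[keep]; W <- W[keep, , drop = FALSE]
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("binary response must contain both classes")
  K <- scale_kinship(unclass(K)[keep, keep, drop = FALSE])
  n <- length(y)
  fit0 <- stats::glm.fit(W, y, family = stats::binomial())
  eta <- fit0$linear.predictors
  sg2 <- 0.1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    reml <- function(log_sg2) {
      s <- exp(log_sg2)
      V <- s * K + diag(1 / w)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(-1e10)
      Vi_z <- backsolve(ch, forwardsolve(t(ch), z))
      Vi_W <- backsolve(ch, forwardsolve(t(ch), W))
      A <- crossprod(W, Vi_W)
      alpha <- solve(A, crossprod(Vi_W, z))
      r <- z - W %*% alpha
      Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
      -0.5 * (2 * sum(log(diag(ch))) +
                determinant(A, logarithm = TRUE)$modulus +
                sum(r * Vi_r))
    }
    sg2_new <- if (!is.null(fixed_sigma_g2)) fixed_sigma_g2 else
      exp(stats::optimize(reml, c(log(1e-8), log(50)), maximum = TRUE,
                          tol = 1e-9)$maximum)
    V <- sg2_new * K + diag(1 / w)
    Vi <- chol2inv(chol(V))
    A <- crossprod(W, Vi %*% W)
    alpha <- solve(A, crossprod(W, Vi %*% z))
    u <- sg2_new * K %*% (Vi %*% (z - W %*% alpha))
    eta <- drop(W %*% alpha + u)
    if (abs(sg2_new - sg2) < tol) { sg2 <- sg2_new; converged <- TRUE; break }
    sg2 <- sg2_new
  }
  if (!converged)
    return(structure(list(converged = FALSE, flags = "pql-nonconvergence"),
                     class = "null_glmm"))
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-8)
  z <- eta + (y - mu) / w
  V <- sg2 * K + diag(1 / w)
  Vi <- chol2inv(chol(V))
  ViW <- Vi %*% W
  P <- Vi - ViW %*% solve(crossprod(W, ViW), t(ViW))
  structure(list(sigma_g2 = sg2, alpha = drop(alpha), mu = mu,
                 P = P, Pz = drop(P %*% z), keep = keep, n = n,
                 converged = TRUE, flags = character(0)),
            class = "null_glmm")
}

#' Score scan for a binarized trait under the logistic mixed model
#'
#' Per-variant score statistic (xt P z)^2 / (xt P x) against chi-square with
#' 1 df, where P is the null-model projection and z the converged working
#' response. With sg2 = 0 this reduces to the ordinary logistic score test.
#'
#' @param y binary trait (0/1).
#' @param W covariates (NULL = intercept only).
#' @param K kinship matrix.
#' @param G a `genotype_matrix`.
#' @param ... passed to [fit_null_glmm()].
#' @return data.frame: id, chrom, pos, stat, p. If the PQL fit does not
#'   converge, a zero-row data.frame with attribute `flags`.
#' @export
glmm_score_scan <- function(y, W = NULL, K, G, ...) {
  null <- fit_null_glmm(y, W, K, ...)
  if (!null$converged) {
    out <- data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), stat = numeric(0), p = numeric(0),
                      method = character(0))
    attr(out, "flags") <- null$flags
    return(out)
  }
  X <- G$G[null$keep, , drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE); mu[is.nan(mu)] <- 0
  na <- is.na(X)
  if (any(na)) X[na] <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)[na]
  U <- drop(crossprod(X, null$Pz))
  PX <- null$P %*% X
  denom <- colSums(X * PX)
  stat <- ifelse(denom > 1e-12, U^2 / denom, NA_real_)
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  data.frame(id = G$variants$id, chrom = G$variants$chrom,
             pos = G$variants$pos, stat = stat, p = p, method = "glmm_score")
}
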