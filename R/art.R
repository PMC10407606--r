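# Augmented rank truncation (ART) combination of p-values over windows.
#
# For ordered p-values p(1) <= ... <= p(L) and truncation point
# k = min(L, k_max), the statistic augments the rank-truncated product with
# a Beta-transformed k-th order statistic so that its null distribution is
# closed form under independence: conditional on p(k), the ratios
# p(i)/p(k), i < k, behave as k-1 independent uniforms, so
#   T = -2 * sum_{i<k} log(p(i)/p(k))
#     + Qchisq2(Beta_{k, L-k+1}(p(k)))
# is chi-square with 2k degrees of freedom, where Qchisq2 maps the Beta CDF
# value of p(k) to an upper-tail chi-square(2) quantile. A Monte-Carlo
# calibration mode (resampling independent uniforms) is provided as an
# independent oracle and runtime fallback.

#' ART statistic for one set of p-values
#' @keywords internal
art_statistic <- function(p, k_max = 5) {
  L <- length(p)
  k <- min(L, k_max)
  ps <- sort(p)
  T <- if (k > 1) -2 * sum(log(ps[seq_len(k - 1)] / ps[k])) else 0
  u <- stats::pbeta(ps[k], k, L - k + 1)
  T <- T + stats::qchisq(u, df = 2, lower.tail = FALSE)
  list(T = T, df = 2 * k, k = k)
}

#' Combine a window's p-values by augmented rank truncation
#'
#' @param p p-values in (0, 1]; zeros are clamped to the machine minimum
#'   with a warning.
#' @param k_max truncation point (the k smallest p-values drive the
#'   statistic).
#' @param method "analytic" (closed-form chi-square null, valid under
#'   independence) or "mc" (Monte-Carlo calibration against resampled
#'   uniform p-value sets).
#' @param B Monte-Carlo draws for `method = "mc"`.
#' @return combined p-value.
#' @export
art_pvalue <- function(p, k_max = 5, method = c("analytic", "mc"),
                       B = 1e5) {
  method <- match.arg(method)
  stopifnot(length(p) >= 1, all(p <= 1), all(p >= 0))
  if (any(p == 0)) {
    warning("p-values of 0 clamped to the machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  st <- art_statistic(p, k_max)
  if (method == "analytic")
    return(stats::pchisq(st$T, df = st$df, lower.tail = FALSE))
  L <- length(p)
  Tnull <- vapply(seq_len(B), function(b)
    art_statistic(stats::runif(L), k_max)$T, 0)
  (sum(Tnull >= st$T) + 1) / (B + 1)
}

#' ART combination of single-variant p-values over 1-kb windows
#'
#' Groups single-SNP p-values (e.g. mixed-model Wald or logistic score
#' results) into non-overlapping windows by position and combines each
#' window's member p-values with [art_pvalue()].
#'
#' @param results data.frame with chrom, pos, p (rows with NA p are
#'   dropped).
#' @param window window length in bp (non-overlapping tiling).
#' @param k_max truncation point.
#' @param method passed to [art_pvalue()].
#' @param B Monte-Carlo draws when `method = "mc"`.
#' @return data.frame: chrom, start, end, center, L, p, method.
#' @export
art_combine <- function(results, window = 1000, k_max = 5,
                        method = "analytic", B = 1e5) {
  res <- results[!is.na(results$p), , drop = FALSE]
  if (!nrow(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), center = numeric(0), L = integer(0),
                      p = numeric(0), method = character(0)))
  start <- ((res$pos - 1) %/% window) * window + 1
  key <- paste(res$chrom, start)
  groups <- split(seq_len(nrow(res)), key)
  out <- lapply(groups, function(ix) {
    s <- start[ix[1]]
    data.frame(chrom = res$chrom[ix[1]], start = s, end = s + window - 1,
               center = s + (window - 1) / 2, L = length(ix),
               p = art_pvalue(res$p[ix], k_max = k_max, method = method,
                              B = B),
               method = "art")
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
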