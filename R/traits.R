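# Genotype-level trait tables and their preparation for association mapping:
# replicate averaging, growth traits, within-trait-group principal
# components, normality assessment, Box-Cox and rank-based inverse-normal
# transformations, outlier/zero handling, and binarization.

TRAIT_FAMILIES <- c("lateral_area", "basal_area", "total_area",
                    "lateral_lrl", "basal_lrl", "overall_lrl")

#' Build the genotype-level trait table from replicate measurements
#'
#' One row per genotype; each base trait (family x week) is the mean over
#' available replicates. Genotypes observed in a single replicate keep that
#' replicate's value and are flagged; genotypes without any replicate for a
#' trait are missing.
#'
#' @param measurements data.frame with genotype_id, replicate, week and the
#'   six trait family columns (see [simulate_phenotypes()] or the output of
#'   the measurement pipeline).
#' @return data.frame with genotype_id and `<family>_wk<week>` columns;
#'   attribute `single_replicate` lists (genotype, trait) cells based on one
#'   replicate.
#' @export
build_trait_table <- function(measurements) {
  need <- c("genotype_id", "replicate", "week")
  stopifnot(all(need %in% names(measurements)))
  fam <- intersect(TRAIT_FAMILIES, names(measurements))
  if (!length(fam)) stop("no trait family columns found")
  dup <- duplicated(measurements[, c("genotype_id", "replicate", "week")])
  if (any(dup)) stop("duplicate (genotype, replicate, week) rows")
  gids <- sort(unique(measurements$genotype_id))
  weeks <- sort(unique(measurements$week))
  out <- data.frame(genotype_id = gids)
  singles <- list()
  for (f in fam) for (w in weeks) {
    sel <- measurements$week == w & !is.na(measurements[[f]])
    agg <- tapply(measurements[[f]][sel], measurements$genotype_id[sel], mean)
    cnt <- tapply(measurements[[f]][sel], measurements$genotype_id[sel],
                  length)
    col <- paste0(f, "_wk", w)
    out[[col]] <- as.numeric(agg[match(gids, names(agg))])
    ones <- names(cnt)[cnt == 1]
    if (length(ones))
      singles[[col]] <- ones
  }
  attr(out, "single_replicate") <- singles
  out
}

#' Add the three growth traits
#'
#' Growth = week-5 value minus week-2 value for lateral, basal and total
#' root area; missing if either endpoint is missing.
#'
#' @param table trait table from [build_trait_table()].
#' @param first_week,last_week endpoints (defaults 2 and 5).
#' @return the table with `<area family>_growth` columns appended.
#' @export
add_growth_traits <- function(table, first_week = 2, last_week = 5) {
  for (f in c("lateral_area", "basal_area", "total_area")) {
    a <- table[[paste0(f, "_wk", first_week)]]
    b <- table[[paste0(f, "_wk", last_week)]]
    if (is.null(a) || is.null(b))
      stop("weeks ", first_week, " and ", last_week, " must be present")
    table[[paste0(f, "_growth")]] <- b - a
  }
  table
}

#' Trait-group principal components
#'
#' PCA (centered and scaled) over three fixed groups of base traits:
#' (1) basal and lateral root area at all time points, (2) basal and lateral
#' LRL at all time points, (3) both together. The first two PCs of each
#' group are appended as traits (`area_pc1/2`, `lrl_pc1/2`, `all_pc1/2`).
#' Rows with missing values are excluded per group; constant columns are
#' dropped with a warning.
#'
#' @param table trait table with the base traits.
#' @param weeks time points used (default 2:5).
#' @return the table with six PC trait columns; attribute `pca` holds per
#'   group loadings, variance explained and scree data.
#' @export
add_pc_traits <- function(table, weeks = 2:5) {
  cols_of <- function(fams) as.vector(outer(fams, weeks,
                                            function(f, w) paste0(f, "_wk", w)))
  groups <- list(
    area = cols_of(c("lateral_area", "basal_area")),
    lrl = cols_of(c("lateral_lrl", "basal_lrl")),
    all = cols_of(c("lateral_area", "basal_area", "lateral_lrl", "basal_lrl")))
  pca_info <- list()
  for (g in names(groups)) {
    cols <- intersect(groups[[g]], names(table))
    M <- as.matrix(table[, cols])
    cc <- stats::complete.cases(M)
    sds <- apply(M[cc, , drop = FALSE], 2, stats::sd)
    if (any(sds < 1e-12)) {
      warning("dropping constant column(s) in PCA group ", g, ": ",
              paste(cols[sds < 1e-12], collapse = ", "))
      cols <- cols[sds >= 1e-12]
      M <- as.matrix(table[, cols])
    }
    pc <- stats::prcomp(M[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    for (j in 1:2) {
      # deterministic sign: largest-magnitude loading positive
      i <- which.max(abs(pc$rotation[, j]))
      s <- sign(pc$rotation[i, j])
      v <- rep(NA_real_, nrow(table))
      v[cc] <- s * pc$x[, j]
      table[[paste0(g, "_pc", j)]] <- v
    }
    pca_info[[g]] <- list(loadings = pc$rotation, var_explained = ve,
                          n_used = sum(cc))
  }
  attr(table, "pca") <- pca_info
  table
}

#' Assess normality of a trait
#'
#' Shapiro-Wilk test, Pearson correlation with theoretical normal quantiles
#' at Blom plotting positions, histogram bin counts and Q-Q coordinates.
#' For n > 5000 the Shapiro-Wilk statistic is computed on an evenly thinned
#' subset of the sorted values (flagged).
#'
#' @param values numeric vector (NAs dropped); needs >= 3 non-missing.
#' @return object of class `normality_report`.
#' @export
assess_normality <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) stop("need at least 3 non-missing values")
  flags <- character(0)
  if (stats::sd(x) < 1e-12) {
    return(structure(list(n = length(x), shapiro_w = NA_real_,
                          shapiro_p = NA_real_, qq_cor = NA_real_,
                          hist = NULL, qq = NULL,
                          flags = "degenerate-constant"),
                     class = "normality_report"))
  }
  xs <- sort(x)
  n <- length(xs)
  theo <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  x_sw <- xs
  if (n > 5000) {
    x_sw <- xs[round(seq(1, n, length.out = 5000))]
    flags <- c(flags, "shapiro-thinned")
  }
  sw <- stats::shapiro.test(x_sw)
  h <- graphics::hist(x, plot = FALSE)
  structure(list(n = n, shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value,
                 qq_cor = stats::cor(xs, theo),
                 hist = list(breaks = h$breaks, counts = h$counts),
                 qq = list(theoretical = theo, sample = xs),
                 flags = flags),
            class = "normality_report")
}

#' Box-Cox profile maximum-likelihood lambda on a grid
#' @keywords internal
boxcox_lambda <- function(x, grid = seq(-5, 5, by = 0.01)) {
  stopifnot(all(x > 0))
  n <- length(x)
  slog <- sum(log(x))
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
    -n / 2 * log(stats::var(y) * (n - 1) / n) + (l - 1) * slog
  }, 0)
  grid[which.max(ll)]
}

#' Transform a trait toward normality
#'
#' Methods: `none`; `boxcox` (profile-ML lambda on a grid over \[-5, 5\] in
#' steps of 0.01; requires strictly positive values, so remove zeros first);
#' `rbinv` (rank-based inverse normal using Blom plotting positions
#' (r - 3/8)/(n + 1/4); ties share averaged ranks). Optionally removes
#' zeros and/or outliers beyond `outlier_k` x IQR from the quartiles before
#' transforming; removed entries become NA in the output so positions are
#' preserved.
#'
#' @param values numeric vector.
#' @param method one of "none", "boxcox", "rbinv".
#' @param remove_zeros drop zeros before transforming.
#' @param outlier_k IQR multiplier for outlier removal (NULL = keep all).
#' @return list with `values` (same length, NA where removed/missing) and
#'   `provenance` (method, lambda, counts of removed zeros/outliers).
#' @export
transform_trait <- function(values, method = c("none", "boxcox", "rbinv"),
                            remove_zeros = FALSE, outlier_k = NULL) {
  method <- match.arg(method)
  x <- values
  n_zero <- 0L; n_out <- 0L
  if (remove_zeros) {
    z <- !is.na(x) & x == 0
    n_zero <- sum(z)
    x[z] <- NA
  }
  if (!is.null(outlier_k)) {
    qs <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)
    iqr <- qs[2] - qs[1]
    out <- !is.na(x) & (x < qs[1] - outlier_k * iqr |
                          x > qs[2] + outlier_k * iqr)
    n_out <- sum(out)
    x[out] <- NA
  }
  ok <- !is.na(x)
  lambda <- NA_real_
  if (method == "boxcox") {
    if (any(x[ok] <= 0))
      stop("Box-Cox requires strictly positive values; remove zeros first")
    lambda <- boxcox_lambda(x[ok])
    y <- x
    y[ok] <- if (abs(lambda) < 1e-12) log(x[ok]) else (x[ok]^lambda - 1) / lambda
  } else if (method == "rbinv") {
    r <- rank(x[ok], ties.method = "average")
    y <- x
    y[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  } else y <- x
  list(values = y,
       provenance = list(method = method, lambda = lambda,
                         zeros_removed = n_zero, outliers_removed = n_out,
                         flags = if (method == "rbinv" &&
                                     anyDuplicated(x[ok])) "ties" else
                           character(0)))
}

#' Binarize a trait
#'
#' Default rule codes rooting presence/absence: 1 if the value is positive,
#' 0 otherwise. `median_split` codes above-median as 1. An all-0 or all-1
#' result is flagged as uninformative for association.
#'
#' @param values numeric vector.
#' @param rule "zero_vs_positive" or "median_split".
#' @return list with `values` (0/1 with NAs preserved) and `flags`.
#' @export
binarize_trait <- function(values, rule = c("zero_vs_positive",
                                            "median_split")) {
  rule <- match.arg(rule)
  ok <- !is.na(values)
  y <- rep(NA_real_, length(values))
  if (rule == "zero_vs_positive") {
    y[ok] <- as.numeric(values[ok] > 0)
  } else {
    med <- stats::median(values[ok])
    y[ok] <- as.numeric(values[ok] > med)
  }
  flags <- character(0)
  if (all(y[ok] == 1) || all(y[ok] == 0))
    flags <- "uninformative-binarization"
  list(values = y, flags = flags)
}

#' Choose the transformation track for association scans
#'
#' Encodes the pipeline's default policy: the kernel-association track uses
#' untransformed values; the mixed-model track uses Box-Cox (after zero
#' removal when needed) unless the transformed values still fail normality
#' (Shapiro-Wilk p < `sw_cut`), in which case the rank-based inverse normal
#' is used; PC traits always run under both Box-Cox and rank-based inverse
#' normal.
#'
#' @param values trait values.
#' @param is_pc whether this is a PC trait.
#' @param sw_cut Shapiro-Wilk cut for accepting the Box-Cox track.
#' @return named list of transformed tracks with provenance.
#' @export
transformation_tracks <- function(values, is_pc = FALSE, sw_cut = 0.01) {
  tracks <- list(untransformed = list(values = values,
                                      provenance = list(method = "none")))
  pos <- values; pos[!is.na(pos) & pos <= 0] <- NA
  shift <- if (all(is.na(pos)) || is_pc) TRUE else FALSE
  bc_in <- if (shift) values - min(values, na.rm = TRUE) +
    1e-6 * max(abs(values), na.rm = TRUE) + 1e-12 else values
  bc <- tryCatch(
    transform_trait(bc_in, "boxcox", remove_zeros = !shift),
    error = function(e) NULL)
  rb <- transform_trait(values, "rbinv")
  if (is_pc) {
    tracks$boxcox <- bc
    tracks$rbinv <- rb
  } else {
    use_bc <- !is.null(bc) &&
      isTRUE(assess_normality(bc$values)$shapiro_p >= sw_cut)
    tracks$normalized <- if (use_bc) bc else rb
  }
  tracks
}
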