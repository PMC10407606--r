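# Multiple-testing thresholds, QTL-peak extraction with the 30-kb rule, and
# nearest-gene annotation with the 5-kb rule and location classes.

#' Multiple-testing threshold flags
#'
#' Computes the conservative Bonferroni cut (alpha_bonf / n_tests_snp), the
#' ART-Bonferroni cut (alpha_bonf / n_tests_art) and Benjamini-Hochberg FDR
#' flags (step-up on the supplied p-vector at alpha_fdr). Every result is
#' flagged for each applicable criterion; ART results are judged against the
#' ART-Bonferroni cut, all others against the conservative cut.
#'
#' @param p numeric p-values (NA allowed, never flagged).
#' @param n_tests_snp number of single-SNP (or SKAT-window) tests behind the
#'   scan.
#' @param n_tests_art number of 1-kb ART windows (NULL if ART not used).
#' @param alpha_bonf family-wise alpha (default 0.05).
#' @param alpha_fdr FDR level (default 0.10).
#' @param is_art logical vector marking ART results (default all FALSE).
#' @return data.frame of flags (bonferroni, fdr, art_bonferroni) with
#'   attribute `cuts` = list(bonferroni, art_bonferroni).
#' @export
significance_thresholds <- function(p, n_tests_snp, n_tests_art = NULL,
                                    alpha_bonf = 0.05, alpha_fdr = 0.10,
                                    is_art = rep(FALSE, length(p))) {
  stopifnot(n_tests_snp >= 1)
  cut_snp <- alpha_bonf / n_tests_snp
  cut_art <- if (!is.null(n_tests_art)) alpha_bonf / n_tests_art else NA_real_
  bonf <- !is_art & !is.na(p) & p <= cut_snp
  artb <- is_art & !is.na(p) & !is.na(cut_art) & p <= cut_art
  fdr <- !is.na(p) & stats::p.adjust(p, method = "BH") <= alpha_fdr
  out <- data.frame(bonferroni = bonf, fdr = fdr, art_bonferroni = artb)
  attr(out, "cuts") <- list(bonferroni = cut_snp, art_bonferroni = cut_art)
  out
}

#' Call QTL peaks with the 30-kb rule
#'
#' A result is a QTL peak iff no other result of the same (trait,
#' transform, method) group on the same chromosome within `radius` bp has a
#' lower p-value (ties broken by lower position), i.e. it is the locally
#' most significant signal of a peak on the Manhattan plot.
#'
#' @param results data.frame with chrom, pos (anchor: SNP position or window
#'   center), p, and optional trait/transform/method columns defining
#'   groups.
#' @param radius exclusion radius in bp (default 30 kb).
#' @return the peak rows of `results`, ordered by group and p.
#' @export
call_peaks <- function(results, radius = 30000) {
  stopifnot(all(c("chrom", "pos", "p") %in% names(results)))
  gcols <- intersect(c("trait", "transform", "method"), names(results))
  key <- if (length(gcols))
    do.call(paste, c(results[gcols], sep = "\r")) else rep("all", nrow(results))
  res <- results[!is.na(results$p), , drop = FALSE]
  key <- key[!is.na(results$p)]
  picked <- logical(nrow(res))
  for (g in unique(key)) {
    for (ch in unique(res$chrom[key == g])) {
      ix <- which(key == g & res$chrom == ch)
      ix <- ix[order(res$pos[ix])]
      pos <- res$pos[ix]; p <- res$p[ix]
      for (a in seq_along(ix)) {
        nb <- which(pos >= pos[a] - radius & pos <= pos[a] + radius)
        nb <- nb[nb != a]
        beaten <- any(p[nb] < p[a] |
                        (p[nb] == p[a] & pos[nb] < pos[a]))
        picked[ix[a]] <- !beaten
      }
    }
  }
  out <- res[picked, , drop = FALSE]
  out[order(key[picked], out$p, out$pos), , drop = FALSE]
}

#' Annotate peaks with the nearest gene
#'
#' The anchor is the SNP position for single-variant methods or the window
#' center for window methods (the caller supplies it as `pos`). Distance is
#' measured to the nearest gene boundary: 0 when the anchor lies inside the
#' gene (class `exonic` if inside an annotated exon, else
#' `intragenic_nonexonic`); otherwise the class is `five_prime` when the
#' anchor is upstream of the gene respecting strand and `three_prime` when
#' downstream, with a flag when the distance is within `near` bp.
#'
#' @param peaks data.frame with chrom and pos.
#' @param genes a `gene_models` object from [read_gene_models()] or
#'   [simulate_gene_models()].
#' @param near proximity rule in bp (default 5 kb).
#' @return `peaks` with nearest_gene, distance, location_class, within_near
#'   columns appended.
#' @export
annotate_peaks <- function(peaks, genes, near = 5000) {
  n <- nrow(peaks)
  out <- peaks
  out$nearest_gene <- NA_character_
  out$distance <- NA_real_
  out$location_class <- NA_character_
  out$within_near <- NA
  if (!nrow(genes$genes)) {
    out$location_class <- "unassigned"
    return(out)
  }
  g <- genes$genes
  gene_gr <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$start, g$end))
  anchor_gr <- GenomicRanges::GRanges(peaks$chrom,
                                      IRanges::IRanges(peaks$pos, peaks$pos))
  hit <- GenomicRanges::nearest(anchor_gr, gene_gr, select = "arbitrary")
  ov <- GenomicRanges::findOverlaps(anchor_gr, gene_gr, select = "first")
  for (i in seq_len(n)) {
    j <- if (!is.na(ov[i])) ov[i] else hit[i]
    if (is.na(j)) { out$location_class[i] <- "unassigned"; next }
    pos <- peaks$pos[i]
    d <- max(0, g$start[j] - pos, pos - g$end[j])
    out$nearest_gene[i] <- g$gene_id[j]
    out$distance[i] <- d
    out$within_near[i] <- d <= near
    if (d == 0) {
      ex <- genes$exons[genes$exons$gene_id == g$gene_id[j], , drop = FALSE]
      inside_exon <- any(pos >= ex$start & pos <= ex$end)
      out$location_class[i] <- if (inside_exon) "exonic" else
        "intragenic_nonexonic"
    } else {
      upstream <- if (g$strand[j] == "+") pos < g$start[j] else pos > g$end[j]
      out$location_class[i] <- if (upstream) "five_prime" else "three_prime"
    }
  }
  out
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features and their exons (exon Parent resolved through mRNA
#' features where needed).
#'
#' @param path GFF3 file.
#' @return object of class `gene_models`: list of `genes` (gene_id, chrom,
#'   strand, start, end) and `exons` (gene_id, start, end), genes sorted by
#'   chromosome and start.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  gene_ix <- which(type == "gene")
  genes <- data.frame(
    gene_id = ids[gene_ix],
    chrom = as.character(GenomicRanges::seqnames(gr))[gene_ix],
    strand = as.character(GenomicRanges::strand(gr))[gene_ix],
    start = GenomicRanges::start(gr)[gene_ix],
    end = GenomicRanges::end(gr)[gene_ix])
  parent_of <- function(i) {
    p <- meta$Parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }
  id2gene <- stats::setNames(genes$gene_id, genes$gene_id)
  mrna_ix <- which(type %in% c("mRNA", "transcript"))
  for (i in mrna_ix) {
    p <- parent_of(i)
    if (!is.na(p) && p %in% names(id2gene)) id2gene[ids[i]] <- id2gene[p]
  }
  exon_ix <- which(type == "exon")
  exons <- data.frame(
    gene_id = vapply(exon_ix, function(i) {
      p <- parent_of(i)
      if (!is.na(p) && p %in% names(id2gene)) unname(id2gene[p])
      else NA_character_
    }, ""),
    start = GenomicRanges::start(gr)[exon_ix],
    end = GenomicRanges::end(gr)[exon_ix])
  exons <- exons[!is.na(exons$gene_id), , drop = FALSE]
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Simulate non-overlapping gene models
#'
#' Synthetic annotation for pipeline tests: genes of 1-5 kb with 1-3 exons,
#' random strand, separated by at least 200 bp.
#'
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param genome_bp genome length to spread genes over.
#' @param seed integer seed.
#' @return a `gene_models` object.
#' @export
simulate_gene_models <- function(n_genes, chrom = "Chr01", genome_bp = 5e5,
                                 seed = 1) {
  set.seed(as.integer(seed))
  lens <- round(stats::runif(n_genes, 1000, 5000))
  gaps <- round(stats::runif(n_genes, 200, max(300,
    (genome_bp - sum(lens)) / max(1, n_genes) * 2)))
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n_genes]))
  ends <- starts + lens - 1
  keep <- ends <= genome_bp
  genes <- data.frame(gene_id = sprintf("GENE%03d", seq_len(n_genes))[keep],
                      chrom = chrom, strand = sample(c("+", "-"), sum(keep),
                                                     replace = TRUE),
                      start = starts[keep], end = ends[keep])
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    ne <- sample(1:3, 1)
    brk <- sort(stats::runif(2 * ne, genes$start[i], genes$end[i]))
    data.frame(gene_id = genes$gene_id[i],
               start = round(brk[seq(1, 2 * ne, 2)]),
               end = round(brk[seq(2, 2 * ne, 2)]))
  }))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models to GFF3
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  g <- genes$genes; e <- genes$exons
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand, type = "gene",
                                 ID = g$gene_id)
  strand_of <- stats::setNames(g$strand, g$gene_id)
  chrom_of <- stats::setNames(g$chrom, g$gene_id)
  gr_e <- GenomicRanges::GRanges(chrom_of[e$gene_id],
                                 IRanges::IRanges(e$start, e$end),
                                 strand = strand_of[e$gene_id],
                                 type = "exon",
                                 ID = sprintf("%s.exon%d", e$gene_id,
                                              seq_len(nrow(e))),
                                 Parent = e$gene_id)
  rtracklayer::export(c(gr_g, gr_e), path, format = "gff3")
  invisible(path)
}
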