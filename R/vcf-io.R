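# VCF read/write for genotype matrices (GT-based dosages, "./." missing),
# via vcfR.

#' Write a genotype matrix to VCF
#'
#' Dosages 0/1/2 become GT fields 0/0, 0/1, 1/1; missing becomes "./.".
#'
#' @param G a `genotype_matrix`.
#' @param path output path; written gzipped if it ends in `.gz`.
#' @return the path, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gtm <- matrix("./.", ncol(G$G), nrow(G$G))
  ok <- !is.na(t(G$G))
  gtm[ok] <- code[as.character(t(G$G)[ok])]
  colnames(gtm) <- G$samples
  gt <- cbind(FORMAT = "GT", gtm)
  obj <- methods::new("vcfR", meta = c("##fileformat=VCFv4.2",
                                       "##source=rootgwas"),
                      fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(obj, file = path)
  } else {
    tmp <- paste0(path, ".gz")
    vcfR::write.vcf(obj, file = tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Biallelic SNPs only; GT fields are converted to dosages with "./." (or any
#' GT containing ".") as missing.
#'
#' @param path VCF path (plain or gzipped).
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  obj <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(obj)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  G <- t(dos)
  fix <- vcfR::getFIX(obj)
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), sprintf("%s_%s", fix[, "CHROM"], fix[, "POS"]),
                fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    maf = ifelse(is.nan(maf), NA_real_, maf),
    missing_frac = colMeans(is.na(G)))
  structure(list(G = G, variants = variants, samples = colnames(gt),
                 subpop = rep(1L, ncol(gt))),
            class = "genotype_matrix")
}
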