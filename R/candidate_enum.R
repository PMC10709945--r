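#' Minor allele frequency from additive dosages
#'
#' @param dosages numeric vector of 0/1/2 dosages (NA allowed).
#' @return `min(f, 1 - f)` where `f` is the alt-allele frequency over
#'   non-missing diploid genotypes.
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Fill per-variant MAF and drop rare variants
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_cut strict lower MAF bound (variants kept iff `maf > maf_cut`).
#' @return filtered [genotype_matrix()] with `variants$maf` filled.
#' @export
filter_by_maf <- function(genotypes, maf_cut = 0.05) {
  maf <- apply(genotypes$dosages, 2, compute_maf)
  genotypes$variants$maf <- maf
  keep <- maf > maf_cut
  genotype_matrix(genotypes$samples,
                  genotypes$variants[keep, , drop = FALSE],
                  genotypes$dosages[, keep, drop = FALSE])
}

#' Greedy LD pruning by squared dosage correlation
#'
#' Variants are scanned left to right in (chrom, pos) order; a variant is
#' removed iff its squared Pearson correlation (complete cases) with any
#' already-retained variant within `window_bp` upstream reaches `r2_cut`.
#' Deterministic for a fixed input order.
#'
#' @param genotypes a [genotype_matrix()] (variants need not be presorted).
#' @param r2_cut squared-correlation threshold (removal when r^2 >= cut).
#' @param window_bp physical window in base pairs.
#' @return pruned [genotype_matrix()].
#' @export
ld_prune <- function(genotypes, r2_cut = 0.8, window_bp = 1e6) {
  v <- genotypes$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  dos <- genotypes$dosages[, ord, drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(v))) {
    prev <- kept[v$chrom[kept] == v$chrom[i] &
                   v$pos[i] - v$pos[kept] <= window_bp]
    drop <- FALSE
    for (k in prev) {
      ok <- !is.na(dos[, i]) & !is.na(dos[, k])
      if (sum(ok) < 3) next
      if (stats::sd(dos[ok, i]) == 0 || stats::sd(dos[ok, k]) == 0) next
      r2 <- stats::cor(dos[ok, i], dos[ok, k])^2
      if (!is.na(r2) && r2 >= r2_cut) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  genotype_matrix(genotypes$samples, v[kept, , drop = FALSE],
                  dos[, kept, drop = FALSE])
}

#' Keep variants falling inside peak regions
#'
#' A 1-based variant position p lies in a 0-based half-open peak \[s, e)
#' iff s < p <= e.
#'
#' @param genotypes a [genotype_matrix()].
#' @param peaks interval data.frame (`chrom`, `start`, `end`).
#' @return filtered [genotype_matrix()].
#' @export
intersect_variants_with_peaks <- function(genotypes, peaks) {
  v <- genotypes$variants
  keep <- vapply(seq_len(nrow(v)), function(i) {
    p <- peaks[peaks$chrom == v$chrom[i], , drop = FALSE]
    any(p$start < v$pos[i] & v$pos[i] <= p$end)
  }, logical(1))
  genotype_matrix(genotypes$samples, v[keep, , drop = FALSE],
                  genotypes$dosages[, keep, drop = FALSE])
}

#' Keep variably methylated CpG sites
#'
#' A site is retained iff its mean beta lies in `mean_range` (inclusive),
#' its IQR exceeds `min_iqr`, and (when supplied) it belongs to
#' `eligible_sites` — typically the CpGs of the representative CpG-CTCF
#' pairs from the occupancy screen.
#'
#' @param methylation a [feature_matrix()] of kind `"methylation"`.
#' @param mean_range length-2 inclusive range for the mean beta.
#' @param min_iqr strict lower bound on the beta IQR.
#' @param eligible_sites optional character vector of `cpg_id`s.
#' @return filtered [feature_matrix()].
#' @export
filter_variable_cpgs <- function(methylation, mean_range = c(0.25, 0.75),
                                 min_iqr = 0.1, eligible_sites = NULL) {
  m <- colMeans(methylation$values, na.rm = TRUE)
  iqr <- apply(methylation$values, 2, stats::IQR, na.rm = TRUE)
  keep <- m >= mean_range[1] & m <= mean_range[2] & iqr > min_iqr
  if (!is.null(eligible_sites))
    keep <- keep & methylation$features$cpg_id %in% eligible_sites
  feature_matrix(methylation$samples,
                 methylation$features[keep, , drop = FALSE],
                 methylation$values[, keep, drop = FALSE],
                 kind = "methylation",
                 coverage = if (!is.null(methylation$coverage))
                   methylation$coverage[, keep, drop = FALSE])
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their average ranks. The default
#' offset is `(rank - 0.5)/n` (symmetric, finite); `"blom"` uses
#' `(rank - 3/8)/(n + 1/4)`.
#'
#' @param x numeric vector (NA preserved).
#' @param offset `"half"` or `"blom"`.
#' @return transformed vector.
#' @export
rank_inverse_normal <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  q <- if (offset == "half") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
  out[ok] <- stats::qnorm(q)
  out
}

#' Filter lowly expressed genes and inverse-normal transform expression
#'
#' Restricts to the allowed biotypes with median FPKM at or above
#' `min_median_fpkm`, then replaces each gene's values by
#' [rank_inverse_normal()] quantiles and flags the matrix as transformed.
#'
#' @param expression an untransformed [feature_matrix()] of kind
#'   `"expression"`.
#' @param min_median_fpkm genes with median FPKM below this are removed.
#' @param biotypes biotypes retained.
#' @param offset passed to [rank_inverse_normal()].
#' @return transformed [feature_matrix()].
#' @export
filter_and_transform_expression <- function(expression, min_median_fpkm = 1,
                                            biotypes = c("protein_coding",
                                                         "lincRNA"),
                                            offset = "half") {
  if (isTRUE(expression$transformed))
    stop("expression matrix is already inverse-normal transformed")
  med <- apply(expression$values, 2, stats::median, na.rm = TRUE)
  keep <- expression$features$biotype %in% biotypes & med >= min_median_fpkm
  vals <- expression$values[, keep, drop = FALSE]
  vals <- apply(vals, 2, rank_inverse_normal, offset = offset)
  if (is.null(dim(vals)))
    vals <- matrix(vals, nrow = length(expression$samples))
  feature_matrix(expression$samples,
                 expression$features[keep, , drop = FALSE],
                 vals, kind = "expression", transformed = TRUE)
}

#' Enumerate candidate SNP-CpG-gene triples
#'
#' Emits every same-chromosome combination with `|snp.pos - gene.tss| <=
#' window_bp` (inclusive) and the CpG strictly between the SNP position and
#' the TSS, sorted by (chrom, snp_pos, cpg_pos, tss). Inputs are expected to
#' be already filtered (MAF, LD, peaks, variable CpGs, expressed genes).
#'
#' @param genotypes a [genotype_matrix()].
#' @param methylation a [feature_matrix()] of kind `"methylation"`.
#' @param expression a [feature_matrix()] of kind `"expression"`.
#' @param window_bp maximum SNP-TSS distance.
#' @return data.frame with one row per triple: `chrom`, `snp_id`, `snp_pos`,
#'   `cpg_id`, `cpg_pos`, `gene_id`, `tss`.
#' @export
enumerate_triples <- function(genotypes, methylation, expression,
                              window_bp = 1e6) {
  snps <- genotypes$variants
  cpgs <- methylation$features
  genes <- expression$features
  out <- list()
  for (chr in unique(snps$chrom)) {
    s <- snps[snps$chrom == chr, , drop = FALSE]
    cg <- cpgs[cpgs$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(s) || !nrow(cg) || !nrow(g)) next
    for (i in seq_len(nrow(s))) {
      near <- which(abs(s$pos[i] - g$tss) <= window_bp)
      for (j in near) {
        lo <- min(s$pos[i], g$tss[j]); hi <- max(s$pos[i], g$tss[j])
        between <- which(cg$pos > lo & cg$pos < hi)
        if (!length(between)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr,
          snp_id = s$rsid[i], snp_pos = s$pos[i],
          cpg_id = cg$cpg_id[between], cpg_pos = cg$pos[between],
          gene_id = g$gene_id[j], tss = g$tss[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), snp_id = character(),
                      snp_pos = integer(), cpg_id = character(),
                      cpg_pos = integer(), gene_id = character(),
                      tss = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$snp_pos, res$cpg_pos, res$tss), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
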