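#' Filter CpG sites and CTCF binding sites for the occupancy screen
#'
#' A CpG is eligible when at least `min_samples` screen samples cover it with
#' more than `min_coverage` bisulfite reads and the IQR of its beta values
#' over those qualifying samples exceeds `min_beta_iqr`. A CTCF site is
#' eligible when the IQR of its binding intensities exceeds `min_ctcf_iqr`.
#'
#' @param methylation a [feature_matrix()] of kind `"methylation"` carrying a
#'   coverage matrix (screen samples are cell lines / tissues).
#' @param ctcf_sites data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, plus one intensity column per screen sample, or a
#'   list with elements `sites` (intervals) and `intensities` (sites x
#'   samples matrix).
#' @param min_samples minimum number of qualifying screen samples per CpG.
#' @param min_coverage read-coverage threshold a sample must exceed to qualify.
#' @param min_beta_iqr minimum beta IQR over qualifying samples.
#' @param min_ctcf_iqr minimum CTCF intensity IQR.
#' @return list with `cpg_keep` (logical over CpG sites) and `ctcf_keep`
#'   (logical over CTCF sites).
#' @export
filter_screen_features <- function(methylation, ctcf_sites,
                                   min_samples = 10, min_coverage = 20,
                                   min_beta_iqr = 0.1, min_ctcf_iqr = 1.0) {
  if (is.null(methylation$coverage))
    stop("screen filtering requires a coverage matrix")
  betas <- methylation$values
  cov <- methylation$coverage
  cpg_keep <- vapply(seq_len(ncol(betas)), function(j) {
    ok <- !is.na(cov[, j]) & cov[, j] > min_coverage & !is.na(betas[, j])
    sum(ok) >= min_samples &&
      stats::IQR(betas[ok, j]) > min_beta_iqr
  }, logical(1))
  intens <- .ctcf_intensity_matrix(ctcf_sites)
  ctcf_keep <- apply(intens, 1, function(v)
    stats::IQR(v, na.rm = TRUE) > min_ctcf_iqr)
  list(cpg_keep = cpg_keep, ctcf_keep = unname(ctcf_keep))
}

.ctcf_intensity_matrix <- function(ctcf_sites) {
  if (is.list(ctcf_sites) && !is.data.frame(ctcf_sites))
    return(as.matrix(ctcf_sites$intensities))
  meta <- c("chrom", "start", "end", "name")
  as.matrix(ctcf_sites[, setdiff(names(ctcf_sites), meta), drop = FALSE])
}

#' Spearman rank correlation with t-approximated p-value
#'
#' Computes the Pearson correlation of average-ranked values on pairwise
#' complete observations, with a two-sided p-value from the t reference with
#' n - 2 degrees of freedom (appropriate for the tied, moderate-n screen).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `scc`, `pvalue` and `n` (complete pairs). A constant
#'   vector yields `NA` with a warning.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(scc = NA_real_, pvalue = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(scc = r, pvalue = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (order-preserving, capped at 1).
#'
#' @param pvalues numeric vector with entries in (0, 1].
#' @return vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Correlate eligible CpGs with their CTCF binding sites
#'
#' Runs [spearman()] for every CpG lying inside an eligible CTCF site (1-based
#' CpG position p is inside 0-based \[start, end) iff start < p <= end) and
#' BH-adjusts the p-values jointly.
#'
#' @param methylation screen methylation [feature_matrix()].
#' @param ctcf_sites CTCF site table (see [filter_screen_features()]).
#' @param cpg_keep,ctcf_keep logical eligibility vectors from
#'   [filter_screen_features()]; default keeps everything.
#' @return data.frame of pair records: `cpg_id`, `cpg_chrom`, `cpg_pos`,
#'   `ctcf_name`, `scc`, `pvalue`, `padj`, `sign`, `dist_to_center`.
#' @export
correlate_cpg_ctcf <- function(methylation, ctcf_sites,
                               cpg_keep = NULL, ctcf_keep = NULL) {
  sites <- if (is.data.frame(ctcf_sites)) ctcf_sites else ctcf_sites$sites
  intens <- .ctcf_intensity_matrix(ctcf_sites)
  feats <- methylation$features
  if (is.null(cpg_keep)) cpg_keep <- rep(TRUE, nrow(feats))
  if (is.null(ctcf_keep)) ctcf_keep <- rep(TRUE, nrow(sites))
  rows <- list()
  for (i in which(ctcf_keep)) {
    in_site <- cpg_keep & feats$chrom == sites$chrom[i] &
      feats$pos > sites$start[i] & feats$pos <= sites$end[i]
    center <- floor((sites$start[i] + sites$end[i]) / 2) + 1L
    for (j in which(in_site)) {
      sp <- suppressWarnings(spearman(methylation$values[, j], intens[i, ]))
      if (is.na(sp$scc)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = feats$cpg_id[j], cpg_chrom = feats$chrom[j],
        cpg_pos = feats$pos[j],
        ctcf_name = sites$name[i],
        scc = sp$scc, pvalue = sp$pvalue,
        dist_to_center = feats$pos[j] - center,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cpg_id = character(), cpg_chrom = character(),
                      cpg_pos = integer(), ctcf_name = character(),
                      scc = numeric(), pvalue = numeric(),
                      padj = numeric(), sign = character(),
                      dist_to_center = integer()))
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(pmax(out$pvalue, .Machine$double.xmin))
  out$sign <- ifelse(out$scc < 0, "neg", "pos")
  out[, c("cpg_id", "cpg_chrom", "cpg_pos", "ctcf_name", "scc",
          "pvalue", "padj", "sign", "dist_to_center")]
}

#' Select one representative CpG-CTCF pair per binding site
#'
#' Keeps significant pairs (`|scc| > scc_cut`, `padj < padj_cut`), removes
#' binding sites carrying significant pairs of both correlation signs, then
#' returns the most significant pair per remaining site (smallest `padj`;
#' ties broken by largest `|scc|`, then leftmost CpG).
#'
#' @param pairs data.frame from [correlate_cpg_ctcf()].
#' @param scc_cut absolute correlation threshold.
#' @param padj_cut adjusted p-value threshold.
#' @return data.frame, at most one row per CTCF site.
#' @export
select_representative_pairs <- function(pairs, scc_cut = 0.5,
                                        padj_cut = 0.05) {
  sig <- pairs[abs(pairs$scc) > scc_cut & pairs$padj < padj_cut, ,
               drop = FALSE]
  if (!nrow(sig)) return(sig)
  both <- tapply(sig$sign, sig$ctcf_name,
                 function(s) length(unique(s)) > 1)
  drop_sites <- names(both)[both]
  sig <- sig[!sig$ctcf_name %in% drop_sites, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  picked <- lapply(split(sig, sig$ctcf_name), function(d) {
    d <- d[order(d$padj, -abs(d$scc), d$cpg_pos), , drop = FALSE]
    d[1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(out$cpg_chrom, out$cpg_pos), , drop = FALSE]
}
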