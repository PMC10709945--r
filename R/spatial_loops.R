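#' Signed strandless distance between two genomic points
#'
#' `a_pos - b_pos`: negative iff the former element lies to the left of the
#' latter. Gene positions should already be reduced to their strand-aware
#' TSS.
#'
#' @param a_pos,b_pos 1-based coordinates.
#' @param a_chrom,b_chrom optional chromosome names; a mismatch is an error.
#' @return integer distance in bp.
#' @export
signed_distance <- function(a_pos, b_pos, a_chrom = NULL, b_chrom = NULL) {
  if (!is.null(a_chrom) && !is.null(b_chrom) && any(a_chrom != b_chrom))
    stop("signed distance is undefined across chromosomes")
  a_pos - b_pos
}

#' Keep chromatin loops with sufficient PET support
#'
#' @param loops data.frame from [load_loops()].
#' @param min_pet inclusive lower bound on the PET count.
#' @return filtered loop data.frame.
#' @export
filter_strong_loops <- function(loops, min_pet = 15) {
  loops[loops$pet >= min_pet, , drop = FALSE]
}

#' Classify a triple's locus against CTCF loops
#'
#' The locus is the closed 1-based interval spanning the SNP position, CpG
#' position and gene TSS. A loop "overlaps" the locus when its full span
#' (anchor1 start to anchor2 end) intersects it. Anchor membership means the
#' CpG position falls inside an anchor (0-based \[s, e): s < pos <= e).
#' With exactly one anchor loop the relation is `"within"` iff both of that
#' loop's anchors lie entirely inside the locus, else `"cross"`; no anchor
#' loop gives `"none"` and two or more give `"multi_anchor"`.
#'
#' @param triple list or one-row data.frame with `chrom`, `snp_pos`,
#'   `cpg_pos`, `tss`.
#' @param loops pre-filtered loop data.frame (see [filter_strong_loops()]).
#' @return list with `n_loops_overlapping`, `anchor_loops` (names), and
#'   `relation` in `c("none", "within", "cross", "multi_anchor")`.
#' @export
classify_loop_relation <- function(triple, loops) {
  lo <- min(triple$snp_pos, triple$cpg_pos, triple$tss)
  hi <- max(triple$snp_pos, triple$cpg_pos, triple$tss)
  ll <- loops[loops$chrom == triple$chrom, , drop = FALSE]
  # loop span in 1-based closed coordinates: [start1 + 1, end2]
  span_olap <- (ll$start1 + 1) <= hi & ll$end2 >= lo
  cpg <- triple$cpg_pos
  in_a1 <- ll$start1 < cpg & cpg <= ll$end1
  in_a2 <- ll$start2 < cpg & cpg <= ll$end2
  anchor <- in_a1 | in_a2
  anchor_loops <- ll$name[anchor]
  relation <- if (sum(anchor) == 0) "none"
  else if (sum(anchor) >= 2) "multi_anchor"
  else {
    al <- ll[anchor, , drop = FALSE]
    both_inside <- (al$start1 + 1) >= lo && al$end1 <= hi &&
      (al$start2 + 1) >= lo && al$end2 <= hi
    if (both_inside) "within" else "cross"
  }
  list(n_loops_overlapping = sum(span_olap),
       anchor_loops = anchor_loops,
       relation = relation)
}

#' Spatial classification of stratified memo-eQTLs
#'
#' Adds pairwise signed distances and the loop relation to each row of a
#' stratification table.
#'
#' @param strat data.frame from [stratify_memo()] (needs `chrom`, `snp_pos`,
#'   `cpg_pos`, `tss`).
#' @param loops loop data.frame.
#' @param min_pet PET filter applied before classification.
#' @return input rows plus `dist_snp_gene`, `dist_snp_cpg`,
#'   `dist_cpg_gene`, `n_loops_overlapping`, `relation`.
#' @export
spatial_classify <- function(strat, loops, min_pet = 15) {
  loops <- filter_strong_loops(loops, min_pet = min_pet)
  res <- lapply(seq_len(nrow(strat)), function(i) {
    tr <- strat[i, , drop = FALSE]
    cl <- classify_loop_relation(tr, loops)
    cbind(tr, data.frame(
      dist_snp_gene = signed_distance(tr$snp_pos, tr$tss),
      dist_snp_cpg = signed_distance(tr$snp_pos, tr$cpg_pos),
      dist_cpg_gene = signed_distance(tr$cpg_pos, tr$tss),
      n_loops_overlapping = cl$n_loops_overlapping,
      relation = cl$relation, stringsAsFactors = FALSE))
  })
  if (!length(res))
    return(cbind(strat, data.frame(dist_snp_gene = integer(),
                                   dist_snp_cpg = integer(),
                                   dist_cpg_gene = integer(),
                                   n_loops_overlapping = integer(),
                                   relation = character())))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Chi-squared test of subgroup x loop-relation preference
#'
#' Pearson chi-squared test without continuity correction on a contingency
#' table of memo-eQTL subgroups against loop relations.
#'
#' @param table numeric count matrix with >= 2 rows and >= 2 columns and no
#'   all-zero row or column (collapse such categories first).
#' @return list with `chi2`, `df`, `p`.
#' @export
contingency_preference_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column: collapse categories first")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
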