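# Independent brute-force oracles, kept deliberately naive and separate from
# the package's own code paths.

# Spearman: explicit average ranking + textbook Pearson formula + t reference
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(scc = r, pvalue = 2 * pt(-abs(tstat), n - 2))
}

# BH: literal step-up on the sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Triple enumeration: naive triple-nested loop
oracle_enumerate <- function(snps, cpgs, genes, window) {
  rows <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(cpgs)))
    for (k in seq_len(nrow(genes))) {
      if (snps$chrom[i] != cpgs$chrom[j] ||
          snps$chrom[i] != genes$chrom[k]) next
      if (abs(snps$pos[i] - genes$tss[k]) > window) next
      lo <- min(snps$pos[i], genes$tss[k])
      hi <- max(snps$pos[i], genes$tss[k])
      if (!(cpgs$pos[j] > lo && cpgs$pos[j] < hi)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = snps$chrom[i], snp_id = snps$rsid[i], snp_pos = snps$pos[i],
        cpg_id = cpgs$cpg_id[j], cpg_pos = cpgs$pos[j],
        gene_id = genes$gene_id[k], tss = genes$tss[k],
        stringsAsFactors = FALSE)
    }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$snp_pos, out$cpg_pos, out$tss), ]
  rownames(out) <- NULL
  out
}

# Loop relation: literal interval arithmetic on one triple and one loop set
oracle_loop_relation <- function(triple, loops) {
  lo <- min(triple$snp_pos, triple$cpg_pos, triple$tss)
  hi <- max(triple$snp_pos, triple$cpg_pos, triple$tss)
  anchors <- character(0)
  n_olap <- 0L
  for (i in seq_len(nrow(loops))) {
    if (loops$chrom[i] != triple$chrom) next
    span_lo <- loops$start1[i] + 1; span_hi <- loops$end2[i]
    if (span_lo <= hi && span_hi >= lo) n_olap <- n_olap + 1L
    p <- triple$cpg_pos
    in1 <- loops$start1[i] < p && p <= loops$end1[i]
    in2 <- loops$start2[i] < p && p <= loops$end2[i]
    if (in1 || in2) anchors <- c(anchors, loops$name[i])
  }
  rel <- if (length(anchors) == 0) "none"
  else if (length(anchors) >= 2) "multi_anchor"
  else {
    l <- loops[loops$name == anchors, ]
    if (l$start1 + 1 >= lo && l$end1 <= hi &&
        l$start2 + 1 >= lo && l$end2 <= hi) "within" else "cross"
  }
  list(n_loops_overlapping = n_olap, relation = rel)
}

# Small fully in-memory cohort for io/mapping tests: 2 planted-free SNPs etc.
toy_cohort <- function(n = 40, seed = 11) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n))
  variants <- data.frame(chrom = "chr1", pos = c(1000L, 5000L),
                         rsid = c("rs1", "rs2"), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  dos <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  gt <- genotype_matrix(samples, variants, dos)
  cpgs <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "chr1",
                     pos = c(3000L, 7000L), stringsAsFactors = FALSE)
  betas <- matrix(runif(2 * n, 0.3, 0.7), n, 2)
  meth <- feature_matrix(samples, cpgs, betas, kind = "methylation")
  genes <- data.frame(gene_id = c("g1", "g2"), name = c("g1", "g2"),
                      chrom = "chr1", strand = c("+", "-"),
                      tss = c(9000L, 400L), biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  vals <- matrix(rexp(2 * n, 0.2), n, 2)
  expr <- feature_matrix(samples, genes, vals, kind = "expression")
  list(genotypes = gt, methylation = meth, expression = expr)
}
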