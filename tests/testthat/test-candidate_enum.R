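test_that("compute_maf counts alleles over non-missing genotypes", {
  expect_equal(compute_maf(c(0, 1, 2, 2)), 0.375)
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(0, 2, NA)), 0.5)
  expect_error(compute_maf(c(NA, NA)), "all dosages missing")
})

test_that("filter_by_maf is strict and records the frequency", {
  samples <- sprintf("s%d", 1:10)
  variants <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                         rsid = c("common", "rare"), ref = "A", alt = "G")
  dos <- cbind(rep(c(0, 1, 2), length.out = 10), c(1, rep(0, 9)))
  gt <- filter_by_maf(genotype_matrix(samples, variants, dos), 0.05)
  expect_equal(gt$variants$rsid, "common")
  expect_true(all(gt$variants$maf > 0.05))
})

test_that("ld_prune removes correlated variants greedily and leaves no high-LD pair", {
  n <- 60
  set.seed(21)
  # construct a correlation chain: A ~ B strongly, B ~ C strongly, A ~ C weak
  repeat {
    a <- rbinom(n, 2, 0.4)
    b <- a; flip <- sample(n, 4); b[flip] <- rbinom(4, 2, 0.4)
    c_ <- b; flip <- sample(n, 12); c_[flip] <- rbinom(12, 2, 0.4)
    r_ab <- cor(a, b)^2; r_bc <- cor(b, c_)^2; r_ac <- cor(a, c_)^2
    if (r_ab >= 0.8 && r_bc >= 0.8 && r_ac < 0.8) break
  }
  gt <- genotype_matrix(sprintf("s%02d", 1:n),
                        data.frame(chrom = "chr1",
                                   pos = c(1000L, 2000L, 3000L),
                                   rsid = c("A", "B", "C"),
                                   ref = "A", alt = "G"),
                        cbind(a, b, c_))
  pruned <- ld_prune(gt, r2_cut = 0.8, window_bp = 1e6)
  expect_equal(pruned$variants$rsid, c("A", "C"))

  # identical columns 1 kb apart -> second removed; far apart -> both kept
  gt2 <- genotype_matrix(sprintf("s%02d", 1:n),
                         data.frame(chrom = "chr1",
                                    pos = c(1000L, 2000L, 5e6L),
                                    rsid = c("v1", "v2", "v3"),
                                    ref = "A", alt = "G"),
                         cbind(a, a, a))
  pruned2 <- ld_prune(gt2)
  expect_equal(pruned2$variants$rsid, c("v1", "v3"))

  # post-condition: no retained pair within the window has r^2 >= cut
  set.seed(22)
  dos <- sapply(1:40, function(i) rbinom(n, 2, runif(1, 0.1, 0.5)))
  dos[, seq(2, 40, by = 7)] <- dos[, seq(1, 39, by = 7)]  # plant duplicates
  gtr <- genotype_matrix(sprintf("s%02d", 1:n),
                         data.frame(chrom = "chr1",
                                    pos = sort(sample.int(5e5, 40)),
                                    rsid = sprintf("v%02d", 1:40),
                                    ref = "A", alt = "G"), dos)
  pr <- ld_prune(gtr, r2_cut = 0.8, window_bp = 1e6)
  d <- pr$dosages
  if (ncol(d) > 1)
    for (i in 2:ncol(d)) for (j in 1:(i - 1))
      expect_lt(cor(d[, i], d[, j])^2, 0.8)
})

test_that("peak intersection uses the 1-based point in half-open interval rule", {
  samples <- sprintf("s%d", 1:4)
  variants <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                         pos = c(150L, 100L, 150L),
                         rsid = c("in", "boundary", "offchrom"),
                         ref = "A", alt = "G")
  gt <- genotype_matrix(samples, variants, matrix(1, 4, 3))
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  kept <- intersect_variants_with_peaks(gt, peaks)
  expect_equal(kept$variants$rsid, "in")
})

test_that("variable-CpG filter applies mean range, IQR and eligibility", {
  samples <- sprintf("s%d", 1:20)
  cpgs <- data.frame(cpg_id = c("keep", "highmean", "flat", "ineligible"),
                     chrom = "chr1", pos = c(1L, 2L, 3L, 4L) * 100L)
  set.seed(3)
  betas <- cbind(runif(20, 0.3, 0.7),
                 runif(20, 0.75, 0.95),
                 rep(0.5, 20) + seq(-0.01, 0.01, length.out = 20),
                 runif(20, 0.3, 0.7))
  meth <- feature_matrix(samples, cpgs, betas, "methylation")
  out <- filter_variable_cpgs(meth, eligible_sites = c("keep", "flat",
                                                       "highmean"))
  expect_equal(out$features$cpg_id, "keep")
})

test_that("inverse normal transform maps ranks to normal quantiles and ignores monotone distortion", {
  expect_equal(rank_inverse_normal(c(5, 1, 3)),
               qnorm(c(2.5, 0.5, 1.5) / 3))
  expect_equal(rank_inverse_normal(c(5, 1, 3)),
               c(0.9674, -0.9674, 0), tolerance = 1e-4)
  expect_equal(rank_inverse_normal(rep(2, 7)), rep(0, 7))
  set.seed(4)
  x <- rexp(50)
  expect_equal(rank_inverse_normal(exp(x) + 10), rank_inverse_normal(x))
})

test_that("expression filtering removes low-expressed and off-biotype genes, then transforms", {
  samples <- sprintf("s%d", 1:9)
  genes <- data.frame(gene_id = c("hi", "lo", "rib"),
                      name = c("hi", "lo", "rib"), chrom = "chr1",
                      strand = "+", tss = c(100L, 200L, 300L),
                      biotype = c("protein_coding", "lincRNA", "other"))
  vals <- cbind(rexp(9, 0.1) + 1, rep(0.4, 9), rexp(9, 0.1) + 1)
  expr <- feature_matrix(samples, genes, vals, "expression")
  tr <- filter_and_transform_expression(expr)
  expect_equal(tr$features$gene_id, "hi")
  expect_true(tr$transformed)
  expect_equal(mean(tr$values[, 1]), 0, tolerance = 1e-10)
  expect_error(filter_and_transform_expression(tr), "already")
})

test_that("enumerate_triples equals the brute-force oracle and honours window and betweenness", {
  snps <- data.frame(chrom = "chr1", pos = 100000L, rsid = "rs1",
                     ref = "A", alt = "G")
  cpgs <- data.frame(cpg_id = c("between", "outside"), chrom = "chr1",
                     pos = c(500000L, 950000L))
  genes <- data.frame(gene_id = c("near", "far"), name = c("near", "far"),
                      chrom = "chr1", strand = "+",
                      tss = c(900000L, 1400000L), biotype = "protein_coding")
  gt <- genotype_matrix("s1", snps, matrix(1, 1, 1))
  meth <- feature_matrix("s1", cpgs, matrix(0.5, 1, 2), "methylation")
  expr <- feature_matrix("s1", genes, matrix(1, 1, 2), "expression")
  tr <- enumerate_triples(gt, meth, expr)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$cpg_id, "between")   # 950000 not between; far gene > 1 Mbp
  expect_equal(tr$gene_id, "near")

  set.seed(31)
  for (rep in 1:10) {
    ns <- sample(3:8, 1); nc <- sample(3:8, 1); ng <- sample(3:8, 1)
    chrs <- c("chr1", "chr2")
    snps <- data.frame(chrom = sample(chrs, ns, TRUE),
                       pos = sample.int(3e6, ns),
                       rsid = sprintf("rs%d", 1:ns), ref = "A", alt = "G")
    cpgs <- data.frame(cpg_id = sprintf("cg%d", 1:nc),
                       chrom = sample(chrs, nc, TRUE),
                       pos = sample.int(3e6, nc))
    genes <- data.frame(gene_id = sprintf("g%d", 1:ng),
                        name = sprintf("g%d", 1:ng),
                        chrom = sample(chrs, ng, TRUE), strand = "+",
                        tss = sample.int(3e6, ng),
                        biotype = "protein_coding")
    gt <- genotype_matrix("s1", snps, matrix(1, 1, ns))
    meth <- feature_matrix("s1", cpgs, matrix(0.5, 1, nc), "methylation")
    expr <- feature_matrix("s1", genes, matrix(1, 1, ng), "expression")
    got <- enumerate_triples(gt, meth, expr, window_bp = 1e6)
    want <- oracle_enumerate(snps, cpgs, genes, 1e6)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got, want)
      # every emitted triple satisfies the type invariants
      expect_true(all(pmin(got$snp_pos, got$tss) < got$cpg_pos &
                        got$cpg_pos < pmax(got$snp_pos, got$tss)))
      expect_true(all(abs(got$snp_pos - got$tss) <= 1e6))
    }
  }
})
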