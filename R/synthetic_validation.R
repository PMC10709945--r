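#' Simulation design for synthetic memo-eQTL cohorts
#'
#' Bundles the generative parameters of the outcome model
#' `y = beta0 + beta1 SNP + beta2 meCpG + beta3 SNP x meCpG + e`,
#' `e ~ N(0, sigma^2)`, together with the cohort size, the Hardy-Weinberg
#' allele frequency and the methylation law. Methylation betas are drawn
#' from a Beta(`beta_shape1`, `beta_shape2`) distribution rescaled into
#' `beta_range`; the default Beta(0.5, 0.5) gives the switch-like bimodal
#' betas typical of variably methylated CpGs at CTCF sites.
#'
#' @param n sample count.
#' @param maf minor (alt) allele frequency in (0, 0.5].
#' @param beta_shape1,beta_shape2 Beta shape parameters for meCpG levels.
#' @param beta_range interval the betas are rescaled into.
#' @param beta0,beta1,beta2,beta3 linear coefficients of the outcome model.
#' @param sigma error standard deviation (> 0).
#' @param seed optional integer seed recorded in the design.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n = 128, maf = 0.3,
                              beta_shape1 = 0.5, beta_shape2 = 0.5,
                              beta_range = c(0.25, 0.75),
                              beta0 = 0, beta1 = 0.5, beta2 = 0.5,
                              beta3 = 0, sigma = 1, seed = NULL) {
  stopifnot(n >= 10, sigma > 0, maf > 0, maf <= 0.5,
            beta_range[1] < beta_range[2])
  structure(list(n = n, maf = maf, beta_shape1 = beta_shape1,
                 beta_shape2 = beta_shape2, beta_range = beta_range,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 beta3 = beta3, sigma = sigma, seed = seed),
            class = "simulation_design")
}

#' Draw Hardy-Weinberg genotype dosages
#' @param n number of samples.
#' @param maf alt-allele frequency.
#' @return integer vector of 0/1/2 dosages (Binomial(2, maf) per sample).
#' @export
simulate_genotypes <- function(n, maf) {
  stats::rbinom(n, 2, maf)
}

#' Draw methylation beta values under a design
#' @param n number of samples.
#' @param design a [simulation_design()].
#' @return numeric vector in `design$beta_range`.
#' @export
simulate_methylation <- function(n, design) {
  b <- stats::rbeta(n, design$beta_shape1, design$beta_shape2)
  design$beta_range[1] + b * diff(design$beta_range)
}

#' Generate an outcome vector from the moderated linear model
#'
#' `y = beta0 + beta1 SNP + beta2 meCpG + beta3 SNP x meCpG + e` with
#' i.i.d. Gaussian errors of standard deviation `design$sigma`.
#'
#' @param snp dosage vector.
#' @param mecpg beta-value vector of the same length.
#' @param design a [simulation_design()].
#' @return numeric outcome vector.
#' @export
simulate_outcome <- function(snp, mecpg, design) {
  stopifnot(length(snp) == length(mecpg))
  design$beta0 + design$beta1 * snp + design$beta2 * mecpg +
    design$beta3 * snp * mecpg +
    stats::rnorm(length(snp), 0, design$sigma)
}

#' Simulate independent SNP-CpG-gene combinations and map them
#'
#' For each combination draws fresh genotypes and methylation under the
#' design, generates the outcome with the requested interaction coefficient,
#' and runs [memo_test()]. The workhorse behind calibration, power and
#' method-comparison studies.
#'
#' @param n_combos number of combinations.
#' @param design a [simulation_design()] (its `beta3` is overridden by
#'   `beta3_values`).
#' @param beta3_values interaction coefficient per combination (recycled).
#' @param alpha significance level passed to [memo_test()].
#' @return data.frame with `beta3_true`, the [memo_test()] p-values,
#'   `b33`, `group` and `is_memo` per combination.
#' @export
simulate_and_map <- function(n_combos, design, beta3_values = design$beta3,
                             alpha = 0.05) {
  beta3_values <- rep_len(beta3_values, n_combos)
  rows <- vector("list", n_combos)
  for (i in seq_len(n_combos)) {
    d <- design
    d$beta3 <- beta3_values[i]
    s <- simulate_genotypes(d$n, d$maf)
    m <- simulate_methylation(d$n, d)
    y <- simulate_outcome(s, m, d)
    r <- memo_test(y, s, m, alpha = alpha)
    rows[[i]] <- data.frame(beta3_true = beta3_values[i], n = r$n,
                            p_m3_overall = r$p_m3_overall,
                            p_m3_vs_m2 = r$p_m3_vs_m2,
                            p_m3_vs_m1 = r$p_m3_vs_m1,
                            b33 = r$b33, group = r$group,
                            is_memo = r$is_memo,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Geometry of the synthetic cohort
#'
#' Controls how SNPs, CpGs and genes are laid out along the synthetic
#' chromosome: `n_planted` isolated blocks each carrying one
#' (SNP, CpG, gene) triple with a true interaction effect, plus
#' `null_blocks` blocks over which the remaining features are spread so
#' that each block contributes several admissible null triples. Blocks are
#' `block_span` apart — larger than the cis window, so triples never span
#' blocks.
#'
#' @param n_planted number of planted memo-eQTL blocks.
#' @param null_blocks number of null blocks.
#' @param block_span spacing between block origins (bp).
#' @param planted_beta1,planted_beta2 marginal SNP and meCpG coefficients of
#'   planted genes.
#' @param planted_beta3 absolute interaction coefficient of planted genes
#'   (sign alternates across blocks).
#' @param fpkm_scale multiplicative FPKM baseline (keeps median FPKM above
#'   the expression filter).
#' @return list of geometry parameters.
#' @export
cohort_geometry <- function(n_planted = 10, null_blocks = 5,
                            block_span = 3e6, planted_beta1 = 0.5,
                            planted_beta2 = 0.5, planted_beta3 = 1.5,
                            fpkm_scale = 10) {
  list(n_planted = n_planted, null_blocks = null_blocks,
       block_span = block_span, planted_beta1 = planted_beta1,
       planted_beta2 = planted_beta2, planted_beta3 = planted_beta3,
       fpkm_scale = fpkm_scale)
}

#' Simulate a full synthetic cohort with planted memo-eQTLs
#'
#' Generates aligned genotype, methylation and expression (FPKM) matrices on
#' one synthetic chromosome, ATAC-like peaks covering every SNP, CTCF-like
#' loops around the planted CpGs, and a truth table of the planted triples.
#' Planted genes follow the moderated outcome model with coefficients from
#' the geometry (interaction sign alternating); null genes are expression
#' noise. FPKM values are `fpkm_scale * exp(y)`, a monotone map, so the
#' rank-based inverse normal transform downstream recovers the latent
#' Gaussian outcome's ranks exactly.
#'
#' @param design a [simulation_design()] (cohort size, MAF, methylation law,
#'   error SD).
#' @param n_snps,n_cpgs,n_genes total feature counts (at least
#'   `geometry$n_planted` each).
#' @param geometry a [cohort_geometry()].
#' @param seed optional integer seed (defaults to `design$seed`).
#' @return list with `genotypes`, `methylation`, `expression`, `peaks`,
#'   `loops`, and `truth` (data.frame of planted triples with their
#'   coefficients).
#' @export
simulate_cohort <- function(design, n_snps = 50, n_cpgs = 20, n_genes = 30,
                            geometry = cohort_geometry(), seed = design$seed) {
  if (!is.null(seed)) set.seed(seed)
  np <- geometry$n_planted
  nb <- geometry$null_blocks
  stopifnot(n_snps >= np, n_cpgs >= np, n_genes >= np)
  chrom <- "chr1"
  samples <- sprintf("S%03d", seq_len(design$n))

  # planted blocks: one snp/cpg/gene each, well separated
  snp_tab <- data.frame(chrom = character(), pos = integer(),
                        rsid = character(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
  cpg_tab <- data.frame(cpg_id = character(), chrom = character(),
                        pos = integer(), stringsAsFactors = FALSE)
  gene_tab <- data.frame(gene_id = character(), name = character(),
                         chrom = character(), strand = character(),
                         tss = integer(), biotype = character(),
                         stringsAsFactors = FALSE)
  for (b in seq_len(np)) {
    base <- (b - 1) * geometry$block_span
    snp_tab <- rbind(snp_tab, data.frame(
      chrom = chrom, pos = base + 100000L, rsid = sprintf("rsP%02d", b),
      ref = "A", alt = "G", stringsAsFactors = FALSE))
    cpg_tab <- rbind(cpg_tab, data.frame(
      cpg_id = sprintf("cgP%02d", b), chrom = chrom,
      pos = base + 300000L, stringsAsFactors = FALSE))
    gene_tab <- rbind(gene_tab, data.frame(
      gene_id = sprintf("GP%02d", b), name = sprintf("GP%02d", b),
      chrom = chrom, strand = "+", tss = base + 500000L,
      biotype = "protein_coding", stringsAsFactors = FALSE))
  }
  # null blocks: remaining features spread as evenly as possible; within a
  # block, snps sit left of alternating (cpg, gene-group) stretches
  split_even <- function(total, k) {
    base <- rep(total %/% k, k)
    if (total %% k) base[seq_len(total %% k)] <- base[seq_len(total %% k)] + 1
    base
  }
  ns_b <- split_even(n_snps - np, nb)
  nc_b <- split_even(n_cpgs - np, nb)
  ng_b <- split_even(n_genes - np, nb)
  for (b in seq_len(nb)) {
    base <- (np + b - 1) * geometry$block_span
    if (ns_b[b] > 0)
      snp_tab <- rbind(snp_tab, data.frame(
        chrom = chrom, pos = base + 100000L + (seq_len(ns_b[b]) - 1L) * 5000L,
        rsid = sprintf("rsN%02d_%02d", b, seq_len(ns_b[b])),
        ref = "A", alt = "G", stringsAsFactors = FALSE))
    if (nc_b[b] > 0 && ng_b[b] > 0) {
      gene_groups <- split(seq_len(ng_b[b]),
                           rep_len(seq_len(nc_b[b]), ng_b[b]))
      for (j in seq_len(nc_b[b])) {
        cpg_tab <- rbind(cpg_tab, data.frame(
          cpg_id = sprintf("cgN%02d_%02d", b, j), chrom = chrom,
          pos = base + 300000L + (j - 1L) * 200000L,
          stringsAsFactors = FALSE))
        gg <- gene_groups[[j]]
        gene_tab <- rbind(gene_tab, data.frame(
          gene_id = sprintf("GN%02d_%02d", b, gg),
          name = sprintf("GN%02d_%02d", b, gg),
          chrom = chrom, strand = rep_len(c("+", "-"), length(gg)),
          tss = base + 350000L + (j - 1L) * 200000L +
            (seq_along(gg) - 1L) * 20000L,
          biotype = "protein_coding", stringsAsFactors = FALSE))
      }
    }
  }

  dosages <- vapply(seq_len(nrow(snp_tab)), function(i)
    simulate_genotypes(design$n, design$maf), numeric(design$n))
  betas <- vapply(seq_len(nrow(cpg_tab)), function(j)
    simulate_methylation(design$n, design), numeric(design$n))

  planted_snp_col <- match(sprintf("rsP%02d", seq_len(np)), snp_tab$rsid)
  planted_cpg_col <- match(sprintf("cgP%02d", seq_len(np)), cpg_tab$cpg_id)
  b3_signs <- rep_len(c(1, -1), np)
  expr <- matrix(NA_real_, design$n, nrow(gene_tab))
  truth_rows <- vector("list", np)
  for (k in seq_len(nrow(gene_tab))) {
    gid <- gene_tab$gene_id[k]
    if (grepl("^GP", gid)) {
      b <- as.integer(sub("GP", "", gid))
      d <- design
      d$beta1 <- geometry$planted_beta1
      d$beta2 <- geometry$planted_beta2
      d$beta3 <- b3_signs[b] * geometry$planted_beta3
      y <- simulate_outcome(dosages[, planted_snp_col[b]],
                            betas[, planted_cpg_col[b]], d)
      truth_rows[[b]] <- data.frame(
        snp_id = snp_tab$rsid[planted_snp_col[b]],
        cpg_id = cpg_tab$cpg_id[planted_cpg_col[b]],
        gene_id = gid, beta1 = d$beta1, beta2 = d$beta2, beta3 = d$beta3,
        stringsAsFactors = FALSE)
    } else {
      y <- design$beta0 + stats::rnorm(design$n, 0, design$sigma)
    }
    expr[, k] <- geometry$fpkm_scale * exp(y)
  }

  peaks <- data.frame(chrom = chrom, start = snp_tab$pos - 101L,
                      end = snp_tab$pos + 100L,
                      name = paste0("peak_", snp_tab$rsid),
                      stringsAsFactors = FALSE)
  loops <- do.call(rbind, lapply(seq_len(np), function(b) {
    cpg <- cpg_tab$pos[planted_cpg_col[b]]
    tss <- (b - 1) * geometry$block_span + 500000L
    data.frame(chrom = chrom, start1 = cpg - 500L, end1 = cpg + 500L,
               start2 = tss + 20000L, end2 = tss + 21000L,
               name = sprintf("loopP%02d", b), pet = 10L + 2L * b,
               stringsAsFactors = FALSE)
  }))

  list(genotypes = genotype_matrix(samples, snp_tab, dosages),
       methylation = feature_matrix(samples, cpg_tab, betas,
                                    kind = "methylation"),
       expression = feature_matrix(samples, gene_tab, expr,
                                   kind = "expression"),
       peaks = peaks, loops = loops,
       truth = do.call(rbind, truth_rows))
}

#' Call memo-eQTLs by p-value gating or BH-FDR gating
#'
#' The p-value method is the triple gate of [memo_test()] at raw `alpha`.
#' The FDR method replaces the M3-vs-M2 raw p-value by its BH-adjusted
#' value (adjustment applied solely to the interaction test, over all
#' combinations in `results`); the M3-significance and M3-vs-M1 gates are
#' kept at raw `alpha` unless `fdr_other_gates = FALSE`.
#'
#' @param results data.frame with columns `p_m3_overall`, `p_m3_vs_m2`,
#'   `p_m3_vs_m1` (from [memo_scan()] or [simulate_and_map()]).
#' @param alpha significance level.
#' @param method `"pvalue"` or `"fdr"`.
#' @param fdr_other_gates keep the other two gates under the FDR method.
#' @return logical call vector (NA p-values give `FALSE`).
#' @export
gate_calls <- function(results, alpha = 0.05,
                       method = c("pvalue", "fdr"),
                       fdr_other_gates = TRUE) {
  method <- match.arg(method)
  p_ov <- results$p_m3_overall
  p32 <- results$p_m3_vs_m2
  p31 <- results$p_m3_vs_m1
  if (method == "pvalue") {
    calls <- p_ov < alpha & p32 < alpha & p31 < alpha
  } else {
    padj <- rep(NA_real_, length(p32))
    ok <- !is.na(p32)
    padj[ok] <- stats::p.adjust(p32[ok], method = "BH")
    calls <- padj < alpha
    if (fdr_other_gates) calls <- calls & p_ov < alpha & p31 < alpha
  }
  calls & !is.na(calls)
}

#' F1 score
#' @param tp,fp,fn confusion counts.
#' @return `2 tp / (2 tp + fp + fn)`, with the 0/0 case defined as 0.
#' @export
f1_score <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  if (denom == 0) 0 else 2 * tp / denom
}

#' Confusion counts and F1 for a detection method
#'
#' @param truth logical vector, `TRUE` where the true interaction
#'   coefficient is nonzero.
#' @param calls logical call vector of the same length.
#' @return list with `tp`, `fp`, `fn`, `tn`, `f1`.
#' @export
evaluate_detection <- function(truth, calls) {
  if (length(truth) != length(calls))
    stop("truth and calls must have equal length")
  truth <- as.logical(truth); calls <- as.logical(calls)
  calls[is.na(calls)] <- FALSE
  tp <- sum(truth & calls); fp <- sum(!truth & calls)
  fn <- sum(truth & !calls); tn <- sum(!truth & !calls)
  list(tp = tp, fp = fp, fn = fn, tn = tn, f1 = f1_score(tp, fp, fn))
}

#' Permutation null for a subsample eQTL association
#'
#' Compares the eQTL-model p-value observed in a designated subsample (e.g.
#' the relL group of a stratified memo-eQTL) with the p-values obtained in
#' `B` random subsamples of the same size, preserving the group sizes of
#' the observed partition. The empirical p-value uses the plus-one rule
#' `(1 + #\{null <= observed\}) / (1 + B)` and therefore never returns 0.
#'
#' @param snp,gene per-sample dosage and expression vectors.
#' @param designated integer indices (or logical mask) of the designated
#'   group.
#' @param B number of random partitions.
#' @param seed optional seed.
#' @return list with `observed_p`, `null_ps` (length `B`), `empirical_p`.
#' @export
permutation_null <- function(snp, gene, designated, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(snp)
  stopifnot(length(gene) == n)
  idx <- if (is.logical(designated)) which(designated) else as.integer(designated)
  k <- length(idx)
  if (k < 4 || n - k < 4) stop("each group must contain at least 4 samples")
  one_p <- function(ii) {
    s <- snp[ii]
    if (stats::sd(s) == 0) return(NA_real_)
    .fast_slope_p(s, gene[ii])[["p"]]
  }
  observed_p <- one_p(idx)
  null_ps <- vapply(seq_len(B), function(b) one_p(sample.int(n, k)),
                    numeric(1))
  emp <- (1 + sum(null_ps <= observed_p, na.rm = TRUE)) / (1 + B)
  list(observed_p = observed_p, null_ps = null_ps, empirical_p = emp)
}
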