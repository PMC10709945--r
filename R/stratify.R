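#' Search the optimal methylation threshold separating relH and relL
#'
#' Dichotomizes the cohort at every distinct observed beta value inside the
#' interquartile range \[Q1, Q3\] into relH (`beta >= tau`) and relL
#' (`beta < tau`) subsamples, fits the simple eQTL model `gene ~ SNP` in
#' each, and returns the threshold maximizing
#' `|log10 p(relL) - log10 p(relH)|` — the split at which the two subsample
#' eQTL models differ the most. Candidates leaving either subsample smaller
#' than `min_frac * n` or with a monomorphic SNP are skipped; ties go to the
#' smallest threshold.
#'
#' @param mecpg,snp,gene numeric vectors over the same samples.
#' @param alpha significance level (recorded, not used in the search).
#' @param min_frac minimum fraction of samples per subsample.
#' @return list with `tau_star`, `p_relh`, `p_rell`, `beta_relh`,
#'   `beta_rell`, `q1`, `q3`, `n_relh`, `n_rell`. All NA (with a warning)
#'   when no admissible candidate exists.
#' @export
search_threshold <- function(mecpg, snp, gene, alpha = 0.05, min_frac = 0.2) {
  ok <- !is.na(mecpg) & !is.na(snp) & !is.na(gene)
  m <- mecpg[ok]; s <- snp[ok]; g <- gene[ok]
  n <- length(m)
  if (n < 20) stop("threshold search requires at least 20 complete cases")
  q <- stats::quantile(m, c(0.25, 0.75), names = FALSE)
  cand <- sort(unique(m[m >= q[1] & m <= q[2]]))
  min_size <- max(ceiling(min_frac * n), 4)
  empty <- list(tau_star = NA_real_, p_relh = NA_real_, p_rell = NA_real_,
                beta_relh = NA_real_, beta_rell = NA_real_,
                q1 = q[1], q3 = q[2], n_relh = NA_integer_,
                n_rell = NA_integer_)
  best <- NULL
  best_obj <- -Inf
  for (tau in cand) {
    hi <- m >= tau
    nh <- sum(hi); nl <- n - nh
    if (nh < min_size || nl < min_size) next
    if (stats::sd(s[hi]) == 0 || stats::sd(s[!hi]) == 0) next
    fh <- .fast_slope_p(s[hi], g[hi])
    fl <- .fast_slope_p(s[!hi], g[!hi])
    obj <- abs(fl[["log10p"]] - fh[["log10p"]])
    if (is.nan(obj)) next
    if (obj > best_obj) {  # strict: ties keep the smallest tau
      best_obj <- obj
      best <- list(tau_star = tau, p_relh = fh[["p"]], p_rell = fl[["p"]],
                   beta_relh = fh[["slope"]], beta_rell = fl[["slope"]],
                   q1 = q[1], q3 = q[2], n_relh = nh, n_rell = nl)
    }
  }
  if (is.null(best)) {
    warning("no admissible threshold candidate in [Q1, Q3]")
    return(empty)
  }
  best
}

#' Classify a memo-eQTL by subsample significance
#'
#' @param p_relh,p_rell eQTL-model (M1) p-values in the relH and relL
#'   subsamples.
#' @param alpha significance cutoff.
#' @return `"sigHigh"`, `"sigLow"`, `"sigBoth"` or `"sigNone"`; NA when a
#'   p-value is missing.
#' @export
classify_subgroup <- function(p_relh, p_rell, alpha = 0.05) {
  if (is.na(p_relh) || is.na(p_rell)) return(NA_character_)
  sh <- p_relh < alpha
  sl <- p_rell < alpha
  if (sh && sl) "sigBoth" else if (sh) "sigHigh"
  else if (sl) "sigLow" else "sigNone"
}

#' Relative explained variances of SNP, meCpG and their interaction
#'
#' Sequential (type-I) sums of squares in the nesting order SNP -> meCpG ->
#' SNP x meCpG, normalized to their sum, so the three fractions are
#' nonnegative and add to one.
#'
#' @param snp,mecpg,gene numeric vectors over the same samples.
#' @return named numeric vector `c(v_snp, v_mecpg, v_inter)`; all NA when
#'   the three terms explain no variance.
#' @export
variance_fractions <- function(snp, mecpg, gene) {
  ok <- !is.na(snp) & !is.na(mecpg) & !is.na(gene)
  s <- snp[ok]; m <- mecpg[ok]; g <- gene[ok]
  n <- length(g)
  if (n < 5) stop("too few complete cases for variance decomposition")
  one <- rep(1, n)
  sse0 <- sum((g - mean(g))^2)
  f1 <- .ols(g, cbind(one, s))
  f2 <- .ols(g, cbind(one, s, m))
  f3 <- .ols(g, cbind(one, s, m, s * m))
  if (f1$degenerate || f2$degenerate || f3$degenerate)
    return(c(v_snp = NA_real_, v_mecpg = NA_real_, v_inter = NA_real_))
  ss <- pmax(c(sse0 - f1$sse, f1$sse - f2$sse, f2$sse - f3$sse), 0)
  tot <- sum(ss)
  if (tot <= 0)
    return(c(v_snp = NA_real_, v_mecpg = NA_real_, v_inter = NA_real_))
  stats::setNames(ss / tot, c("v_snp", "v_mecpg", "v_inter"))
}

#' Stratify mapped memo-eQTLs at their optimal methylation threshold
#'
#' For each result row flagged `is_memo` (or all rows when
#' `memo_only = FALSE`), runs [search_threshold()], [classify_subgroup()]
#' and [variance_fractions()].
#'
#' @param results data.frame from [memo_scan()].
#' @param genotypes,methylation,expression aligned matrices.
#' @param alpha significance cutoff for the subgroup classification.
#' @param min_frac passed to [search_threshold()].
#' @param memo_only restrict to G1 rows (default).
#' @return data.frame: input rows plus `tau_star`, `q1`, `q3`, `p_relh`,
#'   `p_rell`, `beta_relh`, `beta_rell`, `subgroup`, `v_snp`, `v_mecpg`,
#'   `v_inter`.
#' @export
stratify_memo <- function(results, genotypes, methylation, expression,
                          alpha = 0.05, min_frac = 0.2, memo_only = TRUE) {
  rows <- if (memo_only) which(results$is_memo) else seq_len(nrow(results))
  out <- lapply(rows, function(i) {
    tr <- results[i, , drop = FALSE]
    s <- genotypes$dosages[, as.character(tr$snp_id)]
    m <- methylation$values[, as.character(tr$cpg_id)]
    g <- expression$values[, as.character(tr$gene_id)]
    th <- suppressWarnings(
      search_threshold(m, s, g, alpha = alpha, min_frac = min_frac))
    vf <- variance_fractions(s, m, g)
    cbind(tr,
          data.frame(tau_star = th$tau_star, q1 = th$q1, q3 = th$q3,
                     p_relh = th$p_relh, p_rell = th$p_rell,
                     beta_relh = th$beta_relh, beta_rell = th$beta_rell,
                     subgroup = classify_subgroup(th$p_relh, th$p_rell,
                                                  alpha = alpha),
                     v_snp = vf[["v_snp"]], v_mecpg = vf[["v_mecpg"]],
                     v_inter = vf[["v_inter"]],
                     stringsAsFactors = FALSE))
  })
  if (!length(out))
    return(cbind(results[0, , drop = FALSE],
                 data.frame(tau_star = numeric(), q1 = numeric(),
                            q3 = numeric(), p_relh = numeric(),
                            p_rell = numeric(), beta_relh = numeric(),
                            beta_rell = numeric(), subgroup = character(),
                            v_snp = numeric(), v_mecpg = numeric(),
                            v_inter = numeric())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
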