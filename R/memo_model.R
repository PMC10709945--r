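# Ordinary least squares with the quantities the moderation gating needs:
# Gaussian ML log-likelihood, overall F-test, per-slope t-tests. qr-based so
# rank deficiency (e.g. a monomorphic SNP inside a subsample) is detected
# rather than silently dropped.
.ols <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p)
    return(list(degenerate = TRUE, n = n, p = p, coefficients = rep(NA_real_, p),
                sse = NA_real_, loglik = NA_real_, overall_p = NA_real_,
                slope_p = rep(NA_real_, p - 1)))
  coef <- qr.coef(qx, y)
  res <- y - drop(X %*% coef)
  sse <- sum(res^2)
  loglik <- if (sse > 0) -(n / 2) * (log(2 * pi * sse / n) + 1) else Inf
  sst <- sum((y - mean(y))^2)
  if (p > 1) {
    fstat <- ((sst - sse) / (p - 1)) / (sse / (n - p))
    overall_p <- if (sse > 0)
      stats::pf(fstat, p - 1, n - p, lower.tail = FALSE) else 0
  } else overall_p <- NA_real_
  # unscaled covariance, undoing qr pivoting
  R <- qr.R(qx)
  xtxinv <- chol2inv(R)
  unpiv <- order(qx$pivot)
  xtxinv <- xtxinv[unpiv, unpiv, drop = FALSE]
  sigma2 <- sse / (n - p)
  se <- sqrt(pmax(diag(xtxinv), 0) * sigma2)
  tstat <- coef / se
  pvals <- 2 * stats::pt(-abs(tstat), df = n - p)
  pvals[se == 0] <- 0
  list(degenerate = FALSE, n = n, p = p, coefficients = coef,
       se = se, sse = sse, loglik = loglik, overall_p = overall_p,
       slope_p = pvals[-1], coef_p = pvals)
}

#' Fit a Gaussian linear model by ordinary least squares
#'
#' Returns the pieces needed for likelihood-ratio gating: coefficient
#' estimates, residual sum of squares, the Gaussian maximum-likelihood
#' log-likelihood `-(n/2) (log(2 pi sse / n) + 1)`, the overall F-test
#' against the intercept-only model, and per-slope t-test p-values.
#'
#' @param y response vector (complete cases only).
#' @param design model matrix including an intercept column.
#' @param model_id optional label (`"M1"`, `"M2"`, `"M3"`).
#' @return An object of class `memoqtl_fit`. A rank-deficient design yields a
#'   degenerate fit (`degenerate = TRUE`, p-values NA).
#' @export
fit_linear_model <- function(y, design, model_id = NULL) {
  design <- as.matrix(design)
  if (any(is.na(y)) || any(is.na(design)))
    stop("fit_linear_model expects complete cases")
  if (length(y) != nrow(design)) stop("response/design size mismatch")
  if (length(y) <= ncol(design))
    stop("need more observations than parameters")
  fit <- .ols(y, design)
  fit$model_id <- model_id
  class(fit) <- "memoqtl_fit"
  fit
}

#' @export
print.memoqtl_fit <- function(x, ...) {
  cat("memoqtl_fit", if (!is.null(x$model_id)) x$model_id else "", ": n =",
      x$n, ", params =", x$p,
      if (isTRUE(x$degenerate)) "(degenerate)" else
        sprintf(", sse = %.4g, loglik = %.4g", x$sse, x$loglik), "\n")
  invisible(x)
}

#' Likelihood ratio test for nested Gaussian linear models
#'
#' `stat = 2 (loglik_full - loglik_reduced)`, referred to a chi-square with
#' degrees of freedom equal to the parameter-count difference.
#'
#' @param full,reduced `memoqtl_fit` objects fitted to the same response and
#'   samples, with the reduced model's predictors a subset of the full's.
#' @return list with `stat`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$n != reduced$n)
    stop("models were fitted on different sample counts")
  df <- full$p - reduced$p
  if (df < 0) stop("full model must have at least as many parameters as reduced")
  if (isTRUE(full$degenerate) || isTRUE(reduced$degenerate))
    return(list(stat = NA_real_, df = df, p = NA_real_))
  if (df == 0) {
    if (abs(full$loglik - reduced$loglik) >
          1e-8 * max(1, abs(reduced$loglik)))
      stop("models with equal parameter counts must be identical")
    return(list(stat = 0, df = 0L, p = 1))
  }
  if (is.finite(full$loglik) && is.finite(reduced$loglik) &&
      full$loglik < reduced$loglik - 1e-8 * max(1, abs(reduced$loglik)))
    stop("models are not nested: full log-likelihood below reduced")
  stat <- if (is.infinite(full$loglik)) Inf
          else max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Simple linear association of a single marker
#'
#' OLS slope of `y` on `x` with a two-sided t-test p-value; used for the
#' canonical eQTL (expression ~ SNP) and meQTL (methylation ~ SNP) scans.
#'
#' @param x,y numeric vectors (pairwise complete cases used).
#' @return list with `slope`, `p`, `n`; both NA when `x` is constant or
#'   fewer than 4 complete cases remain.
#' @export
single_marker_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0)
    return(list(slope = NA_real_, p = NA_real_, n = n))
  sp <- .fast_slope_p(x, y)
  list(slope = sp[["slope"]], p = sp[["p"]], n = n)
}

# slope + two-sided p for simple regression via the correlation t-statistic
# (identical to the OLS slope t-test); complete inputs assumed. log10p is
# kept separately so near-zero p-values keep their order (no underflow ties).
.fast_slope_p <- function(x, y) {
  n <- length(x)
  sy <- stats::sd(y)
  if (sy == 0) return(c(slope = 0, p = 1, log10p = 0))
  r <- stats::cor(x, y)
  slope <- r * sy / stats::sd(x)
  if (abs(r) >= 1) return(c(slope = slope, p = 0, log10p = -Inf))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  lp <- (stats::pt(-abs(tstat), df = n - 2, log.p = TRUE) + log(2)) / log(10)
  c(slope = slope, p = min(1, 2 * stats::pt(-abs(tstat), df = n - 2)),
    log10p = lp)
}

#' Moderated-eQTL test for one (gene, SNP, meCpG) combination
#'
#' Fits the three nested models on identical complete-case samples —
#' M1: `gene ~ SNP`; M2: `gene ~ SNP + meCpG`; M3: `gene ~ SNP + meCpG +
#' SNP:meCpG` — and applies the gating rule: the M3 overall F-test must be
#' significant, then the combination is classified by the two likelihood
#' ratio tests (M3 vs M2, testing the interaction; M3 vs M1, testing the
#' joint methylation contribution):
#' G1 = both significant (a memo-eQTL), G2 = only M3-vs-M2, G3 = only
#' M3-vs-M1, G4 = neither.
#'
#' @param gene,snp,mecpg numeric vectors over the same samples.
#' @param alpha significance level for every gate.
#' @param min_n minimum complete-case sample count.
#' @return list with complete-case `n`, p-values (`p_m3_overall`,
#'   `p_m3_vs_m2`, `p_m3_vs_m1`, `eqtl_p`, `meqtl_p`), M3 coefficients
#'   (`b31`, `b32`, `b33`), `group` and `is_memo`.
#' @export
memo_test <- function(gene, snp, mecpg, alpha = 0.05, min_n = 30) {
  ok <- !is.na(gene) & !is.na(snp) & !is.na(mecpg)
  g <- gene[ok]; s <- snp[ok]; m <- mecpg[ok]
  n <- length(g)
  na_result <- list(n = n, p_m3_overall = NA_real_, p_m3_vs_m2 = NA_real_,
                    p_m3_vs_m1 = NA_real_, eqtl_p = NA_real_,
                    meqtl_p = NA_real_, b31 = NA_real_, b32 = NA_real_,
                    b33 = NA_real_, group = "not_evaluated", is_memo = FALSE)
  if (n < min_n || stats::sd(s) == 0) return(na_result)
  one <- rep(1, n)
  f1 <- .ols(g, cbind(one, s))
  f2 <- .ols(g, cbind(one, s, m))
  f3 <- .ols(g, cbind(one, s, m, s * m))
  eq <- single_marker_assoc(s, g)
  mq <- single_marker_assoc(s, m)
  if (f1$degenerate || f2$degenerate || f3$degenerate) {
    na_result$eqtl_p <- eq$p
    na_result$meqtl_p <- mq$p
    return(na_result)
  }
  lrt32 <- .lrt_chisq(f3, f2)
  lrt31 <- .lrt_chisq(f3, f1)
  res <- list(n = n, p_m3_overall = f3$overall_p,
              p_m3_vs_m2 = lrt32, p_m3_vs_m1 = lrt31,
              eqtl_p = eq$p, meqtl_p = mq$p,
              b31 = unname(f3$coefficients[2]),
              b32 = unname(f3$coefficients[3]),
              b33 = unname(f3$coefficients[4]))
  if (is.na(f3$overall_p) || f3$overall_p >= alpha) {
    res$group <- "not_evaluated"
  } else {
    s32 <- lrt32 < alpha
    s31 <- lrt31 < alpha
    res$group <- if (s32 && s31) "G1" else if (s32) "G2"
                 else if (s31) "G3" else "G4"
  }
  res$is_memo <- identical(res$group, "G1")
  res
}

.lrt_chisq <- function(full, reduced) {
  stat <- if (is.infinite(full$loglik)) Inf
          else max(0, 2 * (full$loglik - reduced$loglik))
  stats::pchisq(stat, df = full$p - reduced$p, lower.tail = FALSE)
}

#' Moderated-eQTL mapping for one candidate triple
#'
#' Extracts the SNP dosage, CpG beta and (transformed) expression vectors for
#' the triple from aligned matrices and runs [memo_test()].
#'
#' @param triple one-row data.frame from [enumerate_triples()].
#' @param genotypes,methylation,expression aligned matrices (see
#'   [align_cohort()]).
#' @param alpha significance level.
#' @param min_n minimum complete-case count.
#' @return one-row data.frame combining the triple's coordinates and the
#'   [memo_test()] output.
#' @export
map_triple <- function(triple, genotypes, methylation, expression,
                       alpha = 0.05, min_n = 30) {
  stopifnot(identical(genotypes$samples, methylation$samples),
            identical(genotypes$samples, expression$samples))
  s <- genotypes$dosages[, as.character(triple$snp_id)]
  m <- methylation$values[, as.character(triple$cpg_id)]
  g <- expression$values[, as.character(triple$gene_id)]
  res <- memo_test(g, s, m, alpha = alpha, min_n = min_n)
  cbind(as.data.frame(triple, stringsAsFactors = FALSE),
        as.data.frame(res, stringsAsFactors = FALSE))
}

#' Moderated-eQTL mapping over a triple table
#'
#' @param triples data.frame from [enumerate_triples()].
#' @inheritParams map_triple
#' @return data.frame with one result row per triple.
#' @export
memo_scan <- function(triples, genotypes, methylation, expression,
                      alpha = 0.05, min_n = 30) {
  if (!nrow(triples)) stop("no triples to map")
  rows <- lapply(seq_len(nrow(triples)), function(i)
    map_triple(triples[i, , drop = FALSE], genotypes, methylation,
               expression, alpha = alpha, min_n = min_n))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
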