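#' Default run configuration
#'
#' All thresholds of the mapping pipeline with their standard defaults:
#' `alpha` 0.05 significance level for every gate; `maf` 0.05 (strict lower
#' bound); `r2` 0.8 LD pruning cut; `window` 1e6 bp cis window;
#' `mean_range` \[0.25, 0.75\] for CpG mean beta; `cpg_iqr` 0.1;
#' screen filters (>= 10 samples with > 20 reads, beta IQR > 0.1, CTCF
#' intensity IQR > 1, |SCC| > 0.5, Padj < 0.05); `min_median_fpkm` 1;
#' `min_pet` 15; `B` 1000 permutations; `min_frac` 0.2 and `min_n` 30 for
#' subsample fits.
#'
#' @param ... named overrides of any default.
#' @return list of class `memoqtl_config`.
#' @export
memoqtl_config <- function(...) {
  cfg <- list(alpha = 0.05, maf = 0.05, r2 = 0.8, window = 1e6,
              mean_range = c(0.25, 0.75), cpg_iqr = 0.1,
              screen_min_samples = 10, screen_min_coverage = 20,
              screen_beta_iqr = 0.1, ctcf_iqr = 1.0,
              scc_cut = 0.5, padj_cut = 0.05,
              min_median_fpkm = 1, min_pet = 15, B = 1000,
              min_frac = 0.2, min_n = 30, seed = 1,
              genotypes = NULL, genotype_format = "dosage_table",
              methylation = NULL, expression = NULL,
              peaks = NULL, loops = NULL, eligible_cpgs = NULL,
              out_dir = NULL,
              stages = c("enumerate", "map", "stratify", "spatial"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "memoqtl_config")
}

#' Read a flat key=value configuration file
#' @param path config file; one `key = value` pair per line, `#` comments,
#'   commas separating vector elements.
#' @return a [memoqtl_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    v <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(v))
    if (!any(is.na(num))) num else v
  })
  do.call(memoqtl_config, stats::setNames(vals, keys))
}

#' Write a configuration to its flat file form
#' @param config a [memoqtl_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(names(config)[keep], function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  config$out_dir <- NULL  # parameters only: output location is not provenance
  keep <- !vapply(config, is.null, logical(1))
  writeLines(vapply(names(config)[keep], function(k)
    paste0(k, "=", paste(config[[k]], collapse = ",")), character(1)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the mapping pipeline
#'
#' Orchestrates enumerate -> map -> stratify -> spatial over the inputs named
#' in the config, writing one TSV per stage plus a manifest into
#' `config$out_dir`. Every output carries a comment header recording the
#' package version, the config hash and the seed, and deterministic stages
#' are byte-identical across reruns of the same config and inputs.
#'
#' @param config a [memoqtl_config()] with input paths and `out_dir` set.
#' @return data.frame manifest of stage outputs, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "memoqtl_config"))
  for (key in c("genotypes", "methylation", "expression")) {
    if (is.null(config[[key]]))
      stop("config must name an input for: ", key)
    if (!file.exists(config[[key]]))
      stop("missing input file for ", key, ": ", config[[key]])
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  hdr <- c(seed = config$seed, config = .config_hash(config))
  manifest <- list()
  emit <- function(stage, df, file) {
    path <- file.path(config$out_dir, file)
    .write_tsv(df, path, params = hdr)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, path = path, rows = nrow(df), stringsAsFactors = FALSE)
    path
  }

  gt <- load_genotypes(config$genotypes, format = config$genotype_format)
  meth <- load_feature_matrix(config$methylation, kind = "methylation")
  expr <- load_feature_matrix(config$expression, kind = "expression")
  coh <- align_cohort(gt, meth, expr)

  gt <- filter_by_maf(coh$genotypes, maf_cut = config$maf)
  message("maf filter: ", nrow(gt$variants), " variants")
  gt <- ld_prune(gt, r2_cut = config$r2, window_bp = config$window)
  message("ld prune: ", nrow(gt$variants), " variants")
  if (!is.null(config$peaks)) {
    gt <- intersect_variants_with_peaks(gt, load_intervals(config$peaks))
    message("peak intersection: ", nrow(gt$variants), " variants")
  }
  eligible <- if (!is.null(config$eligible_cpgs))
    .read_tsv(config$eligible_cpgs)$cpg_id
  meth <- filter_variable_cpgs(coh$methylation,
                               mean_range = config$mean_range,
                               min_iqr = config$cpg_iqr,
                               eligible_sites = eligible)
  message("cpg filter: ", nrow(meth$features), " sites")
  expr <- filter_and_transform_expression(
    coh$expression, min_median_fpkm = config$min_median_fpkm)
  message("expression filter: ", nrow(expr$features), " genes")

  triples <- enumerate_triples(gt, meth, expr, window_bp = config$window)
  message("enumerate: ", nrow(triples), " triples")
  emit("enumerate", triples, "triples.tsv")

  results <- NULL
  if ("map" %in% config$stages) {
    results <- memo_scan(triples, gt, meth, expr,
                         alpha = config$alpha, min_n = config$min_n)
    message("map: ", sum(results$is_memo), " memo-eQTLs (G1)")
    emit("map", results, "memo_results.tsv")
  }
  strat <- NULL
  if ("stratify" %in% config$stages && !is.null(results)) {
    strat <- stratify_memo(results, gt, meth, expr,
                           alpha = config$alpha, min_frac = config$min_frac)
    emit("stratify", strat, "strat.tsv")
  }
  if ("spatial" %in% config$stages && !is.null(strat) &&
      !is.null(config$loops)) {
    loops <- load_loops(config$loops)
    spatial <- spatial_classify(strat, loops, min_pet = config$min_pet)
    emit("spatial", spatial, "spatial.tsv")
  }
  manifest <- do.call(rbind, manifest)
  .write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
             params = hdr)
  invisible(manifest)
}
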