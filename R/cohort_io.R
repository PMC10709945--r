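#' Construct a genotype matrix
#'
#' Container for additive genotype dosages of a cohort: a samples x variants
#' matrix with entries in \{0, 1, 2, NA\} plus per-variant coordinates.
#'
#' @param samples character vector of sample identifiers.
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `rsid`, `ref`, `alt` and optionally `maf`.
#' @param dosages numeric matrix, `length(samples)` rows and
#'   `nrow(variants)` columns; entries must be 0, 1, 2 or NA.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosages) {
  samples <- as.character(samples)
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants))
    stop("dosage matrix dimensions must equal samples x variants")
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad))
    stop("dosages must be 0, 1, 2 or missing; found value(s): ",
         paste(unique(dosages[bad]), collapse = ", "))
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (!is.null(variants$maf) &&
      any(!is.na(variants$maf) & (variants$maf < 0 | variants$maf > 0.5)))
    stop("maf must lie in [0, 0.5]")
  rownames(dosages) <- samples
  colnames(dosages) <- variants$rsid
  structure(list(samples = samples,
                 variants = as.data.frame(variants),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Construct a feature matrix (methylation betas or expression)
#'
#' @param samples character vector of sample identifiers.
#' @param features data.frame of per-feature metadata. For methylation:
#'   `cpg_id`, `chrom`, `pos`. For expression: `gene_id`, `name`, `chrom`,
#'   `strand`, `tss`, `biotype`.
#' @param values samples x features numeric matrix. Methylation beta values
#'   must lie in \[0, 1\] (or NA); untransformed expression must be >= 0.
#' @param kind `"methylation"` or `"expression"`.
#' @param coverage optional samples x features nonnegative integer matrix of
#'   sequencing read coverage (methylation only).
#' @param transformed logical; `TRUE` once expression has been inverse-normal
#'   transformed (see [filter_and_transform_expression()]).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(samples, features, values,
                           kind = c("methylation", "expression"),
                           coverage = NULL, transformed = FALSE) {
  kind <- match.arg(kind)
  samples <- as.character(samples)
  values <- as.matrix(values)
  if (nrow(values) != length(samples) || ncol(values) != nrow(features))
    stop("value matrix dimensions must equal samples x features")
  if (kind == "methylation") {
    if (any(values < 0 | values > 1, na.rm = TRUE))
      stop("methylation beta values must lie in [0, 1]")
    if (any(features$pos < 1)) stop("CpG positions must be >= 1")
  } else {
    if (!transformed && any(values < 0, na.rm = TRUE))
      stop("untransformed expression (FPKM) must be nonnegative")
    if (any(features$tss < 1)) stop("TSS coordinates must be >= 1")
    if (any(!features$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
  }
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    if (!identical(dim(coverage), dim(values)))
      stop("coverage matrix must have the same shape as the beta matrix")
    if (any(coverage < 0, na.rm = TRUE)) stop("coverage must be nonnegative")
  }
  id_col <- if (kind == "methylation") "cpg_id" else "gene_id"
  rownames(values) <- samples
  colnames(values) <- features[[id_col]]
  if (!is.null(coverage)) dimnames(coverage) <- dimnames(values)
  structure(list(samples = samples,
                 features = as.data.frame(features),
                 values = values,
                 kind = kind,
                 coverage = coverage,
                 transformed = isTRUE(transformed)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix (", x$kind, "):", length(x$samples), "samples x",
      nrow(x$features), "features",
      if (isTRUE(x$transformed)) "[inverse-normal transformed]" else "", "\n")
  invisible(x)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.header_comment <- function(params = character()) {
  ver <- as.character(utils::packageVersion("memoqtl"))
  extra <- if (length(params))
    paste0(" ", paste(names(params), params, sep = "=", collapse = " ")) else ""
  paste0("# memoqtl v", ver, extra)
}

.write_tsv <- function(df, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load genotypes from VCF or a dosage table
#'
#' VCF records are converted to additive alt-allele dosages from the GT field.
#' Multiallelic or non-SNV records are skipped with a warning (biallelic SNPs
#' only). A dosage table is a TSV with columns `chrom`, `pos`, `rsid`, `ref`,
#' `alt` followed by one column per sample holding 0/1/2/NA.
#'
#' @param path input file path.
#' @param format `"vcf"` or `"dosage_table"`.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("vcf", "dosage_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    if (nrow(vcf@gt) == 0 || ncol(vcf@gt) < 2) stop("VCF contains no samples")
    alt <- fix$ALT
    keep <- !grepl(",", alt) & nchar(fix$REF) == 1 &
      nchar(alt) == 1 & alt != "."
    if (any(!keep))
      warning(sum(!keep), " multiallelic or non-SNV record(s) skipped")
    if (!any(keep)) stop("no biallelic SNV records in VCF")
    gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"), function(a)
               sum(a == "1"), numeric(1)))
    }
    dos <- apply(gt, 2, count_alt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                         dimnames = list(NULL, colnames(gt)))
    variants <- data.frame(chrom = fix$CHROM[keep],
                           pos = as.integer(fix$POS[keep]),
                           rsid = fix$ID[keep],
                           ref = fix$REF[keep], alt = alt[keep],
                           stringsAsFactors = FALSE)
    genotype_matrix(colnames(dos), variants, t(dos))
  } else {
    tab <- .read_tsv(path)
    meta_cols <- c("chrom", "pos", "rsid", "ref", "alt")
    if (!all(meta_cols %in% names(tab)))
      stop("dosage table must have columns: ", paste(meta_cols, collapse = ", "))
    samples <- setdiff(names(tab), meta_cols)
    if (!length(samples)) stop("dosage table contains no sample columns")
    dos <- t(as.matrix(tab[, samples, drop = FALSE]))
    genotype_matrix(samples, tab[, meta_cols], dos)
  }
}

#' Write genotypes as a dosage table
#' @param x a [genotype_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(x, path) {
  df <- cbind(x$variants[, c("chrom", "pos", "rsid", "ref", "alt")],
              as.data.frame(t(x$dosages)))
  .write_tsv(df, path)
}

#' Load a methylation or expression matrix from TSV
#'
#' Methylation files carry columns `cpg_id`, `chrom`, `pos`; expression files
#' carry `gene_id`, `name`, `chrom`, `strand`, `tss`, `biotype`. Remaining
#' columns are samples. An optional coverage TSV (same layout as the beta
#' file) supplies per-sample read counts.
#'
#' @param path input TSV path.
#' @param kind `"methylation"` or `"expression"`.
#' @param coverage_path optional coverage TSV (methylation only).
#' @return A [feature_matrix()].
#' @export
load_feature_matrix <- function(path, kind = c("methylation", "expression"),
                                coverage_path = NULL) {
  kind <- match.arg(kind)
  tab <- .read_tsv(path)
  meta_cols <- if (kind == "methylation") c("cpg_id", "chrom", "pos")
               else c("gene_id", "name", "chrom", "strand", "tss", "biotype")
  if (!all(meta_cols %in% names(tab)))
    stop(kind, " table must have columns: ", paste(meta_cols, collapse = ", "))
  samples <- setdiff(names(tab), meta_cols)
  if (!length(samples)) stop("feature table contains no sample columns")
  vals <- t(as.matrix(tab[, samples, drop = FALSE]))
  cov <- NULL
  if (!is.null(coverage_path)) {
    ctab <- .read_tsv(coverage_path)
    cov <- t(as.matrix(ctab[, samples, drop = FALSE]))
  }
  feature_matrix(samples, tab[, meta_cols], vals, kind = kind, coverage = cov)
}

#' Write a feature matrix to TSV
#' @param x a [feature_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  df <- cbind(x$features, as.data.frame(t(x$values)))
  .write_tsv(df, path)
}

#' Restrict genotype, methylation and expression matrices to shared samples
#'
#' Keeps the intersection of the three sample sets in one canonical
#' (lexicographic) order so that per-triple model fits line up row-wise.
#' Idempotent: aligning twice yields the same order.
#'
#' @param genotypes a [genotype_matrix()].
#' @param methylation,expression [feature_matrix()] objects.
#' @return A list with elements `genotypes`, `methylation`, `expression`.
#' @export
align_cohort <- function(genotypes, methylation, expression) {
  common <- Reduce(intersect, list(genotypes$samples, methylation$samples,
                                   expression$samples))
  if (!length(common)) stop("no samples shared by the three matrices")
  common <- sort(common)
  message("align_cohort: ", length(common), " shared samples")
  sub_gt <- genotype_matrix(common, genotypes$variants,
                            genotypes$dosages[common, , drop = FALSE])
  sub_fm <- function(x) feature_matrix(
    common, x$features, x$values[common, , drop = FALSE], kind = x$kind,
    coverage = if (!is.null(x$coverage)) x$coverage[common, , drop = FALSE],
    transformed = x$transformed)
  list(genotypes = sub_gt,
       methylation = sub_fm(methylation),
       expression = sub_fm(expression))
}

#' Load genomic intervals from BED
#'
#' Returns 0-based half-open intervals as a data.frame with columns `chrom`,
#' `start`, `end` (and `name` when present in the file).
#'
#' @param path BED file (>= 3 columns).
#' @param format only `"bed"` is supported.
#' @return data.frame of intervals.
#' @export
load_intervals <- function(path, format = c("bed")) {
  match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L,  # back to BED 0-based
                    end = df$end,
                    stringsAsFactors = FALSE)
  if (!is.null(df$name)) out$name <- df$name
  if (any(out$end <= out$start))
    stop("invalid BED interval: end <= start")
  out
}

#' Write intervals as BED
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("chrom", "start", "end")]
  if (!is.null(intervals$name)) df$name <- intervals$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load chromatin loops from BEDPE
#'
#' Anchors are stored in genomic order (`end1 <= start2`); the PET count is
#' read from column 8 when present, else 0. Trans-chromosomal records are
#' skipped with a warning.
#'
#' @param path BEDPE file (>= 6 columns).
#' @param format only `"bedpe"` is supported.
#' @return data.frame with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `name`, `pet` (anchors 0-based half-open).
#' @export
load_loops <- function(path, format = c("bedpe")) {
  match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           fill = TRUE)
  if (ncol(tab) < 6) stop("BEDPE requires >= 6 columns")
  cis <- tab[[1]] == tab[[4]]
  if (any(!cis))
    warning(sum(!cis), " trans-chromosomal loop(s) skipped")
  tab <- tab[cis, , drop = FALSE]
  s1 <- as.integer(tab[[2]]); e1 <- as.integer(tab[[3]])
  s2 <- as.integer(tab[[5]]); e2 <- as.integer(tab[[6]])
  if (any(e1 <= s1) || any(e2 <= s2))
    stop("invalid BEDPE anchor: end <= start")
  # order the two anchors along the chromosome
  flip <- s1 > s2
  tmp_s <- s1[flip]; tmp_e <- e1[flip]
  s1[flip] <- s2[flip]; e1[flip] <- e2[flip]
  s2[flip] <- tmp_s; e2[flip] <- tmp_e
  name <- if (ncol(tab) >= 7) as.character(tab[[7]])
          else paste0("loop", seq_len(nrow(tab)))
  name[is.na(name) | name == ""] <- paste0("loop", which(is.na(name) |
                                                           name == ""))
  pet <- if (ncol(tab) >= 8) suppressWarnings(as.integer(tab[[8]]))
         else rep(0L, nrow(tab))
  pet[is.na(pet)] <- 0L
  data.frame(chrom = tab[[1]], start1 = s1, end1 = e1,
             start2 = s2, end2 = e2, name = name, pet = pet,
             stringsAsFactors = FALSE)
}

#' Write loops as BEDPE
#' @param loops data.frame as returned by [load_loops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(loops$chrom, loops$start1, loops$end1,
                   loops$chrom, loops$start2, loops$end2,
                   loops$name, loops$pet)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load gene models (TSS table or GTF)
#'
#' The TSS table is a TSV with columns `gene_id`, `name`, `chrom`, `strand`,
#' `tss`, `biotype`. For GTF input, `gene` feature lines are used and the TSS
#' is the strand-aware transcript start (leftmost coordinate for `+` genes,
#' rightmost for `-` genes).
#'
#' @param path input path.
#' @param format `"tss"` or `"gtf"`.
#' @return data.frame of gene models.
#' @export
load_gene_models <- function(path, format = c("tss", "gtf")) {
  format <- match.arg(format)
  if (format == "tss") {
    tab <- .read_tsv(path)
    need <- c("gene_id", "name", "chrom", "strand", "tss", "biotype")
    if (!all(need %in% names(tab)))
      stop("TSS table must have columns: ", paste(need, collapse = ", "))
    return(tab[, need])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(df)) stop("GTF contains no gene feature lines")
  biotype <- if (!is.null(df$gene_biotype)) df$gene_biotype
             else if (!is.null(df$gene_type)) df$gene_type else "other"
  biotype <- ifelse(biotype %in% c("protein_coding", "lincRNA"),
                    biotype, "other")
  data.frame(gene_id = df$gene_id,
             name = if (!is.null(df$gene_name)) df$gene_name else df$gene_id,
             chrom = as.character(df$seqnames),
             strand = as.character(df$strand),
             tss = ifelse(df$strand == "-", df$end, df$start),
             biotype = biotype,
             stringsAsFactors = FALSE)
}
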