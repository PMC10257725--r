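## Qualifying-variant classification and burden construction.
##
## Variant classes follow the exome-wide collapsing scheme: protein-truncating
## variants (stop-gained, splice-disruptive, frameshift) kept only at
## high-confidence LOFTEE, missense stratified by CADD phred into > 30,
## (20, 30] and [0, 20], and synonymous; only rare variants (MAF < 0.1%)
## qualify. Genes are stratified by LoF intolerance at pLI >= 0.9.

PTV_CONSEQUENCES <- c("stop_gained", "splice", "splice_disruptive", "frameshift")
BURDEN_CLASSES <- c("ptv", "missense_gt30", "missense_20_30", "missense_0_20",
                    "synonymous")
BURDEN_STRATA <- c("pli_ge_0.9", "pli_lt_0.9", "all")
RARE_MAF_MAX <- 0.001

#' Classify rare variants into burden categories
#'
#' Assigns each annotated variant to one of the five collapsing classes
#' (`ptv`, `missense_gt30`, `missense_20_30`, `missense_0_20`, `synonymous`)
#' or marks it excluded. A variant is a qualifying PTV iff its consequence is
#' stop-gained, splice-disruptive or frameshift AND LOFTEE labels it
#' high-confidence; low-confidence calls are filtered out. Missense variants
#' are binned by CADD phred, reading the bin edges literally: CADD > 30;
#' 30 >= CADD > 20; 20 >= CADD (an exact phred of 0 is kept in the lowest bin
#' so the classes partition the qualifying variants). Variants with
#' MAF >= 0.001 never qualify.
#'
#' @param variants data.frame with columns `maf`, `consequence`, `loftee`,
#'   `cadd` (as produced by [simulate_cohort()] or read from an annotation
#'   table).
#' @return factor of length `nrow(variants)` with levels the five classes;
#'   `NA` for excluded variants. The attribute `"reason"` holds a character
#'   vector saying why each excluded variant was dropped.
#' @export
classify_variants <- function(variants) {
  need <- c("maf", "consequence", "loftee", "cadd")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("missing annotation columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(variants)
  cls <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  is_mis <- variants$consequence == "missense"
  if (any(is_mis & is.na(variants$cadd)))
    stop("missense variant(s) with missing CADD score: ",
         paste(utils::head(which(is_mis & is.na(variants$cadd)), 5L),
               collapse = ", "), call. = FALSE)

  common <- variants$maf >= RARE_MAF_MAX
  reason[common] <- "maf_ge_0.001"

  ptv_eligible <- variants$consequence %in% PTV_CONSEQUENCES
  hc <- ptv_eligible & variants$loftee == "high-confidence"
  lc <- ptv_eligible & !hc
  cls[hc & !common] <- "ptv"
  reason[lc & !common] <- "loftee_not_high_confidence"

  mis <- is_mis & !common
  cls[mis & variants$cadd > 30] <- "missense_gt30"
  cls[mis & variants$cadd > 20 & variants$cadd <= 30] <- "missense_20_30"
  cls[mis & variants$cadd <= 20] <- "missense_0_20"

  syn <- variants$consequence == "synonymous" & !common
  cls[syn] <- "synonymous"

  other <- !ptv_eligible & !is_mis & variants$consequence != "synonymous"
  reason[other & !common] <- "non_coding_consequence"
  out <- factor(cls, levels = BURDEN_CLASSES)
  attr(out, "reason") <- reason
  out
}

#' Stratify genes by loss-of-function intolerance
#'
#' @param genes data.frame with columns `gene` and `pli`.
#' @return factor with levels `pli_ge_0.9` (intolerant, pLI >= 0.9) and
#'   `pli_lt_0.9`; genes with missing pLI get `NA` with a warning reporting
#'   the count (they are excluded from stratified analyses).
#' @export
assign_stratum <- function(genes) {
  pli <- genes$pli
  if (any(!is.na(pli) & (pli < 0 | pli > 1)))
    stop("pLI values must lie in [0, 1]", call. = FALSE)
  nmiss <- sum(is.na(pli))
  if (nmiss > 0)
    warning(sprintf("%d gene(s) with missing pLI excluded from strata", nmiss),
            call. = FALSE)
  factor(ifelse(pli >= 0.9, "pli_ge_0.9", "pli_lt_0.9"),
         levels = c("pli_ge_0.9", "pli_lt_0.9"))
}

#' Gene-level rare-allele burden matrix
#'
#' Aggregates rare alleles of one variant category per gene: the burden of a
#' sample in a gene is the sum of its alternate-allele dosages over the
#' qualifying variants of that class in the gene. Missing dosages contribute
#' 0 (set `impute_missing = "mean"` for per-variant mean imputation).
#'
#' @param genotypes samples x variants dosage matrix (dense or `dgCMatrix`),
#'   columns named by variant id; values 0/1/2 or `NA`.
#' @param variants annotation data.frame (`id`, `gene`, plus the columns
#'   [classify_variants()] needs).
#' @param class one of `ptv`, `missense_gt30`, `missense_20_30`,
#'   `missense_0_20`, `synonymous`.
#' @param genes optional gene data.frame; when given, variants must map to
#'   known genes (unknown ids are an error) and only that universe is kept.
#' @param carrier_indicator if `TRUE`, collapse to a 0/1 carrier indicator
#'   per gene instead of the allele-count sum.
#' @param impute_missing `"zero"` (default) or `"mean"`.
#' @return samples x genes numeric matrix (integer-valued unless mean
#'   imputation is on) for genes with at least one qualifying variant.
#' @export
gene_burden <- function(genotypes, variants, class = "ptv", genes = NULL,
                        carrier_indicator = FALSE, impute_missing = c("zero", "mean")) {
  impute_missing <- match.arg(impute_missing)
  class <- match.arg(class, BURDEN_CLASSES)
  if (!is.null(genes)) {
    unknown <- setdiff(unique(variants$gene), genes$gene)
    if (length(unknown))
      stop("variants reference unknown gene(s): ",
           paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
  }
  cls <- classify_variants(variants)
  keep <- which(!is.na(cls) & cls == class)
  gene_ids <- sort(unique(variants$gene[keep]))
  out <- matrix(0, nrow(genotypes), length(gene_ids),
                dimnames = list(rownames(genotypes), gene_ids))
  if (!length(keep)) return(out)
  G <- genotypes[, match(variants$id[keep], colnames(genotypes)), drop = FALSE]
  if (anyNA(colnames(genotypes)[match(variants$id[keep], colnames(genotypes))]))
    stop("variant id(s) absent from the genotype matrix", call. = FALSE)
  G <- fill_missing(G, impute_missing)
  gi <- factor(variants$gene[keep], levels = gene_ids)
  Ind <- Matrix::sparseMatrix(i = seq_along(keep), j = as.integer(gi), x = 1,
                              dims = c(length(keep), length(gene_ids)))
  B <- as.matrix(G %*% Ind)
  dimnames(B) <- list(rownames(genotypes), gene_ids)
  if (carrier_indicator) B <- (B >= 1) + 0
  B
}

fill_missing <- function(G, impute = "zero") {
  if (methods::is(G, "sparseMatrix")) {
    if (impute == "mean" && anyNA(G@x)) {
      means <- Matrix::colMeans(G, na.rm = TRUE)
      G <- as(G, "TsparseMatrix")
      na <- is.na(G@x)
      G@x[na] <- means[G@j[na] + 1L]
      G <- as(G, "CsparseMatrix")
    } else if (anyNA(G@x)) G@x[is.na(G@x)] <- 0
  } else {
    if (anyNA(G)) {
      if (impute == "mean") {
        means <- colMeans(G, na.rm = TRUE)
        idx <- which(is.na(G), arr.ind = TRUE)
        G[idx] <- means[idx[, 2L]]
      } else G[is.na(G)] <- 0
    }
  }
  G
}

#' Gene-set and exome-wide burden
#'
#' Sums gene-level burdens over a gene set; the whole-exome burden of a
#' stratum is the special case where the set is every gene in the stratum.
#'
#' @param burden samples x genes matrix from [gene_burden()].
#' @param gene_set character vector of gene ids, a subset of the burden
#'   columns (an empty set is an error).
#' @return named per-sample numeric vector of summed rare-allele counts.
#' @export
set_burden <- function(burden, gene_set) {
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  missing <- setdiff(gene_set, colnames(burden))
  if (length(missing))
    stop("gene set members absent from the burden matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  out <- Matrix::rowSums(burden[, gene_set, drop = FALSE])
  stats::setNames(as.numeric(out), rownames(burden))
}

#' Drop genes with too few carriers
#'
#' A carrier is a sample with burden >= 1 in the gene. Genes with fewer than
#' `min_carriers` carriers are removed (the boundary is literal: a gene with
#' exactly `min_carriers` carriers is retained).
#'
#' @param burden samples x genes burden matrix.
#' @param min_carriers minimum carrier count, default 10.
#' @return the filtered matrix; attributes `"n_removed"` and `"removed"`
#'   record the removal.
#' @export
carrier_filter <- function(burden, min_carriers = 10L) {
  if (min_carriers < 1L) stop("'min_carriers' must be >= 1", call. = FALSE)
  carriers <- Matrix::colSums(burden >= 1)
  keep <- carriers >= min_carriers
  out <- burden[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed") <- colnames(burden)[!keep]
  out
}

#' The 15 exome-wide burden categories
#'
#' @return data.frame of the 5 variant classes crossed with the 3 pLI strata
#'   (`pli_ge_0.9`, `pli_lt_0.9`, `all`), with a human-readable label.
#' @export
variant_categories <- function() {
  out <- expand.grid(class = BURDEN_CLASSES, stratum = BURDEN_STRATA,
                     stringsAsFactors = FALSE)
  out$label <- paste(out$class, out$stratum, sep = ".")
  out
}

#' Whole-exome burden for one category
#'
#' Builds the per-sample exome-wide rare-allele count for one variant class
#' within one pLI stratum of an annotated cohort.
#'
#' @param cohort a `sim_cohort` (or any list with `genotypes`, `variants`,
#'   `genes`).
#' @param class variant class (see [variant_categories()]).
#' @param stratum `"pli_ge_0.9"`, `"pli_lt_0.9"` or `"all"`.
#' @param autosomal_only drop X-linked genes (the default; the X chromosome
#'   is analysed separately).
#' @return per-sample numeric vector; attribute `"n_genes"` gives the number
#'   of contributing genes (0 means the category is untestable).
#' @export
category_burden <- function(cohort, class = "ptv", stratum = "all",
                            autosomal_only = TRUE) {
  stratum <- match.arg(stratum, BURDEN_STRATA)
  genes <- cohort$genes
  if (autosomal_only) genes <- genes[genes$chromosome_class == "autosome", , drop = FALSE]
  if (stratum != "all") {
    st <- assign_stratum(genes)
    genes <- genes[!is.na(st) & st == stratum, , drop = FALSE]
  }
  v <- cohort$variants[cohort$variants$gene %in% genes$gene, , drop = FALSE]
  B <- gene_burden(cohort$genotypes, v, class = class, genes = cohort$genes)
  if (!ncol(B)) {
    out <- rep(0, nrow(cohort$genotypes))
    attr(out, "n_genes") <- 0L
    return(out)
  }
  out <- set_burden(B, colnames(B))
  attr(out, "n_genes") <- ncol(B)
  out
}
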