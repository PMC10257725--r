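#' Covariate design matrix for grip-strength burden tests
#'
#' Builds the covariate expansion used throughout the exome analysis: top 20
#' principal components plus age, sex, age-squared, age x sex, age-squared x
#' sex, standing height, height-squared, height x sex and height-squared x
#' sex, with an intercept. The PheWAS variant of the design drops the height
#' terms (`height_terms = FALSE`); sex-stratified fits drop sex and its
#' interactions (`sex_terms = FALSE`).
#'
#' @param pheno data.frame with `age`, `sex` (0/1), `height` and PC columns.
#' @param n_pcs number of leading principal components to include (columns
#'   `PC1`..`PCn`).
#' @param sex_terms,height_terms include the sex / height blocks.
#' @return numeric matrix with an `intercept` column; an error names any
#'   constant non-intercept column (a constant column cannot be adjusted
#'   for and usually signals an upstream filtering mistake).
#' @export
covariate_design <- function(pheno, n_pcs = 20L, sex_terms = TRUE,
                             height_terms = TRUE) {
  age <- pheno$age
  X <- matrix(1, nrow(pheno), 1L, dimnames = list(NULL, "intercept"))
  if (n_pcs > 0L) {
    pc_cols <- paste0("PC", seq_len(n_pcs))
    miss <- setdiff(pc_cols, names(pheno))
    if (length(miss))
      stop("missing PC column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    X <- cbind(X, as.matrix(pheno[pc_cols]))
  }
  X <- cbind(X, age = age, age2 = age^2)
  if (sex_terms) {
    sex <- pheno$sex
    X <- cbind(X, sex = sex, age_sex = age * sex, age2_sex = age^2 * sex)
  }
  if (height_terms) {
    h <- pheno$height
    X <- cbind(X, height = h, height2 = h^2)
    if (sex_terms) X <- cbind(X, height_sex = h * pheno$sex,
                              height2_sex = h^2 * pheno$sex)
  }
  nonconst <- apply(X[, -1L, drop = FALSE], 2L,
                    function(col) stats::var(col, na.rm = TRUE) > 0)
  if (any(!nonconst))
    stop("constant covariate column(s): ",
         paste(colnames(X)[-1L][!nonconst], collapse = ", "), call. = FALSE)
  X
}

## Shared fast path: OLS of (y - offset) on [X, b] for every column b of B,
## via Frisch-Waugh projection. Equivalent to refitting the full model per
## column (verified against lm in the test suite). B may be sparse.
ols_scan <- function(B, y, X, offset = NULL) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 1L)
  if (!is.null(offset)) y <- y - offset
  ok <- !is.na(y) & stats::complete.cases(as.matrix(X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n < p + 2L) stop("too few complete observations for the design", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p)
    stop("singular covariate design; collinear column(s): ",
         paste(colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]], collapse = ", "),
         call. = FALSE)
  Q <- qr.Q(qr_x)
  ry <- y - Q %*% crossprod(Q, y)
  QtB <- as.matrix(Matrix::crossprod(Q, B))
  bb <- as.numeric(Matrix::colSums(B^2)) - colSums(QtB^2)
  by <- as.numeric(Matrix::crossprod(B, ry))
  yy <- sum(ry^2)
  df <- n - p - 1L
  testable <- bb > max(1e-10, 1e-12 * n)
  beta <- se <- pval <- rep(NA_real_, ncol(B))
  beta[testable] <- by[testable] / bb[testable]
  rss <- yy - beta[testable] * by[testable]
  se[testable] <- sqrt(pmax(rss, 0) / df / bb[testable])
  tt <- beta[testable] / se[testable]
  pval[testable] <- 2 * stats::pt(-abs(tt), df)
  list(beta = beta, se = se, p = pval, df = df, n = n,
       n_carriers = as.numeric(Matrix::colSums(B >= 1)),
       testable = testable)
}

#' Linear burden association test
#'
#' Ordinary least squares of the (optionally offset-corrected) continuous
#' phenotype on a rare-allele burden plus the covariate design; the burden
#' effect is reported in kg per rare allele with a two-sided t-test at the
#' residual degrees of freedom. A polygenic model offset (for example a
#' leave-one-chromosome-out predictor from [loco_offset()]) is subtracted
#' from the response before fitting, so adding any constant to the offset is
#' absorbed by the intercept and leaves the burden coefficient unchanged.
#'
#' @param burden per-sample burden vector (>= 2 distinct values required).
#' @param phenotype continuous outcome in kg.
#' @param design covariate matrix from [covariate_design()].
#' @param offset optional per-sample offset vector.
#' @return object of class `burden_fit` with elements `beta`, `se`, `p`,
#'   `n`, `n_carriers`, `df`.
#' @export
fit_burden_lm <- function(burden, phenotype, design, offset = NULL) {
  if (length(unique(burden[!is.na(phenotype)])) < 2L)
    stop("burden has no variation in the analysis sample", call. = FALSE)
  s <- ols_scan(matrix(burden, ncol = 1L), phenotype, design, offset)
  if (!s$testable[1L])
    stop("burden has no variation after covariate projection", call. = FALSE)
  structure(list(beta = s$beta[1L], se = s$se[1L], p = s$p[1L],
                 df = s$df, n = s$n, n_carriers = s$n_carriers[1L]),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("Burden association (linear model)\n")
  cat(sprintf("  n = %d, carriers = %d\n", x$n, as.integer(x$n_carriers)))
  cat(sprintf("  beta = %.4f kg/allele (SE %.4f), two-sided p = %.3g\n",
              x$beta, x$se, x$p))
  invisible(x)
}

#' @export
coef.burden_fit <- function(object, ...) c(burden = object$beta)

#' Bonferroni significance threshold
#'
#' alpha / m, reported at 2 significant figures in the conventional printed
#' style (e.g. 0.05/15 = 0.0033, 0.05/15786 = 3.2e-6). The unrounded value
#' is kept in the `"raw"` attribute and is what the scans use to declare
#' significance.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @param digits significant figures for the printed value.
#' @return the rounded threshold, with attribute `"raw"` = alpha/m.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m, digits = 2L) {
  if (m < 1L) stop("'m' must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  structure(signif(alpha / m, digits), raw = alpha / m)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()] with
#' `method = "BH"`, which enforces the step-up monotonicity).
#'
#' @param pvalues numeric p-values in (0, 1].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Whole-exome burden scan over the 15 variant categories
#'
#' Tests the association of hand grip strength with each of the 15
#' exome-wide burdens: {PTV, CADD > 30 missense, CADD 20-30 missense,
#' CADD 0-20 missense, synonymous} crossed with {pLI >= 0.9, pLI < 0.9, all
#' genes}. Significance is declared at alpha / 15. Categories with no
#' qualifying variants are flagged untestable rather than dropped.
#'
#' @param cohort a `sim_cohort` (or compatible list).
#' @param alpha family-wise error rate, default 0.05.
#' @param offset optional per-sample model offset.
#' @param apply_qc run [apply_exclusions()] before testing (default `TRUE`).
#' @return data.frame of class `exome_scan`: one row per category with
#'   `class`, `stratum`, `n_genes`, `n_carriers`, `beta`, `se`, `p`,
#'   `significant`, `untestable`; attribute `"threshold"` is the
#'   [bonferroni_threshold()].
#' @export
run_exome_scan <- function(cohort, alpha = 0.05, offset = NULL,
                           apply_qc = TRUE) {
  pheno <- cohort$phenotypes
  keep <- seq_len(nrow(pheno))
  if (apply_qc) {
    pheno <- apply_exclusions(pheno)
    keep <- match(pheno$sample, cohort$phenotypes$sample)
  } else pheno$hgs <- derive_hgs(pheno$hgs_left, pheno$hgs_right)
  design <- covariate_design(pheno)
  if (!is.null(offset)) offset <- offset[keep]
  cats <- variant_categories()
  res <- cats
  res$n_genes <- res$n_carriers <- NA_integer_
  res$beta <- res$se <- res$p <- NA_real_
  res$untestable <- FALSE
  for (k in seq_len(nrow(cats))) {
    b <- category_burden(cohort, cats$class[k], cats$stratum[k])
    res$n_genes[k] <- attr(b, "n_genes")
    b <- b[keep]
    res$n_carriers[k] <- sum(b >= 1)
    if (res$n_genes[k] == 0L || length(unique(b)) < 2L) {
      res$untestable[k] <- TRUE
      next
    }
    f <- fit_burden_lm(b, pheno$hgs, design, offset)
    res$beta[k] <- f$beta; res$se[k] <- f$se; res$p[k] <- f$p
  }
  thr <- bonferroni_threshold(alpha, nrow(cats))
  res$significant <- !res$untestable & res$p < attr(thr, "raw")
  attr(res, "threshold") <- thr
  class(res) <- c("exome_scan", "data.frame")
  res
}

#' @export
print.exome_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Whole-exome burden scan: %d categories, threshold p < %g\n",
              nrow(x), as.numeric(thr)))
  print.data.frame(x[, c("class", "stratum", "n_genes", "n_carriers",
                         "beta", "se", "p", "significant")], digits = 3)
  invisible(x)
}

#' Gene-level burden scan
#'
#' Per-gene linear burden tests with Bonferroni (0.05 / genes tested) and
#' Benjamini-Hochberg adjustment. Apply [carrier_filter()] to the burden
#' matrix first (the scan does it for you with `min_carriers`).
#'
#' @param burden samples x genes burden matrix.
#' @param phenotype continuous outcome (kg).
#' @param design covariate matrix from [covariate_design()].
#' @param offset `NULL`, a per-sample vector, or a named list of per-sample
#'   vectors keyed by chromosome (leave-one-chromosome-out offsets); with a
#'   list, supply `gene_chrom`.
#' @param gene_chrom named chromosome per gene (required for LOCO offsets).
#' @param min_carriers carrier filter threshold (default 10).
#' @param alpha family-wise error rate.
#' @return data.frame of class `gene_scan`: `gene`, `n_carriers`, `beta`,
#'   `se`, `p`, `p_bonf`, `q_bh`, `sig_bonf`, `sig_fdr`; attributes
#'   `"threshold"` (raw and printed) and `"n_filtered"`.
#' @export
run_gene_scan <- function(burden, phenotype, design, offset = NULL,
                          gene_chrom = NULL, min_carriers = 10L, alpha = 0.05) {
  burden <- carrier_filter(burden, min_carriers)
  n_filtered <- attr(burden, "n_removed")
  m <- ncol(burden)
  if (!m) stop("no genes pass the carrier filter", call. = FALSE)
  if (is.list(offset) && !is.null(names(offset))) {
    if (is.null(gene_chrom))
      stop("per-chromosome offsets need 'gene_chrom'", call. = FALSE)
    chroms <- gene_chrom[colnames(burden)]
    parts <- lapply(split(seq_len(m), chroms), function(idx) {
      cc <- chroms[idx[1L]]
      if (!cc %in% names(offset))
        stop("no offset for chromosome ", cc, call. = FALSE)
      s <- ols_scan(burden[, idx, drop = FALSE], phenotype, design, offset[[cc]])
      cbind(idx = idx, beta = s$beta, se = s$se, p = s$p,
            n_carriers = s$n_carriers)
    })
    tab <- do.call(rbind, parts)
    tab <- tab[order(tab[, "idx"]), , drop = FALSE]
    s <- list(beta = tab[, "beta"], se = tab[, "se"], p = tab[, "p"],
              n_carriers = tab[, "n_carriers"])
  } else {
    s <- ols_scan(burden, phenotype, design, offset)
  }
  thr <- bonferroni_threshold(alpha, m)
  ok <- !is.na(s$p)
  q <- rep(NA_real_, m); q[ok] <- bh_fdr(s$p[ok])
  res <- data.frame(gene = colnames(burden),
                    n_carriers = as.integer(s$n_carriers),
                    beta = s$beta, se = s$se, p = s$p,
                    p_bonf = pmin(1, m * s$p), q_bh = q,
                    sig_bonf = ok & s$p < attr(thr, "raw"),
                    sig_fdr = ok & q < alpha,
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- thr
  attr(res, "n_filtered") <- n_filtered
  class(res) <- c("gene_scan", "data.frame")
  res
}

#' @export
print.gene_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Gene-level burden scan: %d genes, Bonferroni p < %g (%d filtered by carriers)\n",
              nrow(x), as.numeric(thr), attr(x, "n_filtered")))
  top <- x[order(x$p), , drop = FALSE]
  print.data.frame(utils::head(top, 10L), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Sex-stratified burden scan with heterogeneity test
#'
#' Fits the burden model separately in males and females, dropping sex and
#' its interaction terms from the design, and reports a between-sex
#' heterogeneity z-test, z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2).
#'
#' @param burden per-sample burden vector or samples x genes matrix.
#' @param phenotype continuous outcome.
#' @param pheno phenotype data.frame (for the per-stratum design).
#' @param min_n minimum stratum size; smaller strata are flagged untestable.
#' @param min_carriers carrier filter within each stratum-tested unit.
#' @return data.frame with per-unit male and female effects and the
#'   heterogeneity `het_z` / `het_p`; untestable strata carry `NA`.
#' @export
sex_stratified_scan <- function(burden, phenotype, pheno, min_n = 50L,
                                min_carriers = 1L) {
  if (is.null(dim(burden))) burden <- matrix(burden, ncol = 1L,
                                             dimnames = list(NULL, "burden"))
  fit_stratum <- function(sx) {
    idx <- which(pheno$sex == sx)
    if (length(idx) < min_n) return(NULL)
    X <- covariate_design(pheno[idx, , drop = FALSE], sex_terms = FALSE)
    ols_scan(burden[idx, , drop = FALSE], phenotype[idx], X)
  }
  m <- fit_stratum(1L); f <- fit_stratum(0L)
  blank <- rep(NA_real_, ncol(burden))
  get <- function(s, fld) if (is.null(s)) blank else s[[fld]]
  out <- data.frame(unit = colnames(burden),
                    beta_m = get(m, "beta"), se_m = get(m, "se"), p_m = get(m, "p"),
                    beta_f = get(f, "beta"), se_f = get(f, "se"), p_f = get(f, "p"),
                    stringsAsFactors = FALSE)
  out$het_z <- (out$beta_m - out$beta_f) / sqrt(out$se_m^2 + out$se_f^2)
  out$het_p <- 2 * stats::pnorm(-abs(out$het_z))
  attr(out, "untestable") <- c(male = is.null(m), female = is.null(f))
  out
}

#' X-chromosome burden scan
#'
#' Removes samples flagged with sex-chromosome aneuploidy, builds the burden
#' for X-linked genes only, and runs the gene-level scan. Male X dosages are
#' haploid in the genotypes; by default they are coded 0/2 (a hemizygous
#' allele counted like a homozygote), with 0/1 available.
#'
#' @param cohort a `sim_cohort` with an X-linked gene fraction > 0.
#' @param class variant class to collapse.
#' @param male_dosage `"0/2"` (default) or `"0/1"`.
#' @param min_carriers,alpha as in [run_gene_scan()].
#' @return a `gene_scan` data.frame over X genes; attribute
#'   `"n_aneuploid_removed"`.
#' @export
xchrom_scan <- function(cohort, class = "ptv", male_dosage = c("0/2", "0/1"),
                        min_carriers = 10L, alpha = 0.05) {
  male_dosage <- match.arg(male_dosage)
  xgenes <- cohort$genes[cohort$genes$chromosome_class == "X", , drop = FALSE]
  if (!nrow(xgenes)) stop("no X-chromosome genes in the cohort", call. = FALSE)
  pheno <- apply_exclusions(cohort$phenotypes)
  aneu <- if ("sex_aneuploidy" %in% names(pheno)) pheno$sex_aneuploidy == 1 else FALSE
  n_aneu <- sum(aneu)
  pheno <- pheno[!aneu, , drop = FALSE]
  keep <- match(pheno$sample, cohort$phenotypes$sample)
  v <- cohort$variants[cohort$variants$gene %in% xgenes$gene, , drop = FALSE]
  G <- cohort$genotypes[keep, , drop = FALSE]
  B <- gene_burden(G, v, class = class, genes = cohort$genes)
  if (male_dosage == "0/2") B[pheno$sex == 1L, ] <- 2 * B[pheno$sex == 1L, ]
  design <- covariate_design(pheno)
  res <- run_gene_scan(B, pheno$hgs, design, min_carriers = min_carriers,
                       alpha = alpha)
  attr(res, "n_aneuploid_removed") <- n_aneu
  res
}

#' Single-variant GWAS of common variants
#'
#' Additive-dosage linear association of every common variant (MAF > 0.01)
#' with the phenotype under the full covariate design; the summary statistics
#' feed polygenic-score weight building. Monomorphic variants are skipped and
#' logged.
#'
#' @param genotypes samples x variants dosage matrix (dense).
#' @param variant_info data.frame with `id`, `chrom`, `maf` (and optionally
#'   `pos`, alleles) matching the genotype columns.
#' @param phenotype continuous outcome.
#' @param design covariate matrix.
#' @param offset optional per-sample offset.
#' @param maf_min exclusive lower MAF bound, default 0.01.
#' @return data.frame `id`, `chrom`, `maf`, `beta`, `se`, `p`; attribute
#'   `"skipped"` lists monomorphic variant ids, `"n_excluded_maf"` counts the
#'   MAF exclusions.
#' @export
single_variant_gwas <- function(genotypes, variant_info, phenotype, design,
                                offset = NULL, maf_min = 0.01) {
  keep <- variant_info$maf > maf_min
  n_excl <- sum(!keep)
  vi <- variant_info[keep, , drop = FALSE]
  G <- genotypes[, match(vi$id, colnames(genotypes)), drop = FALSE]
  s <- ols_scan(G, phenotype, design, offset)
  skipped <- vi$id[!s$testable]
  res <- data.frame(id = vi$id, chrom = vi$chrom, maf = vi$maf,
                    beta = s$beta, se = s$se, p = s$p,
                    stringsAsFactors = FALSE)
  res <- res[s$testable, , drop = FALSE]
  attr(res, "skipped") <- skipped
  attr(res, "n_excluded_maf") <- n_excl
  res
}

#' Leave-one-chromosome-out ridge offsets
#'
#' A streamlined stand-in for whole-genome-regression polygenic offsets: the
#' covariate-residualized phenotype is predicted by ridge regression from all
#' common variants excluding the target chromosome, giving one offset vector
#' per chromosome with, by construction, zero weight on the held-out
#' chromosome. The ridge penalty is chosen once by k-fold cross-validation on
#' the full variant set, then each per-chromosome model is refit at that
#' penalty in closed form.
#'
#' @param genotypes samples x common-variants dosage matrix.
#' @param chrom chromosome label per variant (>= 2 distinct required).
#' @param phenotype continuous outcome.
#' @param design covariate matrix; the offset predicts the residual of the
#'   phenotype on this design.
#' @param k folds for cross-validation.
#' @param lambda_grid ridge penalties to search (default a log grid scaled
#'   by the variant count).
#' @return object of class `loco_offset`: list with `offsets` (named list of
#'   per-sample vectors, one per chromosome), `lambda`, `cv_mse`.
#' @export
loco_offset <- function(genotypes, chrom, phenotype, design, k = 5L,
                        lambda_grid = NULL) {
  chrom <- as.character(chrom)
  if (length(unique(chrom)) < 2L)
    stop("LOCO offsets need common variants on >= 2 chromosomes", call. = FALSE)
  ok <- !is.na(phenotype) & stats::complete.cases(as.matrix(design))
  if (!all(ok)) stop("missing phenotype/covariates; complete cases required",
                     call. = FALSE)
  qr_x <- qr(design)
  yr <- qr.resid(qr_x, phenotype)
  ctr <- colMeans(genotypes)
  Xc <- sweep(genotypes, 2L, ctr)
  m <- ncol(Xc); n <- nrow(Xc)
  if (is.null(lambda_grid)) lambda_grid <- m * 10^seq(-2, 4, length.out = 25L)

  folds <- rep_len(seq_len(k), n)[sample.int(n)]
  cv_mse <- numeric(length(lambda_grid))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    XtX <- crossprod(Xc[tr, , drop = FALSE])
    Xty <- crossprod(Xc[tr, , drop = FALSE], yr[tr])
    eg <- eigen(XtX, symmetric = TRUE)
    Vty <- crossprod(eg$vectors, Xty)
    for (j in seq_along(lambda_grid)) {
      b <- eg$vectors %*% (Vty / (eg$values + lambda_grid[j]))
      pred <- Xc[!tr, , drop = FALSE] %*% b
      cv_mse[j] <- cv_mse[j] + sum((yr[!tr] - pred)^2)
    }
  }
  cv_mse <- cv_mse / n
  lambda <- lambda_grid[which.min(cv_mse)]

  XtX_all <- crossprod(Xc)
  Xty_all <- crossprod(Xc, yr)
  offsets <- list()
  for (cc in unique(chrom)) {
    idx <- which(chrom != cc)
    XtX <- XtX_all[idx, idx, drop = FALSE]
    b <- solve(XtX + diag(lambda, length(idx)), Xty_all[idx, , drop = FALSE])
    offsets[[cc]] <- as.numeric(Xc[, idx, drop = FALSE] %*% b)
  }
  structure(list(offsets = offsets, lambda = lambda,
                 cv_mse = stats::setNames(cv_mse, signif(lambda_grid, 3))),
            class = "loco_offset")
}

#' @export
print.loco_offset <- function(x, ...) {
  cat(sprintf("LOCO ridge offsets for %d chromosomes (lambda = %.3g)\n",
              length(x$offsets), x$lambda))
  invisible(x)
}

#' Overlap of reported GWAS lead variants with burden-tested genes
#'
#' Maps every gene whose body intersects a closed +/- `window` interval
#' around each reported lead variant (GWAS-Catalog style), joins the
#' gene-level burden results, and applies a Bonferroni threshold over the
#' number of overlap genes that were burden-tested.
#'
#' @param lead_variants data.frame `rsid`, `chrom`, `pos`, `maf`; leads with
#'   MAF <= `maf_min` are dropped first (count reported).
#' @param genes gene annotation data.frame (`gene`, `chrom`, `start`, `end`).
#' @param gene_results a [run_gene_scan()] result (or any data.frame with
#'   `gene` and `p`).
#' @param window half-width in bases, default 500 kb.
#' @param maf_min exclusive MAF bound for leads.
#' @param alpha family-wise error rate.
#' @return list with `overlap` (gene, lead rsid, distance, p, significant),
#'   `n_leads_kept`, `n_genes_overlap`, `n_genes_tested`, `threshold`.
#' @export
overlap_analysis <- function(lead_variants, genes, gene_results,
                             window = 5e5, maf_min = 0.01, alpha = 0.05) {
  lv <- lead_variants[lead_variants$maf > maf_min, , drop = FALSE]
  if (!nrow(lv)) stop("no lead variants pass the MAF filter", call. = FALSE)
  if (!any(as.character(lv$chrom) %in% as.character(genes$chrom)))
    stop("chromosome labels of lead variants and genes do not match",
         call. = FALSE)
  hits <- list()
  for (i in seq_len(nrow(lv))) {
    g <- genes[as.character(genes$chrom) == as.character(lv$chrom[i]) &
                 genes$end >= lv$pos[i] - window &
                 genes$start <= lv$pos[i] + window, , drop = FALSE]
    if (nrow(g))
      hits[[length(hits) + 1L]] <-
        data.frame(gene = g$gene, rsid = lv$rsid[i],
                   distance = pmax(0, pmax(g$start - lv$pos[i],
                                           lv$pos[i] - g$end)),
                   stringsAsFactors = FALSE)
  }
  ov <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(0), rsid = character(0), distance = numeric(0))
  ov <- ov[!duplicated(ov$gene), , drop = FALSE]
  ov$p <- gene_results$p[match(ov$gene, gene_results$gene)]
  n_tested <- sum(!is.na(ov$p))
  if (n_tested) {
    thr <- bonferroni_threshold(alpha, n_tested)
    ov$significant <- !is.na(ov$p) & ov$p < attr(thr, "raw")
  } else {
    thr <- NA_real_
    ov$significant <- logical(nrow(ov))
  }
  list(overlap = ov, n_leads_kept = nrow(lv), n_genes_overlap = nrow(ov),
       n_genes_tested = n_tested, threshold = thr)
}
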