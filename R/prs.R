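#' Carrier-based holdout split for polygenic-score building
#'
#' Reserves an evaluation set consisting of every carrier of a qualifying
#' PTV in the listed Mendelian disease genes plus an equal-sized random
#' sample of non-carriers; the remaining samples form the training set used
#' for the weight-building GWAS. The two sets are disjoint by construction,
#' and the split is reproducible given the seed.
#'
#' @param burden samples x genes qualifying-PTV burden matrix (from
#'   [gene_burden()]), rows named by sample id.
#' @param mendelian_genes character vector of gene ids (the inheritance list)
#'   or a data.frame with a `gene` column.
#' @param seed integer seed for the non-carrier draw.
#' @return list with `training` and `evaluation` character vectors of sample
#'   ids and the `carriers` subset of the evaluation set.
#' @export
holdout_split <- function(burden, mendelian_genes, seed = 1L) {
  if (is.data.frame(mendelian_genes)) mendelian_genes <- mendelian_genes$gene
  genes <- intersect(mendelian_genes, colnames(burden))
  samples <- rownames(burden)
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(burden)))
  carrier <- if (length(genes))
    Matrix::rowSums(burden[, genes, drop = FALSE] >= 1) > 0 else
      rep(FALSE, nrow(burden))
  carriers <- samples[carrier]
  noncarriers <- samples[!carrier]
  if (length(noncarriers) < length(carriers))
    stop("fewer non-carriers than carriers: cannot build a matched evaluation set",
         call. = FALSE)
  set.seed(seed)
  matched <- sample(noncarriers, length(carriers))
  evaluation <- c(carriers, matched)
  list(training = setdiff(samples, evaluation),
       evaluation = evaluation, carriers = carriers)
}

#' Build polygenic-score weights by p-value thresholding
#'
#' Converts training-set GWAS summary statistics into a weight table: keep
#' variants with p below the threshold, weight = the estimated additive beta
#' (kg per effect allele). This is a transparent stand-in for posterior
#' shrinkage weight builders; externally produced weight files with the same
#' columns drop straight into [prs_score()].
#'
#' @param gwas_summary data.frame from [single_variant_gwas()] (needs `id`,
#'   `chrom`, `beta`, `p`; `effect_allele` is carried through if present).
#' @param p_threshold inclusion threshold; 1 keeps every variant.
#' @return data.frame of class `prs_weights`: `id`, `chrom`,
#'   `effect_allele`, `weight`.
#' @export
build_weights <- function(gwas_summary, p_threshold = 1) {
  keep <- gwas_summary$p < p_threshold | p_threshold >= 1
  if (!any(keep))
    stop("no variants pass p < ", p_threshold,
         "; use a larger threshold", call. = FALSE)
  out <- data.frame(id = gwas_summary$id[keep],
                    chrom = as.character(gwas_summary$chrom[keep]),
                    effect_allele = if ("effect_allele" %in% names(gwas_summary))
                      gwas_summary$effect_allele[keep] else "ALT",
                    weight = gwas_summary$beta[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_weights", "data.frame")
  out
}

#' Score samples with a polygenic weight table
#'
#' Per-chromosome linear combinations of dosages and weights, summed over
#' chromosomes 1-22 into the final score. Weights whose effect allele is the
#' reference allele of the genotype record are applied to the reflected
#' dosage (2 - d); variants absent from the genotype matrix are skipped and
#' counted.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param weights a [build_weights()] table (or external file with the same
#'   columns).
#' @param variant_info optional data.frame (`id`, `ref`, `alt`) for effect-
#'   allele resolution; without it the effect allele is taken as ALT.
#' @return list of class `prs_score`: `total` per-sample score, `by_chrom`
#'   named matrix of per-chromosome partial scores, `n_skipped`.
#' @export
prs_score <- function(genotypes, weights, variant_info = NULL) {
  found <- weights$id %in% colnames(genotypes)
  n_skipped <- sum(!found)
  w <- weights[found, , drop = FALSE]
  n <- nrow(genotypes)
  chroms <- sort(unique(w$chrom))
  by_chrom <- matrix(0, n, length(chroms),
                     dimnames = list(rownames(genotypes), chroms))
  for (cc in chroms) {
    wc <- w[w$chrom == cc, , drop = FALSE]
    G <- genotypes[, wc$id, drop = FALSE]
    if (!is.null(variant_info)) {
      vi <- variant_info[match(wc$id, variant_info$id), , drop = FALSE]
      flip <- !is.na(vi$ref) & wc$effect_allele == vi$ref
      if (any(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
    }
    by_chrom[, cc] <- as.numeric(as.matrix(G) %*% wc$weight)
  }
  structure(list(total = rowSums(by_chrom), by_chrom = by_chrom,
                 n_skipped = n_skipped),
            class = "prs_score")
}

#' @export
print.prs_score <- function(x, ...) {
  cat(sprintf("Polygenic score: %d samples, %d chromosomes (%d variants skipped)\n",
              length(x$total), ncol(x$by_chrom), x$n_skipped))
  print(summary(x$total))
  invisible(x)
}

#' Additivity model of polygenic score and rare PTV carrier status
#'
#' Least-squares fit of grip strength on the standardized polygenic score,
#' dominant- and recessive-gene PTV carrier indicators, their interactions
#' with the score, and the full grip-strength covariate design:
#'
#'   HGS ~ PRS_std + carrier_dom + carrier_rec +
#'         PRS_std:carrier_dom + PRS_std:carrier_rec + covariates
#'
#' The score is standardized on the analysis (evaluation) sample. A carrier
#' category with no carriers is dropped with a warning. The additivity
#' verdict is read off the interaction p-values: non-significant
#' interactions mean the common- and rare-variant contributions combine
#' additively.
#'
#' @param hgs continuous outcome (kg).
#' @param prs raw polygenic score (standardized internally).
#' @param carrier_dom,carrier_rec 0/1 carrier indicators (a sample carrying
#'   both kinds keeps both set).
#' @param design covariate matrix from [covariate_design()].
#' @param alpha level for the interaction verdict.
#' @return object of class `additivity_fit` with `coefficients` (beta, se,
#'   t, p for the five model terms), `additive` (logical verdict),
#'   `dropped`, `n`.
#' @export
fit_additivity <- function(hgs, prs, carrier_dom, carrier_rec, design,
                           alpha = 0.05) {
  ok <- !is.na(hgs) & !is.na(prs) & stats::complete.cases(as.matrix(design))
  prs_std <- (prs - mean(prs[ok])) / stats::sd(prs[ok])
  terms <- list(PRS_std = prs_std,
                carrier_dom = carrier_dom,
                carrier_rec = carrier_rec,
                PRS_std_x_dom = prs_std * carrier_dom,
                PRS_std_x_rec = prs_std * carrier_rec)
  dropped <- character(0)
  if (sum(carrier_dom[ok]) == 0) {
    warning("no dominant-gene carriers; dropping the term", call. = FALSE)
    terms$carrier_dom <- terms$PRS_std_x_dom <- NULL
    dropped <- c(dropped, "carrier_dom", "PRS_std_x_dom")
  }
  if (sum(carrier_rec[ok]) == 0) {
    warning("no recessive-gene carriers; dropping the term", call. = FALSE)
    terms$carrier_rec <- terms$PRS_std_x_rec <- NULL
    dropped <- c(dropped, "carrier_rec", "PRS_std_x_rec")
  }
  X <- cbind(as.matrix(design), do.call(cbind, terms))
  colnames(X) <- c(colnames(design), names(terms))
  Xo <- X[ok, , drop = FALSE]; yo <- hgs[ok]
  qr_x <- qr(Xo)
  if (qr_x$rank < ncol(Xo)) stop("singular additivity design", call. = FALSE)
  cf <- qr.coef(qr_x, yo)
  res <- qr.resid(qr_x, yo)
  df <- length(yo) - ncol(Xo)
  sigma2 <- sum(res^2) / df
  XtXinv <- solve(crossprod(Xo))
  ses <- stats::setNames(sqrt(sigma2 * diag(XtXinv)), colnames(Xo))
  idx <- names(terms)
  tt <- cf[idx] / ses[idx]
  tab <- data.frame(term = idx, beta = unname(cf[idx]), se = unname(ses[idx]),
                    t = unname(tt), p = unname(2 * stats::pt(-abs(tt), df)),
                    stringsAsFactors = FALSE)
  inter <- tab[grepl("_x_", tab$term), , drop = FALSE]
  structure(list(coefficients = tab, additive = all(inter$p >= alpha),
                 interaction_p = stats::setNames(inter$p, inter$term),
                 dropped = dropped, n = sum(ok), df = df,
                 prs_sd = stats::sd(prs[ok])),
            class = "additivity_fit")
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat(sprintf("PRS x rare-carrier additivity model (n = %d)\n", x$n))
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat(if (x$additive)
    "No significant PRS x carrier interaction: effects combine additively.\n"
    else "PRS x carrier interaction detected: effects deviate from additivity.\n")
  invisible(x)
}

#' @export
coef.additivity_fit <- function(object, ...)
  stats::setNames(object$coefficients$beta, object$coefficients$term)
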