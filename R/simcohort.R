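#' Specification of a synthetic exome cohort
#'
#' Builds a validated parameter object for [simulate_cohort()]. The generator
#' emulates the statistical structure a rare-variant burden analysis of hand
#' grip strength assumes: rare coding variants (MAF < 0.1\%) of classes
#' PTV / missense / synonymous with per-class CADD phred scores and LOFTEE
#' confidence, per-gene pLI constraint scores, common variants (MAF > 0.01)
#' for polygenic scores and offsets, a grip-strength model with age/sex/height
#' covariate effects, injected per-gene burden effects on the kg scale, a
#' polygenic component, and exclusion flags.
#'
#' @param n_samples number of individuals.
#' @param n_genes number of autosomal/X genes carrying rare variants.
#' @param variants_per_gene expected number of rare variants per gene; the
#'   realised count is `1 + rpois(variants_per_gene - 1)` so every gene has at
#'   least one variant.
#' @param rare_maf_range length-2 numeric, MAF bounds for rare variants;
#'   the upper bound must be < 0.001 (the qualifying-variant ceiling).
#' @param n_common_variants number of common variants (PRS / offset material).
#' @param common_maf_range length-2 numeric, MAF bounds for common variants;
#'   lower bound must be > 0.01.
#' @param pli_mixture fraction of genes drawn from the LoF-intolerant
#'   component (pLI >= 0.9). Default 0.18, roughly the gnomAD proportion.
#' @param class_proportions named fractions over `ptv`, `missense`,
#'   `synonymous`; defaults follow the observed exome-wide class mix
#'   (about 6.3\% PTV, 59\% missense, 34.5\% synonymous).
#' @param effect_table named numeric, per-gene phenotypic effect in kg per
#'   qualifying (high-confidence) PTV allele. Names must be simulated genes
#'   (`gene0001`, ...). Empty by default (global null).
#' @param polygenic_h2 fraction of the non-covariate residual variance
#'   explained by the common-variant polygenic component.
#' @param covariate_effects named list of coefficients for the grip-strength
#'   mean model on centred covariates: `intercept` (kg), `age` (kg/yr,
#'   age centred at 55), `age2`, `sex` (kg, male vs female), `height`
#'   (kg/cm, centred at the sex-specific mean), `height2`, `age_sex`.
#' @param noise_sd SD in kg of the residual (polygenic + environmental) part
#'   of grip strength; see Details.
#' @param hand_jitter_frac hand-specific measurement jitter SD as a fraction
#'   of the latent phenotype SD (both hands receive independent jitter and
#'   the analysis phenotype is their maximum).
#' @param prevalence_table named numeric in (0,1): binary traits simulated by
#'   [simulate_binary_traits()] at cohort build time.
#' @param missing_rate fraction of rare-variant dosages set missing.
#' @param x_gene_fraction fraction of genes placed on chromosome X.
#' @param ld_rho autoregressive correlation of common-variant haplotypes
#'   within LD blocks (0 = independent variants).
#' @param ld_block_size number of common variants per LD block.
#' @param exclusion_rates named rates for the confounding-diagnosis and QC
#'   flags (`copd`, `brachial_plexus`, `arm_injury`, `sex_aneuploidy`),
#'   defaults mirroring their population frequencies.
#' @param loftee_low_conf_rate fraction of PTV-consequence variants labelled
#'   low-confidence by the LOFTEE emulation (these never qualify).
#' @param seed integer RNG seed; the same spec (including seed) reproduces
#'   the cohort bit for bit.
#'
#' @details The phenotypic variance decomposition is a generator choice, not
#' an estimate: `noise_sd` is the SD of the combined polygenic + environmental
#' residual and `polygenic_h2` its polygenic fraction, so the polygenic
#' component has SD `noise_sd * sqrt(h2 / (1 - h2))` relative to environmental
#' noise of SD `noise_sd * sqrt(1 - h2) / sqrt(1 - h2)`; equivalently
#' polygenic SD^2 / (polygenic SD^2 + noise SD^2) = `polygenic_h2`.
#'
#' @return an object of class `sim_spec`.
#' @seealso [simulate_cohort()]
#' @export
sim_spec <- function(n_samples = 1000L,
                     n_genes = 100L,
                     variants_per_gene = 8,
                     rare_maf_range = c(5e-5, 5e-4),
                     n_common_variants = 200L,
                     common_maf_range = c(0.05, 0.5),
                     pli_mixture = 0.18,
                     class_proportions = c(ptv = 0.063, missense = 0.592,
                                           synonymous = 0.345),
                     effect_table = numeric(0),
                     polygenic_h2 = 0.3,
                     covariate_effects = list(intercept = 30, age = -0.25,
                                              age2 = -0.004, sex = 11,
                                              height = 0.3, height2 = 0.002,
                                              age_sex = -0.05),
                     noise_sd = 6,
                     hand_jitter_frac = 0.05,
                     prevalence_table = numeric(0),
                     missing_rate = 0,
                     x_gene_fraction = 0,
                     ld_rho = 0,
                     ld_block_size = 10L,
                     exclusion_rates = c(copd = 0.0064,
                                         brachial_plexus = 0.00012,
                                         arm_injury = 0.019,
                                         sex_aneuploidy = 0.001),
                     loftee_low_conf_rate = 0.1,
                     seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_genes = as.integer(n_genes),
               variants_per_gene = variants_per_gene,
               rare_maf_range = as.numeric(rare_maf_range),
               n_common_variants = as.integer(n_common_variants),
               common_maf_range = as.numeric(common_maf_range),
               pli_mixture = pli_mixture,
               class_proportions = class_proportions,
               effect_table = effect_table,
               polygenic_h2 = polygenic_h2,
               covariate_effects = covariate_effects,
               noise_sd = noise_sd,
               hand_jitter_frac = hand_jitter_frac,
               prevalence_table = prevalence_table,
               missing_rate = missing_rate,
               x_gene_fraction = x_gene_fraction,
               ld_rho = ld_rho,
               ld_block_size = as.integer(ld_block_size),
               exclusion_rates = exclusion_rates,
               loftee_low_conf_rate = loftee_low_conf_rate,
               seed = as.integer(seed))
  class(spec) <- "sim_spec"
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  chk_frac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("'%s' must be a fraction in [0, 1]", nm), call. = FALSE)
  }
  if (spec$n_samples < 1L) stop("'n_samples' must be >= 1", call. = FALSE)
  if (spec$n_genes < 1L) stop("'n_genes' must be >= 1", call. = FALSE)
  r <- spec$rare_maf_range
  if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[1] > r[2])
    stop("'rare_maf_range' must be an increasing positive pair", call. = FALSE)
  if (r[2] >= 0.001)
    stop("'rare_maf_range' upper bound must be < 0.001 (rare variants are MAF < 0.1%)",
         call. = FALSE)
  cm <- spec$common_maf_range
  if (length(cm) != 2L || cm[1] <= 0.01 || cm[1] > cm[2] || cm[2] > 0.5)
    stop("'common_maf_range' must lie in (0.01, 0.5]", call. = FALSE)
  chk_frac(spec$pli_mixture, "pli_mixture")
  cp <- spec$class_proportions
  if (!all(c("ptv", "missense", "synonymous") %in% names(cp)))
    stop("'class_proportions' must name ptv, missense, synonymous", call. = FALSE)
  chk_frac(cp, "class_proportions")
  if (abs(sum(cp) - 1) > 1e-8)
    stop("'class_proportions' must sum to 1", call. = FALSE)
  chk_frac(spec$polygenic_h2, "polygenic_h2")
  if (spec$polygenic_h2 >= 1)
    stop("'polygenic_h2' must be < 1", call. = FALSE)
  if (length(spec$effect_table)) {
    if (is.null(names(spec$effect_table)) || any(!nzchar(names(spec$effect_table))))
      stop("'effect_table' must be a named numeric vector (gene -> kg)", call. = FALSE)
    bad <- setdiff(names(spec$effect_table), sim_gene_ids(spec$n_genes))
    if (length(bad))
      stop("'effect_table' names outside the simulated gene set: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(spec$prevalence_table)) {
    if (any(spec$prevalence_table <= 0) || any(spec$prevalence_table >= 1))
      stop("'prevalence_table' entries must lie strictly in (0, 1)", call. = FALSE)
  }
  chk_frac(spec$missing_rate, "missing_rate")
  chk_frac(spec$x_gene_fraction, "x_gene_fraction")
  chk_frac(spec$loftee_low_conf_rate, "loftee_low_conf_rate")
  if (spec$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  invisible(spec)
}

sim_gene_ids <- function(n) sprintf("gene%04d", seq_len(n))

## Sparse Hardy-Weinberg rare genotypes: draw het / hom-alt carrier counts per
## variant and scatter them over samples. Returns a dgCMatrix (samples x variants).
sim_rare_genotypes <- function(n, mafs, missing_rate = 0) {
  m <- length(mafs)
  ii <- vector("list", m); xx <- vector("list", m)
  for (j in seq_len(m)) {
    p <- mafs[j]
    nhet <- stats::rbinom(1L, n, 2 * p * (1 - p))
    nhom <- stats::rbinom(1L, n, p * p)
    k <- nhet + nhom
    if (k > n) { nhom <- max(0L, n - nhet); k <- nhet + nhom }
    if (k == 0L) { ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
    idx <- sample.int(n, k)
    ii[[j]] <- idx
    xx[[j]] <- c(rep(1, nhet), rep(2, nhom))
  }
  i <- unlist(ii); x <- unlist(xx)
  j <- rep.int(seq_len(m), vapply(ii, length, 0L))
  G <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, m))
  if (missing_rate > 0) {
    nmiss <- stats::rbinom(1L, n * m, missing_rate)
    if (nmiss > 0) {
      cells <- sample.int(as.double(n) * m, nmiss)
      mi <- ((cells - 1) %% n) + 1
      mj <- ((cells - 1) %/% n) + 1
      G <- replace_missing_cells(G, mi, mj)
    }
  }
  G
}

replace_missing_cells <- function(G, mi, mj) {
  G <- as(G, "TsparseMatrix")
  key_new <- (mj - 1) * nrow(G) + mi
  key_old <- as.double(G@j) * nrow(G) + G@i + 1
  keep <- !(key_old %in% key_new)
  Matrix::sparseMatrix(i = c(G@i[keep] + 1L, mi), j = c(G@j[keep] + 1L, mj),
                       x = c(G@x[keep], rep(NA_real_, length(mi))),
                       dims = dim(G))
}

## Common genotypes, optionally with blockwise AR(1) haplotype correlation.
sim_common_genotypes <- function(n, mafs, ld_rho = 0, block_size = 10L) {
  m <- length(mafs)
  if (ld_rho == 0) {
    G <- matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n)
    return(G)
  }
  thr <- stats::qnorm(mafs)
  hap <- function() {
    Z <- matrix(stats::rnorm(n * m), nrow = n)
    for (j in seq_len(m)) {
      if ((j - 1L) %% block_size != 0L)
        Z[, j] <- ld_rho * Z[, j - 1L] + sqrt(1 - ld_rho^2) * Z[, j]
    }
    Z
  }
  (hap() < rep(thr, each = n)) + (hap() < rep(thr, each = n)) + 0L
}

#' Simulate a synthetic exome cohort
#'
#' Generates genotypes, variant and gene annotations, covariates and a grip
#' strength phenotype under the generative model described in [sim_spec()].
#' Grip strength is built as covariate polynomial + sum over genes of
#' effect_g x (qualifying PTV allele count in gene g) + polygenic component +
#' Gaussian noise; left- and right-hand measurements are the latent value plus
#' independent hand-specific jitter, so their maximum recovers the latent
#' value up to jitter.
#'
#' @param spec a [sim_spec()] object.
#' @return an object of class `sim_cohort`: a list with
#'   \describe{
#'     \item{genotypes}{samples x rare-variants dosage `dgCMatrix`
#'       (0/1/2, `NA` for missing); males carry 0/1 on X-linked variants.}
#'     \item{variants}{data.frame of rare [VariantRecord]s: chrom, pos, ref,
#'       alt, maf, consequence, loftee, cadd, gene.}
#'     \item{genes}{data.frame: gene, chrom, start, end, pli,
#'       chromosome_class.}
#'     \item{common_genotypes, common_variants}{dense dosages and annotation
#'       for the common (MAF > 0.01) variants.}
#'     \item{phenotypes}{data.frame with sample id, hgs_left/hgs_right (kg),
#'       age, sex, height, weight, 20 PCs, exclusion flags, and any binary
#'       traits from `prevalence_table`.}
#'     \item{truth}{the injected effect table, the polygenic component, the
#'       latent phenotype and the realised per-gene qualifying PTV burden.}
#'   }
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  validate_sim_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_samples

  ## --- genes ---------------------------------------------------------------
  gid <- sim_gene_ids(spec$n_genes)
  n_x <- round(spec$x_gene_fraction * spec$n_genes)
  chrom <- c(rep("X", n_x),
             as.character(rep_len(1:22, spec$n_genes - n_x)))
  chrom <- sample(chrom)  # shuffle so X genes are not a prefix
  start <- integer(spec$n_genes)
  for (cc in unique(chrom)) {
    k <- which(chrom == cc)
    start[k] <- cumsum(c(1e6, rep(2e6, length(k) - 1L)))
  }
  glen <- round(stats::runif(spec$n_genes, 5e3, 5e5))
  pli <- ifelse(stats::runif(spec$n_genes) < spec$pli_mixture,
                stats::runif(spec$n_genes, 0.9, 1),
                stats::runif(spec$n_genes, 0, 0.9))
  genes <- data.frame(gene = gid, chrom = chrom, start = start,
                      end = start + glen, pli = pli,
                      chromosome_class = ifelse(chrom == "X", "X", "autosome"),
                      stringsAsFactors = FALSE)

  ## --- rare variants -------------------------------------------------------
  vpg <- 1L + stats::rpois(spec$n_genes, max(spec$variants_per_gene - 1, 0))
  m <- sum(vpg)
  vgene <- rep(gid, vpg)
  vchrom <- rep(chrom, vpg)
  vpos <- rep(start, vpg) + unlist(lapply(vpg, function(k) sort(sample.int(5e5, k))))
  maf <- stats::runif(m, spec$rare_maf_range[1], spec$rare_maf_range[2])
  cls <- sample(names(spec$class_proportions), m, replace = TRUE,
                prob = spec$class_proportions)
  consequence <- character(m)
  consequence[cls == "ptv"] <- sample(c("stop_gained", "splice", "frameshift"),
                                      sum(cls == "ptv"), replace = TRUE)
  consequence[cls == "missense"] <- "missense"
  consequence[cls == "synonymous"] <- "synonymous"
  loftee <- rep("not-applicable", m)
  is_ptv <- cls == "ptv"
  loftee[is_ptv] <- ifelse(stats::runif(sum(is_ptv)) < spec$loftee_low_conf_rate,
                           "low-confidence", "high-confidence")
  cadd <- rep(NA_real_, m)
  cadd[cls == "missense"] <- stats::runif(sum(cls == "missense"), 1e-6, 40)
  cadd[cls == "synonymous"] <- stats::runif(sum(cls == "synonymous"), 0, 10)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  variants <- data.frame(id = sprintf("rv%05d", seq_len(m)), chrom = vchrom,
                         pos = vpos, ref = ref, alt = alt, maf = maf,
                         consequence = consequence, loftee = loftee,
                         cadd = cadd, gene = vgene, stringsAsFactors = FALSE)

  G <- sim_rare_genotypes(n, maf, spec$missing_rate)
  colnames(G) <- variants$id

  ## sex first: X-linked male dosages are haploid (0/1)
  sex <- stats::rbinom(n, 1L, 0.5)  # 1 = male
  on_x <- vchrom == "X"
  if (any(on_x) && any(sex == 1L)) {
    Gx <- G[, on_x, drop = FALSE]
    Gx@x[Gx@x == 2] <- 1
    Gx[sex == 0L, ] <- G[sex == 0L, on_x, drop = FALSE]
    G[, on_x] <- Gx
  }

  ## --- common variants -----------------------------------------------------
  mc <- spec$n_common_variants
  cmaf <- stats::runif(mc, spec$common_maf_range[1], spec$common_maf_range[2])
  Gc <- sim_common_genotypes(n, cmaf, spec$ld_rho, spec$ld_block_size)
  common_variants <- data.frame(id = sprintf("cv%05d", seq_len(mc)),
                                chrom = as.character(rep_len(1:22, mc)),
                                pos = 1e6 + 1e4 * seq_len(mc),
                                ref = "A", alt = "G", maf = cmaf,
                                stringsAsFactors = FALSE)
  colnames(Gc) <- common_variants$id

  ## --- covariates ----------------------------------------------------------
  age <- stats::runif(n, 40, 70)
  height <- 162 + 13 * sex + stats::rnorm(n, 0, 6.5)
  weight <- pmax(30.5, 62 + 14 * sex + stats::rnorm(n, 0, 12))
  pcs <- matrix(stats::rnorm(n * 20L), nrow = n,
                dimnames = list(NULL, paste0("PC", 1:20)))

  ce <- spec$covariate_effects
  ac <- age - 55; hc <- height - (162 + 13 * sex)
  cov_part <- ce$intercept + ce$age * ac + ce$age2 * ac^2 + ce$sex * sex +
    ce$height * hc + ce$height2 * hc^2 + ce$age_sex * ac * sex

  ## --- genetic part --------------------------------------------------------
  qual_ptv <- is_ptv & loftee == "high-confidence" & maf < 0.001
  burden_truth <- gene_allele_counts(G, vgene, qual_ptv, gid)
  burden_part <- numeric(n)
  if (length(spec$effect_table))
    burden_part <- as.numeric(burden_truth[, names(spec$effect_table), drop = FALSE] %*%
                                spec$effect_table)

  h2 <- spec$polygenic_h2
  poly <- numeric(n)
  if (h2 > 0 && mc > 0) {
    w <- stats::rnorm(mc)
    raw <- as.numeric(scale(Gc, center = TRUE, scale = FALSE) %*% w)
    s <- stats::sd(raw)
    target_sd <- spec$noise_sd * sqrt(h2 / (1 - h2))
    poly <- if (s > 0) raw * target_sd / s else raw
  }
  latent <- cov_part + burden_part + poly +
    stats::rnorm(n, 0, spec$noise_sd)

  jit <- spec$hand_jitter_frac * max(stats::sd(latent), 1e-8)
  hgs_left <- pmax(0, latent + stats::rnorm(n, 0, jit))
  hgs_right <- pmax(0, latent + stats::rnorm(n, 0, jit))

  ex <- spec$exclusion_rates
  flags <- vapply(c("copd", "brachial_plexus", "arm_injury", "sex_aneuploidy"),
                  function(f) stats::rbinom(n, 1L, if (f %in% names(ex)) ex[[f]] else 0),
                  integer(n))
  phenotypes <- data.frame(sample = sprintf("S%05d", seq_len(n)),
                           hgs_left = hgs_left, hgs_right = hgs_right,
                           age = age, sex = sex, height = height,
                           weight = weight, pcs, flags,
                           stringsAsFactors = FALSE)
  rownames(G) <- phenotypes$sample
  rownames(Gc) <- phenotypes$sample

  cohort <- structure(list(genotypes = G, variants = variants, genes = genes,
                           common_genotypes = Gc,
                           common_variants = common_variants,
                           phenotypes = phenotypes,
                           truth = list(effect_table = spec$effect_table,
                                        polygenic = poly, latent = latent,
                                        covariate_part = cov_part,
                                        ptv_burden = burden_truth),
                           spec = spec),
                      class = "sim_cohort")
  if (length(spec$prevalence_table)) {
    bt <- simulate_binary_traits(cohort, spec$prevalence_table)
    cohort$phenotypes <- cbind(cohort$phenotypes,
                               bt[, setdiff(names(bt), "sample"), drop = FALSE])
  }
  cohort
}

## per-sample qualifying allele count for each gene (missing dosages = 0)
gene_allele_counts <- function(G, vgene, keep, gene_ids) {
  idx <- which(keep)
  out <- matrix(0, nrow(G), length(gene_ids),
                dimnames = list(rownames(G), gene_ids))
  if (!length(idx)) return(out)
  Gs <- G[, idx, drop = FALSE]
  if (methods::is(Gs, "sparseMatrix")) Gs@x[is.na(Gs@x)] <- 0
  else Gs[is.na(Gs)] <- 0
  gi <- factor(vgene[idx], levels = gene_ids)
  Ind <- Matrix::sparseMatrix(i = seq_along(idx), j = as.integer(gi), x = 1,
                              dims = c(length(idx), length(gene_ids)))
  out <- as.matrix(Gs %*% Ind)
  dimnames(out) <- list(rownames(G), gene_ids)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic exome cohort\n")
  cat(sprintf("  %d samples, %d rare variants in %d genes, %d common variants\n",
              nrow(x$phenotypes), nrow(x$variants), nrow(x$genes),
              nrow(x$common_variants)))
  cat(sprintf("  injected gene effects: %d, polygenic h2 = %.2f, seed = %d\n",
              length(x$truth$effect_table), x$spec$polygenic_h2, x$spec$seed))
  invisible(x)
}

#' Simulate binary traits for a cohort
#'
#' Draws binary phenome traits at stated prevalences, optionally linked to the
#' qualifying-PTV carrier status of chosen genes through a logistic model:
#' logit P(case) = logit(prevalence) + log_or x carrier.
#'
#' @param cohort a `sim_cohort`.
#' @param prevalence_table named numeric in (0,1), one entry per trait.
#' @param linked optional data.frame with columns `trait`, `gene`, `log_or`
#'   tying a trait's odds to carrier status of a gene.
#' @return data.frame with `sample` plus one 0/1 column per trait (empty
#'   data.frame of the right length if the table is empty).
#' @export
simulate_binary_traits <- function(cohort, prevalence_table, linked = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  n <- nrow(cohort$phenotypes)
  out <- data.frame(sample = cohort$phenotypes$sample, stringsAsFactors = FALSE)
  if (!length(prevalence_table)) return(out)
  if (any(prevalence_table <= 0) || any(prevalence_table >= 1))
    stop("prevalences must lie strictly in (0, 1)", call. = FALSE)
  for (tr in names(prevalence_table)) {
    p0 <- prevalence_table[[tr]]
    eta <- rep(stats::qlogis(p0), n)
    if (!is.null(linked) && tr %in% linked$trait) {
      row <- linked[linked$trait == tr, , drop = FALSE][1L, ]
      carrier <- as.numeric(cohort$truth$ptv_burden[, row$gene] >= 1)
      eta <- eta + row$log_or * carrier
    }
    out[[tr]] <- stats::rbinom(n, 1L, stats::plogis(eta))
  }
  out
}

#' Simulate a mouse grip-strength experiment
#'
#' Emulates a forelimb grip-strength assay on wildtype, heterozygous and
#' homozygous knockout animals measured in independent cohorts: three peak
#' pull-force trials per animal (grams) and a femur length (mm) for body-size
#' normalization. Genotype effects are in grams on the animal-level mean.
#'
#' @param n_per_genotype named counts for `WT`, `HET`, `HOM` (any subset).
#' @param cohort_effects numeric per-cohort shifts (grams); its length sets
#'   the number of cohorts (>= 2 supported; animals are split round-robin).
#' @param genotype_effects named grams for `HET` and `HOM` relative to WT;
#'   a dose effect should be ordered 0 > HET > HOM.
#' @param baseline WT mean grip in grams.
#' @param animal_sd,trial_sd between-animal and within-animal (trial) SDs.
#' @param femur_mean,femur_sd femur length distribution (mm).
#' @param seed integer seed.
#' @return data.frame of class `mouse_table`: animal, genotype, cohort,
#'   trial1..trial3, femur.
#' @export
simulate_mouse_cohort <- function(n_per_genotype = c(WT = 24, HET = 18, HOM = 13),
                                  cohort_effects = c(0, 8),
                                  genotype_effects = c(HET = 0, HOM = 0),
                                  baseline = 110, animal_sd = 12, trial_sd = 8,
                                  femur_mean = 15.5, femur_sd = 0.4,
                                  seed = 1L) {
  if (any(n_per_genotype < 1)) stop("'n_per_genotype' must be >= 1", call. = FALSE)
  if (!all(names(n_per_genotype) %in% c("WT", "HET", "HOM")))
    stop("genotypes must be among WT, HET, HOM", call. = FALSE)
  set.seed(seed)
  geno <- rep(names(n_per_genotype), n_per_genotype)
  n <- length(geno)
  cohort <- rep_len(seq_along(cohort_effects), n)
  cohort <- sample(cohort)  # randomized allocation to cohorts
  shift <- c(WT = 0, genotype_effects)[geno]
  mu <- baseline + shift + cohort_effects[cohort] + stats::rnorm(n, 0, animal_sd)
  trials <- matrix(pmax(1, mu + stats::rnorm(3L * n, 0, trial_sd)), ncol = 3L)
  out <- data.frame(animal = sprintf("M%03d", seq_len(n)),
                    genotype = factor(geno, levels = c("WT", "HET", "HOM")),
                    cohort = factor(paste0("C", cohort)),
                    trial1 = trials[, 1], trial2 = trials[, 2],
                    trial3 = trials[, 3],
                    femur = pmax(1, stats::rnorm(n, femur_mean, femur_sd)),
                    stringsAsFactors = FALSE)
  out$genotype <- droplevels(out$genotype)
  class(out) <- c("mouse_table", "data.frame")
  out
}
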