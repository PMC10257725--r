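## Plain-text interchange: VCF and TSV writers for simulated cohorts, a
## biallelic VCF/dosage reader, and GMT gene-set files.

#' Write a cohort to disk as VCF and TSV tables
#'
#' Writes the rare-variant genotypes as an uncompressed VCF (GT field, one
#' sample column per individual, missing dosage as `./.`), plus dosage,
#' variant-annotation, gene, and phenotype/covariate TSVs.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(vcf = file.path(dir, "genotypes.vcf"),
             dosage = file.path(dir, "dosage.tsv"),
             annot = file.path(dir, "annotations.tsv"),
             genes = file.path(dir, "genes.tsv"),
             pheno = file.path(dir, "phenotypes.tsv"))
  G <- as.matrix(cohort$genotypes)
  v <- cohort$variants
  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow = nrow(G))
  gt[is.na(G)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), files["vcf"])
  dos <- data.frame(sample = rownames(G), G, check.names = FALSE)
  utils::write.table(dos, files["dosage"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(v, files["annot"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$genes, files["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$phenotypes, files["pheno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' Read a biallelic GT VCF into a dosage matrix
#'
#' Parses a VCF with a GT FORMAT field into a samples x variants dosage
#' matrix (alt-allele counts; `./.` becomes `NA`). Multi-allelic records
#' must be split upstream: any ALT containing a comma is rejected with a
#' message listing the offending positions.
#'
#' @param path VCF file path.
#' @return list with `genotypes` (dense matrix) and `variants`
#'   (chrom, pos, id, ref, alt).
#' @export
read_vcf_dosage <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vc <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vc, element = "GT")
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t")[[1]]
    rec <- do.call(rbind, strsplit(lines[!startsWith(lines, "#")], "\t"))
    colnames(rec) <- cols
    fix <- as.data.frame(rec[, 1:8, drop = FALSE], stringsAsFactors = FALSE)
    names(fix)[1] <- "CHROM"
    gt <- rec[, -(1:9), drop = FALSE]
    rownames(gt) <- rec[, "ID"]
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) must be split to biallelic first: ",
         paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5L),
               collapse = ", "), call. = FALSE)
  allele1 <- substr(gt, 1L, 1L)
  allele2 <- substr(gt, 3L, 3L)
  dos <- suppressWarnings(as.integer(allele1) + as.integer(allele2))
  D <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  list(genotypes = t(D),
       variants = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                             id = fix$ID, ref = fix$REF, alt = fix$ALT,
                             stringsAsFactors = FALSE))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, "", 1L))
}

#' Write the mouse table as TSV
#' @param table a `mouse_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mouse_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
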