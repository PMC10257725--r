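make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

test_that("variant classification follows the qualifying rules", {
  v <- make_variants(
    list(id = "v1", maf = 1e-4, consequence = "stop_gained",
         loftee = "high-confidence", cadd = NA, gene = "g1"),
    list(id = "v2", maf = 1e-4, consequence = "stop_gained",
         loftee = "low-confidence", cadd = NA, gene = "g1"),
    list(id = "v3", maf = 1e-4, consequence = "missense",
         loftee = "not-applicable", cadd = 35, gene = "g1"),
    list(id = "v4", maf = 1e-4, consequence = "missense",
         loftee = "not-applicable", cadd = 30, gene = "g1"),
    list(id = "v5", maf = 1e-4, consequence = "missense",
         loftee = "not-applicable", cadd = 20, gene = "g1"),
    list(id = "v6", maf = 1e-4, consequence = "synonymous",
         loftee = "not-applicable", cadd = 2, gene = "g1"),
    list(id = "v7", maf = 0.002, consequence = "frameshift",
         loftee = "high-confidence", cadd = NA, gene = "g1"),
    list(id = "v8", maf = 1e-4, consequence = "intronic",
         loftee = "not-applicable", cadd = NA, gene = "g1"))
  cls <- classify_variants(v)
  expect_equal(as.character(cls),
               c("ptv", NA, "missense_gt30", "missense_20_30",
                 "missense_0_20", "synonymous", NA, NA))
  reasons <- attr(cls, "reason")
  expect_equal(reasons[2], "loftee_not_high_confidence")
  expect_equal(reasons[7], "maf_ge_0.001")
  expect_equal(reasons[8], "non_coding_consequence")
})

test_that("missense without CADD is an explicit error, not a silent bin", {
  v <- data.frame(id = "m", maf = 1e-4, consequence = "missense",
                  loftee = "not-applicable", cadd = NA_real_, gene = "g1",
                  stringsAsFactors = FALSE)
  expect_error(classify_variants(v), "CADD")
})

test_that("pLI stratification uses the closed 0.9 boundary", {
  g <- data.frame(gene = c("a", "b", "c", "d"), pli = c(0.90, 0.10, 1.0, NA))
  expect_warning(st <- assign_stratum(g), "missing pLI")
  expect_equal(as.character(st), c("pli_ge_0.9", "pli_lt_0.9", "pli_ge_0.9", NA))
  expect_error(assign_stratum(data.frame(gene = "x", pli = 1.5)), "pLI")
})

test_that("gene burden equals a per-sample brute-force allele recount", {
  set.seed(31)
  m <- 20; n <- 50
  v <- data.frame(id = paste0("v", 1:m), maf = runif(m, 1e-4, 9e-4),
                  consequence = sample(c("stop_gained", "frameshift", "splice",
                                         "missense", "synonymous"), m, TRUE),
                  loftee = sample(c("high-confidence", "low-confidence"), m, TRUE),
                  cadd = runif(m, 0, 40),
                  gene = sample(paste0("g", 1:5), m, TRUE),
                  stringsAsFactors = FALSE)
  v$loftee[v$consequence %in% c("missense", "synonymous")] <- "not-applicable"
  v$cadd[v$consequence != "missense"] <- ifelse(
    v$consequence[v$consequence != "missense"] == "synonymous", 3, NA)
  G <- matrix(rbinom(n * m, 2, 0.2), n, dimnames = list(paste0("s", 1:n), v$id))
  G[sample(length(G), 20)] <- NA
  for (cl in c("ptv", "missense_gt30", "missense_0_20", "synonymous")) {
    B <- gene_burden(G, v, cl)
    expect_equal(B, burden_brute(G, v, cl), info = cl)
  }
})

test_that("burden additivity: het at 2 PTVs gives 2, hom at 1 gives 2", {
  v <- data.frame(id = c("p1", "p2"), maf = c(1e-4, 1e-4),
                  consequence = "stop_gained", loftee = "high-confidence",
                  cadd = NA_real_, gene = "g1", stringsAsFactors = FALSE)
  G <- matrix(c(1, 1,   # s1 het at both
                2, 0),  # s2 hom at one
              nrow = 2, byrow = TRUE, dimnames = list(c("s1", "s2"), v$id))
  B <- gene_burden(G, v, "ptv")
  expect_equal(unname(B[, "g1"]), c(2, 2))
})

test_that("variants above the rare MAF ceiling contribute nothing", {
  v <- data.frame(id = c("p1", "p2"), maf = c(1e-4, 0.002),
                  consequence = "stop_gained", loftee = "high-confidence",
                  cadd = NA_real_, gene = "g1", stringsAsFactors = FALSE)
  G <- matrix(1, 3, 2, dimnames = list(NULL, v$id))
  expect_equal(unname(gene_burden(G, v, "ptv")[, "g1"]), rep(1, 3))
})

test_that("unknown gene references are an error listing the ids", {
  v <- data.frame(id = "p1", maf = 1e-4, consequence = "stop_gained",
                  loftee = "high-confidence", cadd = NA_real_,
                  gene = "ghost", stringsAsFactors = FALSE)
  G <- matrix(0, 2, 1, dimnames = list(NULL, "p1"))
  expect_error(gene_burden(G, v, "ptv", genes = data.frame(gene = "g1")),
               "ghost")
})

test_that("set burden is an exact column sum and additive over partitions", {
  set.seed(17)
  B <- matrix(rpois(200, 1), 20, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  expect_equal(set_burden(B, "g3"), B[, "g3"])
  expect_equal(set_burden(B, colnames(B)), rowSums(B))
  for (r in 1:5) {
    k <- sample(2:8, 1)
    A <- sample(colnames(B), k)
    Bs <- setdiff(colnames(B), A)
    expect_equal(set_burden(B, A) + set_burden(B, Bs),
                 set_burden(B, colnames(B)))
  }
  expect_error(set_burden(B, character(0)), "empty")
})

test_that("carrier filter boundary: exactly min_carriers is retained", {
  B <- cbind(g9 = c(rep(1, 9), rep(0, 11)),
             g10 = c(rep(1, 10), rep(0, 10)),
             g0 = rep(0, 20))
  out <- carrier_filter(B, 10)
  expect_equal(colnames(out), "g10")
  expect_equal(attr(out, "n_removed"), 2)
  expect_setequal(attr(out, "removed"), c("g9", "g0"))
  expect_error(carrier_filter(B, 0), "min_carriers")
})

test_that("exome-wide burden conserves the sum of gene burdens", {
  co <- simulate_cohort(sim_spec(n_samples = 500, n_genes = 30, seed = 19,
                                 missing_rate = 0.01))
  for (st in c("all", "pli_ge_0.9", "pli_lt_0.9")) {
    genes <- co$genes[co$genes$chromosome_class == "autosome", ]
    if (st != "all") {
      sfac <- assign_stratum(genes)
      genes <- genes[!is.na(sfac) & sfac == st, ]
    }
    v <- co$variants[co$variants$gene %in% genes$gene, ]
    B <- gene_burden(co$genotypes, v, "ptv", co$genes)
    ex <- category_burden(co, "ptv", st)
    if (ncol(B)) expect_equal(unname(as.numeric(ex)), unname(rowSums(B)))
    expect_true(all(as.numeric(ex) == round(as.numeric(ex))))
  }
})

test_that("the 5 classes partition the qualifying variants", {
  co <- simulate_cohort(sim_spec(n_samples = 50, n_genes = 40, seed = 23))
  cls <- classify_variants(co$variants)
  qualifying <- !is.na(cls)
  counts <- table(cls)
  expect_equal(sum(counts), sum(qualifying))
  expect_equal(nrow(variant_categories()), 15L)
  expect_equal(sort(unique(variant_categories()$stratum)),
               sort(c("pli_ge_0.9", "pli_lt_0.9", "all")))
})

test_that("carrier-indicator collapsing caps the burden at one", {
  v <- data.frame(id = c("p1", "p2"), maf = 1e-4,
                  consequence = "stop_gained", loftee = "high-confidence",
                  cadd = NA_real_, gene = "g1", stringsAsFactors = FALSE)
  G <- matrix(c(2, 1, 0, 0), 2, dimnames = list(NULL, v$id))
  expect_equal(unname(gene_burden(G, v, "ptv", carrier_indicator = TRUE)[, 1]),
               c(1, 1))
})
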