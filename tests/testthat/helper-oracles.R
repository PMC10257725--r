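# Independent brute-force oracles used across the suite.

# Step-up BH computed directly from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, (m / i) * p[o[i]])
    q[o[i]] <- running
  }
  pmin(q, 1)
}

# Firth slope closed form for a saturated 2x2 table (Haldane-Anscombe):
# cells a = cases|x=1, b = controls|x=1, c = cases|x=0, d = controls|x=0.
haldane_slope <- function(a, b, c, d) {
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# Expand a 2x2 table into per-observation y / x vectors.
expand_2x2 <- function(a, b, c, d) {
  list(y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
       x = c(rep(1, a + b), rep(0, c + d)))
}

# Per-sample brute-force recount of qualifying alleles per gene.
burden_brute <- function(G, variants, class) {
  G <- as.matrix(G)
  cls <- gripburden::classify_variants(variants)
  genes <- sort(unique(variants$gene[!is.na(cls) & cls == class]))
  out <- matrix(0, nrow(G), length(genes), dimnames = list(rownames(G), genes))
  for (s in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      if (is.na(cls[j]) || cls[j] != class) next
      d <- G[s, j]
      if (!is.na(d)) out[s, variants$gene[j]] <- out[s, variants$gene[j]] + d
    }
  }
  out
}

# Fine-grid profile-likelihood search for the Box-Cox power.
boxcox_grid_oracle <- function(y, cohort, range = c(-2, 2), step = 1e-3) {
  X <- if (is.null(cohort)) matrix(1, length(y), 1) else model.matrix(~ factor(cohort))
  qx <- qr(X)
  ls <- sum(log(y))
  grid <- seq(range[1], range[2], by = step)
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
    rss <- sum(qr.resid(qx, z)^2)
    -length(y) / 2 * log(rss / length(y)) + (l - 1) * ls
  }, 0)
  grid[which.max(ll)]
}

# Small deterministic phenotype/covariate frame for design-level tests.
toy_pheno <- function(n = 200, seed = 42) {
  set.seed(seed)
  data.frame(sample = sprintf("S%04d", seq_len(n)),
             age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5),
             height = rnorm(n, 168, 8), weight = rnorm(n, 75, 10),
             matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("PC", 1:20))),
             stringsAsFactors = FALSE)
}
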