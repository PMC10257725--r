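#' Derive the analysis grip-strength phenotype
#'
#' The analysis outcome is the maximum grip strength over the two hands;
#' samples with at least one measured hand keep a value, samples with both
#' hands missing stay missing (and are dropped later by
#' [apply_exclusions()]).
#'
#' @param left,right numeric kg, `NA` for unmeasured hands.
#' @return numeric vector of per-sample maxima.
#' @export
derive_hgs <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE))
    stop("grip strength cannot be negative", call. = FALSE)
  out <- pmax(left, right, na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_real_
  out
}

#' Apply phenotype exclusions with an audit trail
#'
#' Removes samples whose grip-strength measurement may be confounded:
#' diagnosis flags (COPD, brachial plexus disorders, history of elbow /
#' forearm / wrist / hand injury), body weight missing or outside the normal
#' window of 30-200 kg (closed interval), and samples missing grip strength
#' on both hands. Each sample is counted once, under the first criterion it
#' matches, so the audit counts always sum to rows-in minus rows-out.
#'
#' @param table phenotype data.frame with `hgs_left`, `hgs_right`, `weight`
#'   and the 0/1 flag columns `copd`, `brachial_plexus`, `arm_injury`
#'   (absent flags are treated as all-zero).
#' @param weight_range closed kg window for acceptable body weight.
#' @return the filtered data.frame with a derived `hgs` column; attribute
#'   `"audit"` is a data.frame (criterion, n_removed).
#' @export
apply_exclusions <- function(table, weight_range = c(30, 200)) {
  n <- nrow(table)
  flag <- function(nm) if (nm %in% names(table)) table[[nm]] == 1 else rep(FALSE, n)
  hgs <- derive_hgs(table$hgs_left, table$hgs_right)
  bad_weight <- is.na(table$weight) | table$weight < weight_range[1] |
    table$weight > weight_range[2]
  criteria <- list(copd = flag("copd"),
                   brachial_plexus = flag("brachial_plexus"),
                   arm_injury = flag("arm_injury"),
                   weight_out_of_range = bad_weight,
                   missing_hgs = is.na(hgs))
  removed <- rep(FALSE, n)
  audit <- data.frame(criterion = names(criteria),
                      n_removed = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(criteria)) {
    hit <- criteria[[k]] & !removed
    audit$n_removed[k] <- sum(hit)
    removed <- removed | hit
  }
  out <- table[!removed, , drop = FALSE]
  out$hgs <- hgs[!removed]
  attr(out, "audit") <- audit
  out
}

#' Inverse rank-normal transformation
#'
#' Rank-based mapping to standard-normal quantiles with the Blom offset,
#' z_i = qnorm((r_i - 0.375) / (n + 0.25)), using average ranks for ties —
#' the GWAS convention for quantitative traits. Missing values stay missing
#' and do not affect the ranks of the rest.
#'
#' @param values numeric vector with at least 2 distinct non-missing values.
#' @param offset rank offset; 0.375 is Blom.
#' @return numeric vector of z-scores, `NA` where the input was `NA`.
#' @export
inverse_normal_transform <- function(values, offset = 0.375) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2L)
    stop("need at least 2 non-missing values", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("all values identical: ranks are degenerate", call. = FALSE)
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - offset) / (length(x) - 2 * offset + 1))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Height-normalized, covariate-residualized grip-strength z-scores
#'
#' Normalizes grip strength against standing height (hgs / height), takes
#' least-squares residuals on age, sex and principal components, and maps the
#' residuals through [inverse_normal_transform()]. This is the standardized
#' outcome used for carrier-versus-non-carrier visual comparisons.
#'
#' @param hgs grip strength in kg.
#' @param height standing height in cm (> 0).
#' @param age,sex numeric covariates.
#' @param pcs matrix (or data.frame) of principal components, may be `NULL`.
#' @return numeric z-scores (missing inputs propagate).
#' @export
normalize_residualize <- function(hgs, height, age, sex, pcs = NULL) {
  if (any(height <= 0, na.rm = TRUE))
    stop("height must be positive", call. = FALSE)
  y <- hgs / height
  X <- cbind(intercept = 1, age = age, sex = sex)
  if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs))
  ok <- !is.na(y) & stats::complete.cases(X)
  qr_x <- qr(X[ok, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("singular covariate design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  res <- rep(NA_real_, length(y))
  res[ok] <- qr.resid(qr_x, y[ok])
  inverse_normal_transform(res)
}
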