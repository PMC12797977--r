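#' Filter genes on a strict minimum count
#'
#' Keeps genes whose count is strictly greater than `threshold` in every
#' sample (the all-sample rule used to define the expressed-gene universe;
#' with the default threshold of 10, a gene with a count of exactly 10 in
#' any sample is removed). Gene order is preserved and the filter is
#' idempotent.
#'
#' @param counts Validated count matrix (genes x samples).
#' @param threshold Count threshold; comparison is strict (`>`).
#' @param require_all_samples If `TRUE` (default) a gene must exceed the
#'   threshold in all samples; if `FALSE`, in at least one sample.
#' @return The row-subset count matrix.
#' @export
filter_low_counts <- function(counts, threshold = 10, require_all_samples = TRUE) {
  validate_counts(counts)
  keep <- if (require_all_samples) {
    apply(counts, 1L, function(x) all(x > threshold))
  } else {
    apply(counts, 1L, function(x) any(x > threshold))
  }
  if (!any(keep)) {
    stop("no gene passes the count filter (threshold ", threshold,
         "); review the threshold")
  }
  counts[keep, , drop = FALSE]
}

# weighted trimmed mean of M-values for one sample against the reference;
# returns the scale factor on the natural (2^) scale
.tmm_pair <- function(obs, ref, trim_m, trim_a) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  log_r <- log2((obs / n_obs) / (ref / n_ref))            # M
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2    # A
  # inverse of the binomial delta-method variance of M
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (!length(log_r) || max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * trim_m) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1; hi_s <- n + 1 - lo_s
  keep <- (rank(log_r) >= lo_l & rank(log_r) <= hi_l) &
          (rank(abs_e) >= lo_s & rank(abs_e) <= hi_s)
  if (sum(keep) < 10L) {
    warning("fewer than 10 genes survive TMM trimming; using untrimmed weighted mean")
    keep <- rep(TRUE, n)
  }
  f <- sum(log_r[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) scale factors
#'
#' For each sample against a reference column, per-gene M values (log2
#' ratios of library-size-scaled counts) and A values (average log2
#' abundance) are computed over genes with positive counts in both columns;
#' the extreme `trim_m` fraction by M and `trim_a` fraction by A are
#' discarded on each side, and the factor is 2 to the inverse-variance
#' weighted mean of the remaining M values. Factors are rescaled to
#' geometric mean 1. The reference defaults to the column whose 75th
#' percentile of library-size-scaled counts is closest to the mean of those
#' percentiles.
#'
#' @param counts Count matrix, ideally already filtered for low counts.
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @param reference Optional reference sample: column name or index.
#' @return Named numeric vector of per-sample scale factors, geometric
#'   mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05, reference = NULL) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("column(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (is.null(reference)) {
    f75 <- apply(counts, 2L, function(x) quantile(x, 0.75, names = FALSE)) / lib
    ref_i <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_i <- if (is.character(reference)) match(reference, colnames(counts)) else as.integer(reference)
    if (is.na(ref_i) || ref_i < 1L || ref_i > ncol(counts)) {
      stop("reference sample not found: ", reference)
    }
  }
  ref <- counts[, ref_i]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_i) return(1)
    pos <- counts[, j] > 0 & ref > 0
    .tmm_pair(counts[pos, j], ref[pos], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))   # geometric mean exactly 1
  stats::setNames(f, colnames(counts))
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' Each entry is `log2(count / effective_size * 1e6 + pseudocount)` where
#' the effective size is the library size times its TMM factor. With the
#' default pseudocount of 1 a zero count maps to 0.
#'
#' @param counts Count matrix.
#' @param norm Either a `tmm_norm` object from [normalize_counts()] or a
#'   named numeric vector of per-sample effective library sizes. `NULL`
#'   (default) computes TMM factors on `counts` first.
#' @param pseudocount Positive offset added on the CPM scale before log2.
#' @return Matrix of log2-normalized expression, same dimnames as `counts`.
#' @export
log_cpm <- function(counts, norm = NULL, pseudocount = 1.0) {
  validate_counts(counts)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  eff <- if (is.null(norm)) {
    colSums(counts) * tmm_factors(counts)
  } else if (inherits(norm, "tmm_norm")) {
    norm$effective_sizes
  } else {
    norm
  }
  if (length(eff) != ncol(counts)) stop("effective sizes do not match samples")
  if (any(eff <= 0)) stop("effective library sizes must be positive")
  log2(sweep(counts, 2L, eff, "/") * 1e6 + pseudocount)
}

#' Full normalization chain: TMM factors plus log2-CPM
#'
#' Convenience wrapper producing everything downstream testing needs.
#'
#' @inheritParams tmm_factors
#' @inheritParams log_cpm
#' @return Object of class `tmm_norm`: list with `factors`, `lib_sizes`,
#'   `effective_sizes`, `log_expr`, `pseudocount`.
#' @export
normalize_counts <- function(counts, trim_m = 0.3, trim_a = 0.05,
                             reference = NULL, pseudocount = 1.0) {
  validate_counts(counts)
  f <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a, reference = reference)
  lib <- colSums(counts)
  eff <- lib * f
  out <- list(factors = f, lib_sizes = lib, effective_sizes = eff,
              log_expr = log_cpm(counts, eff, pseudocount),
              pseudocount = pseudocount)
  class(out) <- "tmm_norm"
  out
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("tmm_norm:", nrow(x$log_expr), "genes x", ncol(x$log_expr), "samples\n")
  cat("factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}
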