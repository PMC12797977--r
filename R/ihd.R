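#' Configuration for one treatment-vs-control comparison
#'
#' @param fdr_cut FDR threshold for DEG calls (inclusive; default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (inclusive; default
#'   0.58, i.e. a 1.5-fold change).
#' @param mode Null construction for the median-difference test: `"exact"`
#'   enumerates every label reassignment, `"sampled"` draws `n_perm` random
#'   splits, `"auto"` (default) enumerates when the number of splits is at
#'   most `exact_limit` and samples otherwise.
#' @param n_perm Number of random splits in sampled mode (>= 100).
#' @param seed Integer seed driving every stochastic step.
#' @param pooled_null Pool permutation statistics across genes into one
#'   empirical null (default). With 4-vs-4 groups a per-gene null has only
#'   70 distinct values, too coarse for FDR work; pooling is the standard
#'   remedy. Set `FALSE` for a per-gene null.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student test.
#' @param exact_limit Largest split count enumerated under `mode = "auto"`.
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(fdr_cut = 0.05, lfc_cut = 0.58,
                              mode = c("auto", "exact", "sampled"),
                              n_perm = 10000L, seed = 1L,
                              pooled_null = TRUE, welch = FALSE,
                              exact_limit = 10000L) {
  mode <- match.arg(mode)
  if (fdr_cut <= 0 || lfc_cut <= 0) stop("fdr_cut and lfc_cut must be > 0")
  if (mode == "sampled" && n_perm < 100L) stop("n_perm must be >= 100 in sampled mode")
  structure(list(fdr_cut = fdr_cut, lfc_cut = lfc_cut, mode = mode,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 pooled_null = isTRUE(pooled_null), welch = isTRUE(welch),
                 exact_limit = as.integer(exact_limit)),
            class = "comparison_config")
}

.group_samples <- function(design, group) {
  if (!group %in% design$groups) stop("group absent from design: ", group)
  names(design$assignments)[design$assignments == group]
}

.expr_groups <- function(log_expr, design, treatment, control) {
  trt <- .group_samples(design, treatment)
  ctl <- .group_samples(design, control)
  missing <- setdiff(c(trt, ctl), colnames(log_expr))
  if (length(missing)) {
    stop("sample(s) in design but absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  list(trt = log_expr[, trt, drop = FALSE], ctl = log_expr[, ctl, drop = FALSE])
}

#' Per-gene two-sample t-test on log expression
#'
#' Two-sided Student t-test with pooled variance on each row of the log
#' expression matrix (Welch's unequal-variance form by flag). Genes with
#' zero variance in both groups and equal means get t = 0, p = 1; zero
#' pooled variance with unequal means gives the smallest representable p.
#'
#' @param log_expr Genes x samples matrix of log2-normalized expression.
#' @param design A [sample_design()].
#' @param treatment,control Group labels to compare.
#' @param welch Use Welch's test instead of pooled variance.
#' @return Data.frame with columns `t_stat` and `p_t`, one row per gene.
#' @export
ttest_per_gene <- function(log_expr, design, treatment, control, welch = FALSE) {
  eg <- .expr_groups(log_expr, design, treatment, control)
  x <- eg$trt; y <- eg$ctl
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 replicates")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  d <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, length(se))
  }
  t_stat <- d / se
  zero <- se == 0
  t_stat[zero & d == 0] <- 0
  p_t <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p_t[zero & d == 0] <- 1
  p_t[zero & d != 0] <- .Machine$double.xmin
  t_stat[zero & d != 0] <- sign(d[zero & d != 0]) * .Machine$double.xmax
  data.frame(t_stat = t_stat, p_t = p_t, row.names = rownames(log_expr))
}

# row medians specialized for the small group sizes permutation testing uses
.row_medians <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  if (k == 2L) return((m[, 1L] + m[, 2L]) / 2)
  if (k == 4L) {
    mx <- pmax(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
    mn <- pmin(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
    return((m[, 1L] + m[, 2L] + m[, 3L] + m[, 4L] - mx - mn) / 2)
  }
  apply(m, 1L, stats::median)
}

#' Permutation null for the median-difference test
#'
#' For every relabelling of the pooled treatment+control samples into two
#' pseudo-groups of the original sizes, computes the absolute difference of
#' group medians for each gene. All C(n1+n2, n1) splits are enumerated when
#' that count is within `cfg$exact_limit` (70 splits for 4-vs-4);
#' otherwise `cfg$n_perm` random splits are drawn under `cfg$seed`. With
#' `cfg$pooled_null` the statistics are pooled across genes into one
#' empirical null vector.
#'
#' @inheritParams ttest_per_gene
#' @param cfg A [comparison_config()].
#' @return If pooled, a numeric vector of length n_splits x n_genes with
#'   attributes `n_splits` and `mode`; otherwise a genes x n_splits matrix
#'   with the same attributes.
#' @export
median_null <- function(log_expr, design, treatment, control,
                        cfg = comparison_config()) {
  eg <- .expr_groups(log_expr, design, treatment, control)
  x <- cbind(eg$trt, eg$ctl)
  n1 <- ncol(eg$trt); n <- ncol(x)
  n_splits_exact <- choose(n, n1)
  mode <- cfg$mode
  if (mode == "auto") {
    mode <- if (n_splits_exact <= cfg$exact_limit) "exact" else "sampled"
  }
  if (mode == "exact") {
    splits <- utils::combn(n, n1)
  } else {
    if (cfg$n_perm < 100L) stop("n_perm must be >= 100 in sampled mode")
    splits <- .with_seed(cfg$seed, {
      vapply(seq_len(cfg$n_perm), function(i) sample.int(n, n1), integer(n1))
    })
  }
  n_splits <- ncol(splits)
  stat <- matrix(0, nrow(x), n_splits)
  idx_all <- seq_len(n)
  for (j in seq_len(n_splits)) {
    a <- splits[, j]
    stat[, j] <- abs(.row_medians(x[, a, drop = FALSE]) -
                     .row_medians(x[, setdiff(idx_all, a), drop = FALSE]))
  }
  out <- if (cfg$pooled_null) as.vector(stat) else stat
  attr(out, "n_splits") <- n_splits
  attr(out, "mode") <- mode
  out
}

# run expr with a local RNG seed, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Median-difference statistics and permutation p-values
#'
#' The observed statistic is `median(treatment) - median(control)` per
#' gene; the p-value is `(1 + #(null >= |observed|)) / (1 + N)` against
#' the empirical null from [median_null()] (add-one smoothing keeps p in
#' (0, 1]; ties count as exceedances).
#'
#' @inheritParams ttest_per_gene
#' @param null Null from [median_null()] (pooled vector or per-gene matrix).
#' @return Data.frame with columns `median_diff` and `p_m`.
#' @export
median_diff_p <- function(log_expr, design, treatment, control, null) {
  if (!length(null)) stop("empty permutation null")
  eg <- .expr_groups(log_expr, design, treatment, control)
  obs <- .row_medians(eg$trt) - .row_medians(eg$ctl)
  if (is.matrix(null)) {
    if (nrow(null) != length(obs)) stop("per-gene null does not match gene count")
    n_null <- ncol(null)
    cnt <- rowSums(null >= abs(obs))
  } else {
    n_null <- length(null)
    srt <- sort(null)
    # count of null values >= x, via #(null < x)
    cnt <- n_null - findInterval(abs(obs), srt, left.open = TRUE)
  }
  p_m <- (1 + cnt) / (1 + n_null)
  data.frame(median_diff = obs, p_m = p_m, row.names = rownames(log_expr))
}

#' Combine two-sided p-values by Stouffer's method with effect signs
#'
#' Each two-sided p is mapped to a signed z, `qnorm(1 - p/2) * sign`, so
#' that concordant evidence reinforces and discordant evidence cancels
#' (sign 0 gives z = 0). The combined z is `(z_t + z_m) / sqrt(2)` and the
#' combined p is the two-sided normal tail, clipped into (0, 1].
#'
#' @param p_t,p_m Component two-sided p-values in (0, 1].
#' @param sign_t,sign_m Effect direction for each component (sign of the
#'   log2 fold change and of the median difference, respectively).
#' @return Data.frame with columns `z_combined` and `p_combined`.
#' @export
stouffer_combine <- function(p_t, p_m, sign_t, sign_m) {
  for (p in list(p_t, p_m)) {
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
      stop("component p-values must lie in (0, 1]")
    }
  }
  z_t <- stats::qnorm(1 - p_t / 2) * sign(sign_t)
  z_m <- stats::qnorm(1 - p_m / 2) * sign(sign_m)
  z <- (z_t + z_m) / sqrt(2)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(z_combined = z, p_combined = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment returning q-values in input order: sort p
#' ascending, take the running minimum from the largest rank of
#' `p * m / rank`, cap at 1.
#'
#' @param p Finite p-values in (0, 1].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must be finite and in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `q_fdr <= fdr_cut` and `|log2fc| >= lfc_cut` (both
#' thresholds inclusive). Direction is `up`/`down` by the sign of the fold
#' change, `none` for non-DEGs.
#'
#' @param table Data.frame with columns `q_fdr` and `log2fc`.
#' @param cfg A [comparison_config()] supplying the cuts.
#' @return `table` with `is_deg` (logical) and `direction` columns set.
#' @export
call_degs <- function(table, cfg = comparison_config()) {
  stopifnot(all(c("q_fdr", "log2fc") %in% colnames(table)))
  table$is_deg <- table$q_fdr <= cfg$fdr_cut & abs(table$log2fc) >= cfg$lfc_cut
  table$direction <- ifelse(!table$is_deg, "none",
                            ifelse(table$log2fc > 0, "up", "down"))
  table
}

#' Run one treatment-vs-control comparison end to end
#'
#' Applies the full DEG caller to one comparison: per-gene Student t-test
#' and permutation median-difference test on log2 expression, Stouffer
#' combination with effect signs, BH-FDR adjustment, and thresholded DEG
#' calls. The log2 fold change is the difference of group means of the log
#' expression. Fully deterministic given `cfg$seed`.
#'
#' @param counts Count matrix. Filtered and normalized internally unless
#'   `norm` is supplied.
#' @param design A [sample_design()].
#' @param treatment,control Group labels.
#' @param cfg A [comparison_config()].
#' @param norm Optional precomputed `tmm_norm` (from [normalize_counts()],
#'   typically on the filtered matrix) so repeated comparisons share one
#'   normalization.
#' @param filter_threshold Count filter used when `norm` is `NULL`.
#' @return Data.frame (one row per gene, input order) with columns gene,
#'   log2fc, t_stat, p_t, median_diff, p_m, z_combined, p_combined, q_fdr,
#'   is_deg, direction; attribute `summary` holds `n_deg`, `n_up`,
#'   `n_down`, the labels, and the thresholds.
#' @export
run_comparison <- function(counts, design, treatment, control,
                           cfg = comparison_config(), norm = NULL,
                           filter_threshold = 10) {
  .check_counts_design(counts, design)
  if (is.null(norm)) {
    counts <- filter_low_counts(counts, threshold = filter_threshold)
    norm <- normalize_counts(counts)
  }
  log_expr <- norm$log_expr
  eg <- .expr_groups(log_expr, design, treatment, control)
  lfc <- rowMeans(eg$trt) - rowMeans(eg$ctl)
  tt <- ttest_per_gene(log_expr, design, treatment, control, welch = cfg$welch)
  null <- median_null(log_expr, design, treatment, control, cfg)
  md <- median_diff_p(log_expr, design, treatment, control, null)
  st <- stouffer_combine(tt$p_t, md$p_m, sign(lfc), sign(md$median_diff))
  tab <- data.frame(gene = rownames(log_expr),
                    log2fc = unname(lfc),
                    t_stat = tt$t_stat, p_t = tt$p_t,
                    median_diff = md$median_diff, p_m = md$p_m,
                    z_combined = st$z_combined, p_combined = st$p_combined,
                    q_fdr = bh_adjust(st$p_combined),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- call_degs(tab, cfg)
  attr(tab, "summary") <- list(treatment = treatment, control = control,
                               n_deg = sum(tab$is_deg),
                               n_up = sum(tab$direction == "up"),
                               n_down = sum(tab$direction == "down"),
                               fdr_cut = cfg$fdr_cut, lfc_cut = cfg$lfc_cut,
                               null_mode = attr(null, "mode"),
                               n_splits = attr(null, "n_splits"),
                               seed = cfg$seed)
  tab
}

#' One-line DEG tally for a comparison table
#'
#' @param table Result of [run_comparison()].
#' @return Character scalar like
#'   `"EO vs control: 109 DEGs (91 up-regulated and 18 down-regulated)"`.
#' @export
deg_summary <- function(table) {
  s <- attr(table, "summary")
  if (is.null(s)) {
    s <- list(treatment = "treatment", control = "control",
              n_deg = sum(table$is_deg),
              n_up = sum(table$direction == "up"),
              n_down = sum(table$direction == "down"))
  }
  sprintf("%s vs %s: %d DEGs (%d up-regulated and %d down-regulated)",
          s$treatment, s$control, s$n_deg, s$n_up, s$n_down)
}
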