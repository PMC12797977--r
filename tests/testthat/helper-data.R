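# shared fixture builders; everything is generated in code

make_counts <- function(m, genes = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small two-group simulated dataset used across files
small_sim <- function(n_genes = 200, seed = 42, de_fraction = 0,
                      groups = c(control = 4, T1 = 4), ...) {
  simulate_counts(sim_config(n_genes = n_genes, groups = groups,
                             de_fraction = de_fraction, seed = seed, ...))
}

# independent brute-force BH step-up (quadratic min-over-supersets)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    cand <- vapply(seq(r, m), function(j) (m / j) * p[ord[j]], numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# independent exhaustive median-difference enumeration for one comparison
median_null_oracle <- function(x_trt, x_ctl) {
  # x_*: genes x replicates matrices
  pool <- cbind(x_trt, x_ctl)
  n1 <- ncol(x_trt)
  splits <- combn(ncol(pool), n1)
  out <- matrix(NA_real_, nrow(pool), ncol(splits))
  for (j in seq_len(ncol(splits))) {
    a <- splits[, j]
    b <- setdiff(seq_len(ncol(pool)), a)
    for (g in seq_len(nrow(pool))) {
      out[g, j] <- abs(median(pool[g, a]) - median(pool[g, b]))
    }
  }
  out
}

# exact hypergeometric upper tail P(X >= k) by direct enumeration
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- seq(k, min(K, n))
  if (!length(kk)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

expect_file_bytes_equal <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)), readBin(b, "raw", file.size(b)))
}
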