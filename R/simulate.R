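#' Simulation configuration
#'
#' Describes a synthetic bulk RNA-seq experiment with the statistical
#' structure the pipeline assumes: negative-binomial counts with gene-wise
#' dispersion, per-sample scale factors, a multi-group design with one
#' control, and a chosen fraction of genes spiked as differentially
#' expressed per treatment. The default design mirrors an 8-group study
#' (one vehicle control plus seven treatments, four replicates each, 32
#' samples) with ~12,000 expressed genes.
#'
#' The negative binomial is parameterized by mean and dispersion phi with
#' variance = mu + phi * mu^2 (so `size = 1/phi` in [stats::rnbinom()]).
#'
#' @param n_genes Number of genes (default 12000).
#' @param groups Named integer vector of replicate counts per group; the
#'   first name is not special — `control` names the control group. All
#'   counts must be >= 2.
#' @param control Control group label (default "control").
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for
#'   per-gene baseline mean counts (defaults log(250) and 1, giving a
#'   realistic expressed-gene abundance spread).
#' @param dispersion Per-gene NB dispersion: a single positive number, a
#'   vector of length `n_genes`, or a function of the baseline mean
#'   (default 0.1, a typical bulk biological coefficient of variation of
#'   ~0.32).
#' @param size_factors Per-sample scale factors: a numeric vector (length =
#'   total samples), or `NULL` to draw log-normal factors (sdlog 0.15)
#'   rescaled to geometric mean 1.
#' @param de_fraction Fraction of genes differentially expressed in each
#'   treatment vs control (default 0.1); DE sets are drawn independently
#'   per treatment so they may overlap, emulating shared response genes.
#' @param lfc_sampler Function(n) returning n true log2 fold changes with
#'   `|lfc| >= lfc_floor`; default: random sign times
#'   `lfc_floor + Exponential(rate = 2)`.
#' @param lfc_floor Minimum absolute true log2 fold change (default 0.58,
#'   the DEG gate, so spiked genes are detectable by design).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12000L,
                       groups = c(control = 4L, MO = 4L, EO = 4L, KSO = 4L,
                                  DO = 4L, PFF = 4L, sPFF = 4L, Fib = 4L),
                       control = "control",
                       baseline_meanlog = log(250), baseline_sdlog = 1,
                       dispersion = 0.1,
                       size_factors = NULL,
                       de_fraction = 0.1,
                       lfc_sampler = NULL,
                       lfc_floor = 0.58,
                       seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector of replicate counts")
  }
  if (!control %in% names(groups)) stop("control group '", control, "' not in groups")
  if (any(groups < 2L)) stop("every group needs >= 2 replicates")
  if (de_fraction < 0 || de_fraction >= 1) stop("de_fraction must be in [0, 1)")
  if (is.numeric(dispersion) && any(dispersion <= 0)) stop("dispersion must be > 0")
  if (lfc_floor < 0) stop("lfc_floor must be >= 0")
  if (is.null(lfc_sampler)) {
    force(lfc_floor)
    lfc_sampler <- function(n) {
      sample(c(-1, 1), n, replace = TRUE) * (lfc_floor + stats::rexp(n, rate = 2))
    }
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 control = control,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, size_factors = size_factors,
                 de_fraction = de_fraction, lfc_sampler = lfc_sampler,
                 lfc_floor = lfc_floor, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a count matrix with ground truth
#'
#' Draws `count(g, s) ~ NB(mean = baseline_g * 2^lfc(g, group(s)) *
#' size_factor_s, dispersion_g)` independently, with DE genes spiked per
#' treatment according to the configuration. Identical seeds give
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `counts` (matrix, genes x samples), `design`
#'   (a [sample_design()]) and `truth` (class `synthetic_truth`: logical
#'   `is_de` and numeric `true_lfc` matrices of genes x treatments,
#'   per-sample `size_factors`, per-gene `baseline` and `dispersion`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$n_genes
  group_of <- rep(names(cfg$groups), times = cfg$groups)
  samples <- unlist(lapply(names(cfg$groups), function(g) {
    paste(g, seq_len(cfg$groups[[g]]), sep = "_")
  }))
  S <- length(samples)
  treatments <- setdiff(names(cfg$groups), cfg$control)

  .with_seed(cfg$seed, {
    baseline <- stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
    phi <- if (is.function(cfg$dispersion)) {
      cfg$dispersion(baseline)
    } else {
      rep_len(cfg$dispersion, G)
    }
    if (any(phi <= 0)) stop("dispersion must be > 0")
    sf <- cfg$size_factors
    if (is.null(sf)) {
      sf <- stats::rlnorm(S, 0, 0.15)
      sf <- sf / exp(mean(log(sf)))
    }
    if (length(sf) != S) stop("size_factors length must equal total sample count")
    if (any(sf <= 0)) stop("size factors must be positive")

    is_de <- matrix(FALSE, G, length(treatments),
                    dimnames = list(NULL, treatments))
    true_lfc <- matrix(0, G, length(treatments),
                       dimnames = list(NULL, treatments))
    n_de <- round(cfg$de_fraction * G)
    for (tr in treatments) {
      if (n_de > 0L) {
        idx <- sample.int(G, n_de)
        is_de[idx, tr] <- TRUE
        true_lfc[idx, tr] <- cfg$lfc_sampler(n_de)
      }
    }
    if (any(abs(true_lfc[is_de]) < cfg$lfc_floor)) {
      stop("lfc_sampler produced |lfc| below the floor ", cfg$lfc_floor)
    }

    gene_ids <- sprintf("g%05d", seq_len(G))
    counts <- matrix(0, G, S, dimnames = list(gene_ids, samples))
    for (s in seq_len(S)) {
      grp <- group_of[s]
      lfc_s <- if (grp == cfg$control) 0 else true_lfc[, grp]
      mu <- baseline * 2^lfc_s * sf[s]
      counts[, s] <- stats::rnbinom(G, mu = mu, size = 1 / phi)
    }

    rownames(is_de) <- gene_ids
    rownames(true_lfc) <- gene_ids
    truth <- structure(list(is_de = is_de, true_lfc = true_lfc,
                            size_factors = stats::setNames(sf, samples),
                            baseline = stats::setNames(baseline, gene_ids),
                            dispersion = stats::setNames(phi, gene_ids)),
                       class = "synthetic_truth")
    list(counts = counts,
         design = sample_design(samples, group_of, cfg$control),
         truth = truth)
  })
}

#' Simulate a null dataset (no differential expression)
#'
#' [simulate_counts()] with `de_fraction` forced to 0; convenience for
#' false-discovery-rate suites.
#'
#' @inheritParams simulate_counts
#' @return As [simulate_counts()]; `truth$is_de` is all-FALSE.
#' @export
simulate_null <- function(cfg) {
  cfg$de_fraction <- 0
  simulate_counts(cfg)
}
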