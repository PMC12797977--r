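.log_stage <- function(...) {
  message("[ihtseq ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}

.cfg_get <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate/load -> filter -> TMM + log2-CPM -> per-treatment
#' DEG calling -> gene-set enrichment -> radar export, writing one DEG
#' table per comparison, enrichment tables, an optional radar matrix, and
#' a JSON run manifest recording the configuration snapshot, seeds,
#' per-comparison tallies and the file inventory. Identical configurations
#' (same seeds) give byte-identical result tables.
#'
#' The configuration is a YAML file or an equivalent nested list with
#' blocks:
#' \describe{
#'   \item{simulate}{arguments for [sim_config()] (used when no `counts`
#'     path is given).}
#'   \item{counts, design, control}{paths to a count matrix and design
#'     table plus the control group label, for real data.}
#'   \item{comparisons}{treatment labels to test (default: every
#'     non-control group).}
#'   \item{filter}{`threshold` (default 10; strict `>` in all samples).}
#'   \item{tmm}{`trim_m`, `trim_a`, `reference`.}
#'   \item{logcpm}{`pseudocount` (default 1).}
#'   \item{deg}{`fdr_cut` (0.05), `lfc_cut` (0.58), `mode`, `n_perm`,
#'     `seed`.}
#'   \item{enrich}{`gmt` path, `direction` (up/down/all; default up),
#'     `fdr_cut` (0.05).}
#'   \item{radar}{`pathways`, `cap_min` (0), `cap_max` (required if the
#'     block is present).}
#' }
#'
#' @param config Path to a YAML config file, or a nested list.
#' @param out Output directory (overrides the config's `out`).
#' @return The run manifest, invisibly (also written to
#'   `out/manifest.json`).
#' @export
run_pipeline <- function(config, out = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML path or a list")
  out <- out %||% .cfg_get(cfg, "out") %||% stop("no output directory given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  files <- character(0)

  # ---- input stage: simulate or load -------------------------------------
  if (!is.null(cfg$counts)) {
    .log_stage("loading counts from ", cfg$counts)
    counts <- read_counts(cfg$counts)
    if (is.null(cfg$design)) stop("config gives counts but no design path")
    design <- read_design(cfg$design, control = .cfg_get(cfg, "control"))
  } else if (!is.null(cfg$simulate)) {
    .log_stage("simulating counts")
    sim_args <- cfg$simulate
    if (!is.null(sim_args$groups)) sim_args$groups <- unlist(sim_args$groups)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_counts(scfg)
    counts <- sim$counts
    design <- sim$design
    write_counts(counts, file.path(out, "counts.tsv"))
    write_design(design, file.path(out, "design.tsv"))
    .write_truth(sim$truth, out)
    files <- c(files, "counts.tsv", "design.tsv", "truth_lfc.tsv", "truth_size_factors.tsv")
  } else {
    stop("config must provide either a 'counts' path or a 'simulate' block")
  }
  .check_counts_design(counts, design)

  comparisons <- .cfg_get(cfg, "comparisons",
                          setdiff(design$groups, design$control))
  comparisons <- as.character(comparisons)
  bad <- setdiff(comparisons, design$groups)
  if (length(bad)) {
    stop("comparison group(s) absent from design: ", paste(bad, collapse = ", "))
  }
  timing$input <- proc.time()[["elapsed"]] - t0

  # ---- filter + normalize ------------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  thr <- .cfg_get(cfg$filter, "threshold", 10)
  .log_stage("filtering (count > ", thr, " in all samples)")
  filtered <- filter_low_counts(counts, threshold = thr)
  .log_stage(nrow(filtered), " of ", nrow(counts), " genes retained")
  norm <- normalize_counts(filtered,
                           trim_m = .cfg_get(cfg$tmm, "trim_m", 0.3),
                           trim_a = .cfg_get(cfg$tmm, "trim_a", 0.05),
                           reference = .cfg_get(cfg$tmm, "reference"),
                           pseudocount = .cfg_get(cfg$logcpm, "pseudocount", 1.0))
  timing$normalize <- proc.time()[["elapsed"]] - t1

  # ---- DEG calling per comparison ----------------------------------------
  t2 <- proc.time()[["elapsed"]]
  dcfg <- comparison_config(
    fdr_cut = .cfg_get(cfg$deg, "fdr_cut", 0.05),
    lfc_cut = .cfg_get(cfg$deg, "lfc_cut", 0.58),
    mode = .cfg_get(cfg$deg, "mode", "auto"),
    n_perm = .cfg_get(cfg$deg, "n_perm", 10000L),
    seed = .cfg_get(cfg$deg, "seed", 1L),
    welch = .cfg_get(cfg$deg, "welch", FALSE))
  deg_tables <- list()
  tallies <- list()
  for (tr in comparisons) {
    .log_stage("DEG calling: ", tr, " vs ", design$control)
    tab <- run_comparison(counts, design, tr, design$control,
                          cfg = dcfg, norm = norm)
    deg_tables[[tr]] <- tab
    fn <- paste0("deg_", tr, ".tsv")
    write_deg_table(tab, file.path(out, fn))
    files <- c(files, fn)
    s <- attr(tab, "summary")
    tallies[[tr]] <- list(n_deg = s$n_deg, n_up = s$n_up, n_down = s$n_down)
    .log_stage(deg_summary(tab))
  }
  timing$deg <- proc.time()[["elapsed"]] - t2

  # ---- enrichment + radar ------------------------------------------------
  enr_tables <- NULL
  if (!is.null(cfg$enrich) && !is.null(cfg$enrich$gmt)) {
    t3 <- proc.time()[["elapsed"]]
    sets <- read_gmt(cfg$enrich$gmt)
    direction <- .cfg_get(cfg$enrich, "direction", "up")
    universe <- rownames(norm$log_expr)
    enr_tables <- list()
    for (tr in comparisons) {
      tab <- deg_tables[[tr]]
      query <- switch(direction,
                      up = tab$gene[tab$direction == "up"],
                      down = tab$gene[tab$direction == "down"],
                      all = tab$gene[tab$is_deg],
                      stop("enrich direction must be up, down or all"))
      .log_stage("enrichment: ", tr, " (", length(query), " ", direction,
                 "-regulated query genes)")
      enr <- fisher_enrichment(query, universe, sets,
                               fdr_cut = .cfg_get(cfg$enrich, "fdr_cut", 0.05))
      enr_tables[[tr]] <- enr
      fn <- paste0("enrichment_", tr, ".tsv")
      write_enrichment_table(enr, file.path(out, fn))
      files <- c(files, fn)
    }
    if (!is.null(cfg$radar)) {
      pathways <- .cfg_get(cfg$radar, "pathways", names(sets))
      spec <- radar_values(enr_tables, as.character(pathways),
                           cap_min = .cfg_get(cfg$radar, "cap_min", 0),
                           cap_max = cfg$radar$cap_max)
      write_radar_table(spec, file.path(out, "radar.tsv"))
      files <- c(files, "radar.tsv")
    }
    timing$enrich <- proc.time()[["elapsed"]] - t3
  }

  # ---- manifest ----------------------------------------------------------
  manifest <- list(
    package = "ihtseq",
    version = as.character(utils::packageVersion("ihtseq")),
    config = cfg,
    control = design$control,
    comparisons = comparisons,
    n_genes_input = nrow(counts),
    n_genes_filtered = nrow(filtered),
    thresholds = list(filter = thr, fdr_cut = dcfg$fdr_cut,
                      lfc_cut = dcfg$lfc_cut),
    seed = dcfg$seed,
    tallies = tallies,
    files = files,
    timing_sec = lapply(timing, function(x) round(x, 3))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log_stage("done; manifest at ", file.path(out, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_truth <- function(truth, out) {
  lfc <- truth$true_lfc
  m <- cbind(gene = rownames(lfc),
             as.data.frame(lfc, check.names = FALSE))
  .write_table(m, file.path(out, "truth_lfc.tsv"), "\t",
               num_cols = colnames(lfc))
  sf <- data.frame(sample = names(truth$size_factors),
                   size_factor = unname(truth$size_factors))
  .write_table(sf, file.path(out, "truth_size_factors.tsv"), "\t",
               num_cols = "size_factor")
  invisible(NULL)
}

#' Summarize a run manifest
#'
#' Rebuilds the human-readable tally report (comparisons by n_deg / n_up /
#' n_down plus a threshold echo) from a manifest. Regeneration is
#' idempotent; tallies equal direct recounts from the persisted DEG
#' tables.
#'
#' @param manifest A manifest list from [run_pipeline()] or a path to
#'   `manifest.json`.
#' @return Data.frame with columns comparison, n_deg, n_up, n_down;
#'   printed as a small report with the thresholds.
#' @export
summarize_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  tallies <- manifest$tallies
  df <- if (length(tallies)) {
    data.frame(comparison = names(tallies),
               n_deg = vapply(tallies, function(x) as.integer(x$n_deg), integer(1)),
               n_up = vapply(tallies, function(x) as.integer(x$n_up), integer(1)),
               n_down = vapply(tallies, function(x) as.integer(x$n_down), integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(comparison = character(), n_deg = integer(),
               n_up = integer(), n_down = integer())
  }
  thr <- manifest$thresholds
  if (!is.null(thr)) {
    cat(sprintf("DEG thresholds: FDR <= %s, |log2FC| >= %s (count filter > %s)\n",
                thr$fdr_cut, thr$lfc_cut, thr$filter))
  }
  print(df, row.names = FALSE)
  invisible(df)
}
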