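#' One-sided Fisher's exact gene-set over-representation
#'
#' For each gene set, tests whether the query (e.g. the up-regulated DEGs
#' of one comparison) overlaps the set more than expected under random
#' sampling from the universe. The p-value is the hypergeometric upper
#' tail P(X >= k) with N = universe size, K = set size within the
#' universe, n = query size, k = overlap; q-values come from
#' [bh_adjust()] across the tested sets and significance is `q < fdr_cut`
#' (strict).
#'
#' Sets are intersected with the universe first; sets with an empty
#' intersection are skipped.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of background genes (typically all
#'   genes surviving [filter_low_counts()]).
#' @param sets A `gene_sets` collection from [read_gmt()] (or a named list
#'   of character vectors).
#' @param fdr_cut Significance threshold on q (strict `<`; default 0.05).
#' @return Data.frame with one row per tested set: set_id, description, k,
#'   K, n, N, p_fisher, q_fdr, neg_log10_q, significant; rows in collection
#'   order.
#' @export
fisher_enrichment <- function(query, universe, sets, fdr_cut = 0.05) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  off <- setdiff(query, universe)
  if (length(off)) {
    stop("query gene(s) not in universe: ", paste(off, collapse = ", "))
  }
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("", length(sets)), names(sets))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    # upper tail P(X >= k), exact at k = 0 (p = 1)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = nm, description = unname(descs[[nm]]),
               k = k, K = K, n = n, N = N, p_fisher = min(p, 1),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p_fisher = numeric(), q_fdr = numeric(),
                      neg_log10_q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_fdr <- bh_adjust(out$p_fisher)
  out$neg_log10_q <- -log10(out$q_fdr)
  out$significant <- out$q_fdr < fdr_cut
  rownames(out) <- NULL
  out
}

#' Capped -log10(q) matrix for radar charts
#'
#' Collects, for a fixed ordered list of pathways across several
#' comparisons, the enrichment signal `-log10(q)` clipped into
#' `[cap_min, cap_max]` — the fixed-range convention radar plots need so
#' axes are comparable across panels. A pathway missing from a comparison's
#' table contributes `cap_min` (with a message).
#'
#' @param tables Named list of enrichment tables (one per comparison) from
#'   [fisher_enrichment()]; names label the comparisons.
#' @param pathways Ordered character vector of set_ids to display.
#' @param cap_min,cap_max Display range; every exported value is clipped
#'   into it. `cap_max` has no default: choose it per figure.
#' @return Object of class `radar_spec`: numeric matrix (rows =
#'   comparisons, columns = pathways) with `cap_min`/`cap_max` attributes.
#' @export
radar_values <- function(tables, pathways, cap_min = 0, cap_max) {
  if (missing(cap_max)) stop("cap_max must be given (no default display range)")
  if (cap_min >= cap_max) stop("cap_min must be < cap_max")
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  m <- matrix(cap_min, nrow = length(tables), ncol = length(pathways),
              dimnames = list(names(tables), pathways))
  for (cmp in names(tables)) {
    tab <- tables[[cmp]]
    hit <- match(pathways, tab$set_id)
    absent <- pathways[is.na(hit)]
    if (length(absent)) {
      message("radar_values: pathway(s) absent from '", cmp, "', using cap_min: ",
              paste(absent, collapse = ", "))
    }
    vals <- tab$neg_log10_q[hit]
    vals[is.na(vals)] <- cap_min
    m[cmp, ] <- pmin(pmax(vals, cap_min), cap_max)
  }
  structure(m, cap_min = cap_min, cap_max = cap_max, class = c("radar_spec", "matrix"))
}

#' Write radar-chart values as delimited text
#'
#' Rows are comparisons, columns pathways; any plotting layer (e.g. fmsb)
#' can consume the file directly.
#'
#' @param spec A `radar_spec` from [radar_values()].
#' @param path Output path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_radar_table <- function(spec, path, delimiter = NULL) {
  stopifnot(inherits(spec, "radar_spec"))
  sep <- .detect_delim(path, delimiter)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("comparison", colnames(spec)), collapse = sep), con)
  for (i in seq_len(nrow(spec))) {
    writeLines(paste(c(rownames(spec)[i], .format_num(spec[i, ])), collapse = sep), con)
  }
  invisible(path)
}
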