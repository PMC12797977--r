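#' Read a long-format Ct table
#'
#' Expects columns `sample`, `group`, `gene`, `ct`.
#'
#' @param path Path to a delimited text file.
#' @inheritParams read_counts
#' @return Data.frame with those four columns.
#' @export
read_ct_table <- function(path, delimiter = NULL) {
  sep <- .detect_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% colnames(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.numeric(df$ct)) stop("ct column must be numeric")
  df[, need]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR relative quantification with amplification efficiency
#' fixed at 2: technical replicates are averaged on the Ct scale per
#' sample and gene, then per sample
#' `dCt = Ct(target) - Ct(reference)`,
#' `ddCt = dCt - mean(dCt over calibrator-group samples)`, and
#' `fold = 2^(-ddCt)`. By construction the calibrator group's folds have
#' geometric mean exactly 1, and adding a constant to every Ct value
#' leaves folds unchanged.
#'
#' @param ct Long-format data.frame with columns `sample`, `group`,
#'   `gene`, `ct` (see [read_ct_table()]).
#' @param target_gene Gene to quantify.
#' @param reference_gene Housekeeping reference gene (e.g. beta-actin).
#' @param calibrator_group Group whose mean dCt anchors fold = 1
#'   (typically the vehicle control).
#' @return Data.frame with one row per sample: sample, group, dct, ddct,
#'   fold.
#' @export
ddct_fold <- function(ct, target_gene, reference_gene, calibrator_group) {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(is.data.frame(ct), all(need %in% colnames(ct)))
  if (!calibrator_group %in% ct$group) {
    stop("calibrator group '", calibrator_group, "' absent from Ct table")
  }
  sub <- ct[ct$gene %in% c(target_gene, reference_gene), , drop = FALSE]
  # technical replicates averaged on the Ct scale
  agg <- stats::aggregate(ct ~ sample + group + gene, data = sub, FUN = mean)
  tgt <- agg[agg$gene == target_gene, ]
  ref <- agg[agg$gene == reference_gene, ]
  if (!nrow(tgt)) stop("no Ct values for target gene '", target_gene, "'")
  missing_ref <- setdiff(tgt$sample, ref$sample)
  if (length(missing_ref)) {
    stop("missing reference-gene Ct for sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  i <- match(tgt$sample, ref$sample)
  dct <- tgt$ct - ref$ct[i]
  cal <- tgt$group == calibrator_group
  if (!any(cal)) stop("no samples of calibrator group carry the target gene")
  ddct <- dct - mean(dct[cal])
  data.frame(sample = tgt$sample, group = tgt$group,
             dct = dct, ddct = ddct, fold = 2^(-ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}
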