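# Delimiter convention: .csv -> comma, anything else -> tab, overridable.
.detect_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

.format_num <- function(x) {
  # full round-trip precision for doubles; integers stay integral
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}

#' Read a gene-by-sample count matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values may be fractional:
#' estimated counts from quantifiers such as RSEM are accepted as-is.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter. Defaults to comma for `.csv` files and
#'   tab otherwise.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names, in file order.
#' @export
read_counts <- function(path, delimiter = NULL) {
  sep <- .detect_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("count file must have a gene-ID column plus >=1 sample column")
  gene_ids <- as.character(df[[1L]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene ID(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicate sample ID(s) in ", path, ": ", paste(unique(dup_s), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (length(bad)) {
      paste0(" (first at gene ", gene_ids[bad[1L, 1L]], ", sample ",
             sample_ids[bad[1L, 2L]], ")")
    } else ""
    stop("non-numeric count value in ", path, loc)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing/non-numeric count at gene ", gene_ids[bad[1L, 1L]],
         ", sample ", sample_ids[bad[1L, 2L]])
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop("negative count at gene ", gene_ids[bad[1L, 1L]], ", sample ",
         sample_ids[bad[1L, 2L]])
  }
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  colnames(m) <- sample_ids
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Checks the invariants the pipeline assumes: a numeric matrix with unique,
#' non-missing gene and sample identifiers and no negative entries.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ID(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ID(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative and non-missing")
  counts
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: writes genes in rows with the gene-ID column
#' first, at full double precision so read/write round-trips are exact.
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, delimiter = NULL) {
  validate_counts(counts)
  sep <- .detect_delim(path, delimiter)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(counts)), collapse = sep), con)
  body <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i], .format_num(counts[i, ])), collapse = sep)
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Construct a sample design
#'
#' @param samples Character vector of sample identifiers.
#' @param groups Character vector (parallel to `samples`) of group labels.
#' @param control Label of the control group.
#' @return An object of class `sample_design`: list with `assignments`
#'   (named character vector, sample -> group), `control`, `groups` (unique
#'   labels, control first then remaining in first-appearance order) and
#'   `replicates` (named integer vector of per-group sample counts).
#' @export
sample_design <- function(samples, groups, control) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (length(samples) != length(groups)) stop("samples and groups differ in length")
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID(s) in design: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (!control %in% groups) stop("control group '", control, "' absent from design")
  reps <- table(groups)
  small <- names(reps)[reps < 2L]
  if (length(small)) {
    stop("group(s) with fewer than 2 replicates: ", paste(small, collapse = ", "))
  }
  # canonical form: assignments sorted by sample ID, control group first then
  # remaining groups alphabetically, so the object is independent of row order
  ord <- order(samples, method = "radix")
  assignments <- stats::setNames(groups[ord], samples[ord])
  lv <- c(control, sort(setdiff(unique(groups), control), method = "radix"))
  structure(list(assignments = assignments,
                 control = control,
                 groups = lv,
                 replicates = stats::setNames(as.integer(reps[lv]), lv)),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", length(x$assignments), "samples,",
      length(x$groups), "groups (control:", x$control, ")\n")
  print(x$replicates)
  invisible(x)
}

#' Read a sample design table
#'
#' Expects a delimited file with columns `sample` and `group` (an optional
#' logical/0-1 `is_control` column may flag the control group instead of the
#' `control` argument). Row order is irrelevant.
#'
#' @param path Path to the design file.
#' @param control Control group label; required unless the file carries an
#'   `is_control` column.
#' @inheritParams read_counts
#' @return A [sample_design()] object.
#' @export
read_design <- function(path, control = NULL, delimiter = NULL) {
  sep <- .detect_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "group")
  if (!all(need %in% colnames(df))) {
    stop("design file must have 'sample' and 'group' columns")
  }
  if (is.null(control)) {
    if (!"is_control" %in% colnames(df)) {
      stop("control group not given and no 'is_control' column present")
    }
    flag <- as.logical(df$is_control)
    ctrl <- unique(df$group[flag %in% TRUE])
    if (length(ctrl) != 1L) stop("'is_control' must flag exactly one group")
    control <- ctrl
  }
  sample_design(df$sample, df$group, control)
}

#' Write a sample design table
#'
#' @param design A [sample_design()] object.
#' @param path Output path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, delimiter = NULL) {
  stopifnot(inherits(design, "sample_design"))
  sep <- .detect_delim(path, delimiter)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample", "group", "is_control"), collapse = sep), con)
  grp <- unname(design$assignments)
  writeLines(paste(names(design$assignments), grp,
                   as.integer(grp == design$control), sep = sep), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per tab-separated line, fields are set name,
#' description, then member genes. Duplicate members within a line are
#' dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_sets`: named list of character vectors
#'   of member genes, with a named character `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields (name, description, members...)")
    }
    nm <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " (set ", nm, ") has no members")
    if (anyDuplicated(members)) {
      warning("duplicate member(s) in set ", nm, "; deduplicated")
      members <- unique(members)
    }
    if (nm %in% names(sets)) stop("duplicate set name in GMT: ", nm)
    sets[[nm]] <- members
    descs[nm] <- fields[2L]
  }
  structure(sets, descriptions = descs, class = "gene_sets")
}

#' Write a GMT gene-set collection
#'
#' @param sets A `gene_sets` object (or plain named list of character
#'   vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("", length(sets)), names(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(sets)) {
    writeLines(paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

# fixed, documented column orders for result tables
.deg_cols <- c("gene", "log2fc", "t_stat", "p_t", "median_diff", "p_m",
               "z_combined", "p_combined", "q_fdr", "is_deg", "direction")
.enr_cols <- c("set_id", "description", "k", "K", "n", "N",
               "p_fisher", "q_fdr", "neg_log10_q", "significant")

.write_table <- function(df, path, sep, num_cols) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = sep), con)
  if (nrow(df)) {
    cols <- lapply(colnames(df), function(cn) {
      v <- df[[cn]]
      if (cn %in% num_cols && is.double(v)) .format_num(v)
      else if (is.logical(v)) as.character(as.integer(v))
      else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = sep)), con)
  }
  invisible(path)
}

#' Write a per-gene differential-expression result table
#'
#' Columns, in fixed order: gene, log2fc, t_stat, p_t, median_diff, p_m,
#' z_combined, p_combined, q_fdr, is_deg (0/1), direction. Rows keep the
#' input gene order; doubles are serialized at full precision, so writing is
#' deterministic and round-trips exactly.
#'
#' @param table A gene test table as returned by [run_comparison()].
#' @param path Output path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path, delimiter = NULL) {
  stopifnot(is.data.frame(table), all(.deg_cols %in% colnames(table)))
  sep <- .detect_delim(path, delimiter)
  .write_table(table[, .deg_cols, drop = FALSE], path, sep,
               num_cols = setdiff(.deg_cols, c("gene", "is_deg", "direction")))
}

#' Read back a differential-expression result table
#'
#' @param path Path written by [write_deg_table()].
#' @inheritParams read_counts
#' @return A data.frame with the fixed DEG-table columns; `is_deg` logical.
#' @export
read_deg_table <- function(path, delimiter = NULL) {
  sep <- .detect_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(gene = "character", direction = "character"))
  df$is_deg <- as.logical(df$is_deg)
  df[, .deg_cols, drop = FALSE]
}

#' Write a gene-set enrichment result table
#'
#' Rows are ordered by ascending FDR q then set identifier, so equal inputs
#' give byte-identical files.
#'
#' @param result Enrichment table from [fisher_enrichment()].
#' @param path Output path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(result, path, delimiter = NULL) {
  stopifnot(is.data.frame(result), all(.enr_cols %in% colnames(result)))
  sep <- .detect_delim(path, delimiter)
  ord <- order(result$q_fdr, result$set_id, method = "radix")
  .write_table(result[ord, .enr_cols, drop = FALSE], path, sep,
               num_cols = c("p_fisher", "q_fdr", "neg_log10_q"))
}

#' Read back an enrichment result table
#'
#' @param path Path written by [write_enrichment_table()].
#' @inheritParams read_counts
#' @return A data.frame with the fixed enrichment columns.
#' @export
read_enrichment_table <- function(path, delimiter = NULL) {
  sep <- .detect_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(set_id = "character", description = "character"))
  df$significant <- as.logical(df$significant)
  df[, .enr_cols, drop = FALSE]
}

# design/counts consistency check used at pipeline assembly
.check_counts_design <- function(counts, design) {
  missing <- setdiff(colnames(counts), names(design$assignments))
  if (length(missing)) {
    stop("sample(s) in counts but absent from design: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
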