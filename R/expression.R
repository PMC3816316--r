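#' Construct an ExpressionMatrix
#'
#' Container for gene- or isoform-level expression estimates (counts, TPM
#' or FPKM) over the technical replicates of exactly two biological
#' conditions.
#'
#' @param values Non-negative numeric matrix, elements x replicate
#'   columns, with element ids as rownames.
#' @param condition Factor (or character) of length `ncol(values)` with
#'   exactly two levels assigning each column to a condition.  The first
#'   level is the fold-change numerator by default.
#' @param symbols Optional character vector of gene symbols per element
#'   (HGNC-style; may contain empty strings).  Defaults to the element ids.
#' @param unit One of `"count"`, `"TPM"`, `"FPKM"`.
#' @return Object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, condition, symbols = NULL,
                              unit = c("count", "TPM", "FPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must carry element ids as rownames")
  if (anyDuplicated(rownames(values))) stop("element ids must be unique")
  if (any(values < 0)) stop("expression values must be non-negative")
  condition <- as.factor(condition)
  if (length(condition) != ncol(values)) {
    stop("condition must have one entry per column")
  }
  if (nlevels(condition) != 2L) {
    stop("exactly two conditions are required, got ", nlevels(condition))
  }
  if (is.null(symbols)) symbols <- rownames(values)
  symbols <- trimws(symbols)
  if (length(symbols) != nrow(values)) {
    stop("symbols must have one entry per element")
  }
  structure(list(values = values, condition = condition,
                 symbols = symbols, unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "elements x", ncol(x$values),
      "replicates (", x$unit, ")\n")
  for (lv in levels(x$condition)) {
    cat("  ", lv, ":", sum(x$condition == lv), "replicate(s)\n")
  }
  invisible(x)
}

#' Read an expression table from TSV
#'
#' Expected layout: first column element id, optional second column gene
#' symbol (detected when non-numeric), remaining columns replicate values
#' named `<condition>_<replicate>`.
#'
#' @param path Path to the TSV file.
#' @param condition Optional explicit condition assignment (character or
#'   factor, one per replicate column); by default conditions are derived
#'   by stripping the trailing `_<replicate>` from column names.
#' @param unit One of `"count"`, `"TPM"`, `"FPKM"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition = NULL,
                            unit = c("count", "TPM", "FPKM")) {
  unit <- match.arg(unit)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) stop("expression table needs id plus >=2 value columns")
  ids <- as.character(df[[1L]])
  has_symbol <- !is.numeric(df[[2L]])
  symbols <- if (has_symbol) as.character(df[[2L]]) else NULL
  vals <- as.matrix(df[, (if (has_symbol) 3L else 2L):ncol(df), drop = FALSE])
  if (!is.numeric(vals)) stop("replicate columns must be numeric")
  rownames(vals) <- ids
  if (is.null(condition)) condition <- sub("_[^_]*$", "", colnames(vals))
  expression_matrix(vals, condition = condition, symbols = symbols,
                    unit = unit)
}

#' Cross-annotation common genes
#'
#' Intersects the gene-symbol sets of several annotations.  Empty and
#' missing symbols are excluded before intersecting; matching is
#' case-sensitive after whitespace trimming.
#'
#' @param symbol_sets List (length >= 2) of character vectors of gene
#'   symbols, one per annotation.
#' @return Sorted character vector: the symbols present in every set.
#' @export
common_genes <- function(symbol_sets) {
  stopifnot(is.list(symbol_sets), length(symbol_sets) >= 2L)
  clean <- lapply(symbol_sets, function(s) {
    s <- trimws(as.character(s))
    unique(s[!is.na(s) & nzchar(s)])
  })
  if (any(vapply(clean, length, integer(1)) == 0L)) {
    stop("symbol sets must be non-empty")
  }
  sort(Reduce(intersect, clean))
}

#' Define a gene/isoform subgroup
#'
#' Stability and presence metrics are computed over subgroups: all genes of
#' an annotation, the cross-annotation common genes, the annotation's
#' uncommon (annotation-specific) genes, or all isoforms.
#'
#' @param kind One of `"all_genes"`, `"common_genes"`, `"uncommon_genes"`,
#'   `"all_isoforms"`.
#' @param symbols For `common_genes` / `uncommon_genes`: the
#'   cross-annotation symbol intersection (from [common_genes()]).
#' @return Object of class `SubgroupSpec`.
#' @export
subgroup_spec <- function(kind = c("all_genes", "common_genes",
                                   "uncommon_genes", "all_isoforms"),
                          symbols = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("common_genes", "uncommon_genes") && is.null(symbols)) {
    stop(kind, " requires the common-gene symbol set")
  }
  structure(list(kind = kind,
                 symbols = if (!is.null(symbols)) trimws(symbols)),
            class = "SubgroupSpec")
}

# row indices of a matrix belonging to a subgroup; gene subgroups match by
# symbol, isoform subgroups by element id
subgroup_rows <- function(mat, subgroup) {
  if (is.null(subgroup)) subgroup <- subgroup_spec("all_genes")
  stopifnot(is(subgroup, "SubgroupSpec"))
  switch(subgroup$kind,
         all_genes = ,
         all_isoforms = seq_len(nrow(mat$values)),
         common_genes = which(mat$symbols %in% subgroup$symbols),
         uncommon_genes = which(!(mat$symbols %in% subgroup$symbols)))
}

#' Percentage of present elements
#'
#' A genomic element is "present" when it has nonzero expression in at
#' least one technical replicate (either condition); under a poly-A
#' protocol, absent elements are typically un-expressed or small RNAs.
#'
#' @param mat An [expression_matrix()].
#' @param subgroup A [subgroup_spec()]; default all elements.
#' @return Percentage (0-100) of subgroup elements that are present.
#' @export
present_percentage <- function(mat, subgroup = NULL) {
  stopifnot(is(mat, "ExpressionMatrix"))
  rows <- subgroup_rows(mat, subgroup)
  if (length(rows) == 0L) stop("empty subgroup")
  present <- rowSums(mat$values[rows, , drop = FALSE] > 0) > 0
  100 * mean(present)
}

#' Average coefficient of variation across replicates
#'
#' Replicate-to-replicate stability of expression estimates.  Within each
#' condition the per-element CV is the sample (n-1) standard deviation
#' across that condition's replicates divided by the replicate mean; the
#' condition's CV is the average over elements, and the reported value is
#' the mean of the two condition CVs:
#' \deqn{\mathrm{AvgCV} = \frac{1}{2}\left(\frac{1}{n_1}\sum_i S_i/\bar
#'   x_i\Big|_{c_1} + \frac{1}{n_2}\sum_i S_i/\bar x_i\Big|_{c_2}\right)}
#'
#' Elements absent in every replicate (both conditions) are removed first.
#' An element whose mean is zero in one condition only is, by default,
#' excluded from that condition's sum with `n` reduced accordingly
#' (`zero_mean = "exclude"`), since `S/mean` is undefined;
#' `zero_mean = "zero"` instead keeps it with a CV contribution of 0.
#'
#' @param mat An [expression_matrix()]; each condition needs >= 2
#'   replicates.
#' @param subgroup A [subgroup_spec()]; default all elements.
#' @param zero_mean `"exclude"` (default) or `"zero"`; see Details.
#' @return The average CV (dimensionless, >= 0).
#' @export
average_cv <- function(mat, subgroup = NULL,
                       zero_mean = c("exclude", "zero")) {
  stopifnot(is(mat, "ExpressionMatrix"))
  zero_mean <- match.arg(zero_mean)
  reps <- table(mat$condition)
  if (any(reps < 2L)) {
    stop("each condition needs >= 2 replicates for a sample SD; got ",
         paste(sprintf("%s=%d", names(reps), reps), collapse = ", "))
  }
  present <- rowSums(mat$values > 0) > 0
  rows <- intersect(subgroup_rows(mat, subgroup), which(present))
  if (length(rows) == 0L) {
    stop("subgroup empty after removing all-absent elements")
  }
  v <- mat$values[rows, , drop = FALSE]
  cond_cv <- vapply(levels(mat$condition), function(lv) {
    x <- v[, mat$condition == lv, drop = FALSE]
    m <- rowMeans(x)
    s <- apply(x, 1L, sd)
    if (zero_mean == "exclude") {
      ok <- m > 0
      if (!any(ok)) stop("no expressed elements in condition ", lv)
      mean(s[ok] / m[ok])
    } else {
      cv <- ifelse(m > 0, s / m, 0)
      mean(cv)
    }
  }, numeric(1))
  mean(cond_cv)
}

#' Stability report over annotations and subgroups
#'
#' Convenience wrapper computing [average_cv()] and
#' [present_percentage()] for one expression matrix over several
#' subgroups.
#'
#' @param mat An [expression_matrix()].
#' @param subgroups Named list of [subgroup_spec()] objects.
#' @param source_name Annotation label recorded in the output.
#' @return `data.frame` with columns `source_name`, `subgroup`,
#'   `n_elements`, `average_cv`, `present_percentage`.
#' @export
stability_report <- function(mat, subgroups, source_name = "") {
  rows <- lapply(names(subgroups), function(nm) {
    sg <- subgroups[[nm]]
    data.frame(source_name = source_name, subgroup = nm,
               n_elements = length(subgroup_rows(mat, sg)),
               average_cv = average_cv(mat, sg),
               present_percentage = present_percentage(mat, sg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
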