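#' Per-gene log2 fold-change between two conditions
#'
#' `log2((mean_num + pseudocount) / (mean_den + pseudocount))` over each
#' condition's replicate means.  Elements with zero mean in both
#' conditions are dropped (count recorded in the `"n_dropped"` attribute);
#' with `pseudocount = 0`, elements with zero mean in exactly one
#' condition have an infinite fold-change and are dropped with a warning.
#'
#' @param mat An [expression_matrix()].
#' @param pseudocount Non-negative value added to both means; default 0.
#' @param numerator,denominator Condition names; default the first and
#'   second level of `mat$condition`.
#' @return `data.frame` with columns `id`, `symbol`, `log2_fc`;
#'   attribute `n_dropped` counts removed elements.
#' @export
log2_fold_change <- function(mat, pseudocount = 0, numerator = NULL,
                             denominator = NULL) {
  stopifnot(is(mat, "ExpressionMatrix"), pseudocount >= 0)
  lv <- levels(mat$condition)
  if (is.null(numerator)) numerator <- lv[1L]
  if (is.null(denominator)) denominator <- lv[2L]
  stopifnot(numerator %in% lv, denominator %in% lv,
            numerator != denominator)
  m1 <- rowMeans(mat$values[, mat$condition == numerator, drop = FALSE])
  m2 <- rowMeans(mat$values[, mat$condition == denominator, drop = FALSE])
  both_zero <- m1 == 0 & m2 == 0
  fc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  undefined <- !both_zero & !is.finite(fc)
  if (any(undefined)) {
    warning(sum(undefined), " element(s) with zero mean in one condition ",
            "dropped (infinite fold-change at pseudocount 0)")
  }
  keep <- !both_zero & !undefined
  out <- data.frame(id = rownames(mat$values)[keep],
                    symbol = mat$symbols[keep], log2_fc = fc[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Join RNA-seq and RT-qPCR fold-changes by gene symbol
#'
#' @param rnaseq `data.frame` with columns `symbol` and `log2_fc`
#'   (e.g. from [log2_fold_change()]).
#' @param qpcr `data.frame` with columns `symbol` and `log2_fc` (RT-qPCR
#'   ground truth).
#' @return Object of class `FoldChangeTable`: `data.frame` with columns
#'   `symbol`, `fc_rnaseq`, `fc_qpcr`, one row per gene present (with a
#'   finite value) on both platforms.
#' @export
fold_change_table <- function(rnaseq, qpcr) {
  rnaseq <- as.data.frame(rnaseq); qpcr <- as.data.frame(qpcr)
  stopifnot(all(c("symbol", "log2_fc") %in% names(rnaseq)),
            all(c("symbol", "log2_fc") %in% names(qpcr)))
  for (df in list(rnaseq, qpcr)) {
    if (anyDuplicated(trimws(df$symbol))) {
      stop("duplicate gene symbols in fold-change input")
    }
  }
  rnaseq$symbol <- trimws(rnaseq$symbol)
  qpcr$symbol <- trimws(qpcr$symbol)
  m <- merge(rnaseq[c("symbol", "log2_fc")], qpcr[c("symbol", "log2_fc")],
             by = "symbol", suffixes = c("_rnaseq", "_qpcr"))
  names(m) <- c("symbol", "fc_rnaseq", "fc_qpcr")
  m <- m[is.finite(m$fc_rnaseq) & is.finite(m$fc_qpcr), , drop = FALSE]
  if (nrow(m) == 0L) stop("no genes shared between the two platforms")
  rownames(m) <- NULL
  class(m) <- c("FoldChangeTable", "data.frame")
  m
}

#' Average absolute deviation between fold-change platforms
#'
#' \deqn{\mathrm{AAD} = \frac{1}{n}\sum |FC_{\mathrm{RNA\!-\!seq}} -
#'   FC_{\mathrm{RT\!-\!qPCR}}|}
#'
#' @param table A [fold_change_table()].
#' @return The average absolute deviation (>= 0).
#' @export
aad <- function(table) {
  stopifnot(is(table, "FoldChangeTable"))
  mean(abs(table$fc_rnaseq - table$fc_qpcr))
}

#' Root mean squared error between fold-change platforms
#'
#' @param table A [fold_change_table()].
#' @return `sqrt(mean((fc_rnaseq - fc_qpcr)^2))`.
#' @export
rmse <- function(table) {
  stopifnot(is(table, "FoldChangeTable"))
  sqrt(mean((table$fc_rnaseq - table$fc_qpcr)^2))
}

#' Correlation between fold-change platforms
#'
#' @param table A [fold_change_table()] with >= 2 rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
fc_correlation <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(table, "FoldChangeTable"))
  if (nrow(table) < 2L) stop("correlation needs >= 2 genes")
  if (sd(table$fc_rnaseq) == 0 || sd(table$fc_qpcr) == 0) {
    stop("correlation undefined for a constant fold-change column")
  }
  cor(table$fc_rnaseq, table$fc_qpcr, method = method)
}

#' All three concordance statistics
#'
#' @param table A [fold_change_table()].
#' @param method Correlation method, see [fc_correlation()].
#' @return Object of class `ConcordanceStats`: list with
#'   `average_absolute_deviation`, `rmse`, `correlation`, `n`.
#' @export
concordance_stats <- function(table, method = "pearson") {
  structure(list(average_absolute_deviation = aad(table),
                 rmse = rmse(table),
                 correlation = fc_correlation(table, method),
                 n = nrow(table)),
            class = "ConcordanceStats")
}

#' @export
print.ConcordanceStats <- function(x, ...) {
  cat(sprintf(paste0("ConcordanceStats (n = %d)\n  AAD  %.3f\n",
                     "  RMSE %.3f\n  r    %.3f\n"),
              x$n, x$average_absolute_deviation, x$rmse, x$correlation))
  invisible(x)
}

#' Genes with RT-qPCR present calls in every replicate
#'
#' RT-qPCR panels flag each gene per replicate as present or absent; only
#' genes detected in all replicates of both reference samples are reliable
#' ground truth for fold-change comparison.
#'
#' @param flags `data.frame`: first column gene symbol, remaining columns
#'   per-replicate present flags for both samples (logical, 0/1, or
#'   `"P"`/`"A"` calls).
#' @return Sorted character vector of symbols present in all replicates.
#' @export
qpcr_present_filter <- function(flags) {
  stopifnot(ncol(flags) >= 2L)
  sym <- trimws(as.character(flags[[1L]]))
  pres <- vapply(flags[-1L], function(col) {
    if (is.character(col) || is.factor(col)) {
      toupper(as.character(col)) %in% c("P", "PRESENT", "TRUE", "1")
    } else {
      as.logical(col)
    }
  }, logical(nrow(flags)))
  pres <- matrix(pres, nrow = nrow(flags))
  sort(sym[rowSums(pres) == ncol(pres)])
}

#' Top-k overlap of ranked DEG lists
#'
#' Agreement of the `k` most significant differentially expressed genes
#' between annotations: the pairwise intersection sizes of the top-`k`
#' prefixes, plus a global census of how many top-`k` genes are shared by
#' at least two lists versus specific to exactly one.
#'
#' @param lists Named list of ranked character vectors (most significant
#'   first), each of length >= `k` and duplicate-free.
#' @param k Prefix size; default 20.
#' @return List with `k`, `pairwise` (symmetric integer matrix of
#'   intersection sizes; diagonal `k`), `n_shared` (genes in >= 2 top-`k`
#'   lists) and `n_specific` (genes in exactly 1).
#' @export
top_k_overlap <- function(lists, k = 20L) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  for (nm in names(lists)) {
    if (anyDuplicated(lists[[nm]])) {
      stop("duplicate symbols within ranked list '", nm, "'")
    }
    if (length(lists[[nm]]) < k) {
      stop("ranked list '", nm, "' has fewer than k = ", k, " entries")
    }
  }
  tops <- lapply(lists, head, k)
  p <- length(tops)
  pw <- matrix(0L, p, p, dimnames = list(names(tops), names(tops)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      pw[i, j] <- length(intersect(tops[[i]], tops[[j]]))
    }
  }
  occ <- table(unlist(tops))
  list(k = as.integer(k), pairwise = pw,
       n_shared = sum(occ >= 2L), n_specific = sum(occ == 1L))
}
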