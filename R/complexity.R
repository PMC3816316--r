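#' Complexity profile of an annotation
#'
#' The complexity of a genome annotation is summarized by three counts:
#' number of genes, number of isoforms, and number of exons.  More complex
#' (often more prediction-driven) catalogues annotate more of each.
#'
#' @param ann A harmonized `AnnotationSet` with at least one gene.
#' @param distinct_exons When `TRUE` (default) the exon count is the number
#'   of distinct `(contig, start, end, strand)` exon intervals, so an exon
#'   shared by several isoforms counts once; when `FALSE` every exon row of
#'   every isoform is counted.
#' @return Object of class `ComplexityProfile`: a list with
#'   `source_name`, `n_genes`, `n_isoforms`, `n_exons`,
#'   `avg_isoforms_per_gene` (full precision; round at report time) and
#'   `max_isoforms_per_gene` (list with `count` and `symbol`).
#' @export
complexity_profile <- function(ann, distinct_exons = TRUE) {
  stopifnot(is(ann, "AnnotationSet"))
  if (nrow(ann$genes) == 0L) {
    stop("annotation has zero genes; complexity ratios are undefined")
  }
  per_gene <- table(ann$transcripts$gene_id)
  i_max <- which.max(per_gene)
  sym <- ann$genes$symbol[match(names(per_gene)[i_max], ann$genes$gene_id)]
  n_exons <- if (distinct_exons) {
    nrow(unique(ann$exons[c("contig", "start", "end", "strand")]))
  } else {
    nrow(ann$exons)
  }
  complexity_profile_counts(
    ann$source_name, n_genes = nrow(ann$genes),
    n_isoforms = nrow(ann$transcripts), n_exons = n_exons,
    max_isoforms_per_gene = list(count = as.integer(per_gene[i_max]),
                                 symbol = sym))
}

#' Complexity profile from published counts
#'
#' Builds a `ComplexityProfile` directly from gene/isoform/exon counts,
#' e.g. the summary rows published for the six human catalogues, so that
#' ranking and ratio computations can be applied without the underlying
#' GTF files.
#'
#' @param source_name Annotation source label.
#' @param n_genes,n_isoforms,n_exons Category counts.
#' @param max_isoforms_per_gene Optional list with `count` and `symbol`.
#' @return A `ComplexityProfile`.
#' @export
complexity_profile_counts <- function(source_name, n_genes, n_isoforms,
                                      n_exons,
                                      max_isoforms_per_gene = NULL) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (n_isoforms < n_genes) stop("n_isoforms must be >= n_genes")
  structure(list(source_name = source_name,
                 n_genes = as.numeric(n_genes),
                 n_isoforms = as.numeric(n_isoforms),
                 n_exons = as.numeric(n_exons),
                 avg_isoforms_per_gene = n_isoforms / n_genes,
                 max_isoforms_per_gene = max_isoforms_per_gene),
            class = "ComplexityProfile")
}

#' @export
print.ComplexityProfile <- function(x, ...) {
  cat("ComplexityProfile:", x$source_name, "\n")
  cat(sprintf("  genes %s | isoforms %s | exons %s | avg iso/gene %.2f\n",
              format(x$n_genes, big.mark = ","),
              format(x$n_isoforms, big.mark = ","),
              format(x$n_exons, big.mark = ","),
              x$avg_isoforms_per_gene))
  if (!is.null(x$max_isoforms_per_gene)) {
    cat(sprintf("  max iso/gene %d (%s)\n", x$max_isoforms_per_gene$count,
                x$max_isoforms_per_gene$symbol))
  }
  invisible(x)
}

#' Rank annotations by complexity
#'
#' Each annotation is ranked within each category (genes, isoforms, exons)
#' by decreasing count (rank 1 = largest).  The complexity rank is the
#' average of the three category ranks; ties on the average are broken by
#' the mode of the three ranks (ascending), then by the gene rank, then by
#' source name.  Exact count ties within a category receive the shared
#' minimum rank and emit a warning.
#'
#' @param profiles List of at least two [complexity_profile()] objects with
#'   distinct source names.
#' @return Object of class `ComplexityRanking`: a `data.frame`, rows in
#'   final order (most complex first), with columns `source_name`,
#'   `gene_rank`, `isoform_rank`, `exon_rank`, `average_rank`, `mode_rank`
#'   and `final_rank`.
#' @export
rank_complexity <- function(profiles) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, is, logical(1), "ComplexityProfile")))
  src <- vapply(profiles, `[[`, character(1), "source_name")
  if (anyDuplicated(src)) stop("profiles must have distinct source names")

  rank_desc <- function(counts, what) {
    if (anyDuplicated(counts)) {
      warning("exact tie in ", what, " counts; tied sources share the ",
              "minimum rank")
    }
    rank(-counts, ties.method = "min")
  }
  gr <- rank_desc(vapply(profiles, `[[`, numeric(1), "n_genes"), "gene")
  ir <- rank_desc(vapply(profiles, `[[`, numeric(1), "n_isoforms"), "isoform")
  er <- rank_desc(vapply(profiles, `[[`, numeric(1), "n_exons"), "exon")

  avg <- (gr + ir + er) / 3
  mode3 <- function(v) {
    tb <- table(v)
    if (max(tb) == 1L) median(v) else as.numeric(names(tb)[which.max(tb)])
  }
  mr <- mapply(function(a, b, c) mode3(c(a, b, c)), gr, ir, er)

  out <- data.frame(source_name = src, gene_rank = gr, isoform_rank = ir,
                    exon_rank = er, average_rank = avg, mode_rank = mr,
                    stringsAsFactors = FALSE)
  ord <- order(out$average_rank, out$mode_rank, out$gene_rank,
               out$source_name)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ComplexityRanking", "data.frame")
  out
}

#' Annotated percentage of the genome
#'
#' Fraction of each contig (and of the whole contig set) covered by the
#' annotation at one of three levels: `gene` (union of gene spans), `exon`
#' (union of all exon intervals) or `cds` (union of coding-sequence
#' intervals).  Unions ignore strand, since the denominator -- genomic
#' length -- is strand-free.  By construction CDS coverage <= exon coverage
#' <= gene coverage on every contig.
#'
#' @param ann A harmonized `AnnotationSet` whose contig set carries
#'   lengths.
#' @param level One of `"gene"`, `"exon"`, `"cds"`.
#' @return `data.frame` (class `CoverageReport`) with one row per contig in
#'   the contig set plus a final `"genome"` row; columns `contig`, `level`,
#'   `covered_bases`, `contig_length`, `percentage`.
#' @export
annotated_percentage <- function(ann, level = c("gene", "exon", "cds")) {
  stopifnot(is(ann, "AnnotationSet"))
  level <- match.arg(level)
  contigs <- ann$contigs
  if (nrow(contigs) == 0L) stop("annotation has an empty contig set")
  if (any(is.na(contigs$length))) {
    stop("contig without length: ",
         paste(head(contigs$name[is.na(contigs$length)], 5), collapse = ", "))
  }
  ivl <- switch(level,
                gene = gene_spans(ann),
                exon = ann$exons,
                cds = ann$cds)
  # restrict to the active contig set (features on flagged contigs are not
  # part of the genome denominator)
  ivl <- ivl[ivl$contig %in% contigs$name, , drop = FALSE]
  u <- merge_by_contig(ivl)
  covered <- vapply(contigs$name, function(nm) {
    x <- u[[nm]]
    if (is.null(x)) 0 else sum(x$end - x$start)
  }, numeric(1))
  out <- data.frame(contig = contigs$name, level = level,
                    covered_bases = covered,
                    contig_length = contigs$length,
                    percentage = 100 * covered / contigs$length,
                    row.names = NULL, stringsAsFactors = FALSE)
  genome <- data.frame(contig = "genome", level = level,
                       covered_bases = sum(covered),
                       contig_length = sum(contigs$length),
                       percentage = 100 * sum(covered) / sum(contigs$length),
                       stringsAsFactors = FALSE)
  out <- rbind(out, genome)
  class(out) <- c("CoverageReport", "data.frame")
  out
}
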