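#' Harmonization rules for cross-annotation comparability
#'
#' Public gene catalogues differ in contig naming (e.g. `"1"` vs `"chr1"`),
#' in which contigs they annotate (haplotype and mitochondrial contigs are
#' commonly excluded from comparative work), and in how many small-RNA
#' classes they carry (tRNA, miscRNA, scRNA, snRNA, ...).  A
#' `HarmonizationConfig` bundles the three rule blocks that make a set of
#' annotations comparable.
#'
#' @param contig_whitelist Character vector of contig names to keep, or
#'   `NULL` to keep all contigs.
#' @param contig_map Named character vector translating contig names
#'   (`c("1" = "chr1", "MT" = "chrM")`); applied before the whitelist so
#'   filtering acts in the target naming convention.
#' @param biotype_blacklist Character vector of isoform biotypes to remove
#'   (e.g. `c("tRNA", "miscRNA", "scRNA", "snRNA")`), or `NULL`.
#'
#' @return An object of class `HarmonizationConfig`.
#' @seealso [harmonize()], [read_harmonization_config()]
#' @export
harmonization_config <- function(contig_whitelist = NULL, contig_map = NULL,
                                 biotype_blacklist = NULL) {
  if (!is.null(contig_map)) {
    contig_map <- unlist(contig_map)
    if (is.null(names(contig_map)) || any(!nzchar(names(contig_map)))) {
      stop("contig_map must be a named character vector (old = new)")
    }
  }
  structure(list(contig_whitelist = contig_whitelist,
                 contig_map = contig_map,
                 biotype_blacklist = biotype_blacklist),
            class = "HarmonizationConfig")
}

#' Read a harmonization config from YAML
#'
#' The file has up to three blocks: `contig_whitelist` (list of names),
#' `contig_map` (mapping old -> new name) and `biotype_blacklist` (list of
#' biotypes).
#'
#' @param path Path to a YAML file.
#' @return A [harmonization_config()] object.
#' @export
read_harmonization_config <- function(path) {
  y <- yaml::read_yaml(path)
  harmonization_config(
    contig_whitelist = unlist(y$contig_whitelist),
    contig_map = if (!is.null(y$contig_map)) unlist(y$contig_map),
    biotype_blacklist = unlist(y$biotype_blacklist))
}

#' Harmonize an annotation
#'
#' Applies cross-annotation comparability rules in a fixed order:
#' (1) translate contig names, (2) remove genes on non-whitelisted contigs,
#' (3) remove isoforms with blacklisted biotypes, (4) purge genes left with
#' zero isoforms.  The operation is idempotent.  A removal report (counts
#' per rule) is attached to the result and available via
#' [removal_report()].
#'
#' @param ann An `AnnotationSet`.
#' @param rules A [harmonization_config()].
#' @return A new, harmonized `AnnotationSet`.
#' @export
harmonize <- function(ann, rules) {
  stopifnot(is(ann, "AnnotationSet"), is(rules, "HarmonizationConfig"))
  report <- list(translated_feature_rows = 0L, contig_filtered_genes = 0L,
                 biotype_filtered_isoforms = 0L, empty_purged_genes = 0L)

  translate <- function(x) {
    hit <- x %in% names(rules$contig_map)
    x[hit] <- unname(rules$contig_map[x[hit]])
    x
  }
  if (!is.null(rules$contig_map)) {
    n_hit <- sum(ann$exons$contig %in% names(rules$contig_map)) +
      sum(ann$cds$contig %in% names(rules$contig_map))
    ann$genes$contig <- translate(ann$genes$contig)
    ann$exons$contig <- translate(ann$exons$contig)
    ann$cds$contig <- translate(ann$cds$contig)
    report$translated_feature_rows <- n_hit
    if (anyDuplicated(ann$genes$gene_id)) {
      stop("contig translation produced duplicate gene_ids")
    }
  }

  if (!is.null(rules$contig_whitelist)) {
    drop_gene <- !(ann$genes$contig %in% rules$contig_whitelist)
    report$contig_filtered_genes <- sum(drop_gene)
    ann <- drop_genes(ann, ann$genes$gene_id[drop_gene])
  }

  if (!is.null(rules$biotype_blacklist)) {
    drop_tx <- ann$transcripts$biotype %in% rules$biotype_blacklist
    report$biotype_filtered_isoforms <- sum(drop_tx)
    keys <- tx_key(ann$transcripts)[drop_tx]
    ann$transcripts <- ann$transcripts[!drop_tx, , drop = FALSE]
    ann$exons <- ann$exons[!(tx_key(ann$exons) %in% keys), , drop = FALSE]
    ann$cds <- ann$cds[!(tx_key(ann$cds) %in% keys), , drop = FALSE]
  }

  empty <- !(ann$genes$gene_id %in% ann$transcripts$gene_id)
  report$empty_purged_genes <- sum(empty)
  ann <- drop_genes(ann, ann$genes$gene_id[empty])

  if ("flagged" %in% names(ann$genes)) {
    ann$genes$flagged <- !(ann$genes$contig %in% ann$contigs$name)
  }
  rownames(ann$genes) <- rownames(ann$transcripts) <- NULL
  rownames(ann$exons) <- rownames(ann$cds) <- NULL
  validate_annotation_set(ann)
  attr(ann, "removal_report") <- report
  ann
}

drop_genes <- function(ann, gene_ids) {
  if (length(gene_ids) == 0L) return(ann)
  ann$genes <- ann$genes[!(ann$genes$gene_id %in% gene_ids), , drop = FALSE]
  ann$transcripts <- ann$transcripts[
    !(ann$transcripts$gene_id %in% gene_ids), , drop = FALSE]
  ann$exons <- ann$exons[!(ann$exons$gene_id %in% gene_ids), , drop = FALSE]
  ann$cds <- ann$cds[!(ann$cds$gene_id %in% gene_ids), , drop = FALSE]
  ann
}

#' Removal report of the last harmonization
#'
#' @param ann An `AnnotationSet` returned by [harmonize()].
#' @return Named list with counts `translated_feature_rows`,
#'   `contig_filtered_genes`, `biotype_filtered_isoforms`,
#'   `empty_purged_genes`; `NULL` if `ann` was never harmonized.
#' @export
removal_report <- function(ann) attr(ann, "removal_report")
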