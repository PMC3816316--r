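#' Construct an AnnotationSet
#'
#' An `AnnotationSet` holds the harmonized gene models of one annotation
#' source as a gene -> isoform -> exon/CDS hierarchy.  All coordinates are
#' internal 0-based half-open intervals; conversion from/to the 1-based
#' inclusive GTF convention happens only at file boundaries
#' ([parse_gtf()], [write_gtf()]).
#'
#' @param source_name Annotation source label (e.g. `"RefSeq"`).
#' @param version Free-form version string (may be `""`).
#' @param genes `data.frame` with columns `gene_id`, `symbol`, `contig`,
#'   `strand`. `gene_id` must be unique; `symbol` may be empty.
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `biotype` (may be empty strings).
#' @param exons,cds `data.frame`s with columns `transcript_id`, `gene_id`,
#'   `contig`, `start`, `end`, `strand`; 0-based half-open.  `cds` may have
#'   zero rows.
#' @param contigs `data.frame` with columns `name`, `length`, `category`
#'   (one of `"main"`, `"unplaced"`, `"unlocalized"`), the active contig
#'   set.  `length` may be `NA` when unknown.
#'
#' @return An object of class `AnnotationSet`.
#' @seealso [parse_gtf()], [harmonize()], [exonic_union()]
#' @export
annotation_set <- function(source_name, version = "", genes, transcripts,
                           exons, cds = empty_interval_frame(),
                           contigs = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  if (is.null(contigs)) {
    contigs <- infer_contigs(exons)
  }
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  ann <- structure(
    list(source_name = source_name, version = version,
         genes = genes, transcripts = transcripts,
         exons = exons, cds = cds, contigs = contigs),
    class = "AnnotationSet")
  validate_annotation_set(ann)
  ann
}

empty_interval_frame <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

empty_annotation_set <- function(source_name, version = "", contigs = NULL) {
  annotation_set(
    source_name, version,
    genes = data.frame(gene_id = character(), symbol = character(),
                       contig = character(), strand = character(),
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = character(),
                             gene_id = character(), biotype = character(),
                             stringsAsFactors = FALSE),
    exons = empty_interval_frame(), cds = empty_interval_frame(),
    contigs = contigs)
}

infer_contigs <- function(exons) {
  if (nrow(exons) == 0L) {
    return(data.frame(name = character(), length = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  len <- tapply(exons$end, exons$contig, max)
  data.frame(name = names(len), length = as.integer(len),
             category = "main", row.names = NULL, stringsAsFactors = FALSE)
}

validate_annotation_set <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id in annotation '", ann$source_name, "': ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  }
  if (anyDuplicated(ann$contigs$name)) {
    stop("duplicate contig names in contig set")
  }
  if (any(!is.na(ann$contigs$length) & ann$contigs$length <= 0)) {
    stop("contig lengths must be positive")
  }
  for (tab in list(ann$exons, ann$cds)) {
    if (nrow(tab) && any(tab$start < 0 | tab$start >= tab$end)) {
      stop("invalid interval: require 0 <= start < end")
    }
  }
  if (nrow(g) && nrow(ann$transcripts)) {
    orphan <- setdiff(ann$transcripts$gene_id, g$gene_id)
    if (length(orphan)) stop("transcripts reference unknown gene_id: ",
                             paste(head(orphan, 3), collapse = ", "))
  }
  # every isoform needs >= 1 exon
  no_exon <- setdiff(tx_key(ann$transcripts), tx_key(ann$exons))
  if (length(no_exon)) {
    stop("transcript without exons: ",
         paste(head(sub("^.*\r", "", no_exon), 5), collapse = ", "))
  }
  invisible(ann)
}

# transcripts are keyed by (gene_id, transcript_id): the same transcript_id
# under two genes is two distinct isoforms (warned at parse time)
tx_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  paste0(df$gene_id, "\r", df$transcript_id)
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", x$source_name,
      if (nzchar(x$version)) paste0("(", x$version, ")"), "\n")
  cat("  genes:      ", nrow(x$genes), "\n")
  cat("  isoforms:   ", nrow(x$transcripts), "\n")
  cat("  exon rows:  ", nrow(x$exons), "  cds rows: ", nrow(x$cds), "\n")
  cat("  contig set: ", nrow(x$contigs), "contig(s)\n")
  invisible(x)
}

#' Gene spans of an annotation
#'
#' The span of a gene is `[min exon start, max exon end)` over all of its
#' isoforms.
#'
#' @param ann An `AnnotationSet`.
#' @return `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
gene_spans <- function(ann) {
  stopifnot(is(ann, "AnnotationSet"))
  ex <- ann$exons
  if (nrow(ex) == 0L) {
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  s <- tapply(ex$start, ex$gene_id, min)
  e <- tapply(ex$end, ex$gene_id, max)
  ids <- names(s)
  m <- match(ids, ann$genes$gene_id)
  data.frame(gene_id = ids, contig = ann$genes$contig[m],
             start = as.integer(s), end = as.integer(e),
             strand = ann$genes$strand[m],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a contig-set table
#'
#' Reads a tab-separated contig description with columns `name`, `length`
#' and `category` (`main`, `unplaced` or `unlocalized`), the analogue of
#' restricting an analysis to the main/unplaced/unlocalized contigs of a
#' reference assembly.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `name`, `length`, `category`.
#' @export
read_contigs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "length", "category")
  if (!all(need %in% names(df))) {
    stop("contig table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$category), c("main", "unplaced", "unlocalized"))
  if (length(bad)) stop("unknown contig category: ", paste(bad, collapse = ", "))
  if (any(df$length <= 0)) stop("contig lengths must be positive")
  df[need]
}
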