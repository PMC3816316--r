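#' Parse a GTF file into an AnnotationSet
#'
#' Reads the standard 9-column GTF annotation format, groups exon and CDS
#' features under transcripts and transcripts under genes, and converts the
#' on-disk 1-based inclusive coordinates to the internal 0-based half-open
#' convention.  Features on contigs absent from the supplied contig set are
#' retained but flagged (column `flagged` of `$genes`); [harmonize()]
#' removes them.
#'
#' Gene symbols are taken from the `gene_name` attribute, falling back to
#' `gene_id`.  The isoform biotype is read from the first attribute present
#' among `biotype_attrs` (the six public human catalogues use different
#' dialects), empty if none.
#'
#' @param path Path to a GTF file.
#' @param contigs Optional contig set (`data.frame` as from
#'   [read_contigs()]).  When `NULL` the contig set is inferred from the
#'   data and nothing is flagged.
#' @param source_name Label for the annotation source; defaults to the file
#'   name without extension.
#' @param version Version string stored on the result.
#' @param biotype_attrs Character vector of attribute keys tried, in order,
#'   for the isoform biotype.
#'
#' @return An [AnnotationSet][annotation_set].
#' @section Errors: A line that is not 9 tab-separated fields (or has
#'   non-numeric coordinates) raises a parse error naming the line number;
#'   a transcript with CDS but no exon features raises a structural error
#'   naming the transcript.
#' @export
parse_gtf <- function(path, contigs = NULL,
                      source_name = sub("\\.[^.]*$", "", basename(path)),
                      version = "",
                      biotype_attrs = c("gene_biotype", "gene_type",
                                        "transcript_type")) {
  lines <- readLines(path)
  feature_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(feature_idx) == 0L) {
    return(empty_annotation_set(source_name, version, contigs))
  }
  for (i in feature_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    }
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    }
  }

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(mc))) {
    stop("GTF attributes must contain gene_id and transcript_id")
  }

  type <- as.character(mc$type)
  keep <- type %in% c("exon", "CDS")
  if (!any(keep)) {
    # no exon/CDS rows: any transcript-level rows are structures w/o exons
    tx <- unique(stats::na.omit(as.character(mc$transcript_id)))
    if (length(tx)) stop("transcript without exon features: ",
                         paste(head(tx, 5), collapse = ", "))
    return(empty_annotation_set(source_name, version, contigs))
  }

  feat <- data.frame(
    type = type,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = chartr("*", "*", as.character(GenomicRanges::strand(gr))),
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id),
    stringsAsFactors = FALSE)
  feat$symbol <- if ("gene_name" %in% names(mc)) {
    as.character(mc$gene_name)
  } else NA_character_
  feat$biotype <- NA_character_
  for (key in biotype_attrs) {
    if (key %in% names(mc)) {
      val <- as.character(mc[[key]])
      feat$biotype <- ifelse(is.na(feat$biotype), val, feat$biotype)
    }
  }

  mentioned_tx <- unique(feat$transcript_id[!is.na(feat$transcript_id)])
  feat <- feat[feat$type %in% c("exon", "CDS"), , drop = FALSE]
  if (any(is.na(feat$gene_id)) || any(is.na(feat$transcript_id))) {
    stop("exon/CDS feature lacking gene_id or transcript_id attribute")
  }

  key <- tx_key(feat)
  exon <- feat$type == "exon"
  tx_no_exon <- setdiff(unique(feat$transcript_id),
                        unique(feat$transcript_id[exon]))
  tx_no_exon <- union(tx_no_exon,
                      setdiff(mentioned_tx, unique(feat$transcript_id)))
  if (length(tx_no_exon)) {
    stop("transcript without exon features: ",
         paste(head(sort(tx_no_exon), 5), collapse = ", "))
  }

  # one coherent isoform per (gene_id, transcript_id)
  one_contig <- tapply(feat$contig, key, function(x) length(unique(x)))
  one_strand <- tapply(feat$strand, key, function(x) length(unique(x)))
  if (any(one_contig > 1L) || any(one_strand > 1L)) {
    bad <- names(one_contig)[one_contig > 1L | one_strand > 1L]
    stop("transcript spans multiple contigs or strands ",
         "(duplicate transcript within a gene?): ",
         paste(head(sub("^.*\r", "", bad), 5), collapse = ", "))
  }

  tx_tab <- unique(feat[c("transcript_id", "gene_id")])
  dup_across <- tx_tab$transcript_id[duplicated(tx_tab$transcript_id)]
  if (length(dup_across)) {
    warning("transcript_id used by multiple genes: ",
            paste(head(unique(dup_across), 5), collapse = ", "))
  }
  bt <- tapply(feat$biotype, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1L] else ""
  })
  tx_tab$biotype <- as.character(bt[tx_key(tx_tab)])

  gene_tab <- unique(feat[c("gene_id", "contig", "strand")])
  if (anyDuplicated(gene_tab$gene_id)) {
    bad <- unique(gene_tab$gene_id[duplicated(gene_tab$gene_id)])
    stop("gene spans multiple contigs/strands: ",
         paste(head(bad, 5), collapse = ", "))
  }
  sym <- tapply(feat$symbol, feat$gene_id, function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x)) x[1L] else NA_character_
  })
  gene_tab$symbol <- as.character(sym[gene_tab$gene_id])
  gene_tab$symbol <- ifelse(is.na(gene_tab$symbol), gene_tab$gene_id,
                            gene_tab$symbol)
  gene_tab <- gene_tab[c("gene_id", "symbol", "contig", "strand")]

  cols <- c("transcript_id", "gene_id", "contig", "start", "end", "strand")
  exons <- feat[exon, cols]
  cds <- feat[!exon, cols]
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  cds <- cds[order(cds$gene_id, cds$transcript_id, cds$start), ]
  rownames(exons) <- rownames(cds) <- NULL
  check_exons_disjoint(exons)

  ann <- annotation_set(source_name, version, genes = gene_tab,
                        transcripts = tx_tab[c("transcript_id", "gene_id",
                                               "biotype")],
                        exons = exons, cds = cds, contigs = contigs)
  ann$genes$flagged <- !(ann$genes$contig %in% ann$contigs$name)
  ann
}

# exons must be non-overlapping within an isoform
check_exons_disjoint <- function(exons) {
  if (nrow(exons) < 2L) return(invisible(NULL))
  key <- tx_key(exons)
  ord <- order(key, exons$start)
  k <- key[ord]; s <- exons$start[ord]; e <- exons$end[ord]
  same <- k[-1L] == k[-length(k)]
  overlap <- same & s[-1L] < e[-length(e)]
  if (any(overlap)) {
    stop("overlapping exons within isoform: ",
         paste(head(unique(sub("^.*\r", "", k[-1L][overlap])), 5),
               collapse = ", "))
  }
  invisible(NULL)
}

#' Write an AnnotationSet as GTF
#'
#' Emits one `exon` line per exon interval and one `CDS` line per CDS
#' interval, converting internal 0-based half-open coordinates back to the
#' 1-based inclusive GTF convention.  `gene_id`, `transcript_id`,
#' `gene_name` and `gene_biotype` attributes are written, so
#' `parse_gtf(write_gtf(ann))` round-trips the gene model.
#'
#' @param ann An `AnnotationSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(is(ann, "AnnotationSet"))
  tabs <- list(exon = ann$exons, CDS = ann$cds)
  rows <- do.call(rbind, lapply(names(tabs), function(ty) {
    df <- tabs[[ty]]
    if (nrow(df) == 0L) return(NULL)
    cbind(df, type = ty, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  m_g <- match(rows$gene_id, ann$genes$gene_id)
  m_t <- match(tx_key(rows), tx_key(ann$transcripts))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = ifelse(rows$strand %in% c("+", "-"), rows$strand, "*"))
  S4Vectors::mcols(gr)$source <- ann$source_name
  S4Vectors::mcols(gr)$type <- rows$type
  # phase is not modelled; write frame 0 on CDS rows to keep the file valid
  S4Vectors::mcols(gr)$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$gene_name <- ann$genes$symbol[m_g]
  bt <- ann$transcripts$biotype[m_t]
  if (any(nzchar(bt))) S4Vectors::mcols(gr)$gene_biotype <- bt
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
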