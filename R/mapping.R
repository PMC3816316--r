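#' Read alignment records from SAM or BAM
#'
#' Loads the fields needed for mapping-outcome classification: read name,
#' flag, placement (contig, 1-based position, CIGAR) and the `NH`
#' hit-count tag when the aligner emitted one.  SAM input is converted to
#' BAM on the fly via Rsamtools.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return `data.frame` (class `alignment_records`) with columns `qname`,
#'   `flag`, `contig`, `pos`, `cigar`, `nh`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"), tag = "NH")
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  df <- data.frame(qname = x$qname, flag = x$flag,
                   contig = as.character(x$rname), pos = x$pos,
                   cigar = x$cigar, stringsAsFactors = FALSE)
  df$nh <- if (is.null(x$tag$NH)) NA_integer_ else x$tag$NH
  class(df) <- c("alignment_records", "data.frame")
  df
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) > 0L

check_flag_consistency <- function(alns) {
  mapped <- !flag_bit(alns$flag, 0x4)
  bad <- !mapped & !is.na(alns$cigar) & alns$cigar != "*"
  if (any(bad)) {
    stop("contradictory flags (unmapped bit set but placement present) ",
         "for read(s): ", paste(head(unique(alns$qname[bad]), 5),
                                collapse = ", "))
  }
  bad2 <- mapped & (is.na(alns$pos) | is.na(alns$contig))
  if (any(bad2)) {
    stop("contradictory flags (mapped bit clear but no placement) ",
         "for read(s): ", paste(head(unique(alns$qname[bad2]), 5),
                                collapse = ", "))
  }
  invisible(NULL)
}

# placements per read end: NH tag of a mapped record when present,
# otherwise the number of mapped records for that end
placements_per_end <- function(alns, key) {
  mapped <- !flag_bit(alns$flag, 0x4)
  n_rec <- tapply(mapped, key, sum)
  nh <- tapply(ifelse(mapped, alns$nh, NA_integer_), key,
               function(v) {
                 v <- v[!is.na(v)]
                 if (length(v)) max(v) else NA_integer_
               })
  n <- ifelse(is.na(nh), as.integer(n_rec), as.integer(nh))
  # an end with only unmapped records has zero placements
  n[as.integer(n_rec) == 0L] <- 0L
  n
}

#' Classify read-mapping outcomes
#'
#' Tallies alignment records into mapping categories, counting one unit per
#' read (single-end) or per read pair (paired-end).
#'
#' Single-end categories: `uniquely_mapped` (exactly one placement),
#' `non_uniquely_mapped` (two or more), `unmapped` (none).  Paired-end
#' categories: `uniquely_paired` (both ends placed, one placement each),
#' `non_uniquely_paired` (both ends placed, several placement pairs),
#' `uniquely_mapped_singleton` / `non_uniquely_mapped_singleton` (exactly
#' one end placed, with one / several placements), `unmapped` (neither end
#' placed).  Placement multiplicity comes from the `NH` tag when present,
#' otherwise from counting records per read end.
#'
#' @param alns `alignment_records` from [read_alignments()] (or a
#'   compatible `data.frame`).
#' @param layout `"auto"` (infer from the paired flag bit), `"single"` or
#'   `"paired"`.  A stream mixing layouts is an error.
#' @return Object of class `MappingTally`: list with `layout`, `counts`
#'   (named integer vector), `total` and `percent`.
#' @export
classify_mappings <- function(alns, layout = c("auto", "single", "paired")) {
  layout <- match.arg(layout)
  check_flag_consistency(alns)
  paired_bits <- flag_bit(alns$flag, 0x1)
  if (length(unique(paired_bits)) > 1L) {
    stop("alignment stream mixes single-end and paired-end records")
  }
  observed <- if (nrow(alns) && paired_bits[1L]) "paired" else "single"
  if (layout == "auto") layout <- observed
  if (nrow(alns) && layout != observed) {
    stop("declared layout '", layout, "' but records are ", observed,
         "-end")
  }

  if (layout == "single") {
    n <- placements_per_end(alns, alns$qname)
    cats <- ifelse(n == 0L, "unmapped",
                   ifelse(n == 1L, "uniquely_mapped", "non_uniquely_mapped"))
    lev <- c("uniquely_mapped", "non_uniquely_mapped", "unmapped")
  } else {
    end1 <- flag_bit(alns$flag, 0x40)
    end2 <- flag_bit(alns$flag, 0x80)
    if (any(end1 == end2)) {
      stop("paired record without a valid first/second-of-pair bit: ",
           paste(head(unique(alns$qname[end1 == end2]), 5), collapse = ", "))
    }
    key <- paste0(alns$qname, "\r", ifelse(end1, 1L, 2L))
    n_end <- placements_per_end(alns, key)
    qn <- sub("\r[12]$", "", names(n_end))
    end_no <- as.integer(sub("^.*\r", "", names(n_end)))
    n1 <- tapply(ifelse(end_no == 1L, n_end, 0L), qn, max)
    n2 <- tapply(ifelse(end_no == 2L, n_end, 0L), qn, max)
    both <- n1 > 0L & n2 > 0L
    one <- xor(n1 > 0L, n2 > 0L)
    nmax <- pmax(n1, n2)
    cats <- ifelse(both & n1 == 1L & n2 == 1L, "uniquely_paired",
            ifelse(both, "non_uniquely_paired",
            ifelse(one & nmax == 1L, "uniquely_mapped_singleton",
            ifelse(one, "non_uniquely_mapped_singleton", "unmapped"))))
    lev <- c("uniquely_paired", "non_uniquely_paired",
             "uniquely_mapped_singleton", "non_uniquely_mapped_singleton",
             "unmapped")
  }
  counts <- table(factor(cats, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  total <- sum(counts)
  structure(list(layout = layout, counts = counts, total = total,
                 percent = if (total) 100 * counts / total else counts * NA),
            class = "MappingTally")
}

#' @export
print.MappingTally <- function(x, ...) {
  cat("MappingTally (", x$layout, "-end, ", x$total, " units)\n", sep = "")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-30s %8d  (%5.1f%%)\n", nm, x$counts[[nm]],
                x$percent[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.MappingTally <- function(x, ...) {
  data.frame(layout = x$layout, category = names(x$counts),
             count = unname(x$counts), percent = unname(x$percent),
             stringsAsFactors = FALSE)
}

#' Annotated vs. un-annotated mapping split
#'
#' Fraction of mapped units (reads or read pairs) whose primary placement
#' overlaps the exonic union of an annotation by at least one base.  Reads
#' landing outside annotated exons carry no information for quantifying
#' the annotation's elements.
#'
#' @param alns `alignment_records` from [read_alignments()].
#' @param union Exonic union from [exonic_union()].
#' @param rule For read pairs, `"either"` (default; the unit is annotated
#'   if either end overlaps -- the fragment touches an exon) or `"both"`
#'   (every mapped end must overlap).
#' @param denominator `"mapped"` (default; percentages over mapped units
#'   only) or `"all"` (over all units in the stream).
#' @return List with `annotated_percent`, `un_annotated_percent` (summing
#'   to 100 before rounding), `n_annotated`, `n_units` (the denominator)
#'   and `rule`.
#' @export
annotated_fraction <- function(alns, union, rule = c("either", "both"),
                               denominator = c("mapped", "all")) {
  rule <- match.arg(rule)
  denominator <- match.arg(denominator)
  check_flag_consistency(alns)
  mapped <- !flag_bit(alns$flag, 0x4)
  primary <- mapped & !flag_bit(alns$flag, 0x100) & !flag_bit(alns$flag, 0x800)

  if (union_length(union) == 0) {
    warning("empty exonic union: all mapped units are un-annotated")
    hit <- rep(FALSE, sum(primary))
  } else {
    ug <- union_to_granges(union)
    pr <- alns[primary, , drop = FALSE]
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(pr$cigar)
    gr <- GenomicRanges::GRanges(
      seqnames = pr$contig,
      ranges = IRanges::IRanges(start = pr$pos, width = w))
    n_ov <- suppressWarnings(
      GenomicRanges::countOverlaps(gr, ug, minoverlap = 1L,
                                   ignore.strand = TRUE))
    hit <- n_ov > 0L
  }

  qn <- alns$qname[primary]
  unit_any <- tapply(hit, qn, any)
  unit_all <- tapply(hit, qn, all)
  annotated <- if (rule == "either") unit_any else unit_all

  n_mapped <- length(annotated)
  n_units <- length(unique(alns$qname))
  denom <- if (denominator == "mapped") n_mapped else n_units
  if (denom == 0L) stop("no units in alignment stream")
  n_ann <- sum(annotated)
  list(annotated_percent = 100 * n_ann / denom,
       un_annotated_percent = 100 * (denom - n_ann) / denom,
       n_annotated = as.integer(n_ann), n_units = as.integer(denom),
       rule = rule)
}
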