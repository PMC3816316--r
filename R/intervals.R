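# Interval utilities.  The package-wide convention is 0-based half-open
# [start, end); merging and overlap arithmetic delegate to IRanges, with
# conversion to/from its 1-based inclusive representation kept local to
# this file.

to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

# per-contig merged (disjoint, sorted, non-adjacent) union of a set of
# intervals given as a data.frame with contig/start/end columns
merge_by_contig <- function(df) {
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  sp <- split(df[c("start", "end")], df$contig)
  lapply(sp, function(x) {
    # min.gapwidth = 0 keeps adjacent-but-not-overlapping intervals merged
    # (book-ended pieces form one covered run)
    from_iranges(IRanges::reduce(to_iranges(x$start, x$end)))
  })
}

#' Strand-ignoring exonic union of an annotation
#'
#' Merges all exon intervals of all isoforms into, per contig, a sorted
#' list of disjoint intervals.  This union underlies the exon-level
#' annotated percentage ([annotated_percentage()]) and the annotated
#' vs. un-annotated mapping split ([annotated_fraction()]).
#'
#' @param ann An `AnnotationSet` (typically harmonized).
#' @return Named list (one entry per contig carrying exons) of
#'   `data.frame`s with columns `start`, `end` (0-based half-open),
#'   disjoint and sorted; class `interval_union`.
#' @export
exonic_union <- function(ann) {
  stopifnot(is(ann, "AnnotationSet"))
  structure(merge_by_contig(ann$exons), class = "interval_union")
}

#' Total length of an interval union
#'
#' @param union An `interval_union` (or plain named list of
#'   `start`/`end` data.frames) as returned by [exonic_union()].
#' @return Total covered bases, summed over contigs.
#' @export
union_length <- function(union) {
  sum(vapply(union, function(x) sum(x$end - x$start), numeric(1)))
}

union_to_granges <- function(union) {
  if (length(union) == 0L) return(GenomicRanges::GRanges())
  n <- vapply(union, nrow, integer(1))
  GenomicRanges::GRanges(
    seqnames = rep(names(union), n),
    ranges = to_iranges(unlist(lapply(union, `[[`, "start"), use.names = FALSE),
                        unlist(lapply(union, `[[`, "end"), use.names = FALSE)))
}

# complement of a union within contigs of known length; returns the same
# named-list-of-data.frames shape
union_complement <- function(union, contigs) {
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    nm <- contigs$name[i]; len <- contigs$length[i]
    u <- union[[nm]]
    if (is.null(u) || nrow(u) == 0L) {
      return(data.frame(start = 0L, end = len))
    }
    gaps <- from_iranges(IRanges::gaps(to_iranges(u$start, u$end),
                                       start = 1L, end = len))
    gaps[gaps$end > gaps$start, , drop = FALSE]
  })
  names(out) <- contigs$name
  out
}
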