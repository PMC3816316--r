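# Shared fixture builders and independent oracles.

example_gtf <- function() {
  system.file("extdata", "example.gtf", package = "annoimpact")
}

example_contigs <- function() {
  read_contigs(system.file("extdata", "example_contigs.tsv",
                           package = "annoimpact"))
}

write_tmp_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_line <- function(contig, type, start, end, gene, tx, strand = "+",
                     name = gene, biotype = "protein_coding") {
  sprintf(paste0("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                 "transcript_id \"%s\"; gene_name \"%s\"; ",
                 "gene_biotype \"%s\";"),
          contig, type, start, end, strand, gene, tx, name, biotype)
}

# per-base brute-force coverage oracle: marks every covered base of every
# contig and counts, independent of any interval arithmetic in the package
coverage_oracle <- function(intervals, contigs) {
  covered <- setNames(numeric(nrow(contigs)), contigs$name)
  for (i in seq_len(nrow(contigs))) {
    nm <- contigs$name[i]
    mask <- logical(contigs$length[i])
    rows <- intervals[intervals$contig == nm, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      # 0-based half-open -> 1-based vector indices
      mask[(rows$start[j] + 1L):rows$end[j]] <- TRUE
    }
    covered[nm] <- sum(mask)
  }
  covered
}

# a small annotation with random single-isoform genes on one toy contig;
# used by union/coverage property tests
random_annotation <- function(n_genes = 50, contig_len = 10000,
                              source_name = "rand") {
  genes <- list(); txs <- list(); exs <- list(); cdss <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("g%03d", i)
    tid <- paste0(gid, ".t1")
    s <- sample.int(contig_len - 400L, 1L) - 1L
    ne <- sample(1:3, 1L)
    pos <- s
    ex <- matrix(0L, ne, 2L)
    for (e in seq_len(ne)) {
      w <- sample(20:80, 1L)
      ex[e, ] <- c(pos, pos + w)
      pos <- pos + w + sample(10:40, 1L)
    }
    genes[[i]] <- data.frame(gene_id = gid, symbol = toupper(gid),
                             contig = "ctg", strand = "+")
    txs[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                           biotype = "protein_coding")
    exs[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                           contig = "ctg", start = ex[, 1], end = ex[, 2],
                           strand = "+")
    cd <- ex[1L, , drop = FALSE]
    cd[1L, 1L] <- cd[1L, 1L] + 5L
    cdss[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                            contig = "ctg", start = cd[, 1], end = cd[, 2],
                            strand = "+")
  }
  annotation_set(source_name, genes = do.call(rbind, genes),
                 transcripts = do.call(rbind, txs),
                 exons = do.call(rbind, exs), cds = do.call(rbind, cdss),
                 contigs = data.frame(name = "ctg", length = contig_len,
                                      category = "main"))
}

# hand-built paired-end SAM with an enumerable category composition
sam_header <- function(contig = "chrT", len = 10000L) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", contig, len))
}

sam_rec <- function(qname, flag, contig = "chrT", pos = 0L, cigar = "*",
                    mapq = 50L, nh = NA) {
  line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  qname, flag, contig, pos, mapq, cigar)
  if (!is.na(nh)) line <- paste0(line, sprintf("\tNH:i:%d", nh))
  line
}

write_tmp_sam <- function(records, contig = "chrT", len = 10000L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c(sam_header(contig, len), records), path)
  path
}

# 10 pairs: 3 unique pairs, 2 multi pairs, 2 unique singletons,
# 1 multi singleton, 2 unmapped (hand-enumerated composition)
ten_pair_sam <- function() {
  recs <- character(0)
  add <- function(...) recs <<- c(recs, ...)
  for (i in 1:3) {
    id <- sprintf("up%d", i)
    add(sam_rec(id, 67L, pos = 100L * i, cigar = "36M", nh = 1),
        sam_rec(id, 131L, pos = 100L * i + 200L, cigar = "36M", nh = 1))
  }
  for (i in 1:2) {
    id <- sprintf("mp%d", i)
    add(sam_rec(id, 67L, pos = 1000L + 100L * i, cigar = "36M", nh = 2),
        sam_rec(id, 131L, pos = 1300L + 100L * i, cigar = "36M", nh = 2),
        sam_rec(id, 323L, pos = 5000L + i, cigar = "36M", mapq = 0L, nh = 2),
        sam_rec(id, 387L, pos = 6000L + i, cigar = "36M", mapq = 0L, nh = 2))
  }
  for (i in 1:2) {
    id <- sprintf("us%d", i)
    add(sam_rec(id, 73L, pos = 2000L + 50L * i, cigar = "36M", nh = 1),
        sam_rec(id, 133L, contig = "*", pos = 0L))
  }
  add(sam_rec("ms1", 73L, pos = 3000L, cigar = "36M", nh = 3),
      sam_rec("ms1", 329L, pos = 7000L, cigar = "36M", mapq = 0L, nh = 3),
      sam_rec("ms1", 133L, contig = "*", pos = 0L))
  for (i in 1:2) {
    id <- sprintf("un%d", i)
    add(sam_rec(id, 77L, contig = "*", pos = 0L, mapq = 0L),
        sam_rec(id, 141L, contig = "*", pos = 0L, mapq = 0L))
  }
  write_tmp_sam(recs)
}
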