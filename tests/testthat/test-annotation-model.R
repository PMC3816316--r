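test_that("GTF parsing builds the gene -> isoform -> exon hierarchy", {
  ann <- parse_gtf(example_gtf(), example_contigs(), source_name = "demo")
  expect_s3_class(ann, "AnnotationSet")
  # hand-counted fixture: 3 genes, 5 transcripts, 12 exon lines
  expect_equal(nrow(ann$genes), 3L)
  expect_equal(nrow(ann$transcripts), 5L)
  expect_equal(nrow(ann$exons), 12L)
  expect_equal(nrow(ann$cds), 2L)
  expect_equal(sort(ann$genes$symbol), c("ALPHA", "BETA", "GAMMA"))
  expect_equal(ann$transcripts$biotype[ann$transcripts$gene_id == "g3"],
               "lincRNA")
  expect_false(any(ann$genes$flagged))
})

test_that("GTF coordinates convert to 0-based half-open at the boundary", {
  p <- write_tmp_gtf(gtf_line("chr1", "exon", 1L, 100L, "g", "g.t1"))
  ann <- parse_gtf(p)
  expect_equal(ann$exons$start, 0L)
  expect_equal(ann$exons$end, 100L)
  expect_equal(ann$exons$end - ann$exons$start, 100L)
})

test_that("degenerate and malformed GTF inputs are handled", {
  empty <- write_tmp_gtf(character(0))
  ann <- parse_gtf(empty)
  expect_equal(nrow(ann$genes), 0L)

  comment_only <- write_tmp_gtf(c("# header", "#!genome-build toy"))
  expect_equal(nrow(parse_gtf(comment_only)$genes), 0L)

  bad <- write_tmp_gtf(c(gtf_line("chr1", "exon", 1L, 100L, "g", "g.t1"),
                         "chr1\ttest\texon\t1"))
  expect_error(parse_gtf(bad), "line 2")

  nonnum <- write_tmp_gtf(
    "chr1\ttest\texon\tone\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";")
  expect_error(parse_gtf(nonnum), "line 1")

  cds_only <- write_tmp_gtf(gtf_line("chr1", "CDS", 1L, 90L, "g", "g.t9"))
  expect_error(parse_gtf(cds_only), "g\\.t9")
})

test_that("features on contigs outside the contig set are flagged", {
  p <- write_tmp_gtf(c(gtf_line("chr1", "exon", 1L, 100L, "g1", "g1.t1"),
                       gtf_line("chrUn", "exon", 1L, 100L, "g2", "g2.t1")))
  ann <- parse_gtf(p, example_contigs())
  expect_equal(nrow(ann$genes), 2L)  # retained ...
  expect_equal(ann$genes$flagged[ann$genes$gene_id == "g2"], TRUE)
  expect_equal(ann$genes$flagged[ann$genes$gene_id == "g1"], FALSE)
})

test_that("a transcript_id shared across genes warns; incoherent isoforms error", {
  p <- write_tmp_gtf(c(gtf_line("chr1", "exon", 1L, 100L, "gA", "tX"),
                       gtf_line("chr1", "exon", 201L, 300L, "gB", "tX")))
  expect_warning(ann <- parse_gtf(p), "multiple genes")
  expect_equal(nrow(ann$transcripts), 2L)

  p2 <- write_tmp_gtf(c(gtf_line("chr1", "exon", 1L, 100L, "gA", "tX"),
                        gtf_line("chr1", "exon", 201L, 300L, "gA", "tX",
                                 strand = "-")))
  expect_error(parse_gtf(p2), "strand")
})

strip_report <- function(x) { attr(x, "removal_report") <- NULL; x }

test_that("harmonization applies translate -> contig -> biotype -> purge", {
  lines <- c(
    gtf_line("1", "exon", 1L, 100L, "g1", "g1.t1"),
    gtf_line("MT", "exon", 1L, 100L, "gmt", "gmt.t1"),
    gtf_line("1", "exon", 201L, 260L, "g2", "g2.t1", biotype = "tRNA"),
    gtf_line("1", "exon", 401L, 500L, "g3", "g3.t1"),
    gtf_line("1", "exon", 401L, 500L, "g3", "g3.t2", biotype = "snRNA"))
  ann <- parse_gtf(write_tmp_gtf(lines))
  rules <- harmonization_config(
    contig_whitelist = "chr1",
    contig_map = c("1" = "chr1", "MT" = "chrM"),
    biotype_blacklist = c("tRNA", "miscRNA", "scRNA", "snRNA"))
  h <- harmonize(ann, rules)
  rep <- removal_report(h)

  # mitochondrial gene removed by the contig whitelist
  expect_false("gmt" %in% h$genes$gene_id)
  expect_equal(rep$contig_filtered_genes, 1L)
  # blacklisted small-RNA isoforms removed; g2 left empty and purged
  expect_equal(rep$biotype_filtered_isoforms, 2L)
  expect_equal(rep$empty_purged_genes, 1L)
  expect_equal(sort(h$genes$gene_id), c("g1", "g3"))
  expect_equal(nrow(h$transcripts[h$transcripts$gene_id == "g3", ]), 1L)
  # all intervals re-anchored to the translated contig name
  expect_true(all(h$exons$contig == "chr1"))

  # idempotence: same rules twice = once
  h2 <- harmonize(h, rules)
  expect_equal(strip_report(h2), strip_report(h))
})

test_that("harmonization rules load from a YAML config file", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("contig_whitelist:", "  - chr1", "  - chr2",
               "contig_map:", "  \"1\": chr1", "  MT: chrM",
               "biotype_blacklist:", "  - tRNA", "  - snRNA"), path)
  rules <- read_harmonization_config(path)
  expect_s3_class(rules, "HarmonizationConfig")
  expect_equal(rules$contig_whitelist, c("chr1", "chr2"))
  expect_equal(rules$contig_map, c("1" = "chr1", MT = "chrM"))
  expect_equal(rules$biotype_blacklist, c("tRNA", "snRNA"))
})

test_that("write_gtf/parse_gtf round-trips the gene model", {
  ann <- parse_gtf(example_gtf(), example_contigs(), source_name = "demo")
  out <- tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  back <- parse_gtf(out, example_contigs(), source_name = "demo")
  norm <- function(df, cols) {
    df <- df[do.call(order, df[cols]), cols, drop = FALSE]
    rownames(df) <- NULL
    df
  }
  icols <- c("gene_id", "transcript_id", "contig", "start", "end", "strand")
  expect_equal(norm(back$exons, icols), norm(ann$exons, icols))
  expect_equal(norm(back$cds, icols), norm(ann$cds, icols))
  expect_equal(norm(back$genes, c("gene_id", "symbol", "contig", "strand")),
               norm(ann$genes, c("gene_id", "symbol", "contig", "strand")))
  expect_equal(norm(back$transcripts, c("gene_id", "transcript_id", "biotype")),
               norm(ann$transcripts, c("gene_id", "transcript_id", "biotype")))
})

test_that("exonic union merges overlaps and matches a per-base oracle", {
  mk <- function(starts, ends) {
    n <- length(starts)
    annotation_set("u",
      genes = data.frame(gene_id = paste0("g", seq_len(n)),
                         symbol = paste0("G", seq_len(n)),
                         contig = "ctg", strand = "+"),
      transcripts = data.frame(transcript_id = paste0("t", seq_len(n)),
                               gene_id = paste0("g", seq_len(n)),
                               biotype = ""),
      exons = data.frame(transcript_id = paste0("t", seq_len(n)),
                         gene_id = paste0("g", seq_len(n)), contig = "ctg",
                         start = starts, end = ends, strand = "+"),
      contigs = data.frame(name = "ctg", length = 10000L,
                           category = "main"))
  }
  u1 <- exonic_union(mk(c(0L, 50L), c(100L, 150L)))
  expect_equal(u1$ctg, data.frame(start = 0L, end = 150L))
  u2 <- exonic_union(mk(c(0L, 20L), c(10L, 30L)))
  expect_equal(nrow(u2$ctg), 2L)
  expect_equal(union_length(u2), 20)

  set.seed(11)
  for (rep in 1:3) {
    s <- sample.int(10000L - 60L, 200L) - 1L
    e <- s + sample(5:60, 200L, replace = TRUE)
    ann <- mk(s, e)
    u <- exonic_union(ann)
    oracle <- coverage_oracle(ann$exons,
                              data.frame(name = "ctg", length = 10000L))
    expect_equal(union_length(u), unname(oracle["ctg"]))
  }
})

test_that("union length is invariant to exon order and to splitting", {
  set.seed(21)
  s <- sample.int(5000L, 40L) - 1L
  e <- s + sample(10:50, 40L, replace = TRUE)
  base <- data.frame(transcript_id = "t1", gene_id = "g1", contig = "ctg",
                     start = s, end = e, strand = "+")
  mk_ann <- function(ex) {
    annotation_set("u",
      genes = data.frame(gene_id = "g1", symbol = "G1", contig = "ctg",
                         strand = "+"),
      transcripts = data.frame(transcript_id = "t1", gene_id = "g1",
                               biotype = ""),
      exons = ex,
      contigs = data.frame(name = "ctg", length = 6000L, category = "main"))
  }
  # exons overlap within this synthetic isoform, so bypass the isoform
  # validity check by spreading them over pseudo-transcripts
  base$transcript_id <- paste0("t", seq_len(nrow(base)))
  mk_ann2 <- function(ex) {
    ex$transcript_id <- paste0("t", seq_len(nrow(ex)))
    annotation_set("u",
      genes = data.frame(gene_id = "g1", symbol = "G1", contig = "ctg",
                         strand = "+"),
      transcripts = data.frame(transcript_id = ex$transcript_id,
                               gene_id = "g1", biotype = ""),
      exons = ex,
      contigs = data.frame(name = "ctg", length = 6000L, category = "main"))
  }
  ref <- union_length(exonic_union(mk_ann2(base)))
  shuffled <- base[sample.int(nrow(base)), ]
  expect_equal(union_length(exonic_union(mk_ann2(shuffled))), ref)
  # split every exon into two adjacent pieces
  mid <- floor((base$start + base$end) / 2)
  split2 <- rbind(
    data.frame(transcript_id = "x", gene_id = "g1", contig = "ctg",
               start = base$start, end = mid, strand = "+"),
    data.frame(transcript_id = "x", gene_id = "g1", contig = "ctg",
               start = mid, end = base$end, strand = "+"))
  expect_equal(union_length(exonic_union(mk_ann2(split2))), ref)
})
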