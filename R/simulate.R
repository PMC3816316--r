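#' Configuration for the synthetic-data generator
#'
#' The generator produces, on toy contigs, every input the pipeline
#' consumes -- annotations of controlled complexity, alignments with
#' controlled mapping-category structure, replicate expression matrices
#' and matched RT-qPCR-style fold-changes -- together with ground-truth
#' sidecars, so each metric can be validated without external downloads.
#'
#' All fractions are exact design proportions (counts are rounded, not
#' drawn), so e.g. an `annotated_fraction` of 0.5 yields exactly 50%
#' annotated mapped units whenever the rounded counts divide evenly.
#' The same `seed` always reproduces byte-identical outputs.
#'
#' @param seed Integer seed; a single RNG stream per `simulate_*` call
#'   with a fixed draw order.
#' @param contigs `data.frame` with columns `name`, `length` of the toy
#'   contigs.
#' @param base_genes Number of core genes planted in *every* annotation
#'   (this is the known common-gene set).
#' @param annotations `data.frame` with columns `name`,
#'   `extra_gene_rate`, `extra_isoform_rate`; each annotation adds
#'   `round(rate * base_genes)` annotation-specific genes and extra
#'   isoforms on core genes.  Rows should be ordered by decreasing
#'   complexity.  The defaults emulate the roughly three-fold gene-count
#'   spread observed between the most and least complex public human
#'   catalogues.
#' @param reads List: `n` units (reads or pairs), `layout` (`"single"` or
#'   `"paired"`), `read_length` (bp), `multimap_fraction`,
#'   `unmapped_fraction`, `singleton_fraction` (paired only),
#'   `annotated_fraction` (of mapped units).  Defaults mirror a paired
#'   2 x 101 bp technical-replicate experiment.
#' @param expression List: `meanlog`/`sdlog` of the log-normal per-gene
#'   true mean, `true_cv` (replicate coefficient of variation),
#'   `replicates` (length-2 integer, 2-4 each; replicates per condition),
#'   `absent_fraction` (all-zero elements), `effect_sd` (SD of the
#'   N(0, sd^2) log2 fold-change effect), `qpcr_noise_sd` (additive noise
#'   on the RT-qPCR-style log2 fold-changes), `conditions` (length-2
#'   names; first is the fold-change numerator).
#'
#' @return Object of class `SimulationConfig`.
#' @export
simulation_config <- function(
    seed = 1L,
    contigs = data.frame(name = c("ctgA", "ctgB", "ctgC"),
                         length = c(120000L, 100000L, 80000L),
                         stringsAsFactors = FALSE),
    base_genes = 120L,
    annotations = data.frame(
      name = c("srcA", "srcB", "srcC", "srcD", "srcE", "srcF"),
      extra_gene_rate = c(1.0, 0.6, 0.45, 0.35, 0.15, 0),
      extra_isoform_rate = c(0.9, 0.75, 0.6, 0.45, 0.25, 0.1),
      stringsAsFactors = FALSE),
    reads = list(),
    expression = list()) {
  reads <- modifyList(list(n = 2000L, layout = "paired", read_length = 101L,
                           multimap_fraction = 0.15,
                           unmapped_fraction = 0.05,
                           singleton_fraction = 0.10,
                           annotated_fraction = 0.80), reads)
  expression <- modifyList(list(meanlog = 4, sdlog = 1.5, true_cv = 0.2,
                                replicates = c(3L, 3L),
                                absent_fraction = 0.10, effect_sd = 1,
                                qpcr_noise_sd = 0.25,
                                conditions = c("treatment", "control")),
                           expression)
  fracs <- c(annotations$extra_gene_rate,
             reads$multimap_fraction, reads$unmapped_fraction,
             reads$singleton_fraction, reads$annotated_fraction,
             expression$absent_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("rates/fractions must lie in [0, 1]")
  if (!reads$layout %in% c("single", "paired")) {
    stop("reads$layout must be 'single' or 'paired'")
  }
  if (length(expression$replicates) != 2L ||
      any(expression$replicates < 2L | expression$replicates > 4L)) {
    stop("expression$replicates must be two counts between 2 and 4")
  }
  if (any(contigs$length <= 0)) stop("contig lengths must be positive")
  structure(list(seed = as.integer(seed), contigs = contigs,
                 base_genes = as.integer(base_genes),
                 annotations = annotations, reads = reads,
                 expression = expression),
            class = "SimulationConfig")
}

# gene slots: non-overlapping windows of `slot` bp, interleaved across
# contigs so genes spread over the genome
gene_slots <- function(contigs, slot = 1000L) {
  per <- lapply(seq_len(nrow(contigs)), function(i) {
    k <- contigs$length[i] %/% slot
    data.frame(contig = contigs$name[i],
               start = slot * (seq_len(k) - 1L),
               rank = seq_len(k), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per)
  df[order(df$rank, match(df$contig, contigs$name)), c("contig", "start")]
}

# one random multi-exon structure inside [slot_start, slot_start + 1000)
random_isoform_structure <- function(slot_start) {
  pos <- slot_start + 100L + sample.int(50L, 1L)
  ne <- sample(2:4, 1L)
  ex <- matrix(0L, ne, 2L)
  for (e in seq_len(ne)) {
    w <- sample(80:140, 1L)
    ex[e, ] <- c(pos, pos + w)
    pos <- pos + w + sample(40:80, 1L)
  }
  ex
}

# alternative-splicing variant of an exon matrix: drop an internal exon
# when possible, otherwise shift the first exon boundary inward
variant_structure <- function(ex) {
  if (nrow(ex) >= 3L) {
    drop <- sample(2:(nrow(ex) - 1L), 1L)
    ex[-drop, , drop = FALSE]
  } else {
    ex[1L, 1L] <- ex[1L, 1L] + 20L
    ex
  }
}

cds_from_exons <- function(ex, trim = 30L) {
  cds <- ex
  if (cds[1L, 2L] - cds[1L, 1L] > 2L * trim) cds[1L, 1L] <- cds[1L, 1L] + trim
  n <- nrow(cds)
  if (cds[n, 2L] - cds[n, 1L] > 2L * trim) cds[n, 2L] <- cds[n, 2L] - trim
  cds
}

#' Simulate annotations of controlled complexity
#'
#' Plants a core gene set, with identical coordinates and symbols, in
#' every annotation -- guaranteeing that [common_genes()] recovers exactly
#' the core symbols -- and adds per-annotation extra genes and extra
#' isoforms at the configured rates.  With strictly decreasing rates the
#' returned sets are ordered by decreasing complexity and
#' [rank_complexity()] recovers the configured order.
#'
#' @param cfg A [simulation_config()].
#' @return Named list of `AnnotationSet`s, in the configured order.
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  slots <- gene_slots(cfg$contigs)
  max_extra <- max(round(cfg$annotations$extra_gene_rate * cfg$base_genes))
  need <- cfg$base_genes + max_extra
  if (nrow(slots) < need) {
    stop("contigs too short for ", need, " genes (capacity ", nrow(slots), ")")
  }
  contig_set <- data.frame(name = cfg$contigs$name,
                           length = cfg$contigs$length,
                           category = "main", stringsAsFactors = FALSE)

  # core structures generated once and shared by every annotation
  core <- lapply(seq_len(cfg$base_genes), function(i) {
    random_isoform_structure(slots$start[i])
  })
  core_contig <- slots$contig[seq_len(cfg$base_genes)]
  core_strand <- sample(c("+", "-"), cfg$base_genes, replace = TRUE)

  out <- lapply(seq_len(nrow(cfg$annotations)), function(a) {
    nm <- cfg$annotations$name[a]
    n_extra_g <- round(cfg$annotations$extra_gene_rate[a] * cfg$base_genes)
    n_extra_iso <- round(cfg$annotations$extra_isoform_rate[a] *
                           cfg$base_genes)
    genes <- list(); txs <- list(); exs <- list(); cdss <- list()
    add_tx <- function(gid, tid, contig, strand, ex, coding = TRUE) {
      txs[[length(txs) + 1L]] <<- data.frame(
        transcript_id = tid, gene_id = gid, biotype = "protein_coding",
        stringsAsFactors = FALSE)
      exs[[length(exs) + 1L]] <<- data.frame(
        transcript_id = tid, gene_id = gid, contig = contig,
        start = ex[, 1L], end = ex[, 2L], strand = strand,
        stringsAsFactors = FALSE)
      if (coding) {
        cd <- cds_from_exons(ex)
        cdss[[length(cdss) + 1L]] <<- data.frame(
          transcript_id = tid, gene_id = gid, contig = contig,
          start = cd[, 1L], end = cd[, 2L], strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    # core genes
    extra_per_gene <- tabulate((seq_len(n_extra_iso) - 1L) %%
                                 cfg$base_genes + 1L, cfg$base_genes)
    for (i in seq_len(cfg$base_genes)) {
      gid <- sprintf("%s.g%04d", nm, i)
      genes[[i]] <- data.frame(gene_id = gid,
                               symbol = sprintf("GENE%04d", i),
                               contig = core_contig[i],
                               strand = core_strand[i],
                               stringsAsFactors = FALSE)
      add_tx(gid, paste0(gid, ".t1"), core_contig[i], core_strand[i],
             core[[i]])
      if (extra_per_gene[i] > 0L) {
        for (k in seq_len(extra_per_gene[i])) {
          add_tx(gid, sprintf("%s.t%d", gid, k + 1L), core_contig[i],
                 core_strand[i], variant_structure(core[[i]]))
        }
      }
    }
    # annotation-specific extra genes in the shared extra-slot pool
    tag <- toupper(gsub("[^A-Za-z0-9]", "", nm))
    for (j in seq_len(n_extra_g)) {
      idx <- cfg$base_genes + j
      gid <- sprintf("%s.g%04d", nm, cfg$base_genes + j)
      strand <- sample(c("+", "-"), 1L)
      ex <- random_isoform_structure(slots$start[idx])
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, symbol = sprintf("%sX%04d", tag, j),
        contig = slots$contig[idx], strand = strand,
        stringsAsFactors = FALSE)
      add_tx(gid, paste0(gid, ".t1"), slots$contig[idx], strand, ex)
    }
    annotation_set(nm, version = "sim",
                   genes = do.call(rbind, genes),
                   transcripts = do.call(rbind, txs),
                   exons = do.call(rbind, exs),
                   cds = do.call(rbind, cdss),
                   contigs = contig_set)
  })
  names(out) <- cfg$annotations$name
  out
}

#' Simulate an alignment stream with known mapping categories
#'
#' Writes a SAM file whose reads (single-end) or read pairs (paired-end)
#' realize exact design counts of every mapping category, with primary
#' placements inside or outside the annotation's exonic union according to
#' `annotated_fraction`.  A truth sidecar labels every unit, so
#' [classify_mappings()] and [annotated_fraction()] can be checked
#' record-for-record.
#'
#' Both ends of a pair share the unit's annotated/un-annotated label, so
#' the either-end and both-ends overlap rules agree on the truth.
#' Non-unique units carry `NH:i:2` plus one secondary record per mapped
#' end.
#'
#' @param cfg A [simulation_config()].
#' @param ann An `AnnotationSet` (typically from [simulate_annotations()]).
#' @param path Output SAM path.
#' @return List with `sam` (the path) and `truth`: a `data.frame` with one
#'   row per unit (`read_id`, `layout`, `category`, `annotated`,
#'   `n_placements`).
#' @export
simulate_alignments <- function(cfg, ann,
                                path = tempfile(fileext = ".sam")) {
  stopifnot(is(cfg, "SimulationConfig"), is(ann, "AnnotationSet"))
  set.seed(cfg$seed + 1L)
  r <- cfg$reads
  rl <- r$read_length
  union <- exonic_union(ann)
  if (union_length(union) == 0) stop("annotation has no exons to place reads in")
  contigs <- ann$contigs
  clen <- setNames(contigs$length, contigs$name)
  gaps <- union_complement(union, contigs)
  gap_df <- do.call(rbind, lapply(names(gaps), function(nm) {
    g <- gaps[[nm]]
    g <- g[g$end - g$start >= rl, , drop = FALSE]
    if (nrow(g)) cbind(contig = nm, g, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(gap_df) || nrow(gap_df) == 0L) {
    stop("no un-annotated gap wide enough for read length ", rl)
  }
  un_df <- do.call(rbind, lapply(names(union), function(nm) {
    cbind(contig = nm, union[[nm]], stringsAsFactors = FALSE)
  }))

  place_annotated <- function(n) {
    if (n == 0L) return(NULL)
    i <- sample.int(nrow(un_df), n, replace = TRUE,
                    prob = un_df$end - un_df$start)
    lo <- pmax(0L, un_df$start[i] - rl + 1L)
    hi <- pmin(un_df$end[i] - 1L, clen[un_df$contig[i]] - rl)
    hi <- pmax(hi, lo)
    start <- lo + floor(runif(n) * (hi - lo + 1L))
    data.frame(contig = un_df$contig[i], start = as.integer(start),
               stringsAsFactors = FALSE)
  }
  place_unannotated <- function(n) {
    if (n == 0L) return(NULL)
    i <- sample.int(nrow(gap_df), n, replace = TRUE,
                    prob = gap_df$end - gap_df$start - rl + 1L)
    start <- gap_df$start[i] +
      floor(runif(n) * (gap_df$end[i] - gap_df$start[i] - rl + 1L))
    data.frame(contig = gap_df$contig[i], start = as.integer(start),
               stringsAsFactors = FALSE)
  }
  place_by_label <- function(lab) {
    out <- data.frame(contig = rep(NA_character_, length(lab)),
                      start = NA_integer_, stringsAsFactors = FALSE)
    out[lab, ] <- place_annotated(sum(lab))
    out[!lab, ] <- place_unannotated(sum(!lab))
    out
  }

  n <- r$n
  n_unmapped <- round(r$unmapped_fraction * n)
  n_mapped <- n - n_unmapped
  cig <- sprintf("%dM", rl)
  sam <- character(0)
  rec <- function(qname, flag, contig, start, mapq, cigar, rnext, pnext,
                  nh = NA) {
    line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
                    qname, flag, contig, start, mapq, cigar, rnext, pnext)
    if (!is.na(nh)) line <- paste0(line, sprintf("\tNH:i:%d", nh))
    sam[[length(sam) + 1L]] <<- line
  }

  if (r$layout == "single") {
    n_multi <- round(r$multimap_fraction * n_mapped)
    n_annot <- round(r$annotated_fraction * n_mapped)
    multi <- seq_len(n_mapped) <= n_multi
    # annotated labels run from the other end so the two labels decorrelate
    annot <- rev(seq_len(n_mapped)) <= n_annot
    pl <- place_by_label(annot)
    ids <- sprintf("read%06d", seq_len(n))
    for (u in seq_len(n_mapped)) {
      nh <- if (multi[u]) 2L else 1L
      rec(ids[u], 0L, pl$contig[u], pl$start[u] + 1L, 50L, cig, "*", 0L, nh)
      if (multi[u]) {
        p2 <- place_by_label(annot[u])
        rec(ids[u], 256L, p2$contig, p2$start + 1L, 0L, cig, "*", 0L, nh)
      }
    }
    for (u in seq_len(n_unmapped)) {
      rec(ids[n_mapped + u], 4L, "*", 0L, 0L, "*", "*", 0L)
    }
    truth <- data.frame(
      read_id = ids, layout = "single",
      category = c(ifelse(multi, "non_uniquely_mapped", "uniquely_mapped"),
                   rep("unmapped", n_unmapped)),
      annotated = c(annot, rep(NA, n_unmapped)),
      n_placements = c(ifelse(multi, 2L, 1L), rep(0L, n_unmapped)),
      stringsAsFactors = FALSE)
  } else {
    n_single <- round(r$singleton_fraction * n_mapped)
    n_full <- n_mapped - n_single
    n_multi_full <- round(r$multimap_fraction * n_full)
    n_multi_single <- round(r$multimap_fraction * n_single)
    n_annot_full <- round(r$annotated_fraction * n_full)
    n_annot_single <- round(r$annotated_fraction * n_single)
    ids <- sprintf("pair%06d", seq_len(n))

    full_multi <- seq_len(n_full) <= n_multi_full
    # decorrelate annotated from multi labels: spread annotated over the
    # index order reversed
    full_annot <- rev(seq_len(n_full)) <= n_annot_full
    p1 <- place_by_label(full_annot)
    p2 <- place_by_label(full_annot)
    for (u in seq_len(n_full)) {
      nh <- if (full_multi[u]) 2L else 1L
      rec(ids[u], 67L, p1$contig[u], p1$start[u] + 1L, 50L, cig,
          if (p2$contig[u] == p1$contig[u]) "=" else p2$contig[u],
          p2$start[u] + 1L, nh)
      rec(ids[u], 131L, p2$contig[u], p2$start[u] + 1L, 50L, cig,
          if (p2$contig[u] == p1$contig[u]) "=" else p1$contig[u],
          p1$start[u] + 1L, nh)
      if (full_multi[u]) {
        s1 <- place_by_label(full_annot[u]); s2 <- place_by_label(full_annot[u])
        rec(ids[u], 323L, s1$contig, s1$start + 1L, 0L, cig, "*", 0L, nh)
        rec(ids[u], 387L, s2$contig, s2$start + 1L, 0L, cig, "*", 0L, nh)
      }
    }
    single_multi <- seq_len(n_single) <= n_multi_single
    single_annot <- rev(seq_len(n_single)) <= n_annot_single
    ps <- place_by_label(single_annot)
    for (u in seq_len(n_single)) {
      id <- ids[n_full + u]
      nh <- if (single_multi[u]) 2L else 1L
      rec(id, 73L, ps$contig[u], ps$start[u] + 1L, 50L, cig, "*", 0L, nh)
      rec(id, 133L, "*", 0L, 0L, "*", "*", 0L)
      if (single_multi[u]) {
        s1 <- place_by_label(single_annot[u])
        rec(id, 329L, s1$contig, s1$start + 1L, 0L, cig, "*", 0L, nh)
      }
    }
    for (u in seq_len(n_unmapped)) {
      id <- ids[n_mapped + u]
      rec(id, 77L, "*", 0L, 0L, "*", "*", 0L)
      rec(id, 141L, "*", 0L, 0L, "*", "*", 0L)
    }
    truth <- data.frame(
      read_id = ids, layout = "paired",
      category = c(ifelse(full_multi, "non_uniquely_paired",
                          "uniquely_paired"),
                   ifelse(single_multi, "non_uniquely_mapped_singleton",
                          "uniquely_mapped_singleton"),
                   rep("unmapped", n_unmapped)),
      annotated = c(full_annot, single_annot, rep(NA, n_unmapped)),
      n_placements = c(ifelse(full_multi, 2L, 1L),
                       ifelse(single_multi, 2L, 1L),
                       rep(0L, n_unmapped)),
      stringsAsFactors = FALSE)
  }

  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name, contigs$length))
  writeLines(c(header, unlist(sam)), path)
  list(sam = path, truth = truth)
}

#' Simulate a replicate expression matrix with matched RT-qPCR truth
#'
#' Per gene, a log-normal true mean; a configured fraction of elements is
#' all-zero ("absent"); replicate values are the condition mean times
#' multiplicative log-normal noise whose coefficient of variation equals
#' `true_cv` (`sdlog = sqrt(log(1 + cv^2))`, unit mean); the
#' first-condition mean is scaled by `2^effect` with
#' `effect ~ N(0, effect_sd^2)`.  The matched RT-qPCR-style table reports
#' `effect + N(0, qpcr_noise_sd^2)` for present genes, and a per-replicate
#' present/absent flag table plants exactly the present genes as
#' all-present.
#'
#' @param cfg A [simulation_config()].
#' @param ann An `AnnotationSet` supplying the gene ids and symbols.
#' @param unit Unit label stored on the matrix.
#' @return List with `matrix` (an [expression_matrix()]), `truth`
#'   (`data.frame`: `gene_id`, `symbol`, `base_mean`, `effect`, `absent`),
#'   `qpcr` (`data.frame`: `symbol`, `log2_fc` for present genes) and
#'   `qpcr_flags` (symbol plus per-replicate present calls).
#' @export
simulate_expression <- function(cfg, ann, unit = "TPM") {
  stopifnot(is(cfg, "SimulationConfig"), is(ann, "AnnotationSet"))
  set.seed(cfg$seed + 2L)
  e <- cfg$expression
  genes <- ann$genes
  n <- nrow(genes)
  if (n == 0L) stop("annotation has no genes")
  base_mean <- rlnorm(n, e$meanlog, e$sdlog)
  n_absent <- round(e$absent_fraction * n)
  absent <- rep(FALSE, n)
  if (n_absent > 0L) absent[sample.int(n, n_absent)] <- TRUE
  effect <- rnorm(n, 0, e$effect_sd)

  sdlog_noise <- sqrt(log(1 + e$true_cv^2))
  meanlog_noise <- -sdlog_noise^2 / 2     # unit-mean multiplicative noise
  r1 <- e$replicates[1L]; r2 <- e$replicates[2L]
  mean1 <- base_mean * 2^effect           # numerator condition
  mean2 <- base_mean
  noise <- function(k) {
    if (sdlog_noise == 0) matrix(1, n, k)
    else matrix(rlnorm(n * k, meanlog_noise, sdlog_noise), n, k)
  }
  vals <- cbind(mean1 * noise(r1), mean2 * noise(r2))
  vals[absent, ] <- 0
  colnames(vals) <- c(paste0(e$conditions[1L], "_", seq_len(r1)),
                      paste0(e$conditions[2L], "_", seq_len(r2)))
  rownames(vals) <- genes$gene_id
  mat <- expression_matrix(vals,
                           condition = factor(rep(e$conditions, c(r1, r2)),
                                              levels = e$conditions),
                           symbols = genes$symbol, unit = unit)

  qpcr <- data.frame(symbol = genes$symbol[!absent],
                     log2_fc = effect[!absent] +
                       rnorm(sum(!absent), 0, e$qpcr_noise_sd),
                     stringsAsFactors = FALSE)
  flags <- matrix(TRUE, n, r1 + r2)
  if (any(absent)) {
    flags[absent, ] <- matrix(runif(sum(absent) * (r1 + r2)) < 0.5,
                              ncol = r1 + r2)
    # guarantee every absent gene misses at least one call
    kill <- sample.int(r1 + r2, sum(absent), replace = TRUE)
    flags[cbind(which(absent), kill)] <- FALSE
  }
  qpcr_flags <- data.frame(symbol = genes$symbol,
                           ifelse(flags, "P", "A"),
                           stringsAsFactors = FALSE)
  names(qpcr_flags) <- c("symbol", paste0("rep", seq_len(r1 + r2)))

  list(matrix = mat,
       truth = data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                          base_mean = base_mean, effect = effect,
                          absent = absent, stringsAsFactors = FALSE),
       qpcr = qpcr, qpcr_flags = qpcr_flags)
}
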