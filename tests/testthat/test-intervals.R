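test_that("peak_set validates and sorts", {
  ps <- peak_set(c("chr2", "chr1"), c(100, 5), c(300, 50))
  expect_equal(ps$peaks$chrom, c("chr1", "chr2"))
  expect_equal(length(ps), 2L)
  expect_error(peak_set("chr1", 10, 10), "start < end")
  expect_error(peak_set("chr1", -1, 10), "start < end")
  expect_error(peak_set(c("chr1", "chr1"), c(1, 2), c(5, 6),
                        id = c("a", "a")), "unique")
})

test_that("annotate_peaks handles the window classes", {
  genes <- toy_genes()
  # midpoint 1100 within TSS(10000)? no -> use peaks near the fixture genes
  ps <- peak_set(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr3"),
    start = c(10400, 18400, 14000, 30000, 100),
    end   = c(10600, 18600, 14200, 30200, 300),
    name = "t")
  ann <- annotate_peaks(ps, genes)
  # sorted order: by start; classes: 10500 promoter (|10500-10000| <= 1000),
  # 18500 TTS of g1 (+ strand end 18000, window -100/+1000),
  # 14100 inside g1 transcript -> exon (transcript-as-exon default),
  # 30100 intergenic, chr3 -> NA
  expect_equal(as.character(ann$class),
               c("promoter", "exon", "TTS", "intergenic", "NA"))
  expect_equal(sum(ann$fractions), 1)
})

test_that("TTS window respects strand", {
  genes <- toy_genes()  # g2 on chr1 is '-' with transcript start 42000
  ps <- peak_set("chr1", 41400, 41600, name = "t")  # midpoint 41500
  ann <- annotate_peaks(ps, genes)
  expect_equal(as.character(ann$class), "TTS")
  # 500 bp on the upstream (genomic +) side of a minus-strand end is
  # downstream of transcription: inside the -100/+1000 window
  ps2 <- peak_set("chr1", 42300, 42500, name = "t")  # midpoint 42400, genic
  expect_equal(as.character(annotate_peaks(ps2, genes)$class), "exon")
})

test_that("annotation matches a brute-force per-peak scan", {
  genes <- random_genes(12)
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    brk <- sort(round(seq(g$tx_start, g$tx_end, length.out = 5)))
    data.frame(chrom = g$chrom, start = brk[c(1, 3)], end = brk[c(2, 4)])
  }))
  ps <- random_peaks(200, seed = 7)
  p <- analysis_params()
  ann <- annotate_peaks(ps, genes, p, exons = exons)
  mids <- floor((ps$peaks$start + ps$peaks$end) / 2)
  oracle <- vapply(seq_len(200), function(i) {
    ch <- ps$peaks$chrom[i]; m <- mids[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) return("NA")
    if (any(abs(m - g$tss_bp) <= p$promoter_window)) return("promoter")
    tend <- ifelse(g$strand == "+", g$tx_end, g$tx_start)
    lo <- ifelse(g$strand == "+", tend - p$tts_upstream,
                 tend - p$tts_downstream)
    hi <- ifelse(g$strand == "+", tend + p$tts_downstream,
                 tend + p$tts_upstream)
    if (any(m >= lo & m <= hi)) return("TTS")
    e <- exons[exons$chrom == ch, , drop = FALSE]
    if (any(m >= e$start & m < e$end)) return("exon")
    if (any(m >= g$tx_start & m < g$tx_end)) return("intron")
    "intergenic"
  }, character(1))
  expect_equal(as.character(ann$class), oracle)
})

test_that("annotation is permutation-invariant and errors on disjoint naming", {
  genes <- toy_genes()
  ps <- random_peaks(50, seed = 3)
  shuf <- peak_set(rev(ps$peaks$chrom), rev(ps$peaks$start),
                   rev(ps$peaks$end), id = rev(ps$peaks$id), name = "s")
  a1 <- annotate_peaks(ps, genes)
  a2 <- annotate_peaks(shuf, genes)
  expect_equal(as.character(a1$class)[order(ps$peaks$id)],
               as.character(a2$class)[order(shuf$peaks$id)])
  bad <- peak_set("scaffold_99", 100, 300, name = "bad")
  expect_error(annotate_peaks(bad, genes), "scaffold_99")
})

test_that("overlap_peak_sets partitions against the all-pairs oracle", {
  a <- random_peaks(50, chroms = "chr1", seed = 11, name = "a")
  b <- random_peaks(50, chroms = "chr1", seed = 12, name = "b")
  res <- overlap_peak_sets(a, b)
  ov <- function(x, y) x$start < y$end & y$start < x$end  # >=1 bp overlap
  both_a <- vapply(seq_len(50), function(i) {
    any(ov(a$peaks[i, ], b$peaks))
  }, logical(1))
  both_b <- vapply(seq_len(50), function(i) {
    any(ov(b$peaks[i, ], a$peaks))
  }, logical(1))
  expect_setequal(res$both_a, a$peaks$id[both_a])
  expect_setequal(res$both_b, b$peaks$id[both_b])
  expect_setequal(res$a_only, a$peaks$id[!both_a])
  # partition exhaustive and disjoint
  expect_equal(sort(c(res$a_only, res$both_a)), sort(a$peaks$id))
  # merged-site count symmetric
  res2 <- overlap_peak_sets(b, a)
  expect_equal(res$counts$merged_sites, res2$counts$merged_sites)
})

test_that("disjoint chromosomes and empty sets give zero overlap", {
  a <- random_peaks(10, chroms = "chr1", seed = 1, name = "a")
  b <- random_peaks(10, chroms = "chr2", seed = 2, name = "b")
  res <- overlap_peak_sets(a, b)
  expect_equal(res$counts$both_a, 0)
  expect_equal(res$counts$merged_sites, 0)
  empty <- peak_set(character(), numeric(), numeric(), name = "e")
  res0 <- overlap_peak_sets(a, empty)
  expect_equal(res0$counts$both_a, 0)
  expect_equal(res0$counts$a_only, 10)
})

test_that("flanking_enhancer_density matches the argmin-distance oracle", {
  genes <- random_genes(10, chroms = "chr1")
  ps <- random_peaks(30, chroms = "chr1", seed = 21)
  res <- flanking_enhancer_density(genes, ps, merge = FALSE)
  mids <- floor((ps$peaks$start + ps$peaks$end) / 2)
  oracle <- table(factor(vapply(mids, function(m) {
    d <- abs(m - genes$tss_bp)
    cand <- which(d == min(d))
    # tie -> smaller TSS coordinate
    genes$gene_id[cand[which.min(genes$tss_bp[cand])]]
  }, character(1)), levels = genes$gene_id))
  expect_equal(res$per_gene$n_flanking_peaks, as.integer(oracle))
  # conservation: all peaks on gene-bearing chromosomes assigned
  expect_equal(sum(res$per_gene$n_flanking_peaks), 30)
  expect_equal(res$mean, 3)
})

test_that("single gene absorbs all peaks; group means reported", {
  genes <- toy_genes()[3, ]  # the only chr2 gene
  ps <- random_peaks(5, chroms = "chr2", seed = 5)
  res <- flanking_enhancer_density(genes, ps,
                                   gene_groups = list(all = "g3"))
  expect_equal(res$per_gene$n_flanking_peaks, 5L)
  expect_equal(unname(res$group_means["all"]), 5)
})

test_that("match_tss_to_peaks applies the inclusive 2 kb window", {
  genes <- toy_genes()
  # centers: exactly on g1 TSS (10000), 2001 bp past g2 TSS (50000)
  ps <- peak_set(c("chr1", "chr1"), c(9900, 51901), c(10100, 52101),
                 name = "m")
  res <- match_tss_to_peaks(genes, ps)
  expect_true("g1" %in% res$matched)
  expect_true("g2" %in% res$unmatched)
  # boundary: exactly 2000 bp away is matched (inclusive window)
  ps2 <- peak_set("chr1", 51900, 52100, name = "m2")  # center 52000
  expect_true("g2" %in% match_tss_to_peaks(genes, ps2)$matched)
})

test_that("match_tss_to_peaks equals the brute-force window scan", {
  genes <- random_genes(15)
  ps <- random_peaks(60, seed = 31)
  p <- analysis_params()
  res <- match_tss_to_peaks(genes, ps, p)
  mids <- floor((ps$peaks$start + ps$peaks$end) / 2)
  oracle <- vapply(seq_len(nrow(genes)), function(i) {
    same <- ps$peaks$chrom == genes$chrom[i]
    any(abs(mids[same] - genes$tss_bp[i]) <= p$tss_match_window)
  }, logical(1))
  expect_setequal(res$matched, genes$gene_id[oracle])
})

test_that("BED and gene-table round trips are exact", {
  dir <- withr::local_tempdir()
  ps <- random_peaks(25, seed = 41, name = "rt")
  f <- file.path(dir, "x.bed")
  write_bed(ps, f)
  back <- read_bed(f, name = "rt")
  expect_equal(back$peaks[c("chrom", "start", "end", "id")],
               ps$peaks[c("chrom", "start", "end", "id")])
  genes <- random_genes(8)
  g <- file.path(dir, "g.tsv")
  write_gene_table(genes, g)
  expect_equal(as.data.frame(read_gene_table(g)), as.data.frame(genes))
})
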