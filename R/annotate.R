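# Peak annotation, overlap partitioning, closest-TSS density, TSS matching.

# 0-based half-open window -> GRanges (clips at chromosome start)
window_gr <- function(chrom, start0, end0) {
  start0 <- pmax(start0, 0)
  keep <- end0 > start0
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start0[keep] + 1, end0[keep]))
}

point_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
}

#' Annotate peaks relative to gene features
#'
#' Classifies each peak by its midpoint with priority
#' promoter > TTS > exon > intron > intergenic. Promoters are the TSS
#' +/- `promoter_window`; the TTS window spans `tts_upstream` bp upstream to
#' `tts_downstream` bp downstream of the strand-appropriate transcript end.
#' Peaks on chromosomes carrying no annotated gene are classed `NA`
#' (unplaced scaffolds). When no exon table is supplied each transcript
#' counts as a single exon, so the `intron` class only arises with explicit
#' exon models.
#'
#' @param peaks A [peak_set].
#' @param genes A [gene_annotation] data.frame.
#' @param params [analysis_params].
#' @param exons Optional data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open exon intervals.
#' @return list with `class` (factor per peak, levels promoter/TTS/exon/
#'   intron/intergenic/NA, aligned with `peaks$peaks`), and `fractions`
#'   (named numeric summing to 1).
#' @export
annotate_peaks <- function(peaks, genes, params = analysis_params(),
                           exons = NULL) {
  if (nrow(genes) == 0) stop("gene annotation is empty")
  df <- peaks$peaks
  lv <- c("promoter", "TTS", "exon", "intron", "intergenic", "NA")
  if (nrow(df) == 0) {
    return(list(class = factor(character(), levels = lv),
                fractions = stats::setNames(rep(NaN, 6), lv)))
  }
  if (!any(unique(df$chrom) %in% unique(genes$chrom))) {
    stop("no chromosome shared between peaks and genes; peaks: ",
         paste(unique(df$chrom), collapse = ","), " vs genes: ",
         paste(unique(genes$chrom), collapse = ","))
  }
  mids <- point_gr(df$chrom, peak_midpoints(peaks))

  w <- params$promoter_window
  prom <- window_gr(genes$chrom, genes$tss_bp - w, genes$tss_bp + w + 1)
  tend <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
  tts_lo <- ifelse(genes$strand == "+", tend - params$tts_upstream,
                   tend - params$tts_downstream)
  tts_hi <- ifelse(genes$strand == "+", tend + params$tts_downstream,
                   tend + params$tts_upstream)
  tts <- window_gr(genes$chrom, tts_lo, tts_hi + 1)
  ex <- if (is.null(exons)) {
    window_gr(genes$chrom, genes$tx_start, genes$tx_end)
  } else {
    window_gr(exons$chrom, exons$start, exons$end)
  }
  body <- window_gr(genes$chrom, genes$tx_start, genes$tx_end)

  hit <- function(subject) {
    overlaps_any(mids, subject)
  }
  cls <- rep("intergenic", nrow(df))
  cls[hit(body)] <- "intron"
  cls[hit(ex)] <- "exon"
  cls[hit(tts)] <- "TTS"
  cls[hit(prom)] <- "promoter"
  cls[!(df$chrom %in% genes$chrom)] <- "NA"
  cls <- factor(cls, levels = lv)
  fr <- table(cls) / nrow(df)
  list(class = cls, fractions = stats::setNames(as.numeric(fr), names(fr)))
}

#' Partition two peak sets by overlap
#'
#' A peak is co-bound ("both") iff it intersects at least one bp of any peak
#' in the other set. Counts are reported from each set's perspective, plus a
#' merged-site count: the number of union intervals formed by merging all
#' co-bound peaks from both sets.
#'
#' @param a,b [peak_set] objects.
#' @return list with id vectors `a_only`, `b_only`, `both_a`, `both_b` and a
#'   `counts` list (`a_only`, `b_only`, `both_a`, `both_b`, `merged_sites`).
#' @export
overlap_peak_sets <- function(a, b) {
  gra <- ps_granges(a); grb <- ps_granges(b)
  in_b <- overlaps_any(gra, grb)
  in_a <- overlaps_any(grb, gra)
  comb <- rbind(a$peaks[in_b, c("chrom", "start", "end")],
                b$peaks[in_a, c("chrom", "start", "end")])
  merged <- if (nrow(comb)) {
    length(GenomicRanges::reduce(window_gr(comb$chrom, comb$start,
                                           comb$end)))
  } else 0L
  list(
    a_only = a$peaks$id[!in_b], b_only = b$peaks$id[!in_a],
    both_a = a$peaks$id[in_b], both_b = b$peaks$id[in_a],
    counts = list(a_only = sum(!in_b), b_only = sum(!in_a),
                  both_a = sum(in_b), both_b = sum(in_a),
                  merged_sites = merged)
  )
}

#' Flanking active-peak density per gene
#'
#' Assigns each active peak (by midpoint) to the single gene whose TSS is
#' nearest, a local enhancer-density estimate rather than an
#' enhancer-target prediction. Equidistant ties go to the gene with the
#' smaller TSS coordinate. Peaks on chromosomes without genes are left
#' unassigned. Overlapping or book-ended active peaks are merged into single
#' sites before assignment (disable with `merge = FALSE`).
#'
#' @param genes A [gene_annotation] data.frame.
#' @param active_peaks A [peak_set] of active-chromatin peaks.
#' @param gene_groups Optional named list of gene-id vectors; the mean count
#'   of each group is reported alongside the genome-wide mean.
#' @param merge Merge overlapping peaks before assignment (default TRUE).
#' @return list with `per_gene` (data.frame gene_id, n_flanking_peaks),
#'   `mean` (genome-wide), `group_means`, and `n_assigned`.
#' @export
flanking_enhancer_density <- function(genes, active_peaks, gene_groups = NULL,
                                      merge = TRUE) {
  gr <- ps_granges(active_peaks)
  if (merge) gr <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  pchrom <- as.character(GenomicRanges::seqnames(gr))
  pmid <- floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)

  counts <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  n_assigned <- 0L
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    # candidate order: by TSS, ties broken toward smaller TSS automatically
    o <- order(g$tss_bp, g$gene_id)
    g <- g[o, , drop = FALSE]
    mid <- pmid[pchrom == ch]
    if (!length(mid)) next
    tss <- g$tss_bp
    idx <- findInterval(mid, tss)  # last tss <= mid
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(tss))
    dlo <- abs(mid - tss[lo]); dhi <- abs(mid - tss[hi])
    # tie (dlo == dhi) -> lo, the smaller TSS coordinate
    pick <- ifelse(dhi < dlo, hi, lo)
    tb <- table(factor(g$gene_id[pick], levels = names(counts)))
    counts <- counts + as.integer(tb)
    n_assigned <- n_assigned + length(mid)
  }
  per_gene <- data.frame(gene_id = names(counts),
                         n_flanking_peaks = as.integer(counts),
                         stringsAsFactors = FALSE)
  gm <- if (is.null(gene_groups)) NULL else {
    vapply(gene_groups, function(ids) mean(counts[ids]), numeric(1))
  }
  list(per_gene = per_gene, mean = mean(counts), group_means = gm,
       n_assigned = n_assigned)
}

#' Match TSSs to promoter peaks
#'
#' A TSS is matched iff some peak center lies within `tss_match_window` bp
#' of it (inclusive).
#'
#' @param genes A [gene_annotation] data.frame.
#' @param promoter_peaks A [peak_set].
#' @param params [analysis_params].
#' @return list with `matched`, `unmatched` (gene-id vectors) and
#'   `match_rate`.
#' @export
match_tss_to_peaks <- function(genes, promoter_peaks,
                               params = analysis_params()) {
  w <- params$tss_match_window
  tss <- point_gr(genes$chrom, genes$tss_bp)
  mids <- point_gr(promoter_peaks$peaks$chrom, peak_midpoints(promoter_peaks))
  # width-1 ranges at distance d have an inter-range gap of d-1, so a
  # maxgap of w-1 implements the inclusive |center - tss| <= w rule
  hit <- overlaps_any(tss, mids, maxgap = w - 1L)
  list(matched = genes$gene_id[hit], unmatched = genes$gene_id[!hit],
       match_rate = if (nrow(genes)) mean(hit) else NaN)
}
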