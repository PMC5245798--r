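#' Analysis parameters
#'
#' Bundles the tunable windows, thresholds and depths used throughout the
#' peak-annotation and co-binding statistics. Defaults follow common
#' regulatory-genomics conventions: promoters are the TSS +/- 1 kb,
#' transcription termination sites span -100 bp/+1 kb around the transcript
#' end, permutation nulls use 1,000 iterations, and tag counts are
#' depth-normalized to 10 million mapped reads.
#'
#' @param promoter_window Half-width in bp of the promoter window around the
#'   TSS (default 1000, i.e. TSS +/- 1 kb).
#' @param tss_match_window Distance in bp within which a peak center matches
#'   a TSS (default 2000).
#' @param tts_upstream,tts_downstream Window around the transcript 3' end
#'   defining the TTS class, in bp upstream/downstream of the end in the
#'   direction of transcription (defaults 100 and 1000).
#' @param n_permutations Iterations for permutation nulls (default 1000).
#' @param norm_depth Library size to which tag counts are scaled
#'   (default 1e7).
#' @param fold_thresholds Knockdown fold-change class thresholds
#'   (default c(3, 10)).
#' @param padj_cutoff Adjusted-p cutoff for differential-expression
#'   membership (default 0.05).
#' @param correlation_cutoff Per-bin Pearson correlation below which a bin is
#'   flagged as poorly correlated between conditions (default 0.5).
#' @param metagene_flank Flank in bp profiled on each side of a domain
#'   (default 2e5).
#' @param bins_per_quartile Bins per metagene segment (default 175; the
#'   profile has 4 segments, hence 700 bins).
#' @param tad_bin_size Contact-map bin size in bp for domain calling
#'   (default 25000; sensible range 10-25 kb).
#'
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(promoter_window = 1000L,
                            tss_match_window = 2000L,
                            tts_upstream = 100L,
                            tts_downstream = 1000L,
                            n_permutations = 1000L,
                            norm_depth = 1e7,
                            fold_thresholds = c(3, 10),
                            padj_cutoff = 0.05,
                            correlation_cutoff = 0.5,
                            metagene_flank = 200000L,
                            bins_per_quartile = 175L,
                            tad_bin_size = 25000L) {
  p <- list(
    promoter_window = as.integer(promoter_window),
    tss_match_window = as.integer(tss_match_window),
    tts_upstream = as.integer(tts_upstream),
    tts_downstream = as.integer(tts_downstream),
    n_permutations = as.integer(n_permutations),
    norm_depth = as.numeric(norm_depth),
    fold_thresholds = sort(as.numeric(fold_thresholds)),
    padj_cutoff = as.numeric(padj_cutoff),
    correlation_cutoff = as.numeric(correlation_cutoff),
    metagene_flank = as.integer(metagene_flank),
    bins_per_quartile = as.integer(bins_per_quartile),
    tad_bin_size = as.integer(tad_bin_size)
  )
  vals <- unlist(p[c("promoter_window", "tss_match_window", "tts_downstream",
                     "n_permutations", "norm_depth", "padj_cutoff",
                     "correlation_cutoff", "metagene_flank",
                     "bins_per_quartile", "tad_bin_size")])
  if (any(vals <= 0)) stop("all analysis parameters must be positive")
  if (p$bins_per_quartile < 1L) stop("bins_per_quartile must be >= 1")
  class(p) <- "analysis_params"
  p
}
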