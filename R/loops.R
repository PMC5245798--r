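# Significant-interaction (loop) calling, differential scoring, and
# anchor feature-pair enrichment.

#' Call significant interactions with a cumulative binomial test
#'
#' For every candidate bin pair (i, j) with separation at least
#' `min_separation` and at most `max_distance` bins, both ends unmasked:
#' the number of trials is the total number of reads with an end in bin i
#' plus the total with an end in bin j; the per-trial success probability
#' is the background-expected count of the pair divided by the trials; the
#' p-value is the upper-tail binomial probability of at least the observed
#' count. Benjamini-Hochberg q-values are computed over all tested pairs,
#' and pairs with q below `q_cutoff` are returned sorted by p. Pairs with
#' zero expected count but positive observed count cannot be tested under
#' this model; they are flagged, not dropped.
#'
#' @param cm A [contact_matrix].
#' @param bg Its `background_model` (fitted on the same matrix).
#' @param params [analysis_params] (reserved; resolution bookkeeping).
#' @param min_separation Minimum anchor separation in bins (default 2;
#'   adjacent bins are dominated by decay and self-ligation).
#' @param max_distance Maximum separation in bins (default 100).
#' @param q_cutoff Significance threshold on the BH q-value (default 0.05).
#' @return list of class `interaction_calls`: `calls` (significant pairs),
#'   `tested` (all tested pairs with o, n, p_s, p, q, strength, flagged),
#'   plus chrom/bin_size.
#' @export
call_interactions <- function(cm, bg, params = analysis_params(),
                              min_separation = 2L, max_distance = 100L,
                              q_cutoff = 0.05) {
  if (cm$n_bins != bg$n_bins || cm$chrom != bg$chrom) {
    stop("background must be fitted on the same matrix binning")
  }
  n_bins <- cm$n_bins
  e <- expected_matrix(bg)
  tot <- rowSums(cm$counts)
  idx <- which(upper.tri(cm$counts), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  keep <- d >= min_separation & d <= max_distance &
    !bg$masked[idx[, 1]] & !bg$masked[idx[, 2]]
  idx <- idx[keep, , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  o <- cm$counts[idx]
  ee <- e[idx]
  n <- round(tot[i] + tot[j])
  p_s <- pmin(ee / n, 1)
  flagged <- (ee == 0 & o > 0) | n == 0
  p <- rep(NA_real_, length(o))
  okp <- !flagged
  p[okp] <- stats::pbinom(o[okp] - 1, n[okp], p_s[okp], lower.tail = FALSE)
  p[okp & o == 0] <- 1
  q <- rep(NA_real_, length(o))
  q[okp] <- stats::p.adjust(p[okp], method = "BH")
  tested <- data.frame(
    bin1 = i - 1L, bin2 = j - 1L,
    start1 = (i - 1) * cm$bin_size, end1 = i * cm$bin_size,
    start2 = (j - 1) * cm$bin_size, end2 = j * cm$bin_size,
    o = o, n = n, p_s = p_s, p = p, q = q,
    strength = ifelse(ee > 0, o / ee, NA_real_),
    flagged = flagged
  )
  calls <- tested[!tested$flagged & tested$q < q_cutoff, , drop = FALSE]
  calls <- calls[order(calls$p), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(chrom = cm$chrom, bin_size = cm$bin_size,
                 n_bins = n_bins, calls = calls, tested = tested,
                 q_cutoff = q_cutoff),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf("interaction_calls %s: %d significant of %d tested (q < %g)\n",
              x$chrom, nrow(x$calls), nrow(x$tested), x$q_cutoff))
  invisible(x)
}

#' Score interaction strength in a second condition
#'
#' Interactions called in one condition are re-scored with the reads of the
#' other: score = log2((o1/e1 + psi) / (o2/e2 + psi)). Calls are
#' partitioned into stronger-in-1 / stronger-in-2 / unchanged by a
#' symmetric threshold on the score.
#'
#' @param ic An `interaction_calls` object (condition 1).
#' @param cm_other,bg_other Contact matrix and background of condition 2,
#'   on the same binning.
#' @param pseudocount psi added to both observed/expected ratios
#'   (default 0.1).
#' @param threshold Unchanged band half-width on the log2 score
#'   (default log2(1.5)).
#' @return list with `calls` (calls plus `strength_other`, `score`,
#'   `direction`), and index vectors `stronger_in_1`, `stronger_in_2`.
#' @export
score_differential <- function(ic, cm_other, bg_other, pseudocount = 0.1,
                               threshold = log2(1.5)) {
  if (cm_other$n_bins != ic$n_bins || cm_other$bin_size != ic$bin_size) {
    stop("conditions must share binning")
  }
  calls <- ic$calls
  e2 <- expected_matrix(bg_other)
  ij <- cbind(calls$bin1 + 1, calls$bin2 + 1)
  o2 <- cm_other$counts[ij]
  s2 <- o2 / e2[ij]
  score <- log2((calls$strength + pseudocount) / (s2 + pseudocount))
  direction <- cut(score, c(-Inf, -threshold, threshold, Inf),
                   labels = c("stronger_in_2", "unchanged", "stronger_in_1"))
  calls$strength_other <- s2
  calls$score <- score
  calls$direction <- direction
  list(calls = calls,
       stronger_in_1 = which(direction == "stronger_in_1"),
       stronger_in_2 = which(direction == "stronger_in_2"))
}

# which calls have an anchor-bin interval intersecting >= 1 feature
anchor_touches <- function(ic, features) {
  calls <- ic$calls
  gr1 <- window_gr(rep(ic$chrom, nrow(calls)), calls$start1, calls$end1)
  gr2 <- window_gr(rep(ic$chrom, nrow(calls)), calls$start2, calls$end2)
  fg <- ps_granges(features)
  cbind(end1 = overlaps_any(gr1, fg),
        end2 = overlaps_any(gr2, fg))
}

#' Feature-pair enrichment at loop anchors
#'
#' Asks whether loops connect features of set a to features of set b more
#' often than chance, using the called loops as the universe. A loop
#' "touches" a set at an end iff that anchor bin intersects at least one
#' feature. K is the number of loops touching a (either end), n the number
#' touching b, and k the number with one end touching a and the opposite
#' end touching b (either orientation). When a and b are the same set, k
#' requires both ends to touch and the expected count is K*K/N. The p-value
#' is the upper-tail hypergeometric probability from
#' [hypergeometric_overlap()].
#'
#' @param ic An `interaction_calls` object with at least one call.
#' @param features_a,features_b [peak_set] objects.
#' @return list of class `anchor_edge` with `a`, `b`, `N`, `K`, `n`, `k`,
#'   `expected`, `fold`, `p`.
#' @export
anchor_enrichment <- function(ic, features_a, features_b = features_a) {
  if (!nrow(ic$calls)) stop("no interaction calls to test")
  ta <- anchor_touches(ic, features_a)
  same <- identical(features_a, features_b)
  tb <- if (same) ta else anchor_touches(ic, features_b)
  N <- nrow(ic$calls)
  K <- sum(ta[, 1] | ta[, 2])
  n <- sum(tb[, 1] | tb[, 2])
  if (same) {
    k <- sum(ta[, 1] & ta[, 2])
    expected <- K * K / N
  } else {
    k <- sum((ta[, 1] & tb[, 2]) | (ta[, 2] & tb[, 1]))
    expected <- K * n / N
  }
  p <- hypergeometric_overlap(N, K, n, min(k, min(K, n)))$p
  structure(list(a = features_a$name, b = features_b$name,
                 N = N, K = K, n = n, k = k, expected = expected,
                 fold = if (expected > 0) k / expected else NaN, p = p),
            class = "anchor_edge")
}

#' @export
print.anchor_edge <- function(x, ...) {
  cat(sprintf("anchor edge %s -- %s: k=%d (expected %.2f, fold %.2f), p %s\n",
              x$a, x$b, x$k, x$expected, x$fold,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Export anchor-enrichment edges as a network table
#'
#' Writes a TSV loadable by standard network tools (e.g. Cytoscape) with
#' columns source, target, n_loops, k, expected, fold, p and -log10(p)
#' as a line-weight surrogate.
#'
#' @param edges list of `anchor_edge` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_network <- function(edges, path) {
  df <- do.call(rbind, lapply(edges, function(e) {
    data.frame(source = e$a, target = e$b, n_loops = e$N, K = e$K, n = e$n,
               k = e$k, expected = e$expected, fold = e$fold, p = e$p,
               neg_log10_p = -log10(max(e$p, .Machine$double.xmin)))
  }))
  if (is.null(df)) {
    df <- data.frame(source = character(), target = character(),
                     n_loops = integer(), K = integer(), n = integer(),
                     k = integer(), expected = numeric(), fold = numeric(),
                     p = numeric(), neg_log10_p = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network table written by [export_network()]
#' @param path File path.
#' @return data.frame of edges.
#' @export
read_network <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write interaction calls as BEDPE
#'
#' Standard 7+1 column BEDPE: both anchor intervals, a call name, and
#' -log10(q) as the score.
#'
#' @param ic An `interaction_calls` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(ic, path) {
  calls <- ic$calls
  df <- data.frame(
    chrom1 = rep(ic$chrom, nrow(calls)),
    start1 = format_bp(calls$start1), end1 = format_bp(calls$end1),
    chrom2 = rep(ic$chrom, nrow(calls)),
    start2 = format_bp(calls$start2), end2 = format_bp(calls$end2),
    name = sprintf("loop_%d", seq_len(nrow(calls))),
    score = -log10(pmax(calls$q, .Machine$double.xmin))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
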