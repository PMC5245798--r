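# Directionality index, domain calling, boundary-relative metagene
# profiles.

#' Directionality index of a contact matrix
#'
#' For each bin, sums contacts to bins within `window` bins upstream (A)
#' and downstream (B) and computes the signed chi-square-style statistic
#' DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E) with E = (A + B)/2.
#' DI is 0 when A = B or E = 0. Bins closer than `window` to a chromosome
#' edge use truncated windows and are flagged.
#'
#' @param cm A [contact_matrix].
#' @param window Window half-width in bins (default 20, i.e. 500 kb at
#'   25 kb resolution).
#' @return list of class `directionality_track`: `di` (per-bin value),
#'   `truncated` (logical), `window`, plus binning metadata.
#' @export
directionality_index <- function(cm, window = 20L) {
  n <- cm$n_bins
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1 bin")
  if (window >= n) stop("window exceeds the chromosome")
  m <- cm$counts
  di <- numeric(n)
  for (i in seq_len(n)) {
    a <- if (i > 1) sum(m[i, max(1, i - window):(i - 1)]) else 0  # upstream
    b <- if (i < n) sum(m[i, (i + 1):min(n, i + window)]) else 0  # downstream
    e <- (a + b) / 2
    di[i] <- if (e == 0 || a == b) 0 else {
      sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
    }
  }
  structure(list(di = di, truncated = seq_len(n) <= window |
                   seq_len(n) > n - window,
                 window = window, chrom = cm$chrom,
                 bin_size = cm$bin_size, n_bins = n),
            class = "directionality_track")
}

#' Call domains from a directionality track
#'
#' Threshold/run-length state machine: a domain opens at the start of a
#' sustained run (at least `min_run` bins) of DI above `pos_threshold` and
#' closes at the end of the last sustained run of DI below
#' `-neg_threshold` preceding the next domain opening (the downstream-bias
#' stretch of a domain spans its whole second half at fine resolutions and
#' may fragment into several runs). Domains shorter than 3 bins are
#' discarded; the output
#' is non-overlapping by construction. Thresholds default to the 90th
#' percentile of |DI|, which makes the caller invariant to rescaling DI by
#' a positive constant.
#'
#' @param track A `directionality_track`.
#' @param pos_threshold,neg_threshold Positive thresholds on DI; `NULL`
#'   (default) uses the 90th percentile of |DI|.
#' @param min_run Minimum run length in bins (default 3).
#' @return An object of class `domain_set`: data.frame `domains`
#'   (start_bin, end_bin inclusive, start_bp, end_bp) and `boundaries`
#'   (bp positions of both ends of each domain).
#' @export
call_domains <- function(track, pos_threshold = NULL, neg_threshold = NULL,
                         min_run = 3L) {
  di <- track$di
  if (is.null(pos_threshold) || is.null(neg_threshold)) {
    q <- stats::quantile(abs(di[!track$truncated]), 0.9, names = FALSE)
    pos_threshold <- pos_threshold %||% q
    neg_threshold <- neg_threshold %||% q
  }
  if (pos_threshold <= 0 || neg_threshold <= 0) {
    stop("thresholds must be positive")
  }
  cat3 <- ifelse(di > pos_threshold, 1L, ifelse(di < -neg_threshold, -1L, 0L))
  # truncated-window edge bins carry artifactually extreme DI; they can
  # neither open nor close a domain
  cat3[track$truncated] <- 0L
  r <- rle(cat3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dom_start <- integer(0); dom_end <- integer(0)
  open_at <- NA_integer_; close_at <- NA_integer_
  emit <- function() {
    if (!is.na(open_at) && !is.na(close_at) &&
        close_at - open_at + 1L >= 3L) {
      dom_start <<- c(dom_start, open_at)
      dom_end <<- c(dom_end, close_at)
    }
  }
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1L && r$lengths[k] >= min_run) {
      if (is.na(open_at) || !is.na(close_at)) {
        # finalize any pending domain, then open a new one; a positive run
        # with no intervening close continues the current opening stretch
        emit()
        open_at <- starts[k]; close_at <- NA_integer_
      }
    } else if (r$values[k] == -1L && r$lengths[k] >= min_run &&
               !is.na(open_at)) {
      # extend the close through consecutive qualifying negative runs;
      # the domain is finalized when the next domain opens (or at the end)
      close_at <- ends[k]
    }
  }
  emit()
  bs <- track$bin_size
  domains <- data.frame(
    start_bin = dom_start - 1L, end_bin = dom_end - 1L,
    start_bp = (dom_start - 1L) * bs, end_bp = dom_end * bs
  )
  structure(list(chrom = track$chrom, bin_size = bs, domains = domains,
                 boundaries = sort(c(domains$start_bp, domains$end_bp))),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set %s: %d domains (%d bp bins)\n",
              x$chrom, nrow(x$domains), x$bin_size))
  invisible(x)
}

#' Boundary-relative metagene profile
#'
#' Averages feature density over size-normalized domains: each domain
#' contributes four segments - the upstream flank (`metagene_flank` bp),
#' the first and second halves of the domain body (midpoint rounded down),
#' and the downstream flank - each divided into `bins_per_quartile`
#' equal-width bins. Feature midpoints falling in a bin are counted and
#' converted to density per bp, then averaged across domains. The profile
#' has length `4 * bins_per_quartile` (700 by default); the two domain
#' boundaries sit at profile positions `bins_per_quartile` and
#' `3 * bins_per_quartile` (0-based).
#'
#' @param features A [peak_set], or a numeric vector of bp positions on the
#'   domain chromosome.
#' @param domains A `domain_set`.
#' @param params [analysis_params] (`metagene_flank`, `bins_per_quartile`).
#' @return list of class `metagene_profile`: `density` (length 700 by
#'   default), `segment`, `bin_index`, `n_domains`, `n_features_profiled`.
#' @export
metagene_profile <- function(features, domains,
                             params = analysis_params()) {
  if (!nrow(domains$domains)) stop("domain set is empty")
  pos <- if (inherits(features, "peak_set")) {
    peak_midpoints(features)[features$peaks$chrom == domains$chrom]
  } else as.numeric(features)
  B <- params$bins_per_quartile
  fl <- params$metagene_flank
  segs <- c("upstream_flank", "domain_first_half", "domain_second_half",
            "downstream_flank")
  acc <- matrix(0, nrow(domains$domains), 4L * B)
  n_prof <- 0L
  for (di in seq_len(nrow(domains$domains))) {
    s <- domains$domains$start_bp[di]
    e <- domains$domains$end_bp[di]
    mid <- s + floor((e - s) / 2)
    bounds <- rbind(c(s - fl, s), c(s, mid), c(mid, e), c(e, e + fl))
    for (sg in 1:4) {
      lo <- bounds[sg, 1]; hi <- bounds[sg, 2]
      wdt <- (hi - lo) / B
      if (wdt <= 0) next
      x <- pos[pos >= lo & pos < hi]
      n_prof <- n_prof + length(x)
      if (length(x)) {
        bin <- pmin(floor((x - lo) / wdt), B - 1)
        cnt <- tabulate(bin + 1, nbins = B)
        acc[di, ((sg - 1) * B + 1):(sg * B)] <- cnt / wdt
      }
    }
  }
  density <- colMeans(acc)
  structure(list(density = density,
                 segment = rep(segs, each = B),
                 bin_index = rep(seq_len(B) - 1L, 4L),
                 n_domains = nrow(domains$domains),
                 n_features_profiled = n_prof,
                 bins_per_quartile = B),
            class = "metagene_profile")
}

#' Write a domain set as BED
#' @param ds A `domain_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domains_bed <- function(ds, path) {
  df <- ds$domains
  out <- data.frame(rep(ds$chrom, nrow(df)), format_bp(df$start_bp),
                    format_bp(df$end_bp),
                    sprintf("domain_%d", seq_len(nrow(df))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a directionality track as bedGraph
#' @param track A `directionality_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_di_bedgraph <- function(track, path) {
  bs <- track$bin_size
  n <- track$n_bins
  out <- data.frame(rep(track$chrom, n), format_bp((0:(n - 1)) * bs),
                    format_bp((1:n) * bs), track$di)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a metagene profile as TSV
#' @param mp A `metagene_profile`.
#' @param path Output path (columns segment, bin_index, density).
#' @return Invisibly, `path`.
#' @export
write_metagene <- function(mp, path) {
  utils::write.table(
    data.frame(segment = mp$segment, bin_index = mp$bin_index,
               density = mp$density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
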