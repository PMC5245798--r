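# Binned cis contact matrices, the distance-decay background model, and
# cross-condition per-bin correlation.

#' Construct a contact matrix
#'
#' Symmetric binned cis contact counts for one chromosome. The dense matrix
#' representation is practical at the resolutions used here (10-25 kb bins
#' on chromosome-scale sequences).
#'
#' @param counts Symmetric nonnegative square matrix of pair counts.
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param total_pairs Total read pairs (cis + trans) from the source
#'   library, if known.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, bin_size, total_pairs = NA_real_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!isTRUE(all.equal(counts, t(counts)))) stop("counts must be symmetric")
  total_cis <- sum(counts[upper.tri(counts, diag = TRUE)])
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 n_bins = nrow(counts), counts = counts,
                 total_cis_pairs = total_cis, total_pairs = total_pairs),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s: %d bins of %d bp, %s cis pairs\n",
              x$chrom, x$n_bins, x$bin_size, format(x$total_cis_pairs)))
  invisible(x)
}

#' Bin read pairs into contact matrices
#'
#' Builds one symmetric contact matrix per chromosome from a cis-oriented
#' pairs table (`chrom1 pos1 chrom2 pos2`, 0-based positions). Trans pairs
#' are tallied in the summary only.
#'
#' @param pairs A data.frame with columns chrom1, pos1, chrom2, pos2, or a
#'   path to a pairs TSV as written by [write_pairs()].
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric of chromosome lengths in bp.
#' @param dedup Drop exact-duplicate pairs (default FALSE; duplicate removal
#'   normally happens upstream at alignment).
#' @return list with `matrices` (named list of [contact_matrix]) and
#'   `summary` (n_pairs, n_cis, n_trans, cis_fraction).
#' @export
bin_pairs <- function(pairs, bin_size, chrom_sizes, dedup = FALSE) {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns ", paste(need, collapse = ", "))
  }
  if (dedup && nrow(pairs)) {
    pairs <- pairs[!duplicated(pairs[need]), , drop = FALSE]
  }
  unknown <- setdiff(unique(c(pairs$chrom1, pairs$chrom2)),
                     names(chrom_sizes))
  if (length(unknown)) stop("pairs reference unknown chromosomes: ",
                            paste(unknown, collapse = ", "))
  bad <- pairs$pos1 < 0 | pairs$pos2 < 0 |
    pairs$pos1 >= chrom_sizes[pairs$chrom1] |
    pairs$pos2 >= chrom_sizes[pairs$chrom2]
  if (any(bad)) stop("pair positions outside chromosome bounds at rows: ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  is_cis <- pairs$chrom1 == pairs$chrom2
  mats <- list()
  for (ch in names(chrom_sizes)) {
    n <- ceiling(chrom_sizes[[ch]] / bin_size)
    sel <- is_cis & pairs$chrom1 == ch
    m <- matrix(0, n, n)
    if (any(sel)) {
      i <- pairs$pos1[sel] %/% bin_size
      j <- pairs$pos2[sel] %/% bin_size
      lo <- pmin(i, j); hi <- pmax(i, j)
      cnt <- tabulate(lo * n + hi + 1, nbins = n * n)
      low <- matrix(cnt, n, n)      # low[hi+1, lo+1] = count
      m <- low + t(low)
      diag(m) <- diag(low)
    }
    mats[[ch]] <- contact_matrix(m, ch, bin_size, total_pairs = nrow(pairs))
  }
  list(matrices = mats,
       summary = list(n_pairs = nrow(pairs), n_cis = sum(is_cis),
                      n_trans = sum(!is_cis),
                      cis_fraction = if (nrow(pairs)) mean(is_cis) else NaN))
}

# distance -> stratum map: single-bin strata up to `single_max`, then
# geometrically pooled (stable estimates at long range)
distance_strata <- function(n_bins, single_max = 100L, ratio = 1.15) {
  d <- 0:(n_bins - 1)
  s <- integer(n_bins)
  s[d <= single_max] <- d[d <= single_max]
  if (n_bins - 1 > single_max) {
    far <- d[d > single_max]
    s[d > single_max] <- single_max +
      floor(log(far / single_max) / log(ratio)) + 1L
  }
  s + 1L  # 1-based stratum ids
}

#' Fit the distance-decay background model
#'
#' Models the expected contact count of every bin pair as the product of a
#' distance-decay term and two per-bin coverage weights. The decay term
#' f(d) is the mean observed count over pairs at bin distance d (single-bin
#' strata up to `single_max` bin distances, geometrically pooled beyond).
#' The coverage weight of bin i is its observed total divided by the total
#' the decay law predicts for its position, normalized to mean 1 over
#' retained bins; this absorbs mappability and restriction-site
#' accessibility biases while handling chromosome-edge effects exactly.
#' Bins with weight below `coverage_floor` are masked. Expected counts are
#' rescaled within every distance stratum so that the expected total equals
#' the observed total over unmasked pairs (relative error < 1e-6).
#' A per-stratum empirical variance of observed counts is also reported.
#'
#' @param cm A [contact_matrix].
#' @param coverage_floor Mask bins with coverage weight below this fraction
#'   of the mean (default 0.2).
#' @param single_max Largest bin distance given its own stratum
#'   (default 100).
#' @return An object of class `background_model` with elements `f`
#'   (per-distance per-pair expectation), `v` (per-distance variance), `w`
#'   (coverage weights, mean 1 over unmasked bins), `masked`, `scale`
#'   (per-distance stratum rescale), plus binning metadata.
#' @export
fit_background <- function(cm, coverage_floor = 0.2, single_max = 100L) {
  m <- cm$counts
  n <- cm$n_bins
  if (cm$total_cis_pairs <= 0) stop("contact matrix holds no cis pairs")
  drow <- abs(row(m) - col(m))
  up <- row(m) <= col(m)

  # raw decay: mean count per pair at each distance (all pairs)
  obs_d <- vapply(0:(n - 1), function(d) sum(m[up & drow == d]), numeric(1))
  npair_d <- n - (0:(n - 1))
  f0 <- obs_d / npair_d

  # coverage weight: observed bin total over decay-predicted bin total
  tot <- rowSums(m)
  # predicted bin total under the decay law alone (diagonal counted once,
  # matching rowSums of the symmetric matrix)
  pred <- vapply(seq_len(n), function(i) {
    sum(f0[abs(seq_len(n) - i) + 1])
  }, numeric(1))
  w <- ifelse(pred > 0, tot / pred, 0)
  masked <- w < coverage_floor * mean(w[w > 0])
  if (all(masked)) stop("all bins masked by the coverage floor")
  w <- w / mean(w[!masked])

  strata <- distance_strata(n, single_max = single_max)
  sid <- strata[drow + 1]
  ok <- up & !masked[row(m)] & !masked[col(m)]

  # per-stratum mean and variance over unmasked pairs
  ns <- max(strata)
  s_obs <- vapply(seq_len(ns), function(s) sum(m[ok & sid == s]), numeric(1))
  s_n <- vapply(seq_len(ns), function(s) sum(ok & sid == s), numeric(1))
  s_f <- ifelse(s_n > 0, s_obs / s_n, 0)
  s_v <- vapply(seq_len(ns), function(s) {
    x <- m[ok & sid == s]
    if (length(x) > 1) stats::var(x) else 0
  }, numeric(1))

  # stratum rescale enforcing sum(expected) == sum(observed) per stratum
  ww <- outer(w, w)
  s_wsum <- vapply(seq_len(ns), function(s) sum(ww[ok & sid == s]),
                   numeric(1))
  s_scale <- ifelse(s_f * s_wsum > 0, s_obs / (s_f * s_wsum), 0)

  f_by_d <- s_f[strata]
  v_by_d <- s_v[strata]
  scale_by_d <- s_scale[strata]
  structure(list(chrom = cm$chrom, bin_size = cm$bin_size, n_bins = n,
                 f = f_by_d, v = v_by_d, w = w, masked = masked,
                 scale = scale_by_d, strata = strata,
                 total_cis_pairs = cm$total_cis_pairs),
            class = "background_model")
}

#' Expected contact counts under a background model
#'
#' @param bg A `background_model` from [fit_background()].
#' @return Dense matrix of expected counts; masked rows/columns are `NA`.
#' @export
expected_matrix <- function(bg) {
  n <- bg$n_bins
  g <- bg$f * bg$scale
  d <- abs(row(diag(n)) - col(diag(n)))
  e <- matrix(g[d + 1], n, n) * outer(bg$w, bg$w)
  e[bg$masked, ] <- NA_real_
  e[, bg$masked] <- NA_real_
  e
}

#' Per-bin cross-condition correlation
#'
#' For each bin, correlates its observed/expected contact profile (against
#' all bins within `max_distance`) between two conditions. Bins masked in
#' either background, or with fewer than `min_points` finite profile
#' entries, are flagged invalid.
#'
#' @param cm_a,cm_b [contact_matrix] objects on the same binning.
#' @param bg_a,bg_b Matching `background_model`s.
#' @param max_distance Profile half-width in bins (default 100).
#' @param params [analysis_params]; supplies `correlation_cutoff`.
#' @param min_points Minimum profile entries for a valid correlation
#'   (default 10).
#' @return list with `r` (per-bin Pearson r), `valid`, and `n_below`
#'   (valid bins with r below the cutoff).
#' @export
condition_correlation <- function(cm_a, cm_b, bg_a, bg_b,
                                  max_distance = 100L,
                                  params = analysis_params(),
                                  min_points = 10L) {
  if (cm_a$n_bins != cm_b$n_bins || cm_a$bin_size != cm_b$bin_size ||
      cm_a$chrom != cm_b$chrom) {
    stop("contact matrices must share chromosome and binning")
  }
  n <- cm_a$n_bins
  ea <- expected_matrix(bg_a); eb <- expected_matrix(bg_b)
  oa <- cm_a$counts / ea; ob <- cm_b$counts / eb
  r <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (bg_a$masked[i] || bg_b$masked[i]) next
    j <- max(1, i - max_distance):min(n, i + max_distance)
    j <- j[j != i]
    x <- oa[i, j]; y <- ob[i, j]
    use <- is.finite(x) & is.finite(y)
    if (sum(use) < min_points) next
    if (stats::sd(x[use]) == 0 || stats::sd(y[use]) == 0) next
    r[i] <- stats::cor(x[use], y[use])
    valid[i] <- TRUE
  }
  list(r = r, valid = valid,
       n_below = sum(valid & r < params$correlation_cutoff))
}

#' Read a pairs file
#'
#' Cis-oriented pairs dialect: tab-separated `chrom1 pos1 chrom2 pos2`,
#' `#`-prefixed header lines. Malformed lines raise an error naming the
#' line number.
#'
#' @param path File path.
#' @return data.frame with columns chrom1, pos1, chrom2, pos2.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (!length(body_idx)) {
    return(data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric()))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    stop("malformed pair line(s) at: ",
         paste(utils::head(body_idx[nf != 4], 5), collapse = ", "))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 2]))
  pos2 <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(pos1) || anyNA(pos2)) {
    stop("non-numeric position at line(s): ",
         paste(utils::head(body_idx[is.na(pos1) | is.na(pos2)], 5),
               collapse = ", "))
  }
  data.frame(chrom1 = m[, 1], pos1 = pos1, chrom2 = m[, 3], pos2 = pos2,
             stringsAsFactors = FALSE)
}

#' Write a pairs file
#' @param pairs data.frame with chrom1, pos1, chrom2, pos2.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom1\tpos1\tchrom2\tpos2", con)
  if (nrow(pairs)) {
    utils::write.table(
      data.frame(pairs$chrom1, format_bp(pairs$pos1),
                 pairs$chrom2, format_bp(pairs$pos2)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a contact matrix as sparse triples
#'
#' Upper-triangle `bin1 bin2 count` TSV plus a JSON sidecar
#' (`<path>.json`) holding chrom, bin_size, n_bins and totals.
#'
#' @param cm A [contact_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_matrix <- function(cm, path) {
  up <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0,
              arr.ind = TRUE)
  df <- data.frame(bin1 = up[, 1] - 1, bin2 = up[, 2] - 1,
                   count = cm$counts[up])
  df <- df[order(df$bin1, df$bin2), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(chrom = cm$chrom, bin_size = cm$bin_size, n_bins = cm$n_bins,
         total_cis_pairs = cm$total_cis_pairs,
         total_pairs = cm$total_pairs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sparse contact matrix written by [write_contact_matrix()]
#' @param path Path to the triple TSV (sidecar `<path>.json` required).
#' @return A [contact_matrix].
#' @export
read_contact_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- meta$n_bins
  m <- matrix(0, n, n)
  m[cbind(df$bin1 + 1, df$bin2 + 1)] <- df$count
  m[cbind(df$bin2 + 1, df$bin1 + 1)] <- df$count
  contact_matrix(m, meta$chrom, meta$bin_size,
                 total_pairs = meta$total_pairs %||% NA_real_)
}

#' Write a background model's decay table
#' @param bg A `background_model`.
#' @param path Output path (TSV: distance_bins, f, v).
#' @return Invisibly, `path`.
#' @export
write_background <- function(bg, path) {
  utils::write.table(
    data.frame(distance_bins = 0:(bg$n_bins - 1), f = bg$f, v = bg$v),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
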