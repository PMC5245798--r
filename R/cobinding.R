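# Co-binding statistics: permutation nulls over the open-chromatin
# universe, hypergeometric overlap, knockdown fold-change classes.

new_null_distribution <- function(samples, observed, seed = NA_integer_) {
  n <- length(samples)
  structure(list(
    n_iter = n,
    samples = samples,
    mean = mean(samples),
    sd = stats::sd(samples),
    observed = observed,
    empirical_p = (1 + sum(samples >= observed)) / (n + 1),
    seed = seed
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "permutation null: observed %s vs null mean %.2f (SD %.2f), p %s (n_iter %d)\n",
    format(x$observed), x$mean, x$sd,
    format.pval(x$empirical_p, digits = 3), x$n_iter))
  invisible(x)
}

#' Open-chromatin permutation null for peak co-occurrence
#'
#' Tests whether two factors share open-chromatin sites more often than
#' chance, given that binding is confined to open chromatin. Each iteration
#' independently draws `n_a` and `n_b` whole sites without replacement from
#' the open-chromatin universe and records the number of sites present in
#' both draws. The empirical p-value uses the (r+1)/(n+1) estimator, so it
#' is never exactly zero; at 1,000 iterations the smallest reportable value
#' is just under 0.001.
#'
#' @param open_sites A [peak_set] (or a single count) giving the
#'   open-chromatin universe; only its size enters the null.
#' @param n_a,n_b Number of sites bound by each factor.
#' @param observed Observed number of co-bound sites.
#' @param n_iter Number of iterations (default 1000).
#' @param seed RNG seed (default 1007, recorded in the result).
#' @return A `null_distribution` with fields `n_iter`, `samples`, `mean`,
#'   `sd`, `observed`, `empirical_p`.
#' @export
open_chromatin_permutation <- function(open_sites, n_a, n_b, observed,
                                       n_iter = 1000L, seed = 1007L) {
  N <- if (inherits(open_sites, "peak_set")) nrow(open_sites$peaks)
       else as.integer(open_sites)
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  if (n_a > N || n_b > N) {
    stop(sprintf("draw sizes (%d, %d) exceed the open-chromatin universe (%d)",
                 n_a, n_b, N))
  }
  samples <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      in_a <- logical(N)
      in_a[sample.int(N, n_a)] <- TRUE
      sum(in_a[sample.int(N, n_b)])
    }, integer(1))
  })
  new_null_distribution(samples, observed, seed = as.integer(seed))
}

#' Promoter-preference permutation null
#'
#' Asks whether an observed subset of peaks (e.g. the co-bound ones) sits at
#' promoters more often than a random subset of the same size would. Each
#' iteration draws `ceiling(k/2)` peaks from set a and `floor(k/2)` from set
#' b without replacement and counts how many of the drawn peaks are
#' classified as promoter by [annotate_peaks()].
#'
#' @param peaks_a,peaks_b [peak_set] objects (the two factors' full peak
#'   sets).
#' @param k Size of the null draw (typically the co-bound count).
#' @param observed Observed promoter count of the tested subset.
#' @param genes [gene_annotation].
#' @param params [analysis_params].
#' @param n_iter Iterations (default `params$n_permutations`).
#' @param seed RNG seed.
#' @return A `null_distribution`.
#' @export
promoter_preference_permutation <- function(peaks_a, peaks_b, k, observed,
                                            genes,
                                            params = analysis_params(),
                                            n_iter = params$n_permutations,
                                            seed = 1007L) {
  ka <- as.integer(ceiling(k / 2)); kb <- as.integer(floor(k / 2))
  na <- nrow(peaks_a$peaks); nb <- nrow(peaks_b$peaks)
  if (ka > na || kb > nb) {
    stop(sprintf("draw of %d + %d exceeds set sizes %d + %d", ka, kb, na, nb))
  }
  prom_a <- annotate_peaks(peaks_a, genes, params)$class == "promoter"
  prom_b <- annotate_peaks(peaks_b, genes, params)$class == "promoter"
  samples <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      sum(prom_a[sample.int(na, ka)]) + sum(prom_b[sample.int(nb, kb)])
    }, integer(1))
  })
  new_null_distribution(samples, observed, seed = as.integer(seed))
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability that two subsets of sizes `n_a` and `n_b`, drawn
#' from a universe of `N` elements, share at least `k` elements:
#' P(X >= k) for X ~ Hypergeometric(N, n_a, n_b). Computed on the log scale
#' via the stable cumulative distribution, valid for universes up to 1e7.
#'
#' @param N Universe size.
#' @param n_a,n_b Subset sizes.
#' @param k Observed overlap.
#' @return list of class `overlap_test` with `N`, `n_a`, `n_b`, `k`,
#'   `expected` (= n_a n_b / N), `fold` (= k / expected), `p`.
#' @export
hypergeometric_overlap <- function(N, n_a, n_b, k) {
  N <- as.numeric(N); n_a <- as.numeric(n_a); n_b <- as.numeric(n_b)
  k <- as.numeric(k)
  if (n_a > N || n_b > N) stop("subset sizes must not exceed the universe")
  if (k > min(n_a, n_b)) stop("overlap k cannot exceed min(n_a, n_b)")
  # k below the feasible minimum max(0, n_a + n_b - N) simply yields p = 1
  # P(X >= k) with X ~ Hyper(m = n_a, n = N - n_a, k = n_b)
  p <- if (k <= 0) 1 else {
    stats::phyper(k - 1, m = n_a, n = N - n_a, k = n_b, lower.tail = FALSE)
  }
  expected <- n_a * n_b / N
  structure(list(N = N, n_a = n_a, n_b = n_b, k = k, expected = expected,
                 fold = if (expected > 0) k / expected else NaN,
                 p = min(max(p, 0), 1)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "hypergeometric overlap: k=%g of (n_a=%g, n_b=%g) in N=%g; expected %.2f, fold %.2f, p %s\n",
    x$k, x$n_a, x$n_b, x$N, x$expected, x$fold,
    format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Classify knockdown response of peaks
#'
#' Scales control and knockdown tag counts to a common depth
#' (`params$norm_depth`, by default 10 million mapped tags), computes the
#' per-peak fold reduction control/knockdown with a pseudocount of one
#' scaled tag in the denominator, and counts peaks in the nested classes
#' at the configured thresholds (by default >= 3-fold and >= 10-fold
#' reduced).
#'
#' @param peaks A [peak_set] whose `tags` has columns `control` and
#'   `knockdown` and whose `library_total` names both conditions.
#' @param params [analysis_params].
#' @return list with `fold` (per-peak normalized fold change, aligned with
#'   `peaks$peaks`), `class` (factor: `ge10`, `ge3`, `other`; classes are
#'   nested so `ge10` peaks also count toward `n_ge3`), and counts `n`,
#'   `n_ge3`, `n_ge10`.
#' @export
knockdown_response <- function(peaks, params = analysis_params()) {
  if (is.null(peaks$tags) ||
      !all(c("control", "knockdown") %in% colnames(peaks$tags))) {
    stop("peak set must carry 'control' and 'knockdown' tag columns")
  }
  lt <- peaks$library_total
  if (is.null(lt) || !all(c("control", "knockdown") %in% names(lt)) ||
      any(lt[c("control", "knockdown")] <= 0)) {
    stop("positive library totals required for both conditions")
  }
  sc_ctrl <- peaks$tags$control * params$norm_depth / lt[["control"]]
  sc_kd <- peaks$tags$knockdown * params$norm_depth / lt[["knockdown"]]
  # pseudocount of one tag on the normalized scale keeps classes invariant
  # to jointly rescaling tags and library totals
  fold <- sc_ctrl / pmax(sc_kd, 1)
  th <- params$fold_thresholds
  cls <- cut(fold, breaks = c(-Inf, th, Inf), right = FALSE,
             labels = c("other", paste0("ge", th)))
  list(fold = fold,
       class = cls,
       n = length(fold),
       n_ge3 = sum(fold >= th[1]),
       n_ge10 = sum(fold >= th[2]))
}
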