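test_that("hypergeometric_overlap matches direct enumeration", {
  # worked instance: N=10, n_a=4, n_b=5, k=3 -> 66/252
  res <- hypergeometric_overlap(10, 4, 5, 3)
  expect_equal(res$p, 66 / 252, tolerance = 1e-14)
  expect_equal(res$p, hyper_tail_enum(10, 4, 5, 3), tolerance = 1e-14)
  expect_equal(res$expected, 2)
  expect_equal(res$fold, 1.5)

  # full subset enumeration on small universes
  for (N in c(6, 9, 12)) {
    for (na in c(2, N %/% 2)) {
      for (nb in c(3, N %/% 2)) {
        for (k in 0:min(na, nb)) {
          expect_equal(hypergeometric_overlap(N, na, nb, k)$p,
                       hyper_tail_enum(N, na, nb, k), tolerance = 1e-12,
                       label = sprintf("enum N=%d na=%d nb=%d k=%d",
                                       N, na, nb, k))
        }
      }
    }
  }

  # direct-summation oracle across all instances with N <= 25
  worst <- 0
  for (N in 2:25) {
    for (na in 1:N) {
      for (nb in 1:N) {
        for (k in 0:min(na, nb)) {
          d <- abs(hypergeometric_overlap(N, na, nb, k)$p -
                     hyper_tail_oracle(N, na, nb, k))
          worst <- max(worst, d)
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("hypergeometric_overlap edge cases and validation", {
  expect_equal(hypergeometric_overlap(100, 10, 20, 0)$p, 1)
  # saturated marginal: n_a = N forces k = n_b
  sat <- hypergeometric_overlap(50, 50, 12, 12)
  expect_equal(sat$p, 1)
  expect_error(hypergeometric_overlap(10, 11, 5, 2), "exceed")
  expect_error(hypergeometric_overlap(10, 4, 5, 5), "exceed")
  # numerically stable at large N
  big <- hypergeometric_overlap(1e7, 2e4, 3e4, 200)
  expect_gt(big$p, 0)
  expect_lt(big$p, 1e-20)
})

test_that("open_chromatin_permutation matches the exact expectation", {
  # universe of 6, draws of 2 and 3: E[overlap] = 2*3/6 = 1 exactly,
  # verified against complete enumeration of all C(6,2) x C(6,3) draw pairs
  pairs_a <- utils::combn(6, 2)
  pairs_b <- utils::combn(6, 3)
  exact <- mean(apply(pairs_a, 2, function(a) {
    apply(pairs_b, 2, function(b) length(intersect(a, b)))
  }))
  expect_equal(exact, 1.0)
  nd <- open_chromatin_permutation(6, 2, 3, observed = 3, n_iter = 2000,
                                   seed = 11)
  se <- nd$sd / sqrt(nd$n_iter)
  expect_lt(abs(nd$mean - exact), 3 * se)
  expect_equal(nd$n_iter, 2000)
  expect_true(nd$empirical_p > 0 && nd$empirical_p <= 1)
})

test_that("permutation mean converges to n_a*n_b/N on a 100-site universe", {
  nd <- open_chromatin_permutation(100, 30, 40, observed = 20,
                                   n_iter = 5000, seed = 7)
  se <- nd$sd / sqrt(nd$n_iter)
  expect_lt(abs(nd$mean - 30 * 40 / 100), 3 * se)
})

test_that("open_chromatin_permutation edge and error cases", {
  nd <- open_chromatin_permutation(10, 0, 5, observed = 0, n_iter = 100,
                                   seed = 1)
  expect_equal(nd$mean, 0)
  expect_equal(nd$sd, 0)
  expect_equal(nd$empirical_p, 1)
  expect_error(open_chromatin_permutation(10, 11, 5, 0), "exceed")
  # reproducible under the same seed
  a <- open_chromatin_permutation(50, 10, 10, 3, n_iter = 50, seed = 5)
  b <- open_chromatin_permutation(50, 10, 10, 3, n_iter = 50, seed = 5)
  expect_identical(a$samples, b$samples)
})

test_that("promoter_preference_permutation matches the closed form", {
  set.seed(99)
  genes <- random_genes(20, chroms = "chr1", L = 2e6)
  # build two sets with known promoter composition: a = 12/20 at
  # promoters, b = 4/20
  mk <- function(n_prom, n_other, name, seed) {
    set.seed(seed)
    gsel <- sample(nrow(genes), n_prom)
    start <- c(genes$tss_bp[gsel] - 100,
               sample(seq(1e6, 1.9e6, by = 5000), n_other))
    peak_set("chr1", start, start + 200, name = name)
  }
  a <- mk(12, 8, "a", 1)
  b <- mk(4, 16, "b", 2)
  p <- analysis_params()
  f_a <- mean(annotate_peaks(a, genes, p)$class == "promoter")
  f_b <- mean(annotate_peaks(b, genes, p)$class == "promoter")
  k <- 10
  nd <- promoter_preference_permutation(a, b, k, observed = 9, genes, p,
                                        n_iter = 3000, seed = 3)
  closed <- (k / 2) * (f_a + f_b)
  se <- nd$sd / sqrt(nd$n_iter)
  expect_lt(abs(nd$mean - closed), 3 * se)
})

test_that("promoter null degenerates when everything is a promoter", {
  genes <- toy_genes()
  a <- peak_set("chr1", c(9900, 9950), c(10100, 10150), name = "a")
  b <- peak_set("chr1", c(49900, 49950), c(50100, 50150), name = "b")
  nd <- promoter_preference_permutation(a, b, 4, observed = 4, genes,
                                        n_iter = 50, seed = 1)
  expect_equal(nd$mean, 4)
  expect_equal(nd$sd, 0)
  expect_error(
    promoter_preference_permutation(a, b, 10, observed = 1, genes,
                                    n_iter = 10, seed = 1),
    "exceeds")
})

test_that("knockdown_response normalizes, classifies, and is scale-invariant", {
  mk_ps <- function(ctrl, kd, lt_c, lt_k) {
    n <- length(ctrl)
    peak_set("chr1", seq(1000, by = 1000, length.out = n) ,
             seq(1200, by = 1000, length.out = n),
             name = "f", tags = data.frame(control = ctrl, knockdown = kd),
             library_total = c(control = lt_c, knockdown = lt_k))
  }
  # equal totals, equal tags -> fold 1, no reduced classes
  r <- knockdown_response(mk_ps(c(50, 80), c(50, 80), 1e7, 1e7))
  expect_equal(r$fold, c(1, 1))
  expect_equal(r$n_ge3, 0)
  # normalization arithmetic: totals 5M vs 20M, tags 100 vs 100
  # -> scaled 200 vs 50, fold 4
  r2 <- knockdown_response(mk_ps(100, 100, 5e6, 2e7))
  expect_equal(r2$fold, 4)
  expect_equal(r2$n_ge3, 1)
  expect_equal(r2$n_ge10, 0)
  expect_equal(as.character(r2$class), "ge3")
  # nested classes
  r3 <- knockdown_response(mk_ps(c(100, 100, 100), c(100, 30, 5), 1e7, 1e7))
  expect_equal(r3$n_ge3, 2)
  expect_equal(r3$n_ge10, 1)
  # invariance to joint rescaling of tags and totals
  r4 <- knockdown_response(mk_ps(c(700, 700, 700), c(700, 210, 35),
                                 7e7, 7e7))
  expect_equal(r4$n_ge3, r3$n_ge3)
  expect_equal(r4$n_ge10, r3$n_ge10)
  expect_error(knockdown_response(mk_ps(1, 1, 0, 1e7)), "positive")
  ps_no <- peak_set("chr1", 1, 100, name = "x")
  expect_error(knockdown_response(ps_no), "tag")
})

test_that("empirical p under a neutral generator is approximately uniform", {
  # small-scale version of the calibration criterion (full version in the
  # acceptance suite): 40 neutral replicates should not produce a grossly
  # non-uniform p distribution
  ps <- replicate(40, NA_real_)
  for (r in seq_len(40)) {
    cfg <- simulation_config(
      seed = 5000 + r, n_genes = 40, n_open_sites = 300,
      chrom_length = 5e6, bin_size = 25000,
      factors = list(list(name = "A", n_peaks = 80, promoter_fraction = 0.5),
                     list(name = "B", n_peaks = 80, promoter_fraction = 0.5)),
      cobinding_rate = NA, depth = 0)
    reg <- simulate_regulatory_genome(cfg)
    obs <- length(reg$truth$cobound_sites)
    nd <- open_chromatin_permutation(reg$open_sites, 80, 80, obs,
                                     n_iter = 200, seed = 600 + r)
    ps[r] <- nd$empirical_p
  }
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_lt(sum(ps < 0.05), 8)
})
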