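test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(chrom_length = 1e6 + 1, bin_size = 25000),
               "divide")
  expect_error(simulation_config(cobinding_rate = 1.2), "0, 1")
  expect_error(simulation_config(depth = -1), "depth")
  expect_error(simulation_config(knockdown_fold = 0.5), "knockdown_fold")
  expect_error(simulation_config(
    tad_layout = list(list(start = 1e6, end = 3e7, enrichment = 2))),
    "bounds")
  expect_error(simulation_config(
    loops = list(list(anchor1 = 5e6, anchor2 = 1e6,
                      intensity1 = 1, intensity2 = 1))),
    "unordered")
})

test_that("regulatory genome is deterministic and respects its contract", {
  cfg <- simulation_config(seed = 101, depth = 0)
  r1 <- simulate_regulatory_genome(cfg)
  r2 <- simulate_regulatory_genome(cfg)
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$factors$factorA$peaks, r2$factors$factorA$peaks)
  expect_identical(r1$truth, r2$truth)
  # unique TSSs
  expect_false(any(duplicated(paste(r1$genes$chrom, r1$genes$tss_bp))))
  # every peak lies inside an open-chromatin site
  for (nm in names(r1$factors)) {
    ov <- overlap_peak_sets(r1$factors[[nm]], r1$open_sites)
    within <- GenomicRanges::countOverlaps(
      ps_gr <- tfloops:::ps_granges(r1$factors[[nm]]),
      tfloops:::ps_granges(r1$open_sites), type = "within")
    expect_true(all(within >= 1))
  }
  # different seed, different draw
  r3 <- simulate_regulatory_genome(simulation_config(seed = 102, depth = 0))
  expect_false(identical(r1$genes$tss_bp, r3$genes$tss_bp))
})

test_that("cobinding_rate controls shared sites", {
  cfg0 <- simulation_config(seed = 103, cobinding_rate = 0, depth = 0)
  r0 <- simulate_regulatory_genome(cfg0)
  expect_length(r0$truth$cobound_sites, 0)
  # shared fraction at rate 0.4 with 500 peaks each falls in the exact
  # binomial 99% interval
  cfg4 <- simulation_config(
    seed = 104, n_genes = 600, n_open_sites = 1500,
    factors = list(list(name = "A", n_peaks = 500, promoter_fraction = 0.5),
                   list(name = "B", n_peaks = 500, promoter_fraction = 0.5)),
    cobinding_rate = 0.4, depth = 0)
  r4 <- simulate_regulatory_genome(cfg4)
  shared <- length(r4$truth$cobound_sites)
  lo <- qbinom(0.005, 500, 0.4); hi <- qbinom(0.995, 500, 0.4)
  expect_gte(shared, lo)
  expect_lte(shared, hi)
  # truth is recoverable from the emitted artifacts by direct lookup:
  # assign each peak to the open-chromatin site containing it and
  # intersect the two factors' site sets (co-binding is site sharing;
  # promoter-placed peaks of the two factors need not overlap in bp)
  site_of <- function(ps) {
    hits <- GenomicRanges::findOverlaps(
      tfloops:::ps_granges(ps), tfloops:::ps_granges(r4$open_sites),
      type = "within", select = "first")
    r4$open_sites$peaks$id[hits]
  }
  shared_rec <- intersect(site_of(r4$factors$A), site_of(r4$factors$B))
  expect_setequal(shared_rec, r4$truth$cobound_sites)
})

test_that("knockdown classifier round-trips the planted peaks exactly", {
  cfg <- simulation_config(seed = 105, cobinding_rate = 0.3,
                           knockdown_fold = 3, depth = 0)
  reg <- simulate_regulatory_genome(cfg)
  res <- knockdown_response(reg$factors$factorA)
  affected <- reg$factors$factorA$peaks$id[res$fold >= 3]
  expect_setequal(affected, reg$truth$knockdown_affected)
  expect_equal(res$n_ge3, length(reg$truth$knockdown_affected))
  expect_equal(res$n_ge10, 0)
  # at 10-fold the same planted set classifies at the higher threshold
  cfg10 <- simulation_config(seed = 105, cobinding_rate = 0.3,
                             knockdown_fold = 10, depth = 0)
  reg10 <- simulate_regulatory_genome(cfg10)
  res10 <- knockdown_response(reg10$factors$factorA)
  expect_equal(res10$n_ge10, length(reg10$truth$knockdown_affected))
})

test_that("generator errors name the offending counts", {
  expect_error(
    simulate_regulatory_genome(simulation_config(n_open_sites = 100,
                                                 n_genes = 200)),
    "100.*200|200.*100")
  cfg_big <- simulation_config(
    n_genes = 50, n_open_sites = 100,
    factors = list(list(name = "A", n_peaks = 150,
                        promoter_fraction = 0.5)))
  expect_error(simulate_regulatory_genome(cfg_big), "150")
})

test_that("contact reads are deterministic, cis-only, and respect depth", {
  cfg <- simulation_config(seed = 106, chrom_length = 2e6, depth = 5000)
  c1 <- simulate_contact_reads(cfg)
  c2 <- simulate_contact_reads(cfg)
  expect_identical(c1$pairs, c2$pairs)
  pr <- c1$pairs$condition1
  expect_equal(nrow(pr), 5000)
  expect_true(all(pr$chrom1 == pr$chrom2))
  expect_true(all(pr$pos1 >= 0 & pr$pos1 < 2e6))
  # depth 0 -> empty frame, header-only file
  c0 <- simulate_contact_reads(simulation_config(seed = 1, depth = 0))
  expect_equal(nrow(c0$pairs$condition1), 0)
  f <- withr::local_tempfile()
  write_pairs(c0$pairs$condition1, f)
  expect_equal(readLines(f), "#chrom1\tpos1\tchrom2\tpos2")
  expect_error(
    simulate_contact_reads(simulation_config(n_chroms = 0, depth = 10)),
    "chromosome")
})

test_that("fitted decay slope matches the configured exponent", {
  cfg <- simulation_config(seed = 107, decay_exponent = 1.0, depth = 1e6)
  ct <- simulate_contact_reads(cfg, conditions = 1)
  cm <- bin_pairs(ct$pairs$condition1, cfg$bin_size,
                  ct$chrom_sizes)$matrices$chr1
  bg <- fit_background(cm)
  d <- 5:50
  slope <- unname(coef(lm(log(bg$f[d + 1]) ~ log(d)))[2])
  expect_lt(abs(slope - (-1.0)), 0.1)
})

test_that("a planted loop is visible over the fitted background", {
  cfg <- simulation_config(
    seed = 108, depth = 1e6,
    loops = list(list(anchor1 = 8e6, anchor2 = 9e6,
                      intensity1 = 5, intensity2 = 1)))
  ct <- simulate_contact_reads(cfg)
  lt <- ct$truth$loops[[1]]
  for (cond in c("condition1", "condition2")) {
    cm <- bin_pairs(ct$pairs[[cond]], cfg$bin_size,
                    ct$chrom_sizes)$matrices$chr1
    e <- expected_matrix(fit_background(cm))
    ratio <- cm$counts[lt$bin1 + 1, lt$bin2 + 1] /
      e[lt$bin1 + 1, lt$bin2 + 1]
    if (cond == "condition1") expect_gte(ratio, 2.5) else {
      expect_lt(ratio, 2.5)
    }
  }
})

test_that("write_simulation emits all artifacts with recoverable truth", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(
    seed = 109, chrom_length = 2e6, n_genes = 20, n_open_sites = 60,
    factors = list(list(name = "A", n_peaks = 20, promoter_fraction = 0.5),
                   list(name = "B", n_peaks = 20, promoter_fraction = 0.5)),
    depth = 2000,
    tad_layout = list(list(start = 5e5, end = 1e6, enrichment = 3)))
  reg <- simulate_regulatory_genome(cfg)
  ct <- simulate_contact_reads(cfg)
  write_simulation(reg, ct, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genes.tsv", "open_sites.bed", "A.bed", "A_tags.tsv",
           "pairs_condition1.tsv", "pairs_condition2.tsv", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$cobound_sites, reg$truth$cobound_sites)
  # emitted records can be reloaded and match the in-memory objects
  back <- read_bed(file.path(dir, "A.bed"), name = "A")
  expect_equal(back$peaks$start, reg$factors$A$peaks$start)
  tg <- read_peak_tags(file.path(dir, "A_tags.tsv"))
  expect_equal(tg$tags$control, reg$factors$A$tags$control)
  expect_equal(tg$library_total[["control"]], 1e7)
  pr <- read_pairs(file.path(dir, "pairs_condition1.tsv"))
  expect_equal(nrow(pr), 2000)
  # byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  write_simulation(simulate_regulatory_genome(cfg),
                   simulate_contact_reads(cfg), dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
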