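# Synthetic regulatory-genome and contact-read generator with planted
# ground truth. Every downstream statistic in the package can be exercised
# against data whose co-binding, knockdown response, domains and loops are
# known exactly.

#' Simulation configuration
#'
#' Describes a synthetic genome: chromosome layout, gene and open-chromatin
#' site counts, per-factor peak sets with a controllable co-binding rate
#' and promoter preference, a knockdown tag-reduction factor, and a cis
#' contact model with power-law distance decay, planted self-interacting
#' domains and planted loops. One RNG stream per output artifact is derived
#' from the master seed, so adding artifacts never perturbs existing ones.
#'
#' @param seed Master RNG seed.
#' @param n_chroms Number of chromosomes (planted domains/loops go on the
#'   first).
#' @param chrom_length Chromosome length in bp; must be a multiple of
#'   `bin_size`.
#' @param bin_size Contact-map bin size in bp.
#' @param n_genes Total genes (distributed evenly across chromosomes).
#' @param n_open_sites Open-chromatin universe size; must be at least
#'   `n_genes` (one promoter site per gene, the rest distal).
#' @param factors List of factors, each `list(name, n_peaks,
#'   promoter_fraction)`. Co-binding couples the first two.
#' @param cobinding_rate Probability that a peak of the second factor is
#'   placed onto a site occupied by the first. `NA` requests neutral
#'   placement: the second factor's sites are drawn uniformly from the
#'   whole universe (ignoring `promoter_fraction`), the no-structure null
#'   whose overlap follows the hypergeometric chance level.
#' @param knockdown_fold Tag reduction (integer division) applied to the
#'   first factor's co-bound peaks in the knockdown condition.
#' @param decay_exponent Power-law slope of contact probability vs bin
#'   distance (1.0 is the usual polymer-like convention).
#' @param tad_layout List of planted domains `list(start, end, enrichment)`
#'   in bp (first chromosome).
#' @param loops List of planted loops `list(anchor1, anchor2, intensity1,
#'   intensity2)` in bp with per-condition intensity multipliers.
#' @param depth Read pairs per condition.
#' @param peak_width Fixed peak width in bp (default 200).
#' @param open_site_width Distal open-chromatin site width in bp
#'   (default 1000).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 1L,
                              chrom_length = 2e7,
                              bin_size = 25000L,
                              n_genes = 200L,
                              n_open_sites = 1000L,
                              factors = list(
                                list(name = "factorA", n_peaks = 300L,
                                     promoter_fraction = 0.5),
                                list(name = "factorB", n_peaks = 300L,
                                     promoter_fraction = 0.5)),
                              cobinding_rate = 0.3,
                              knockdown_fold = 3,
                              tad_layout = list(),
                              loops = list(),
                              decay_exponent = 1.0,
                              depth = 1e6,
                              peak_width = 200L,
                              open_site_width = 1000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              bin_size = as.integer(bin_size),
              n_genes = as.integer(n_genes),
              n_open_sites = as.integer(n_open_sites),
              factors = factors, cobinding_rate = as.numeric(cobinding_rate),
              knockdown_fold = as.numeric(knockdown_fold),
              tad_layout = tad_layout, loops = loops,
              decay_exponent = as.numeric(decay_exponent),
              depth = as.numeric(depth),
              peak_width = as.integer(peak_width),
              open_site_width = as.integer(open_site_width))
  if (cfg$chrom_length %% cfg$bin_size != 0) {
    stop("bin_size must divide chrom_length")
  }
  if (!is.na(cfg$cobinding_rate) &&
      (cfg$cobinding_rate < 0 || cfg$cobinding_rate > 1)) {
    stop("cobinding_rate must be in [0, 1] (or NA for neutral placement)")
  }
  for (f in cfg$factors) {
    if (f$promoter_fraction < 0 || f$promoter_fraction > 1) {
      stop("promoter_fraction must be in [0, 1]")
    }
  }
  if (cfg$depth < 0) stop("depth must be >= 0")
  if (cfg$knockdown_fold < 1) stop("knockdown_fold must be >= 1")
  if (cfg$decay_exponent <= 0) stop("decay_exponent must be positive")
  for (td in cfg$tad_layout) {
    if (td$start < 0 || td$end > cfg$chrom_length || td$start >= td$end) {
      stop("planted domain outside chromosome bounds")
    }
  }
  for (lp in cfg$loops) {
    if (lp$anchor1 < 0 || lp$anchor2 >= cfg$chrom_length ||
        lp$anchor1 >= lp$anchor2) {
      stop("planted loop anchors outside chromosome bounds or unordered")
    }
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

#' Simulate a regulatory genome
#'
#' Generates a gene table with unique TSSs, an open-chromatin universe (one
#' promoter site per gene plus distal sites), and one fixed-width peak set
#' per configured factor. All peaks lie inside open-chromatin sites.
#' Promoter-placed peaks have their center drawn uniformly within the TSS
#' +/- 1 kb window. A Binomial(`n_peaks`, `cobinding_rate`) number of the
#' second factor's peaks is placed onto sites occupied by the first factor;
#' at `cobinding_rate = 0` the two factors never share a site. The first
#' factor's peak set carries control and knockdown tag counts with equal
#' library totals; its co-bound peaks have knockdown tags reduced by
#' integer division with `knockdown_fold`, so the planted peaks - and only
#' they - classify as reduced at that threshold.
#'
#' @param cfg A [simulation_config].
#' @return list with `genes` ([gene_annotation]), `open_sites`
#'   ([peak_set]), `factors` (named list of [peak_set] with tags on the
#'   first), and `truth` (cobound site/peak ids, knockdown-affected ids).
#' @export
simulate_regulatory_genome <- function(cfg) {
  chroms <- sim_chrom_names(cfg)
  L <- cfg$chrom_length

  # genes on a jittered grid: unique, well-separated TSSs
  genes <- with_seed(derive_seed(cfg$seed, "genes"), {
    per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
    out <- list()
    for (ci in seq_len(cfg$n_chroms)) {
      n <- per[ci]
      if (n == 0) next
      grid <- seq(10000, L - 30000, by = 10000)
      if (n > length(grid)) {
        stop(sprintf("%d genes do not fit chromosome of %g bp", n, L))
      }
      tss <- sort(sample_from(grid, n)) + sample(-2000:2000, n, replace = TRUE)
      len <- round(stats::runif(n, 2000, 15000))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      tx_start <- ifelse(strand == "+", tss, pmax(tss - len, 0))
      tx_end <- ifelse(strand == "+", pmin(tss + len, L - 1), tss)
      out[[ci]] <- data.frame(
        gene_id = sprintf("%s_g%04d", chroms[ci], seq_len(n)),
        chrom = chroms[ci], strand = strand, tss_bp = tss,
        tx_start = tx_start, tx_end = tx_end, stringsAsFactors = FALSE)
    }
    gene_annotation(do.call(rbind, out))
  })

  # open-chromatin universe: a promoter site per gene + distal sites
  if (cfg$n_open_sites < nrow(genes)) {
    stop(sprintf("n_open_sites (%d) must be at least n_genes (%d)",
                 cfg$n_open_sites, nrow(genes)))
  }
  prom_half <- 1000L + cfg$peak_width  # contains any TSS +/- 1 kb peak
  n_distal <- cfg$n_open_sites - nrow(genes)
  sites <- with_seed(derive_seed(cfg$seed, "open_sites"), {
    prom <- data.frame(
      chrom = genes$chrom, center = genes$tss_bp, kind = "promoter",
      half = prom_half, gene_id = genes$gene_id, stringsAsFactors = FALSE)
    dist_list <- list()
    per <- diff(round(seq(0, n_distal, length.out = cfg$n_chroms + 1)))
    for (ci in seq_len(cfg$n_chroms)) {
      n <- per[ci]
      if (n == 0) next
      cand <- seq(5000, L - 5000, by = cfg$open_site_width + 2000)
      tssc <- genes$tss_bp[genes$chrom == chroms[ci]]
      near_tss <- vapply(cand, function(p) any(abs(p - tssc) < 4000),
                         logical(1))
      cand <- cand[!near_tss]
      if (n > length(cand)) {
        stop(sprintf("%d distal open sites do not fit chromosome %s",
                     n, chroms[ci]))
      }
      dist_list[[ci]] <- data.frame(
        chrom = chroms[ci], center = sort(sample_from(cand, n)),
        kind = "distal", half = cfg$open_site_width %/% 2L,
        gene_id = NA_character_, stringsAsFactors = FALSE)
    }
    s <- rbind(prom, do.call(rbind, dist_list))
    s <- s[order(s$chrom, s$center), , drop = FALSE]
    s$site_id <- sprintf("site_%05d", seq_len(nrow(s)))
    s
  })
  open_sites <- peak_set(sites$chrom, pmax(sites$center - sites$half, 0),
                         sites$center + sites$half, id = sites$site_id,
                         name = "open_chromatin")

  # factor peak placement
  prom_idx <- which(sites$kind == "promoter")
  dist_idx <- which(sites$kind == "distal")
  place_peaks <- function(site_rows, fname) {
    s <- sites[site_rows, , drop = FALSE]
    center <- ifelse(
      s$kind == "promoter",
      s$center + sample(-1000:1000, nrow(s), replace = TRUE),
      s$center)
    data.frame(chrom = s$chrom,
               start = center - cfg$peak_width %/% 2L,
               end = center + cfg$peak_width %/% 2L,
               site_id = s$site_id, stringsAsFactors = FALSE)
  }

  truth <- list()
  factor_sets <- list()
  site_of <- list()  # per factor: site indices used
  seed_peaks <- derive_seed(cfg$seed, "peaks")
  placements <- with_seed(seed_peaks, {
    pl <- list()
    for (fi in seq_along(cfg$factors)) {
      f <- cfg$factors[[fi]]
      if (f$n_peaks > cfg$n_open_sites) {
        stop(sprintf(
          "factor '%s' requests %d peaks but the universe has only %d open sites",
          f$name, f$n_peaks, cfg$n_open_sites))
      }
      n_prom <- round(f$n_peaks * f$promoter_fraction)
      n_dist <- f$n_peaks - n_prom
      if (fi == 2 && is.na(cfg$cobinding_rate)) {
        # neutral (chance-level) placement: sites drawn uniformly from the
        # whole universe, independent of the first factor; overlap follows
        # the hypergeometric chance expectation
        pl[[fi]] <- sample_from(c(prom_idx, dist_idx), f$n_peaks)
      } else if (fi == 2 && cfg$cobinding_rate > 0) {
        a_sites <- pl[[1]]
        n_co <- stats::rbinom(1, f$n_peaks, cfg$cobinding_rate)
        n_co <- min(n_co, length(a_sites))
        co <- sample_from(a_sites, n_co)
        rest <- f$n_peaks - n_co
        free_prom <- setdiff(prom_idx, a_sites)
        free_dist <- setdiff(dist_idx, a_sites)
        n_prom <- min(round(rest * f$promoter_fraction), length(free_prom))
        n_dist <- rest - n_prom
        if (n_dist > length(free_dist)) {
          stop(sprintf(
            "factor '%s' requests %d distal peaks but only %d free distal sites remain",
            f$name, n_dist, length(free_dist)))
        }
        pl[[fi]] <- c(co,
                      if (n_prom) sample_from(free_prom, n_prom) else integer(),
                      if (n_dist) sample_from(free_dist, n_dist) else integer())
      } else {
        avoid <- if (fi == 2) pl[[1]] else integer()
        free_prom <- setdiff(prom_idx, avoid)
        free_dist <- setdiff(dist_idx, avoid)
        if (f$n_peaks > length(free_prom) + length(free_dist)) {
          stop(sprintf(
            "factor '%s' requests %d peaks but only %d free open sites remain",
            f$name, f$n_peaks, length(free_prom) + length(free_dist)))
        }
        # honor promoter_fraction up to availability, spill the rest
        n_prom <- min(n_prom, length(free_prom))
        n_dist <- f$n_peaks - n_prom
        if (n_dist > length(free_dist)) {
          n_dist <- length(free_dist)
          n_prom <- f$n_peaks - n_dist
        }
        pl[[fi]] <- c(if (n_prom) sample_from(free_prom, n_prom) else integer(),
                      if (n_dist) sample_from(free_dist, n_dist) else integer())
      }
    }
    lapply(pl, function(ix) place_peaks(ix, NULL))
  })

  shared_sites <- if (length(placements) >= 2) {
    intersect(placements[[1]]$site_id, placements[[2]]$site_id)
  } else character()

  tag_seed <- derive_seed(cfg$seed, "tags")
  for (fi in seq_along(cfg$factors)) {
    f <- cfg$factors[[fi]]
    pp <- placements[[fi]]
    ids <- sprintf("%s_p%05d", f$name, seq_len(nrow(pp)))
    tags <- with_seed(derive_seed(tag_seed, f$name), {
      ctrl <- 20L + stats::rpois(nrow(pp), 40)
      kd <- ctrl
      if (fi == 1 && length(shared_sites)) {
        hit <- pp$site_id %in% shared_sites
        kd[hit] <- floor(ctrl[hit] / cfg$knockdown_fold)
      }
      data.frame(control = ctrl, knockdown = kd)
    })
    factor_sets[[f$name]] <- peak_set(
      pp$chrom, pp$start, pp$end, id = ids, score = tags$control,
      name = f$name, tags = tags,
      library_total = c(control = 1e7, knockdown = 1e7))
    site_of[[f$name]] <- stats::setNames(pp$site_id, ids)
  }

  fa <- names(factor_sets)[1]
  truth$cobound_sites <- shared_sites
  truth$cobound_peaks <- lapply(site_of[1:min(2, length(site_of))],
                                function(m) names(m)[m %in% shared_sites])
  truth$knockdown_affected <- if (length(shared_sites)) {
    names(site_of[[fa]])[site_of[[fa]] %in% shared_sites]
  } else character()
  truth$peak_sites <- site_of

  list(genes = genes, open_sites = open_sites, factors = factor_sets,
       truth = truth, config = cfg)
}

# per-chromosome bin-pair sampling weights for one condition
pair_weights <- function(cfg, chrom_index, condition) {
  n <- as.integer(cfg$chrom_length / cfg$bin_size)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- j - i
  w <- pmax(d, 1)^(-cfg$decay_exponent)
  if (chrom_index == 1) {
    for (td in cfg$tad_layout) {
      b1 <- floor(td$start / cfg$bin_size) + 1
      b2 <- ceiling(td$end / cfg$bin_size)
      inside <- i >= b1 & j <= b2
      w[inside] <- w[inside] * td$enrichment
    }
    for (lp in cfg$loops) {
      l1 <- floor(lp$anchor1 / cfg$bin_size) + 1
      l2 <- floor(lp$anchor2 / cfg$bin_size) + 1
      hit <- i == min(l1, l2) & j == max(l1, l2)
      intens <- if (condition == 1) lp$intensity1 else lp$intensity2
      w[hit] <- w[hit] * intens
    }
  }
  list(i = i, j = j, w = w, n_bins = n)
}

#' Simulate cis contact read pairs
#'
#' Draws read pairs per condition by inverse-CDF sampling over discrete
#' bin-pair probabilities: baseline probability proportional to
#' (bin distance)^(-decay_exponent), multiplied by the enrichment factor of
#' any planted domain containing both bins and by the per-condition
#' intensity of any planted loop at that exact bin pair. Read positions are
#' drawn uniformly within their bins. Planted structure lives on the first
#' chromosome; additional chromosomes carry pure decay.
#'
#' @param cfg A [simulation_config].
#' @param conditions Which conditions to simulate (default `1:2`).
#' @return list with `pairs` (per-condition data.frames with chrom1, pos1,
#'   chrom2, pos2), `truth` (planted boundaries in bp, domain and loop bin
#'   coordinates and intensities), and `chrom_sizes`.
#' @export
simulate_contact_reads <- function(cfg, conditions = 1:2) {
  if (cfg$depth > 0 && cfg$n_chroms < 1) {
    stop("depth > 0 requires at least one chromosome")
  }
  chroms <- sim_chrom_names(cfg)
  bs <- cfg$bin_size
  out <- list()
  for (cond in conditions) {
    nm <- paste0("condition", cond)
    if (cfg$depth == 0 || cfg$n_chroms == 0) {
      out[[nm]] <- data.frame(chrom1 = character(), pos1 = numeric(),
                              chrom2 = character(), pos2 = numeric())
      next
    }
    pw <- lapply(seq_len(cfg$n_chroms), pair_weights, cfg = cfg,
                 condition = cond)
    totw <- vapply(pw, function(x) sum(x$w), numeric(1))
    out[[nm]] <- with_seed(derive_seed(cfg$seed, paste0("contacts_", nm)), {
      n_per <- as.vector(stats::rmultinom(1, cfg$depth, totw))
      parts <- list()
      for (ci in seq_len(cfg$n_chroms)) {
        np <- n_per[ci]
        if (np == 0) next
        cw <- cumsum(pw[[ci]]$w)
        pick <- findInterval(stats::runif(np) * cw[length(cw)], cw,
                             left.open = TRUE) + 1L
        i <- pw[[ci]]$i[pick]; j <- pw[[ci]]$j[pick]
        parts[[ci]] <- data.frame(
          chrom1 = chroms[ci],
          pos1 = (i - 1) * bs + floor(stats::runif(np) * bs),
          chrom2 = chroms[ci],
          pos2 = (j - 1) * bs + floor(stats::runif(np) * bs),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, parts)
    })
  }
  truth <- list(
    boundaries_bp = sort(unique(unlist(lapply(cfg$tad_layout, function(td) {
      c(floor(td$start / bs) * bs, ceiling(td$end / bs) * bs)
    })))),
    domains = lapply(cfg$tad_layout, function(td) {
      list(start_bin = floor(td$start / bs), end_bin = ceiling(td$end / bs) - 1,
           start_bp = floor(td$start / bs) * bs,
           end_bp = ceiling(td$end / bs) * bs,
           enrichment = td$enrichment)
    }),
    loops = lapply(cfg$loops, function(lp) {
      list(bin1 = floor(lp$anchor1 / bs), bin2 = floor(lp$anchor2 / bs),
           intensity1 = lp$intensity1, intensity2 = lp$intensity2)
    })
  )
  list(pairs = out, truth = truth,
       chrom_sizes = stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                     chroms))
}

#' Planted expression effects for a binding matrix
#'
#' Assigns each gene a log2 fold change built from its promoter binding:
#' `coef_single` per bound factor plus `coef_cobound` when the first two
#' factors are both bound, plus Gaussian noise. Under these defaults the
#' co-bound combination has the highest expected fold change.
#'
#' @param binding data.frame from [promoter_binding_matrix()].
#' @param coef_single Additive effect per bound factor (default 0.75).
#' @param coef_cobound Extra effect when the first two factors co-bind
#'   (default 1.5).
#' @param sd Noise SD (default 0.5).
#' @param seed RNG seed.
#' @return Named numeric of per-gene log2 fold changes.
#' @export
simulate_expression_effects <- function(binding, coef_single = 0.75,
                                        coef_cobound = 1.5, sd = 0.5,
                                        seed = 1L) {
  factors <- setdiff(names(binding), "gene_id")
  bm <- as.matrix(binding[factors]) != 0
  eff <- coef_single * rowSums(bm)
  if (length(factors) >= 2) {
    eff <- eff + coef_cobound * (bm[, 1] & bm[, 2])
  }
  with_seed(derive_seed(seed, "expression_effects"), {
    stats::setNames(eff + stats::rnorm(nrow(binding), 0, sd),
                    binding$gene_id)
  })
}

#' Simulate differential-expression contrast tables
#'
#' Emits `n_contrasts` contrasts in which a designated core gene set is
#' consistently upregulated (planted positive log2 fold change, small
#' adjusted p in every contrast) while the remaining genes fluctuate around
#' zero with uniform adjusted p, so single contrasts admit false positives
#' that the intersection removes.
#'
#' @param genes A [gene_annotation] data.frame.
#' @param core_genes Gene ids planted as the true core set.
#' @param n_contrasts Number of contrasts (default 3).
#' @param effect Mean planted log2 fold change (default 2).
#' @param seed RNG seed.
#' @return Named list of contrast data.frames (gene, log2fc, padj).
#' @export
simulate_de_contrasts <- function(genes, core_genes, n_contrasts = 3L,
                                  effect = 2, seed = 1L) {
  ids <- genes$gene_id
  core <- ids %in% core_genes
  out <- list()
  for (ci in seq_len(n_contrasts)) {
    out[[paste0("contrast_", ci)]] <-
      with_seed(derive_seed(seed, paste0("contrast_", ci)), {
        log2fc <- stats::rnorm(length(ids), 0, 0.75)
        log2fc[core] <- stats::rnorm(sum(core), effect, 0.5)
        padj <- stats::runif(length(ids))
        padj[core] <- 10^(-stats::runif(sum(core), 2, 8))
        data.frame(gene = ids, log2fc = log2fc, padj = padj,
                   stringsAsFactors = FALSE)
      })
  }
  out
}

#' Write simulated artifacts to a directory
#'
#' Emits the gene table, the open-chromatin BED, a BED plus tag TSV per
#' factor, per-condition pairs files, and a `truth.json` sidecar containing
#' the planted ground truth.
#'
#' @param reg Output of [simulate_regulatory_genome()] (or NULL to skip).
#' @param contacts Output of [simulate_contact_reads()] (or NULL to skip).
#' @param outdir Output directory (created if absent).
#' @return Invisibly, `outdir`.
#' @export
write_simulation <- function(reg = NULL, contacts = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  if (!is.null(reg)) {
    write_gene_table(reg$genes, file.path(outdir, "genes.tsv"))
    write_bed(reg$open_sites, file.path(outdir, "open_sites.bed"))
    for (nm in names(reg$factors)) {
      write_bed(reg$factors[[nm]], file.path(outdir, paste0(nm, ".bed")))
      write_peak_tags(reg$factors[[nm]],
                      file.path(outdir, paste0(nm, "_tags.tsv")))
    }
    truth <- c(truth, reg$truth[c("cobound_sites", "cobound_peaks",
                                  "knockdown_affected")])
  }
  if (!is.null(contacts)) {
    for (nm in names(contacts$pairs)) {
      write_pairs(contacts$pairs[[nm]],
                  file.path(outdir, paste0("pairs_", nm, ".tsv")))
    }
    truth <- c(truth, contacts$truth)
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Example planted-domain layout
#'
#' Five self-interacting domains of 0.5-0.6 Mb at 4x internal enrichment on
#' a 20 Mb chromosome, with all boundaries on 100 kb multiples so the same
#' layout bins exactly at 10, 20 and 25 kb resolution.
#'
#' @param enrichment Within-domain enrichment factor (default 4).
#' @return A list suitable for `simulation_config(tad_layout = ...)`.
#' @export
example_tad_layout <- function(enrichment = 4) {
  lapply(list(c(2e6, 2.5e6), c(5e6, 5.6e6), c(1e7, 1.05e7),
              c(1.4e7, 1.45e7), c(1.7e7, 1.76e7)),
         function(x) list(start = x[1], end = x[2],
                          enrichment = enrichment))
}

#' Study-mimic simulation world
#'
#' A reduced-scale configuration that mirrors the structure of the
#' biological study the package's statistics were built for: two
#' co-binding factors with elevated expression effects at co-bound
#' promoters; promoter-like features at planted domain boundaries and
#' enhancer-like features inside domains; and chromatin loops whose
#' anchors carry features - twelve "regulatory" loops connecting
#' knockdown-sensitive (F3-type) anchors to promoter anchors, weak in
#' condition 1 and strong in condition 2, on top of twenty constant
#' single-ended baseline loops present in both conditions.
#'
#' @param seed Master seed.
#' @param depth Read pairs per condition (default 1e6).
#' @return list with `config` (a [simulation_config]), `f3_bins`,
#'   `promoter_bins` (0-based bins carrying the two feature classes) and
#'   `regulatory_pairs` (bin pairs of the condition-2-strengthened loops).
#' @export
study_mimic_config <- function(seed = 1L, depth = 1e6) {
  bs <- 25000
  reg_anch <- lapply(0:11, function(i) {
    c(30 + i * 60, 30 + i * 60 + 12 + (i %% 4) * 8)
  })
  reg_loops <- lapply(reg_anch, function(a) {
    list(anchor1 = a[1] * bs + 100, anchor2 = a[2] * bs + 100,
         intensity1 = 2.5, intensity2 = 7)
  })
  f3_base <- lapply(0:9, function(i) c(15 + i * 75, 15 + i * 75 + 25))
  mcc_base <- lapply(0:9, function(i) c(45 + i * 72, 45 + i * 72 + 30))
  base_loops <- c(
    lapply(f3_base, function(a) {
      list(anchor1 = a[1] * bs + 100, anchor2 = a[2] * bs + 100,
           intensity1 = 5, intensity2 = 5)
    }),
    lapply(mcc_base, function(a) {
      list(anchor1 = a[1] * bs + 100, anchor2 = a[2] * bs + 100,
           intensity1 = 5, intensity2 = 5)
    }))
  cfg <- simulation_config(
    seed = seed, depth = depth, bin_size = bs,
    tad_layout = example_tad_layout(),
    loops = c(reg_loops, base_loops), cobinding_rate = 0.4)
  list(config = cfg,
       f3_bins = c(vapply(reg_anch, `[`, numeric(1), 1),
                   vapply(f3_base, `[`, numeric(1), 1)),
       promoter_bins = c(vapply(reg_anch, `[`, numeric(1), 2),
                         vapply(mcc_base, `[`, numeric(1), 2)),
       regulatory_pairs = reg_anch)
}
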