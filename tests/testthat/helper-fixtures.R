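# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

toy_genes <- function() {
  gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss_bp = c(10000, 50000, 20000),
    tx_start = c(10000, 42000, 20000),
    tx_end = c(18000, 50000, 27000),
    stringsAsFactors = FALSE
  ))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), L = 1e6,
                         width = 200, seed = 1, name = "rp") {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - width, n)
  peak_set(chrom, start, start + width, name = name,
           id = paste0(name, "_", seq_len(n)))
}

random_genes <- function(n, chroms = c("chr1", "chr2"), L = 1e6, seed = 2) {
  set.seed(seed)
  chrom <- sort(sample(chroms, n, replace = TRUE))
  tss <- sample.int(L - 30000, n) + 10000
  len <- sample(2000:10000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_annotation(data.frame(
    gene_id = paste0("g", seq_len(n)), chrom = chrom, strand = strand,
    tss_bp = tss,
    tx_start = ifelse(strand == "+", tss, pmax(tss - len, 0)),
    tx_end = ifelse(strand == "+", tss + len, tss),
    stringsAsFactors = FALSE
  ))
}

# dense symmetric matrix where every pair at distance d has count counts[d+1]
uniform_matrix <- function(n, counts, chrom = "chr1", bin_size = 1000) {
  m <- matrix(0, n, n)
  d <- abs(row(m) - col(m))
  m[] <- counts[d + 1]
  contact_matrix(m, chrom, bin_size)
}

# two enriched diagonal blocks on a decaying background (deterministic)
block_matrix <- function(n = 80, blocks = list(c(20, 39), c(45, 64)),
                         enrich = 4, base = 100, chrom = "chr1",
                         bin_size = 25000) {
  m <- matrix(0, n, n)
  d <- abs(row(m) - col(m))
  m[] <- base / pmax(d, 1)
  for (b in blocks) {
    i <- (b[1]:b[2]) + 1
    m[i, i] <- m[i, i] * enrich
  }
  contact_matrix(round(m), chrom, bin_size)
}

# independent direct-summation oracle for the upper-tail hypergeometric
hyper_tail_oracle <- function(N, na, nb, k) {
  if (k <= 0) return(1)
  i <- k:min(na, nb)
  sum(choose(na, i) * choose(N - na, nb - i)) / choose(N, nb)
}

# brute-force subset-enumeration oracle (small N only)
hyper_tail_enum <- function(N, na, nb, k) {
  a <- seq_len(na)  # overlap distribution is exchangeable in the labels
  subs <- utils::combn(N, nb)
  mean(colSums(subs <= na) >= k)
}

# direct-summation oracle for the upper-tail binomial
binom_tail_oracle <- function(o, n, p) {
  if (o <= 0) return(1)
  i <- o:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}
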