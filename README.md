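# tfloops

Statistics linking transcription-factor co-binding to 3D chromatin
structure, for regulatory genomicists who have ChIP-seq peak sets, gene
annotations and proximity-ligation (Hi-C/TCC-style) read pairs and want the
analysis layer between those files and biological claims:

* **Does factor B bind where factor A binds more than chance allows,
  given that both live in open chromatin?** Permutation null over the
  open-chromatin site universe plus the hypergeometric overlap test
  `P(X >= k)` for `X ~ Hypergeom(N, n_a, n_b)`.
* **Do co-bound peaks prefer promoters?** Resampling null drawing half the
  peaks from each factor and counting promoter-classified draws.
* **Which interactions are chromatin loops?** A distance-decay background
  `E[o_ij] = f(|i-j|) w_i w_j` (stratum-conserving, coverage-normalized),
  then a cumulative binomial test with trials `n = T_i + T_j`,
  success probability `E_ij / n`, BH correction, differential scoring
  `log2((o1/e1 + psi)/(o2/e2 + psi))` between conditions, and
  hypergeometric feature-pair enrichment at loop anchors.
* **Where are the TADs, and what lives at their boundaries?**
  Directionality index
  `DI = sign(B - A) ((A-E)^2 + (B-E)^2)/E`, `E = (A+B)/2`, a run-length
  domain caller, and 700-bin boundary-relative metagene profiles
  (175 bins per quartile: flank, two body halves, flank).
* **Which peaks lose binding when a partner factor is knocked down?**
  Depth-normalized (10M tags) fold-change classes at >= 3- and >= 10-fold.
* **Which genes form the core program?** Intersection of
  differential-expression contrasts (padj < 0.05, positive log2FC in all),
  and expression summaries per promoter binding combination.

A synthetic-data module (`simulation_config`, `simulate_regulatory_genome`,
`simulate_contact_reads`, `simulate_de_contrasts`) generates every input
format with planted co-binding, knockdown effects, domains and loops, so
the whole pipeline is testable offline with known truth.

## Worked example

```r
library(tfloops)

cfg <- simulation_config(
  seed = 7, cobinding_rate = 0.4,
  tad_layout = example_tad_layout(),                     # five 4x domains
  loops = list(list(anchor1 = 8e6, anchor2 = 8.75e6,     # one loop,
                    intensity1 = 5, intensity2 = 1)))    # condition-1 only

reg <- simulate_regulatory_genome(cfg)
open_chromatin_permutation(reg$open_sites, n_a = 300, n_b = 300,
                           observed = length(reg$truth$cobound_sites),
                           n_iter = 1000, seed = 7)
#> permutation null: observed 115 vs null mean 89.78 (SD 6.47),
#>   p 0.000999 (n_iter 1000)
```

The two factors share 115 open-chromatin sites; random placement predicts
89.8 (SD 6.5), so the planted co-binding is detected at the permutation
floor p < 0.001. The knockdown classifier recovers exactly the planted
peaks:

```r
kd <- knockdown_response(reg$factors$factorA)
#> 115 of 300 peaks reduced >= 3-fold (planted: 115)
```

Contact analysis on the same configuration:

```r
ct <- simulate_contact_reads(cfg)
cm <- bin_pairs(ct$pairs$condition1, cfg$bin_size,
                ct$chrom_sizes)$matrices$chr1
ic <- call_interactions(cm, fit_background(cm))
ic
#> interaction_calls chr1: 9 significant of 74151 tested (q < 0.05)
head(ic$calls[, c("bin1", "bin2", "o", "n", "p_s", "q", "strength")], 1)
#>   bin1 bin2  o    n          p_s            q strength
#> 1  320  350 27 4097 0.0008592529 1.235771e-10 7.669672
```

The top call sits at bins 320-350, i.e. 8.00-8.75 Mb: the planted loop,
observed 27 pairs against an expectation of ~3.5 (strength 7.7). Domain
calling recovers all five planted domains with exact boundaries:

```r
call_domains(directionality_index(cm))$domains
#>   start_bin end_bin start_bp   end_bp
#> 1        80      99  2000000  2500000
#> 2       200     223  5000000  5600000
#> 3       400     419 10000000 10500000
#> 4       560     579 14000000 14500000
#> 5       680     703 17000000 17600000
```

## Command line

`inst/cli/tfloops.R` wraps the exported functions:

```sh
Rscript inst/cli/tfloops.R simulate --outdir sim --seed 7
Rscript inst/cli/tfloops.R overlap --a sim/factorA.bed --b sim/factorB.bed
Rscript inst/cli/tfloops.R cobind-hyper --N 1000 --na 300 --nb 300 --k 120
Rscript inst/cli/tfloops.R loops-call --matrix mat.chr1.tsv --out calls.bedpe
Rscript inst/cli/tfloops.R tads-call --matrix mat.chr1.tsv --out domains.bed
```

See `vignettes/cobinding-and-chromatin-structure.Rmd` for the models,
parameter defaults, numerical choices and known limitations.
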