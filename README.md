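# poolMHC

Pooled-amplicon MHC genotyping and population genetics for colony-based
seabird surveys.

Wild colonies of Humboldt-current and Patagonian penguins (and many other
colonial seabirds) are surveyed for immune-gene diversity by pooling the
PCR products of all individuals from one colony into a single sequencing
barcode. Each barcode then yields a read set — not individual genotypes —
from which the colony's MHC allele pool must be reconstructed and
compared across colonies. `poolMHC` implements that workflow end to end
for two amplicons with contrasting architecture: a 261-bp class I exon 3
(multi-copy, so more than two alleles per individual) and a 270-bp class
II exon 2 (single-copy), together with a truth-tracked 454-style read
simulator so every stage is testable without access to raw runs.

The pipeline:

* **read_qc** — the six-rule cleaning cascade: length ≥ 180 bp; ≥ 70%
  free-end-gap alignment identity to a locus reference (both
  orientations); 100%-identity dereplication into variants; per-barcode
  singleton removal; ≥ 80% of bases at Phred ≥ 20; removal of variants
  whose net indel vs the reference is not a multiple of 3.
* **diversity_stats** — per barcode × locus: segregating sites S, allele
  counts and alleles per individual A/N, haplotype diversity
  Hd = n/(n−1)·(1−Σp²), nucleotide diversity π = k̂/L, Tajima's
  D = (k̂ − S/a₁)/√(e₁S + e₂S(S−1)), Fu's
  Fs = ln(S′/(1−S′)) with S′ = Pr(K ≥ k_obs) under the Ewens sampling
  formula (log-space Stirling numbers), and Nei–Gojobori Ka/Ks with
  pathway enumeration and Jukes–Cantor correction. A mean-centered
  diversity vs population size drift check is included.
* **differentiation** — pairwise Φ_ST = (π_total − π_within)/π_total with
  permutation significance, haversine great-circle distances (R = 6371
  km), and Mantel isolation-by-distance tests with **exact** p by complete
  enumeration of all k! permutations for fewer than 8 localities.
* **allele_catalog** — shared / private / trans-species allele
  bookkeeping and figure-ready frequency tables.
* **synthetic_data** — coalescent allele pools with a tunable dN/dS dial,
  stepping-stone colonies at mutation–migration–drift balance along a
  coastline, and 454-style substitution / homopolymer-indel / chimera
  errors with truth tables down to per-read provenance.

## Worked example

Simulate a three-colony pooled run, clean it, and summarize:

```r
library(poolMHC)

cfg <- sim_config(n_populations = 3, individuals_per_population = 10,
                  coastline_positions = c(0, 500, 1000),
                  depth_per_individual = 20, migration_rate = 0.1, seed = 7)
sim <- simulate_dataset(cfg)
write_simulation(sim, "demo")

fq <- list.files("demo", pattern = "fastq$", full.names = TRUE)
names(fq) <- sub(".fastq$", "", basename(fq))
out <- run_pipeline(fq, "demo/references.fasta", "demo/manifest.tsv",
                    run_config(seed = 7, output_dir = "demo_out"))
out$qc
#> qc_result: 35 retained variants, 404 retained reads
out$diversity[, c("barcode", "locus", "reads", "S", "n_alleles",
                  "alleles_per_ind", "Hd", "pi", "tajima_D", "fu_Fs", "Ka_Ks")]
#>             barcode   locus reads  S n_alleles alleles_per_ind    Hd      pi tajima_D fu_Fs Ka_Ks
#> BC1.MHC1ex3     BC1 MHC1ex3    61 12         8             0.8 0.793 0.01064    0.237 1.107 0.437
#> BC2.MHC1ex3     BC2 MHC1ex3    75 14        11             1.1 0.862 0.01656    1.449 1.451 0.394
#> BC3.MHC1ex3     BC3 MHC1ex3    72 18        10             1.0 0.868 0.01800    0.790 2.501 0.662
#> BC1.MHC2ex2     BC1 MHC2ex2    72 15         5             0.5 0.426 0.01968    2.076 9.665 1.078
#> BC2.MHC2ex2     BC2 MHC2ex2    60 16         6             0.6 0.499 0.00513   -1.794 0.149 0.814
#> BC3.MHC2ex2     BC3 MHC2ex2    64 18         8             0.8 0.868 0.02666    2.699 7.491 0.732
```

Each row summarizes one barcode at one locus: 61–75 retained reads
collapse to 5–11 validated alleles; Hd is the chance two random reads
carry different alleles; π the per-site mean pairwise difference; D and
Fs the neutrality statistics (missing, never zero, when S = 0); and
Ka/Ks the selection signal across the variant pairs.

Isolation by distance on a published four-colony class II FST matrix
(shipped as a fixture) against great-circle distances rebuilt from the
colony coordinates:

```r
m <- read_manifest(system.file("extdata", "colony_manifest.tsv",
                               package = "poolMHC"))
hum <- m[m$species == "S. humboldti", ]
fst <- as.matrix(read_tsv(system.file("extdata", "humboldt_mhcii_fst.tsv",
                                      package = "poolMHC"))[, -1])
rownames(fst) <- colnames(fst) <- hum$locality
mantel(fst, distance_matrix_km(hum))
#> Mantel test: Z = 4770, r = 0.9373, p = 0.04167 (exhaustive permutations)
```

With four localities there are only 4! = 24 label permutations, so the
p-value is exact: the observed correlation (0.94) is the largest of all
24, hence p = 1/24 ≈ 0.04 — a significant distance decay driven by the
northernmost colony's near-complete differentiation.

A thin command-line wrapper is shipped at `inst/scripts/poolmhc.R`
(`simulate`, `qc`, `stats`, `diff`, `catalog`, `all` subcommands); the R
functions above are the primary interface.

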