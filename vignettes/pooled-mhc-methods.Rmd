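---
title: "Methods: pooled-amplicon MHC genotyping and colony-level population genetics"
author: "poolMHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-amplicon MHC genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolMHC)
```

## The problem

Colony-level surveys of major histocompatibility complex (MHC) diversity in
wild seabirds are often run by pooling PCR products of all individuals from
one colony into a single sequencing barcode. Pooling trades individual
genotypes (heterozygosity cannot be estimated) for breadth: each barcode
yields a read set from which the colony's allele pool, its diversity and
the signature of selection can be summarized, and colonies can be compared
through pairwise differentiation and isolation by distance (IBD).

`poolMHC` implements that workflow for two amplicons with contrasting
architecture: a 261-bp class I exon (multi-copy — more than one locus
amplifies, so more than two alleles per individual are expected) and a
270-bp class II exon (single-copy, at most two alleles per individual).
Because raw pooled pyrosequencing runs are rarely redistributable, the
package also ships a truth-tracked simulator so every downstream stage can
be validated against known inputs.

## Read cleaning: the six-rule cascade

`run_qc_pipeline()` applies, in order:

1. **Length**: reads under 180 bp are removed (boundary retained — "under"
   is read as strict).
2. **Locus assignment**: global alignment with free end gaps (match +1,
   mismatch −1, gap −2) against each reference, in both orientations;
   identity is matches over alignment columns, gap columns included. Reads
   below 70% identity to both references are removed;
   reverse-complement hits are normalized to reference orientation.
3. **Dereplication**: reads grouped at 100% identity into variants with
   per-barcode counts; ordering is deterministic (descending total count,
   ties broken lexicographically).
4. **Singletons**: a count-of-1 occurrence is removed *from that barcode*;
   a variant disappears entirely only when every occurrence was a
   singleton. A global mode exists because the per-barcode scoping is an
   interpretive choice.
5. **Quality**: reads with fewer than 80% of bases at Phred ≥ 20 are
   removed (boundary retained). "80% quality" is not a standard quantity;
   fraction-of-bases-at-Q20 is the conventional amplicon reading, and both
   thresholds are configurable. The filter runs after dereplication,
   following the narrative order of the protocol it mirrors; a
   `quality_first` switch restores the more common order.
6. **Frameshift**: variants whose net indel length versus their reference
   is not a multiple of three are removed; in-frame indels are kept.
   Insertions are treated like deletions — the frameshift logic is the
   same. This check uses *end-to-end* (global) alignment: variants at this
   stage are complete amplicons, and a single-base indel in the terminal
   homopolymer run is invisible to a free-end-gap alignment (it is clipped
   at zero cost) yet shifts the frame all the same. In simulations such
   terminal indels recur often enough at depth to pass the singleton
   filter, so the global measurement matters in practice.

The filter report records per-barcode read counts after every stage;
attrition is monotone by construction.

## Per-barcode statistics

All statistics are computed on read-count-weighted variants by default
(the read set is what a pooled barcode actually yields); an unweighted
"unique alleles" mode is available since protocols are often ambiguous
about which was used.

* **Segregating sites S**: columns with ≥ 2 unambiguous bases observed,
  presence-based.
* **Allelic diversity** `Hd = n/(n−1) · (1 − Σ p²)`.
* **Nucleotide diversity** `π = k̂/L`, with `k̂` the mean pairwise
  difference count over reads.
* **Tajima's D** with the standard constants computed at `n` = read count.
  With pooled data the "true" sample size is ambiguous (reads oversample
  gene copies); read count is the default and the caveat is that D is
  biased upward when depth far exceeds the number of gene copies.
  Undefined cases (S = 0) are reported missing, never zero.
* **Fu's Fs** via the Ewens sampling formula:
  `S' = Pr(K ≥ k_obs | θ = k̂)` with unsigned Stirling numbers of the
  first kind computed by recurrence in log space (stable to n in the
  thousands), and `Fs = ln(S'/(1−S'))`. Significance requires coalescent
  simulation and is out of scope; the statistic itself is the deliverable.
* **Ka/Ks** by the Nei–Gojobori pathway method: per codon pair, synonymous
  site counts averaged between the two sequences (changes that would
  create a stop codon are excluded from the per-position denominator, so
  synonymous + nonsynonymous sites always sum to 3 per codon), differences
  averaged over all orderings of the changed positions with
  stop-traversing pathways excluded, Jukes–Cantor correction
  `d = −(3/4)·ln(1 − 4p/3)`, and unweighted averaging over distinct
  variant pairs (the usual way haplotype data are fed to this estimator;
  a count-weighted mode exists). `ω` is reported undefined when Ks = 0
  rather than infinite.

The drift check (`mean_centered_diversity()`) divides each population's
allele count by the across-population mean and correlates the centered
values with supplied population sizes (positive correlation expected under
drift), with a permutation p-value.

## Differentiation and isolation by distance

`pairwise_fst()` defaults to a Φ~ST~-style decomposition of nucleotide
diversity, `Φ = (π_total − π_within)/π_total`, computed on variant
*frequencies* (expected pairwise differences with replacement) for both
terms. The frequency form is what makes `FST(A, A) = 0` hold exactly;
pair-count forms leave a small negative bias when a sample is compared
with itself. A haplotype-identity estimator (`mode = "freq"`) is kept for
sensitivity analysis. Negative estimates are reported as computed, with an
optional display clamp. Permutation significance reassigns reads to the
two populations at their original sizes.

`mantel()` reports the cross-product statistic Z, the Pearson correlation
r over off-diagonal pairs, and a one-tailed permutation p for positive
association, with the observed permutation counted in the numerator. For
fewer than 8 localities **all k! label permutations are enumerated and p
is exact** — this covers the 4-colony and 3-colony designs the package
targets, where sampled permutations would only add noise; larger matrices
fall back to sampling (10,000 by default). Geographic distances are
great-circle (haversine, Earth radius 6371.0 km) from manifest
coordinates, which accept degree–minute strings ("15°22′ S"). Along-coast
distances can be supplied as a file instead where the coastline geometry
matters.

## The simulator

`simulate_dataset()` chains three stages, all truth-tracked:

1. **Allele pool** (`generate_allele_pool()`): a Kingman coalescent over
   `n_alleles` lineages with the reference at the root and
   Poisson(θ/2 · branch length) substitutions. Mutations are proposed
   uniformly and accepted with probability min(1, ω) if nonsynonymous and
   min(1, 1/ω) if synonymous, which biases the realized pool dN/dS toward
   the dial without distorting the site-frequency structure; stop-creating
   proposals are rejected and resampled, keeping alleles plausibly
   functional. ω = 0 with no synonymous change available is an explicit
   error.
2. **Genotypes** (`assign_genotypes()`): two regimes. *Partition*
   (panmixia) deals pool lineages out without replacement, so each barcode
   is an exact coalescent subsample — this is what makes the neutral
   Tajima's D check honest (mean D ≈ −0.07 over 60 replicates in the
   shipped test). *Frequency* (stepping-stone) runs Wright–Fisher drift
   with nearest-neighbour migration along the 1-D coastline **with
   recurrent codon-aware mutation** at the per-copy rate implied by θ
   (θ = 2·N_total·μ). Without mutation, long runs fix alleles and IBD is
   erratic; at mutation–migration–drift balance, low migration produces
   the expected distance decay (positive Mantel r in every prototype
   seed). Final-generation counts are dealt to individuals, so truth
   frequencies are exact.
3. **Reads** (`simulate_reads()`): fixed depth per individual split evenly
   over allele slots (exact truth frequencies; a Poisson option exists),
   chimeras spliced at a uniform breakpoint with a frequency-weighted
   second parent, per-homopolymer-run single-base gains/losses,
   i.i.d. substitution errors, and a small fraction of "degraded" reads
   with pervasive low-confidence bases so the 80%-quality rule is
   exercised. Qualities encode per-base confidence after errors:
   untouched bases carry `round(−10·log10(substitution rate))`,
   error/low-confidence bases Q10.

Defaults emulate the pooled-colony study design this package targets:
7 barcodes × 25 individuals, amplicons of 261 bp (2 locus copies) and
270 bp (1 copy), coastline positions at the cumulative great-circle
distances of the seven real colonies (0, 1287, 1678, 2012, 3074, 4325,
4980 km). Where no published value exists the defaults are chosen once
for 454-era realism: θ = 8 (π of a few percent on a ~270-bp amplicon),
depth 20 reads/individual/locus, substitution errors 5·10⁻⁴ per base
(substitutions are a minor 454 error mode), homopolymer indels 0.02 per
run ≥ 2 (the dominant mode), chimeras 2% of reads, 2% degraded reads.
Depth heterogeneity from pooled-concentration differences is not
modelled by default (`poisson_depth` adds dispersion but not skew).

What the simulator does *not* emulate: flowgram signal space, per-template
PCR amplification bias, and pseudogene divergence as a separate class.
Passing tests therefore show the pipeline's logic is correct under the
stated error model — not that any particular real run was cleaned
perfectly.

## Numerical choices and degenerate inputs

* Coordinates 0-based half-open where alignment spans are reported.
* Undefined statistics (D with S = 0, ω with Ks = 0, FST with zero total
  diversity, Mantel on constant matrices) are `NA`/errors, never silent
  zeros; `Fs` uses ±∞ sentinels at the boundary of the Ewens tail.
* Jukes–Cantor is undefined at p ≥ 0.75; such pairs are skipped with the
  pair dropped from the average.
* Variant ordering, shared-allele keys, and every output table are
  deterministic under a fixed seed and config; the serialized
  `run_config.json`/`config.json` in each output directory records the
  provenance.
* Problem sizes in the shipped tests (colonies of 6–10 individuals,
  depth 8–20, 100 oracle fixtures with n ≤ 36 reads and L ≤ 60, 500
  Mantel calibration replicates at 999 permutations) are chosen so the
  whole suite exercises every claim at desk scale.

## Known limitations

* Read-weighted D and Fs inherit the pooling ambiguity about n; compare
  the allele-weighted mode before interpreting magnitudes.
* The cascade cannot remove recurrent chimeras between high-frequency
  parents, nor distinguish pseudogene from functional copies at a
  multi-copy locus — both are properties of the method, not the
  implementation.
* Exact-sequence allele identity means an in-frame indel variant is a
  different allele; no clustering radius is applied.
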