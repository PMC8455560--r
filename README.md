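# crmkit

An R toolkit for the computational dissection of a developmental gene's
*cis*-regulatory landscape — the kind of analysis used to map the enhancer
modules (CRMs) that control *Gremlin1* expression in vertebrate limb buds.
It is aimed at regulatory-genomics analysts who need the full desk-side
chain, reproducible from a single seed:

- **4C-seq viewpoint profiling** — in-silico double restriction digestion
  (DpnII × NlaIII), valid-fragment filtering (a fragment is kept iff it
  contains a secondary-enzyme site and is ≥ 20 bp), primer filtering,
  exact-match read assignment to fragment boundaries, viewpoint exclusion
  zones (fragment neighbours plus ±10 kb), sliding-window normalisation to
  reads per million over windows of 5 informative fragments, and
  genotype-vs-genotype profile subtraction. An ATAC-style binned RPKM
  track (`count / (library_size · bin_size) · 1e9`) is included.
- **CRM orthology by bidirectional best hits (BBH)** — a built-in
  seed-and-extend local search with Karlin–Altschul E-values
  (`E = K·m·n·e^{-λS}`, cap 1e−5), target extraction with unaligned-flank
  plus 20 nt extension, and a reciprocal search that must land back on the
  query CRM. Gblocks-style alignment trimming (≤ 50 % gapped columns,
  blocks ≥ 10) and VISTA-style windowed conservation calls (100-bp
  windows, ≥ 70 % identity) complete the comparative toolkit.
- **Binding-site analysis** — JASPAR-format PWMs with exact p-values
  computed by dynamic programming over the discretised score distribution
  (`p(s) = P(S ≥ s)` for a random background k-mer), both-strand scanning
  at p < 0.01, Hox/Gli-style site-overlap detection, fully conserved MSA
  column marks, and a mutagenesis designer that disrupts every site and
  verifies that no residual or de-novo site survives.
- **Expression statistics** — 2^−ΔΔCq fold changes against a reference
  gene and the exact two-tailed Mann–Whitney test by full enumeration of
  all C(n₁+n₂, n₁) group assignments (with a seeded permutation fallback
  for ties or larger samples).
- **Synthetic data with ground truth** — seeded generators for genomes,
  Jukes–Cantor-diverged CRM families along a tree, planted motif sites,
  4C reads with capture probability ∝ (1+|d|)^−α, and replicate Cq
  tables; every downstream stage can therefore be validated against known
  truth.

## Worked example

```r
library(crmkit)

genome <- make_genome(60000, gc = 0.5, seed = 7)
lib <- digest(genome)          # DpnII x NlaIII double digest
lib
#> fragment_library: 208 fragments on 1 chromosome(s)
#>   primary/secondary motif: GATC / CATG  min valid length: 20 bp
#>   valid fragments: 121

primer <- substr(genome[[1]], 30001, 30020)
vp <- viewpoint_spec("chr1", 30000, primer, exclusion_radius = 2000)
sim <- simulate_4c_reads(lib, vp, alpha = 1, n_reads = 20000, seed = 8,
                         decoy_fraction = 0.05)
kept <- filter_primer_reads(sim$reads, primer)$kept
counts <- assign_reads(kept, lib)$counts
prof <- viewpoint_profile(lib, vp, counts, window_width = 5)
prof
#> viewpoint_profile: 110 informative fragments, 18972 mapped reads, window 5
cor(prof$rpm[prof$mask], sim$truth$prob[prof$mask], method = "spearman")
#> [1] 0.991

cq <- simulate_cq(c(wild_type = 7, mutant = 7),
                  c(wild_type = 1, mutant = 0.5), noise_sd = 0.2, seed = 9)
ddcq_fold_change(cq, control_group = "wild_type")
#> 2^-ddCq fold changes (target vs reference, control = wild_type)
#>      group n mean_fold     sem  U   p_value
#>  wild_type 7    1.0000 0.05719 NA        NA
#>     mutant 7    0.5117 0.04169  0 0.0005828
```

Reading the output: 19 of every 20 simulated reads carry the real
viewpoint primer (5 % decoys are discarded), the smoothed RPM profile
rank-recovers the true contact decay (ρ = 0.991), and a simulated 2-fold
knock-down with 7 biological replicates per genotype is estimated at
0.51 ± 0.04 with the exact two-tailed Mann–Whitney p = 0.000583 — the
smallest p-value attainable at n = 7/7, corresponding to complete
separation of the groups.

A full synthetic run of every stage (digestion → 4C profiles and
subtraction → BBH orthology → conservation → motif scan → mutagenesis →
qPCR) is one call:

```r
run_pipeline(run_config(seed = 11), "my_run")   # writes a checksummed manifest
```

or, from a shell, `inst/scripts/crmkit simulate --seed 11 --out my_run`.
The same script exposes `digest`, `4c-profile`, `4c-subtract`, `bbh`,
`conserve`, `trim-msa`, `scan`, `mutate`, `verify`, `qpcr` and friends on
files (FASTA/FASTQ/BED/bedGraph/JASPAR/TSV).

## Package layout

| Path | Contents |
| --- | --- |
| `R/synth.R` | seeded generators (genomes, diverged CRMs, 4C reads, Cq tables) |
| `R/digest4c.R` | digestion, filtering, counting, RPM smoothing, subtraction, RPKM bins |
| `R/orthomap.R` | local search, BBH detection, MSA trimming, conservation calling |
| `R/motifscan.R` | PWMs, exact p-values, scanning, overlaps, mutagenesis design |
| `R/qstats.R` | 2^−ΔΔCq fold changes, exact/permutation Mann–Whitney |
| `R/io.R`, `R/cli.R`, `R/pipeline.R` | formats, umbrella CLI, end-to-end runs |
| `vignettes/crmkit-methods.Rmd` | models, assumptions, parameter choices, limitations |
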