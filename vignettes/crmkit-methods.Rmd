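---
title: "crmkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crmkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmkit)
```

crmkit implements the desk-side computations used to dissect an enhancer
landscape around a developmental gene: 4C-seq viewpoint profiling,
cross-species detection of cis-regulatory modules (CRMs), conservation
calling, binding-site identification and disruption, and small-sample
expression statistics. This vignette explains each model, the parameters
that matter, and the choices made where the design was genuinely open.

## 4C-seq fragment model

Chromosome conformation capture with sequencing (4C-seq) measures how
often one anchor locus — the viewpoint, here a gene promoter — contacts
the rest of the genome. The computational unit is the restriction
fragment of the primary enzyme.

**Digestion.** `digest()` cuts at every occurrence start of the primary
motif (DpnII `GATC` by default). Both default motifs are palindromic, so
a forward-strand scan finds every site, and the blunt `^GATC` cut makes
the occurrence start a natural boundary. Fragments tile each chromosome
exactly: the first starts at 0, the last ends at the chromosome length,
and fragment *k*'s end is fragment *k+1*'s start. A fragment is **valid**
iff it contains at least one secondary-enzyme site (NlaIII `CATG`) and is
at least `min_length = 20` bp long — fragments failing either cannot be
interrogated by the double-digestion protocol and are excluded from all
counting.

**Read filtering and assignment.** Reads must begin with the viewpoint
primer (0 mismatches by default); the primer is trimmed. A trimmed read
is located in the genome by exact matching and assigned to the valid
fragment whose boundary coincides with the match: forward matches at a
fragment start, reverse-oriented matches ending at a fragment end — both
ends of a fragment are eligible because ligation can occur at either
DpnII site. Reads matching nowhere, away from boundaries, or only on
invalid fragments are tallied as unassigned; reads matching more than one
valid boundary are dropped as ambiguous rather than fractionally
assigned, a conservative and deterministic choice.

**Exclusion and normalisation.** The viewpoint fragment, one adjacent
(undigested-neighbour) fragment on each side, and every fragment
overlapping viewpoint ± `exclusion_radius` (default 10 kb) are excluded,
as is anything outside the analysis interval; the remainder are the
*informative* fragments. The profile value at informative fragment *i* is
the mean raw count over a centred window of `window_width = 5`
informative fragments, scaled by `1e6 / total_mapped` (reads per
million). Two open points were settled as follows: the RPM denominator is
the count sum over informative fragments of the analysed region (a config
switch could widen it to the whole library, but a region-restricted total
makes genotype profiles comparable after exclusion); and windows shrink
symmetrically at the profile edges, since edge handling is otherwise
unspecified. Genotype comparison subtracts normalised RPM values
fragment-by-fragment (positive = gain in the first profile); profiles
must share a library and mask, and subtraction after normalisation keeps
libraries of different depth comparable.

Coordinates are 0-based half-open throughout; browser-style region
strings (`"chr2:113326224-113894862"`, 1-based inclusive) are converted
on parsing — that example spans 568,639 bp.

**ATAC-style track.** `atac_rpkm()` counts both 5'-ends of each fragment
(plus-strand end = start, minus-strand end = last base) into fixed 10-bp
bins; the per-bin value is `count / (library_size * bin_size) * 1e9`.

## BBH orthology detection

Orthologous CRMs are detected by a modified bidirectional-best-hit
procedure: (1) search the CRM sequence against the target genome and
keep hits with E-value below 1e−5; (2) take the top hit, extract its
target interval widened by the unaligned query flank lengths plus 20 nt
per side (to absorb indels), clipped to the chromosome; (3) search the
extract back against the source genome; (4) score "detected" iff the
best reciprocal hit overlaps the original CRM by at least 1 bp.

Two readings were open. First, whether forward hits beyond the top one
seed reciprocal searches: only the top hit does, which is deterministic
and standard BBH practice. Second, whether any reciprocal hit or only
the best one decides: the best one does — this is what makes the
procedure a reciprocity test at all, since a paralog more similar to the
extract than the original CRM then correctly breaks detection. The 20-nt
extension is applied after flank addition.

The built-in engine is an ungapped seed-and-extend search: 11-nt exact
seed words, match +1 / mismatch −2, X-drop 20, Karlin–Altschul E-values
`E = K m n e^{-λ S}` with λ = 1.28, K = 0.46 (the published constants
for that scoring). The engine is a plug point — `bbh_detect(engine =
...)` accepts any function with the same signature, so an external
search tool can replace it without touching the procedure. Ungapped
extension is sufficient for the package's substitution-only divergence
model; under the optional indel model, orthologs are still found through
the strongest ungapped segment.

## Conservation

`trim_msa()` reproduces the standard block-trimming rule: columns with
more than 50 % gaps are removed, then surviving runs of consecutive
columns shorter than 10 are removed; the column map back into the input
is returned, and the operation is idempotent.

`conservation_windows()` computes VISTA-style percent identity on a
pairwise alignment in sliding windows of 100 reference positions,
clamped at the ends. Columns where the reference carries a gap do not
advance the reference coordinate but count as mismatches within the
window span — mirroring identity-against-reference plotting. Positions
at ≥ 70 % identity merge into conserved-region calls; calls shorter than
`min_call_length` (default: one window length, since the tool's "default
settings" do not pin this) are dropped. `global_align()` provides the
desk-scale (≤ 50 kb) Needleman–Wunsch alignment with affine gaps behind
this, with deterministic tie-breaking from the underlying dynamic
program.

## Binding sites and mutagenesis

A PWM is built from a count matrix with per-column probabilities
`(count + pc·bg) / (colsum + pc)` (pseudocount `pc = 0.1`; the source
protocol does not state one) and log-odds `log2(p / bg)`. The background
defaults to uniform 0.25 per base and is configurable — a genome-derived
background is legitimate but the scan tool's setting was unstated, and
uniform keeps p-values analytic. Scores are discretised on a 1e−3
log-odds grid; the exact distribution of the score of a random
background k-mer is obtained by dynamic-programming convolution over
columns, giving `p(s) = P(S ≥ s)` without approximation (the test suite
checks it against exhaustive k-mer enumeration to 1e−9). Scanning
reports every window on either strand with p below the cutoff (0.01, the
conventional binding-site threshold), with coordinates always on the
forward frame; the threshold is applied per window on each strand.
Overlapping sites between two motif sets are strand-agnostic ≥ 1 bp
interval intersections merged into maximal regions, and fully conserved
alignment columns require all sequences to agree with no gap in any
sequence — a gap is never "100 % conserved".

**Mutagenesis design.** The goal is a minimal set of substitutions after
which a full both-strand rescan with every PWM finds no site — neither
residual nor de novo. The designer is greedy: for each site, columns are
considered in decreasing information content and the substitution is the
base of lowest log-odds (ties alphabetical; minus-strand sites edit the
complement at the mirrored position). Two refinements proved necessary
and are deliberate design choices rather than spec-stated rules. First,
a candidate substitution is committed only if no site covers the edited
position afterwards (checked by a local rescan): the naive lowest-odds
edit of an AT-rich motif routinely creates the same motif on the
opposite strand, and an unguarded loop oscillates between strands
indefinitely. Second, when no locally clean candidate exists, the
fallback is the first strictly score-lowering greedy edit, so repeated
rounds always make progress instead of re-editing a spent column. Each
round ends with a full rescan; residual and de-novo hits feed the next
round, and non-convergence within `max_rounds = 10` is an explicit
failure listing the surviving sites. Accepted plans are re-verified by
`verify_mutagenesis()`, whose clean/not-clean verdict is the
ground-truth oracle for the whole designer. A user-supplied edit list
(for instance, published mutant constructs) can be checked with the same
verifier.

## Expression statistics

`ddcq_fold_change()` implements relative quantification with a reference
gene: per sample ΔCq = Cq(target) − Cq(reference); per group ΔΔCq =
ΔCq − mean(ΔCq of control), fold = 2^−ΔΔCq. Centring uses the
control-group arithmetic mean of ΔCq (the centring statistic is not
dictated by the protocol); because that fixes the *geometric* control
mean at 1, per-sample folds are then rescaled by the control group's
arithmetic mean fold so that the reported control mean fold is exactly 1
by construction. The rescaling is a positive constant, so rank-based
testing is unaffected.

`mann_whitney_exact()` enumerates all C(n₁+n₂, n₁) assignments of the
pooled ranks (capped at n₁+n₂ ≤ 24), computes U = #{(xᵢ, yⱼ): xᵢ < yⱼ},
and doubles the smaller tail, capping at 1. Tail doubling is adopted as
canonical because it reproduces the printed reference p-values at
n = 7/7: 2/3432 = 0.000583 for complete separation, 0.011072 at a
min-tail U of 5, 0.017483 at 6. Ties are a hard error directing to
`mann_whitney_permutation()` (midranks would silently change the exact
distribution); the permutation fallback uses the add-one corrected
(r+1)/(n_perm+1) estimate on the deviation |U − n₁n₂/2|.

## Synthetic data: what it emulates and what it does not

All generators derive their RNG streams from one integer seed via
`split_seed()`, so any stage can be re-run in isolation bit-for-bit.

- `make_genome()` draws i.i.d. bases at a given GC content; at GC 0.5 a
  4-bp motif occurs every ~256 bp, matching the fragment-size scale of a
  real DpnII digest.
- `evolve_crm()` mutates along a rooted tree under Jukes–Cantor
  (probability ¾(1−e^{−4t/3}) that a site differs after t subs/site),
  chosen because the expected divergence is analytically checkable;
  indels are off by default and available at a small rate for orthology
  stress tests.
- `simulate_4c_reads()` draws captured fragments with probability
  ∝ (1+|d|)^−α (α = 1 default; d = fragment midpoint to viewpoint),
  restricted to informative fragments, and emits primer-prefixed reads
  starting at a fragment boundary, with a configurable decoy fraction
  carrying a corrupted primer. Ligation-junction chimeras, PCR
  duplicates and sequencing errors are *not* modelled — the model is
  fragment-end based because that is exactly what the counting stage
  assigns, and it exercises every downstream filter.
- `simulate_cq()` writes target Cq = baseline − log2(fold) + Gaussian
  noise and a group-independent reference gene, so zero-noise runs
  recover specified fold changes exactly.

Because the genome is i.i.d. and reads are noise-free exact matches,
passing tests demonstrate the correctness of the computational chain —
not robustness to mapping artefacts, repeats, chimeric reads or
amplification bias in real libraries.

## Problem sizes and numerical notes

The test-suite and the end-to-end examples run at deliberately desk
scale: 20–150 kb genomes, 10³–10⁵ reads, 400–600 bp CRMs in 15–30 kb
genomes for orthology (20 seeded replicates per divergence rate),
100 seeded 400-bp sequences for mutagenesis closure, and full
enumeration at n = 7/7 for the rank test. These sizes give stable
statistical behaviour (e.g. smoothed-RPM rank correlation with true
capture probabilities exceeds 0.9 at 10⁵ reads) while keeping a full
check-run in minutes. PWM p-values are exact on the 1e−3 score grid;
coordinates are integers throughout; profile smoothing uses cumulative
sums (no floating-point window drift); and all E-values use the total
target length as the search-space factor on both strands.

## Known limitations

- The local search engine is ungapped; heavily indel-riddled orthologs
  are found only through their longest conserved segment.
- Exact binding-site counts on real enhancers depend on the exact ChIP
  matrix used; with a different Gli matrix the per-sequence site count
  will differ even at the same p cutoff.
- The Mann–Whitney enumeration is limited to 24 samples; larger designs
  use the permutation fallback.
- `global_align()` is quadratic and capped at 50 kb per sequence; whole
  genomic landscapes should be aligned with dedicated chained aligners
  upstream and imported as aligned FASTA.
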