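---
title: "Methods: multi-omics statistics for C4 gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics statistics for C4 gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4omics)
```

## Scope and model

`c4omics` implements the statistical core of a cross-species multi-omics
analysis of C4 photosynthesis gene regulation in the *Flaveria* genus, where
five closely related species span the C3 -> C3-C4 intermediate -> C4
transition. The question the statistics address is mechanistic: when a C4
pathway gene ends up with more protein in the C4 species, is that driven by
transcription (more mRNA), by translation (more ribosome loading per mRNA),
or by protein turnover? The package answers it with ratio statistics layered
over three abundance measurements per gene:

* **PTR** (protein-to-mRNA ratio): iBAQ protein abundance divided by TPM
  transcript abundance, per gene per species. If protein rises mainly
  because mRNA rises, PTR *falls* for the up-regulated genes.
* **TE** (translation efficiency): ribosome-protected-fragment (RPF)
  abundance over RNA abundance from matched Ribo-seq/RNA-seq. Unchanged TE
  under rising RNA implicates transcription, not translation.
* **Protein-to-RPF ratio**: the remaining link from ribosome loading to
  steady-state protein.

Two sequence-level classifiers support the same argument: GC3 (third-codon
G+C, a known correlate of translation efficiency) and a scanner for the
retroduplication signature — an inverted-repeat pair flanked by a short
direct-repeat target-site duplication (TSD) — that marks
retrotransposon-mediated gene copies. A cis-regulatory layer tests which
known CREs are over-represented among motif occurrences in accessible
chromatin (ATAC-seq ACRs) associated with the C4 gene set, and a
regulatory-network layer filters TF -> gene edges by cognate promoter CREs
and summarizes TF families.

All of this runs end-to-end on a synthetic generator with recorded ground
truth, so every stage is testable without the multi-gigabase deposited
datasets.

## Abundance model and detection

Abundance tables are genes x samples with `SPECIES_R<k>` columns. Missing
protein/RPF values are *absent* (`NA`), never zero: iBAQ non-detection is
censoring. Ratio stages require detection in both roles; the detection floor
defaults to species-mean TPM >= 1 for TPM roles and any positive iBAQ for
protein. The floors are configurable (`run_config(min_tpm = ...)`) because
the underlying studies report detected-gene counts without stating floors.

PTR classes use the mean +/- 1 SD rule; the package computes them on
log10(PTR) by default. Abundance ratios span decades and are right-skewed on
the linear scale, where mean +/- SD thresholds would be dominated by the
upper tail; `run_config(ptr_log_scale = FALSE)` restores linear-scale
thresholds. Thresholds are computed per species (species differ in detected
gene sets and dynamic range); this is a package choice, not asserted as the
original authors' — pooled thresholds would shift class counts by a few
percent.

TE and protein-to-RPF classes instead use exact tails: `floor(frac * n)`
genes per tail (default 5%), with ties at the cutoff broken by ascending
gene identifier so classification is deterministic. The TE normalizer is the
arithmetic mean of raw TE over photosynthesis genes excluding the C4 set
("mean" is the stated summary; the scale is a package choice, with
`te_normalizer = "median"` available). By construction the mean normalized
TE over that set is exactly 1 per species, making distributions comparable
across species.

## Gene-set comparisons

`compare_groups()` runs one-way ANOVA across species, then all pairwise
two-tailed Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment over
the pairwise family of one analysis. The ANOVA acts as a gate (alpha 0.05,
configurable): pairwise rows are flagged `gated` rather than suppressed when
the omnibus test is not significant, because the gate's alpha is a
convention, not part of the test statistics. `resample_null()` implements
the size-matched control: 100 draws of 14 random classified genes per
species, whose per-draw mean log10 PTR distributions should show no
between-species effect when the gene-set effect is real rather than a
normalization artifact.

## CRE enrichment in accessible chromatin

Occurrences of known CREs inside ACRs (a FIMO-dialect table filtered at
q <= 0.05) are assigned genomic contexts per gene: `gACR` (overlapping the
gene body), `upACR` (within 3 kb upstream of the start codon), `downACR`
(within 3 kb downstream of the stop codon), strand-aware from the codon
anchors. An occurrence may label several genes; it counts **once** toward k
(the target-associated total) if any of its labels hits the target set,
because the counting unit is the occurrence, not the label.

The null asks: if k occurrences were picked at random from the N-occurrence
background pool, how often would CRE c appear at least as often as observed?
Each of B = 1000 permutations draws k occurrences *without replacement*
(an exact multivariate hypergeometric draw, implemented as sequential
conditional hypergeometric sampling so permutation counts always sum to k).
Whether the original procedure drew with or without replacement is not
stated; "selected from the pool" reads as without, and at pool scale the two
are nearly indistinguishable. The permutation preserves only occurrence
counts, not ACR spatial structure — a known limitation of this null.

The default p estimator is `(1 + #{count_b >= k_c}) / (B + 1)`. The literal
"proportion of permutations surpassing the observed value" (strict `>`,
divided by B) is available as `p_mode = "strict_paper"`, but it can return
p = 0, and in the degenerate single-CRE pool — where every permutation
reproduces the observed count exactly — it declares certainty from no
evidence, so it is not the default. Fisher's exact test (one-sided,
hypergeometric tail) on the 2x2 table
`[k_c, k - k_c; n_c - k_c, (N - n_c) - (k - k_c)]` is the analytic
cross-check; the two methods' -log10 p rank-correlate above 0.99 on spiked
synthetic pools. The sample odds ratio gets a 0.5 continuity correction
(flagged) when a cell is zero. BH q-values are computed per method;
"enriched" means permutation q < 0.05.

## Retroduplication signature scanner

A signature is a maximal inverted-repeat pair with an exact direct repeat
immediately outside it. The scanner walks anti-diagonals of the implicit
complementarity matrix (`s[p] == comp(s[q])` with `p + q` constant), where
maximal complementary runs are maximal inverted repeats; arms are kept
disjoint (spacer >= 0) and within `max_spacer`. For each maximal pair the
largest TSD length `t` in `tsd_range` with identical, N-free flanking copies
is reported. With a mismatch budget, maximal windows with at most
`max_mismatch` non-complementary positions (match-anchored at both ends) are
used instead. Score is `L + t - 2 * mismatches`; ties rank leftmost-first so
output order is deterministic. Defaults are `min_ir = 6` and
`tsd_range = c(3, 6)`: deliberately below/around the published 9-bp repeat
and 4-bp TSD, so recovering that geometry is a discovery of the scanner, not
an assumption. The TSD sits *outside* the inverted repeats (the standard
TSD geometry); the alternative inside-geometry was considered and rejected
as inconsistent with the insertion mechanism that creates TSDs.

The functional-paralog rule implements the two transcript criteria: the
candidate must (1) have the highest TPM among the group's members in
C4-type species and (2) exceed the strongest C3-species counterpart; ties
return no call. "Counterpart" within a multi-member group is taken as the
maximum C3-species member — the strictest reading. Experimental
verification (light-induction time courses) is out of scope by design.

## The synthetic generator

The generator is the package's study stand-in, not a fixture. Its defaults
*are* the emulated study conditions:

* five species — `Frob` (C3), `Fson`/`Fram`/`Flin` (C3-C4), `Ftri` (C4) —
  with 6 RNA/protein replicates and 2 Ribo-seq replicates for `Frob`/`Ftri`;
* gene-level log10-normal RNA (mean 1.5, SD 0.5 on log10 TPM ~ median
  30 TPM); per-gene log10-normal PTR and TE (SD 0.3) shared across species;
  protein and RPF coupled to the species RNA mean (proteomics and RNA-seq
  replicates are unpaired in such designs, so coupling per replicate would
  fake a pairing that does not exist);
* C4-set effects in the C4 species: RNA x10 (the reported ~10-fold
  activity/abundance increase), protein x3 — so the true PTR ratio is
  G/F = 0.3 and true TE is unchanged, reproducing the study's logical
  chain (lower PTR and protein-RPF ratio, comparable TE) at desk scale;
* replicate noise SD 0.1 on log10 per role. No quantitative iBAQ noise
  model is published; 0.1 is a realistic within-condition spread and is the
  condition under which parameter recovery is tested;
* a CRE pool of N = 100,000 occurrences of 50 CREs with Dirichlet
  (concentration 10) background frequencies and k = 2,000 target-associated
  draws — the pool-scale geometry at which the permutation null is
  calibrated — plus a coordinate-level dataset (60 genes, three ACRs each in
  the three contexts, 30 distal ACRs, 6,000 occurrences) whose geometry
  makes every ACR-gene association unambiguous, so expected pool counts are
  exact ground truth;
* planted retro-signatures whose spacer terminal bases and flanking guard
  bases are resampled so the planted repeat can extend neither inward nor
  outward: the recorded geometry is exact, not a lower bound;
* a TF network of 100 TFs over 2,000 genes, cognate fraction 0.6, and ERF
  edges onto the C4 set over-weighted x20 — large enough gene space that
  same-family CRE collisions keep the realized post-filter retention within
  a few percent of the cognate fraction.

What the generator does **not** emulate: read-level noise, mappability and
quantification bias, compositional (TPM renormalization) coupling between
genes, correlated replicates, ACR spatial clustering, motif sequence
content (occurrences are labels, not matched sequences), and ortholog
mapping across genomes (a shared gene namespace is assumed; real
cross-species tables require an ortholog map upstream). Passing tests
therefore validate the statistics and their implementations under the
stated generative model — not the upstream bioinformatics.

## Numerical and I/O conventions

Internal coordinates are 0-based half-open everywhere; GFF3 and FIMO
(1-based inclusive) are converted at the boundary, BED passes through. On
the minus strand the start codon anchors at the highest CDS coordinate and
"upstream" runs toward larger coordinates. Weighted without-replacement
sampling (occurrence spiking) uses exponential sorting keys
(Efraimidis-Spirakis), which is O(N log N) and exact. All generators and
every stochastic stage are pure functions of (config, seed); permutation
p-values are reproducible from `(pool, B, seed)`. Degenerate inputs are
defined, not accidental: identical values classify as all-moderate (SD 0);
constant rows Z-score to zeros and are flagged; sequences too short for any
signature return an empty result rather than an error; a species with fewer
than two classified PTR values gets `NA` classes.

## Problem sizes

The shipped analyses and tests use 2,000 genes x 5 species, pools of
100,000 occurrences with B = 1000 permutations, 20-seed replication for the
pattern-recovery and calibration checks, 50 x 300 bp sequences for the
scanner-vs-enumeration equivalence, and 1,000 CDS for the GC3 oracle —
sizes at which the exhaustive oracles are exact and the whole suite runs in
a couple of minutes on one core.

## Known limitations

Ortholog mapping, read processing, peak calling and motif scanning are
inputs, not computations. The permutation null ignores spatial structure of
ACRs. Per-species classification thresholds and the without-replacement
permutation are documented choices where the original description is
silent; both alternatives are one configuration flag away.
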