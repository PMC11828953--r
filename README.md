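# c4omics

Multi-omics statistics for the regulation of C4 photosynthesis genes.

When a C4 pathway gene carries more protein in a C4 species than in its C3
relatives, is that extra protein made by transcribing more mRNA, by
translating each mRNA harder, or by slower turnover? `c4omics` implements
the statistics that separate these mechanisms across species, plus the
sequence- and chromatin-level classifiers that accompany them:

* **Protein-to-mRNA ratio (PTR)** — per gene and species,
  `PTR = iBAQ / TPM`, with mean ± 1 SD classes on log10 PTR, row-wise
  Z-score normalization for heatmaps, log-scale Pearson correlation, and
  gene-set comparisons by one-way ANOVA followed by two-tailed Wilcoxon
  rank-sum tests with Benjamini–Hochberg adjustment, controlled by a
  100 × 14-gene resampling null. Transcription-driven up-regulation shows
  up as *lower* PTR for the up-regulated set.
* **Translation efficiency (TE)** — `TE = RPF / RNA` from Ribo-seq,
  normalized by the mean TE of photosynthesis genes excluding the C4 set,
  with exact top/bottom-5% classes (`floor(0.05·n)` per tail) and
  between-species set tests; protein-to-RPF ratios complete the chain.
* **CRE enrichment in accessible chromatin** — motif occurrences in ATAC
  peaks are context-labeled (genic / ≤3 kb upstream of the start codon /
  ≤3 kb downstream of the stop codon, strand-aware), pooled, and tested per
  CRE by a Monte Carlo permutation null (B = 1000 draws of k occurrences
  from the N-occurrence pool, without replacement) cross-checked by
  one-sided Fisher's exact tests, with BH FDR.
* **Sequence classifiers** — GC3 (third-codon G+C), a scanner for
  retroduplication signatures (maximal inverted-repeat pairs flanked by a
  direct-repeat target-site duplication), and the two-criterion
  functional-paralog rule based on transcript abundance.
* **Regulatory-network summaries** — cognate-CRE filtering of TF→gene
  edges, C4 sub-network extraction, TF-family counts and the
  ERF-per-C4-gene rate.

A synthetic multi-omics generator (`sim_config()`, `gen_*()`) emulates the
five-species study design with recorded ground truth, so the entire
pipeline is exercised and tested without any external download.

## Worked example

Plant the published retroduplication motifs — the 9-bp inverted repeat
`AAAATAAAG` (reverse complement `CTTTATTTT`) flanked by the `TTTT` direct
repeat — into a random background and rediscover them with default scanner
settings (minimum repeat 6 bp, TSD range 3–6 bp, i.e. below the planted
geometry):

```r
library(c4omics)
set.seed(1)
bg <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
pl <- plant_retro_signature(bg, pos = 100, ir = "AAAATAAAG",
                            tsd = "TTTT", spacer = 120)
find_inverted_repeat_tsd(pl$seq)[1, ]
#>   left_start left_end right_start right_end ir_len spacer_len tsd_len
#> 1        104      113         233       242      9        120       4
#>   mismatches    ir_seq tsd_seq score
#> 1          0 AAAATAAAG    TTTT    13
```

The scanner reports the inverted repeat at 9 bp and the target-site
duplication at 4 bp — the signature of a retrotransposon-mediated gene
copy.

The full analysis sequence lives under `analysis/` (each script states what
it finds and writes tables under `results/`):

```sh
Rscript analysis/01_simulate.R              # synthetic five-species study
Rscript analysis/02_ptr.R                   # PTR classes + gene-set tests
Rscript analysis/03_translation_efficiency.R
Rscript analysis/04_cre_enrichment.R        # permutation + Fisher enrichment
Rscript analysis/05_sequence_features.R     # GC3, scanner, functional copies
Rscript analysis/06_grn_summary.R           # cognate filtering, TF families
```

Representative output (stage 2, seed 1): the C4 gene set's PTR is
significantly lower in the C4-type species against every other species
(adjusted p ≤ 0.006), the photorespiratory set shows no shift (adjusted
p ≈ 0.96), and the 14-gene resampling control is non-significant (ANOVA
p ≈ 0.34) — the pattern expected when transcription drives the protein
increase. Stage 4 recovers exactly the three ERF-family CREs spiked into
the accessible chromatin of the target genes, with the permutation and
Fisher p-values in near-perfect rank agreement (Spearman ≈ 0.998).

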