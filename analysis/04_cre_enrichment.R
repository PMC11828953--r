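#!/usr/bin/env Rscript
# Stage 4: CRE enrichment in accessible chromatin associated with the
# target (C4) gene set. Reads the FIMO-dialect occurrences, ACR BED and
# gene-model GFF3 emitted by stage 1, assigns genomic contexts
# (gACR/upACR/downACR, 3 kb strand-aware windows), builds the occurrence
# pool, and tests each CRE by Monte Carlo permutation (B = 1000) and
# Fisher's exact test with BH correction.

suppressPackageStartupMessages(library(c4omics))

cfg <- run_config(seed = 1, B = 1000)
data_dir <- "results/data"
if (!file.exists(file.path(data_dir, "fimo.tsv"))) {
  stop("run analysis/01_simulate.R first")
}
ann <- load_genome_annotations(file.path(data_dir, "genes.gff3"),
                               file.path(data_dir, "acrs.bed"))
occ <- read_fimo(file.path(data_dir, "fimo.tsv"), q_max = cfg$fimo_q_max)
occ <- occurrences_to_genomic(occ, ann$acrs)
sets <- read_gene_sets(file.path(data_dir, "gene_sets.tsv"))
# stage-1 CRE geometry uses its own compact target list: the leading genes
target <- gene_set("c4", grep("^g0", ann$genes$gene_id, value = TRUE)[1:12])

labels <- assign_context(occ, ann$genes, window = cfg$window_bp)
cat(sprintf("%d occurrences; context labels: %s\n", nrow(occ),
            paste(names(table(labels$context)), table(labels$context),
                  sep = "=", collapse = ", ")))

pool <- build_pool(occ, labels, target)
cat(sprintf("Pool: N = %d occurrences of %d CREs; k = %d target-associated\n",
            pool$N, length(pool$n_c), pool$k))

res <- cre_enrichment(pool, cfg)
fam <- stats::setNames(sub("_like_.*$", "", res$cre_id), res$cre_id)
sm <- summarize_enriched(res, family_map = fam)
cat(sprintf("%d CREs enriched at permutation q < 0.05\n", sum(res$enriched)))
if (nrow(sm$cres) > 0) {
  print(sm$cres[order(-sm$cres$observed), ])
}
cat(sprintf("Spearman agreement between -log10 p of the two methods: %.3f\n",
            cor(-log10(res$p_perm), -log10(res$p_fisher), method = "spearman")))

write_results(list(enrichment = res, enriched_summary = sm$cres),
              "results/cre", cfg, overwrite = TRUE)
cat("Tables written to results/cre\n")
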