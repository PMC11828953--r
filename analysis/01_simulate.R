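#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-omics study.
#
# Emulates the five-species design (one C3, three C3-C4 intermediates, one
# C4): RNA and protein for all species (6 replicates), Ribo-seq for the C3
# and C4 representatives (2 replicates), a CRE occurrence pool over
# accessible chromatin with genic/upstream/downstream geometry, CDS with
# controlled GC3, fragments with planted retroduplication signatures, and a
# TF-target network. All files land in results/data/ and are the inputs of
# every later stage.

suppressPackageStartupMessages(library(c4omics))

# ERF-family CREs are spiked among target-gene ACR occurrences, emulating
# the ERF enrichment the enrichment stage is designed to detect
cfg <- sim_config(seed = 1,
                  spike_cres = c("ERF_like_1", "ERF_like_6", "ERF_like_11"),
                  spike_mult = 3)
outdir <- "results/data"
write_synthetic_dataset(cfg, outdir)

om <- gen_multiomics(cfg)
cat("Synthetic study written to", outdir, "\n")
cat(sprintf("  %d genes x %d species; gene sets: c4=%d, photosynthesis=%d, photorespiratory=%d\n",
            cfg$n_genes, nrow(cfg$species),
            length(om$sets$c4$members),
            length(om$sets$photosynthesis$members),
            length(om$sets$photorespiratory$members)))
cat(sprintf("  C4-set effects in the C4 species: RNA x%g, protein x%g (true PTR ratio %g)\n",
            cfg$c4_rna_fold, cfg$c4_protein_fold,
            cfg$c4_protein_fold / cfg$c4_rna_fold))
cat(sprintf("  CRE geometry: %d genes, %d occurrences placed in ACRs\n",
            cfg$n_cre_genes, cfg$n_geom_occ))
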