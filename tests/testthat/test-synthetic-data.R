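test_that("noise-free generator obeys its closed-form effect sizes", {
  cfg <- sim_config(seed = 5, n_genes = 200, noise_sd = c(rna = 0, protein = 0, rpf = 0),
                    c4_rna_fold = 10, c4_protein_fold = 3)
  om <- gen_multiomics(cfg)
  c4 <- om$sets$c4$members
  # realized PTR of every C4 gene in the C4 species is exactly G/F times its
  # value in a non-C4 species
  ptr_c4 <- om$truth$ptr[c4, "Ftri"]
  ptr_c3 <- om$truth$ptr[c4, "Frob"]
  expect_equal(unname(ptr_c4 / ptr_c3), rep(0.3, length(c4)))
  # true TE unchanged by the C4 folds
  expect_equal(om$truth$te[, "Ftri"], om$truth$te[, "Frob"])
  # replicate values equal truth when noise is off
  expect_equal(unname(om$tables$rna$values[, "Ftri_R1"]),
               unname(om$truth$rna[, "Ftri"]))
})

test_that("generators are pure functions of the config", {
  cfg <- sim_config(seed = 9, n_genes = 150)
  a <- gen_multiomics(cfg)
  b <- gen_multiomics(cfg)
  expect_identical(a$tables$rna$values, b$tables$rna$values)
  expect_identical(a$tables$protein$values, b$tables$protein$values)
  p1 <- gen_occurrence_pool(cfg)
  p2 <- gen_occurrence_pool(cfg)
  expect_identical(p1$pool$k_c, p2$pool$k_c)
  s1 <- gen_sequences(cfg)
  s2 <- gen_sequences(cfg)
  expect_identical(as.character(s1$fragments), as.character(s2$fragments))
})

test_that("log10 RNA sample mean is within 3 SE of the configured mean", {
  cfg <- sim_config(seed = 2, n_genes = 2000, rna_mu = 1.5, rna_sigma = 0.5)
  om <- gen_multiomics(cfg)
  lm_ <- log10(om$truth$rna[, "Frob"])
  se <- 0.5 / sqrt(2000)
  expect_lt(abs(mean(lm_) - 1.5), 3 * se)
})

test_that("occurrence pool conserves counts and spikes bias the target draw", {
  pp <- gen_occurrence_pool(sim_config(seed = 4))
  expect_equal(sum(pp$pool$n_c), 100000L)
  expect_equal(sum(pp$pool$k_c), 2000L)
  expect_true(all(pp$pool$k_c <= pp$pool$n_c))

  # spiked CRE over-represented among target draws in every tried seed
  hits <- vapply(1:25, function(s) {
    p <- gen_occurrence_pool(sim_config(
      seed = s, n_cre = 20, n_occurrences = 20000, n_target_occ = 1000,
      spike_cres = "ERF_like_1", spike_mult = 5))$pool
    (p$k_c[["ERF_like_1"]] / p$k) > (p$n_c[["ERF_like_1"]] / p$N)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("unspiked target draws are unbiased (chi-square GOF calibration)", {
  pvals <- vapply(1:15, function(s) {
    p <- gen_occurrence_pool(sim_config(seed = 50 + s, n_cre = 20,
                                        n_occurrences = 50000,
                                        n_target_occ = 1000))$pool
    suppressWarnings(stats::chisq.test(p$k_c, p = p$n_c / p$N)$p.value)
  }, numeric(1))
  # roughly uniform: no mass collapse at 0, Kolmogorov-style sanity bound
  expect_gt(min(pvals), 1e-4)
  expect_gt(mean(pvals > 0.1), 0.5)
})

test_that("coordinate-level CRE dataset matches its recorded ground truth", {
  cd <- gen_cre_dataset(sim_config(seed = 3, spike_cres = "ERF_like_1",
                                   spike_mult = 4))
  expect_equal(sum(cd$truth$n_c), nrow(cd$occurrences))
  lab <- assign_context(cd$occurrences, cd$genes)
  pool <- build_pool(cd$occurrences, lab, cd$target_set)
  present <- names(cd$truth$n_c)[cd$truth$n_c > 0]
  expect_equal(unname(pool$n_c[present]), unname(cd$truth$n_c[present]))
  expect_equal(unname(pool$k_c[present]), unname(cd$truth$k_c[present]))
  # all three context categories planted
  expect_setequal(unique(lab$context), c("gACR", "upACR", "downACR"))
})

test_that("planted CDS hit the target GC3 and planted signatures are findable", {
  sq <- gen_sequences(sim_config(seed = 6, n_cds = 40, cds_codons = 250,
                                 gc3_target = 0.5))
  vals <- gc3(sq$cds)
  pooled <- mean(vals)
  expect_lt(abs(pooled - 0.5), 0.02)  # 10,000 codons, binomial SE ~ 0.005

  all_gc <- gc3(as.character(gen_sequences(sim_config(seed = 7, gc3_target = 1))$cds))
  expect_true(all(all_gc == 1))

  # planted coordinates match a direct string search of the emitted FASTA
  frag <- as.character(sq$fragments)
  for (i in seq_len(nrow(sq$truth$planted))) {
    tr <- sq$truth$planted[i, ]
    s <- frag[[tr$seq_id]]
    expect_identical(substr(s, tr$ir_left_start + 1, tr$ir_left_end), tr$ir_seq)
    expect_identical(substr(s, tr$ir_right_start + 1, tr$ir_right_end),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(tr$ir_seq))))
    expect_identical(substr(s, tr$ir_left_start - tr$tsd_len + 1, tr$ir_left_start),
                     tr$tsd_seq)
  }
})

test_that("regulatory-network generator honours cognate fraction edge cases", {
  full <- gen_grn(sim_config(seed = 8, cognate_fraction = 1, n_tfs = 40))
  net <- grn(full$edges, full$tf_families, full$promoter_cres, full$cognate_map)
  expect_equal(nrow(filter_tfs_by_cognate_cre(net)$edges), nrow(full$edges))

  none <- gen_grn(sim_config(seed = 8, cognate_fraction = 0, n_tfs = 40))
  net0 <- grn(none$edges, none$tf_families, none$promoter_cres, none$cognate_map)
  expect_equal(nrow(filter_tfs_by_cognate_cre(net0)$edges), 0L)

  mid <- gen_grn(sim_config(seed = 12))
  netm <- grn(mid$edges, mid$tf_families, mid$promoter_cres, mid$cognate_map)
  frac <- nrow(filter_tfs_by_cognate_cre(netm)$edges) / nrow(mid$edges)
  expect_lt(abs(frac - 0.6), 0.15)
})

test_that("every emitted file is readable by the loaders without warnings", {
  d <- withr::local_tempdir()
  expect_no_warning(write_synthetic_dataset(sim_config(
    seed = 10, n_genes = 150, n_geom_occ = 800, n_cre = 15), d))
  expect_no_warning({
    bundle <- load_omics_bundle(c(rna = file.path(d, "rna.tsv"),
                                  protein = file.path(d, "protein.tsv"),
                                  rpf = file.path(d, "rpf.tsv")))
    sets <- read_gene_sets(file.path(d, "gene_sets.tsv"))
    ann <- load_genome_annotations(file.path(d, "genes.gff3"),
                                   file.path(d, "acrs.bed"))
    occ <- read_fimo(file.path(d, "fimo.tsv"), q_max = 0.05)
  })
  expect_equal(nrow(bundle$rna$values), 150L)
  expect_named(sets, c("c4", "photorespiratory", "photosynthesis"),
               ignore.order = TRUE)
  expect_equal(nrow(occ), 800L)
  # relative FIMO coordinates lift back onto the genome consistently
  gen_occ <- occurrences_to_genomic(occ, ann$acrs)
  expect_true(all(gen_occ$start >= ann$acrs$start[match(gen_occ$acr_id, ann$acrs$acr_id)]))
})

test_that("paralog-group generator's designated copy satisfies both criteria", {
  pg <- gen_paralog_groups(sim_config(seed = 13), n_groups = 12)
  sp <- sim_config()$species
  for (gid in unique(pg$groups$group_id)) {
    g <- pg$groups[pg$groups$group_id == gid, ]
    res <- identify_functional_copy(g, c4_species = sp$code[sp$type == "C4"],
                                    c3_species = sp$code[sp$type == "C3"])
    expect_identical(res$gene, unname(pg$truth$functional[gid]))
  }
})
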