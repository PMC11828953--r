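toy_genes <- function() {
  data.frame(
    gene_id = c("gP", "gM"), chrom = "chr1",
    start = c(10000L, 30000L), end = c(11000L, 31000L),
    strand = c("+", "-"),
    start_codon = c(10000L, 30999L), stop_codon = c(10999L, 30000L),
    has_cds = TRUE, stringsAsFactors = FALSE
  )
}

occ_at <- function(start, end, cre = "m1") {
  data.frame(cre_id = cre, acr_id = "a", chrom = "chr1",
             start = start, end = end, stringsAsFactors = FALSE)
}

test_that("context labels follow strand-aware windows with exact boundaries", {
  genes <- toy_genes()
  expect_equal(assign_context(occ_at(10500L, 10508L), genes)$context, "gACR")

  # + strand upstream window is [start_codon - 3000, start_codon)
  inside <- assign_context(occ_at(7000L, 7008L), genes)
  expect_true(any(inside$context == "upACR" & inside$gene_id == "gP"))
  at_edge <- assign_context(occ_at(6992L, 7000L), genes)   # ends exactly at boundary
  expect_false(any(at_edge$context == "upACR"))

  # - strand: upstream extends to larger coordinates from the start codon
  up_minus <- assign_context(occ_at(32000L, 32008L), genes)
  expect_true(any(up_minus$context == "upACR" & up_minus$gene_id == "gM"))
  dn_minus <- assign_context(occ_at(28000L, 28008L), genes)
  expect_true(any(dn_minus$context == "downACR" & dn_minus$gene_id == "gM"))

  far <- assign_context(occ_at(50000L, 50008L), genes)
  expect_equal(nrow(far), 0L)
})

test_that("context assignment agrees with the all-pairs oracle on random data", {
  set.seed(81)
  n_g <- 100
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:n_g),
    chrom = sample(paste0("chr", 1:3), n_g, TRUE),
    start = sample.int(2e5, n_g), strand = sample(c("+", "-"), n_g, TRUE),
    has_cds = sample(c(TRUE, TRUE, TRUE, FALSE), n_g, TRUE),
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + sample(500:3000, n_g, TRUE)
  genes$start_codon <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$stop_codon <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  occ <- data.frame(
    cre_id = "m", acr_id = "a",
    chrom = sample(paste0("chr", 1:3), 1000, TRUE),
    start = sample.int(2e5, 1000), stringsAsFactors = FALSE
  )
  occ$end <- occ$start + 8L
  got <- assign_context(occ, genes)
  want <- oracle_context(occ, genes)
  key <- function(df) sort(paste(df$occ_idx, df$gene_id, df$context))
  expect_identical(key(got), key(want))
})

test_that("pool construction counts multi-labeled occurrences once", {
  occ <- rbind(occ_at(10500L, 10508L, "m1"),   # genic in gP
               occ_at(7000L, 7008L, "m1"),     # upstream of gP
               occ_at(50000L, 50008L, "m2"))   # unassociated
  lab <- assign_context(occ, toy_genes())
  pool <- build_pool(occ, lab, gene_set("t", "gP"))
  expect_equal(pool$N, 3L)
  expect_equal(pool$k, 2L)
  expect_equal(unname(pool$k_c[c("m1", "m2")]), c(2L, 0L))

  # target = all genes -> k equals the number of labelled occurrences
  pool_all <- build_pool(occ, lab, gene_set("t", c("gP", "gM")))
  expect_equal(pool_all$k, 2L)
  expect_error(build_pool(occ, lab, gene_set("t", "absent")), "nothing to test")
})

test_that("degenerate single-CRE pool motivates the default p estimator", {
  pool <- occurrence_pool(c(only = 50L), c(only = 10L))
  pe <- permutation_enrichment(pool, B = 200, seed = 1)
  expect_true(all(attr(pe, "perm_counts") == 10L))
  expect_equal(pe$p_perm, 1)
  strict <- permutation_enrichment(pool, B = 200, seed = 1, p_mode = "strict_paper")
  expect_equal(strict$p_perm, 0)  # the literal rule claims certainty
})

test_that("permuted counts conserve k, match the hypergeometric mean, and are seed-stable", {
  pp <- gen_occurrence_pool(sim_config(seed = 82, n_cre = 30))
  pe <- permutation_enrichment(pp$pool, B = 1000, seed = 7)
  counts <- attr(pe, "perm_counts")
  expect_true(all(rowSums(counts) == pp$pool$k))
  expect_lt(mean(abs(pe$perm_mean - pe$expected) / pe$expected), 0.02)
  pe2 <- permutation_enrichment(pp$pool, B = 1000, seed = 7)
  expect_identical(pe$p_perm, pe2$p_perm)
  pe3 <- permutation_enrichment(pp$pool, B = 1000, seed = 8)
  expect_false(identical(pe$p_perm, pe3$p_perm))
})

test_that("null permutation p-values are calibrated on unspiked pools", {
  fr <- vapply(1:8, function(s) {
    pp <- gen_occurrence_pool(sim_config(seed = 600 + s))
    mean(permutation_enrichment(pp$pool, B = 500, seed = s)$p_perm <= 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.03)
})

test_that("Fisher enrichment equals direct hypergeometric tail sums", {
  pool <- occurrence_pool(c(a = 10L, b = 90L), c(a = 10L, b = 10L))
  fe <- fisher_enrichment(pool)
  expect_equal(fe$p_fisher[fe$cre_id == "a"], oracle_hyper_tail(10, 10, 100, 20))
  # cross-check against fisher.test on the same 2x2
  ft <- fisher.test(matrix(c(10, 10, 0, 80), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(fe$p_fisher[fe$cre_id == "a"], ft$p.value, tolerance = 1e-12)

  set.seed(83)
  pp <- gen_occurrence_pool(sim_config(seed = 83, n_cre = 12,
                                       n_occurrences = 5000, n_target_occ = 300))
  fe2 <- fisher_enrichment(pp$pool)
  want <- mapply(oracle_hyper_tail, pp$pool$k_c, pp$pool$n_c,
                 MoreArgs = list(N = pp$pool$N, k = pp$pool$k))
  expect_equal(fe2$p_fisher, unname(want), tolerance = 1e-9)

  # proportional counts give odds ratio 1
  prop <- occurrence_pool(c(a = 100L, b = 300L), c(a = 10L, b = 30L))
  expect_equal(fisher_enrichment(prop)$odds_ratio, c(1, 1))
})

test_that("BH adjustment equals the definitional step-up on random vectors", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(84)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
})

test_that("spiked CREs are recovered by both methods, which agree", {
  spk <- c("ERF_like_1", "bHLH_like_2", "MYB_like_3", "NAC_like_4", "C2H2_like_5")
  sens_p <- sens_f <- rho <- numeric(6)
  for (s in 1:6) {
    pp <- gen_occurrence_pool(sim_config(seed = 700 + s, spike_cres = spk,
                                         spike_mult = 3))
    res <- cre_enrichment(pp$pool, run_config(seed = 700 + s))
    sens_p[s] <- mean(res$q_perm[res$cre_id %in% spk] < 0.05)
    sens_f[s] <- mean(res$q_fisher[res$cre_id %in% spk] < 0.05)
    rho[s] <- cor(-log10(res$p_perm), -log10(res$p_fisher), method = "spearman")
  }
  expect_gte(mean(sens_p), 0.9)
  expect_gte(mean(sens_f), 0.9)
  expect_true(all(rho >= 0.9))
})

test_that("enrichment p is monotone in the observed count", {
  n_c <- stats::setNames(rep(100L, 10), paste0("c", 1:10))
  p_perm <- p_fish <- numeric(0)
  for (kc in c(2L, 5L, 10L, 15L)) {
    k_c <- stats::setNames(c(kc, rep(2L, 9)), names(n_c))
    pool <- occurrence_pool(n_c, k_c)
    p_perm <- c(p_perm, permutation_enrichment(pool, B = 400, seed = 5)$p_perm[1])
    p_fish <- c(p_fish, fisher_enrichment(pool)$p_fisher[1])
  }
  expect_true(all(diff(p_perm) <= 0))
  expect_true(all(diff(p_fish) < 0))
})

test_that("enriched-CRE summary reports log2 frequencies and family shares", {
  res <- data.frame(cre_id = c("e1", "e2", "x"), observed = c(8L, 16L, 4L),
                    q_perm = c(0.001, 0.01, 0.5), q_fisher = c(0.001, 0.01, 0.5))
  sm <- summarize_enriched(res, family_map = c(e1 = "ERF", e2 = "ERF", x = "MYB"))
  expect_equal(sm$cres$log2_freq, c(3, 4))
  expect_equal(sm$families$family, "ERF")
  expect_equal(sm$families$share, 1)

  none <- summarize_enriched(res[res$q_perm > 0.2, , drop = FALSE])
  expect_equal(nrow(none$cres), 0L)

  # ERF-spiked pools push the ERF share of enriched CREs above background
  pp <- gen_occurrence_pool(sim_config(
    seed = 85, spike_cres = c("ERF_like_1", "ERF_like_6", "ERF_like_11"),
    spike_mult = 3))
  res2 <- cre_enrichment(pp$pool, run_config(seed = 85))
  fam <- stats::setNames(sub("_like_.*$", "", res2$cre_id), res2$cre_id)
  sm2 <- summarize_enriched(res2, family_map = fam)
  bg_share <- mean(fam == "ERF")
  expect_gt(sm2$families$share[sm2$families$family == "ERF"], bg_share)
})
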