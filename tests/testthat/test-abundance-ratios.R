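make_pair <- function(rna_vals, prot_vals, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_along(rna_vals))
  rna <- abundance_table(matrix(rna_vals, ncol = 1,
                                dimnames = list(genes, "Fs_R1")), "rna")
  prot <- abundance_table(matrix(prot_vals, ncol = 1,
                                 dimnames = list(genes, "Fs_R1")), "protein")
  list(rna = rna, prot = prot)
}

test_that("PTR is protein mean over RNA mean with censoring, not imputation", {
  p <- make_pair(c(100, 50, 0.5, 200), c(200, NA, 40, 0))
  tab <- compute_ptr(p$rna, p$prot)
  expect_equal(tab$ptr[tab$gene == "g01"], 2.0)
  # protein absent -> excluded; RNA below floor -> excluded; zero protein -> excluded
  expect_setequal(tab$gene, "g01")
  expect_equal(attr(tab, "n_excluded"), 3L)
})

test_that("zero RNA mean with detected protein is excluded with a warning", {
  p <- make_pair(c(0, 100, 120, 90), c(10, 20, 30, 40))
  cfg <- run_config(min_tpm = 0)
  expect_warning(tab <- compute_ptr(p$rna, p$prot, cfg), "zero RNA")
  expect_false("g01" %in% tab$gene)
})

test_that("PTR on noise-free generator output equals ground truth exactly", {
  om <- gen_multiomics(sim_config(seed = 21, n_genes = 200,
                                  noise_sd = c(rna = 0, protein = 0, rpf = 0)))
  tab <- compute_ptr(om$tables$rna, om$tables$protein)
  idx <- cbind(match(tab$gene, rownames(om$truth$ptr)),
               match(tab$species, colnames(om$truth$ptr)))
  expect_equal(tab$ptr, unname(om$truth$ptr[idx]))
})

test_that("mean +/- m SD classification handles boundaries, degenerates and tails", {
  v <- c(0, 0, 0, 0, 10)  # mean 2, sd ~4.47
  cls <- classify_by_sd(v, m = 1)
  expect_equal(as.character(cls[5]), "high")
  # element exactly at the mean is moderate
  expect_equal(as.character(classify_by_sd(c(1, 2, 3), 1)[2]), "moderate")
  # all identical -> SD 0, everything moderate
  expect_true(all(classify_by_sd(rep(4, 5)) == "moderate"))
  # standard-normal tails approach the Gaussian tail probability
  set.seed(31)
  z <- rnorm(1e5)
  cls <- classify_by_sd(z, 1)
  expect_lt(abs(mean(cls == "low") - pnorm(-1)), 0.01)
  expect_lt(abs(mean(cls == "high") - pnorm(-1)), 0.01)
})

test_that("classes partition classified genes in every species", {
  om <- gen_multiomics(sim_config(seed = 22, n_genes = 300))
  tab <- compute_ptr(om$tables$rna, om$tables$protein)
  for (sp in unique(tab$species)) {
    cls <- tab$ptr_class[tab$species == sp]
    expect_equal(sum(cls == "low") + sum(cls == "moderate") + sum(cls == "high"),
                 length(cls))
  }
})

test_that("group comparison matches exact rank-sum enumeration and flags gating", {
  cfg <- run_config()
  cmp <- compare_groups(list(a = c(1, 2, 3, 4), b = c(101, 102, 103, 104)), cfg)
  expect_equal(cmp$pairs$p, 2 / 70)
  expect_equal(cmp$pairs$p, oracle_wilcox_exact(c(1, 2, 3, 4), c(101, 102, 103, 104)))

  # identical groups: non-significant, ANOVA gate closes
  same <- compare_groups(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5)), cfg)
  expect_gte(same$pairs$p_adj, 0.99)
  expect_true(all(same$pairs$gated))

  expect_error(compare_groups(list(a = 1, b = c(1, 2)), cfg), "a")

  # invariant to group input order up to pair labelling
  g3 <- list(x = rnorm(5), y = rnorm(5) + 1, z = rnorm(5))
  c1 <- compare_groups(g3, cfg)
  c2 <- compare_groups(g3[c(3, 1, 2)], cfg)
  key <- function(df) {
    k <- apply(df[, c("group1", "group2")], 1, function(r) paste(sort(r), collapse = "-"))
    df$p[order(k)]
  }
  expect_equal(key(c1$pairs), key(c2$pairs))
})

test_that("C4-set PTR drops in the C4-type species but not for photorespiratory genes", {
  hits <- ctrl <- 0L
  for (s in 1:6) {
    om <- gen_multiomics(sim_config(seed = 400 + s))
    tab <- compute_ptr(om$tables$rna, om$tables$protein)
    grp <- function(set) {
      sel <- tab$gene %in% set$members
      split(tab$log10_ptr[sel], tab$species[sel])
    }
    cmp <- compare_groups(grp(om$sets$c4))
    pr <- cmp$pairs[cmp$pairs$group1 == "Ftri" | cmp$pairs$group2 == "Ftri", ]
    med <- vapply(grp(om$sets$c4), median, numeric(1))
    if (all(pr$p_adj < 0.05) && med[["Ftri"]] == min(med)) hits <- hits + 1L
    cmp2 <- compare_groups(grp(om$sets$photorespiratory))
    pr2 <- cmp2$pairs[cmp2$pairs$group1 == "Ftri" | cmp2$pairs$group2 == "Ftri", ]
    if (all(pr2$p_adj >= 0.05)) ctrl <- ctrl + 1L
  }
  expect_gte(hits, 5L)
  expect_gte(ctrl, 5L)
})

test_that("PTR parameter recovery: median C4/C3 ratio approaches G/F", {
  om <- gen_multiomics(sim_config(seed = 23))
  tab <- compute_ptr(om$tables$rna, om$tables$protein)
  c4 <- om$sets$c4$members
  r4 <- tab$ptr[match(paste(c4, "Ftri"), paste(tab$gene, tab$species))]
  r3 <- tab$ptr[match(paste(c4, "Frob"), paste(tab$gene, tab$species))]
  expect_lt(abs(median(r4 / r3, na.rm = TRUE) / 0.3 - 1), 0.1)
})

test_that("resampling control yields the requested draws and stable means", {
  om <- gen_multiomics(sim_config(seed = 24, n_genes = 300))
  tab <- compute_ptr(om$tables$rna, om$tables$protein)
  rs <- resample_null(tab, n_genes = 14, n_resamples = 100, seed = 99)
  expect_equal(unname(table(rs$draws$species)),
               rep(100L, length(unique(tab$species))), ignore_attr = TRUE)
  for (sp in unique(tab$species)) {
    v <- tab$log10_ptr[tab$species == sp & !is.na(tab$ptr_class)]
    se <- sd(v) / sqrt(14)
    expect_lt(abs(mean(rs$draws$mean_log10_ptr[rs$draws$species == sp]) - mean(v)),
              3 * se)
  }
  rs2 <- resample_null(tab, n_genes = 14, n_resamples = 100, seed = 99)
  expect_identical(rs$draws, rs2$draws)
  expect_error(resample_null(tab, n_genes = 10000), "classified genes")
})

test_that("Z-score normalization gives row mean 0 / SD 1 and flags constants", {
  expect_equal(unname(zscore_matrix(matrix(c(1, 2, 3), 1))[1, ]),
               c(-1, 0, 1), tolerance = 1e-12)
  m <- rbind(a = c(5, 5, 5), b = rnorm(3))
  z <- zscore_matrix(m)
  expect_equal(attr(z, "flagged"), "a")
  expect_equal(unname(z["a", ]), c(0, 0, 0))
  set.seed(41)
  r <- matrix(rnorm(60), 10)
  z2 <- zscore_matrix(r)
  expect_equal(unname(rowMeans(z2)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 10), tolerance = 1e-12)
})

test_that("log-scale correlation matches the covariance formula and nulls out", {
  set.seed(42)
  x <- 10^rnorm(50)
  expect_equal(correlate_log(x, 10 * x)$r, 1)
  lx <- log10(x); ly <- log10(3 * x^1.3)
  manual <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(correlate_log(x, 3 * x^1.3)$r, manual)
  y <- 10^rnorm(1e4)
  xn <- 10^rnorm(1e4)
  expect_lt(abs(correlate_log(xn, y)$r), 0.05)
  expect_error(correlate_log(c(1, 2), c(1, 2)), "at least 3")
})
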