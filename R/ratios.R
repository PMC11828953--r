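#' Classify values by mean +/- m standard deviations
#'
#' The abundance-ratio classification rule: on the supplied vector (log10
#' ratios by default elsewhere in the package), values below mean - m*SD are
#' `low`, above mean + m*SD are `high`, all others `moderate`. Values exactly
#' at a threshold are moderate. If all values are identical the SD is 0 and
#' everything is moderate.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param m SD multiplier (> 0), default 1.
#' @return Character vector in `{"low","moderate","high"}` with attributes
#'   `mean`, `sd`, `lower`, `upper`.
#' @export
classify_by_sd <- function(values, m = 1) {
  stopifnot(m > 0, sum(is.finite(values)) >= 2L)
  mu <- mean(values[is.finite(values)])
  s <- stats::sd(values[is.finite(values)])
  lo <- mu - m * s
  hi <- mu + m * s
  cls <- rep("moderate", length(values))
  cls[values < lo] <- "low"
  cls[values > hi] <- "high"
  cls[!is.finite(values)] <- NA_character_
  structure(cls, mean = mu, sd = s, lower = lo, upper = hi)
}

#' Protein-to-mRNA ratio (PTR) table
#'
#' For every (gene, species) pair where both roles pass detection (species
#' RNA mean at or above the TPM floor, any detected protein), computes
#' PTR = protein mean (iBAQ) / RNA mean (TPM), its log10, and the
#' mean +/- m*SD class computed per species (on the log10 scale unless
#' `cfg$ptr_log_scale` is `FALSE`). Pairs failing detection are excluded and
#' counted; a zero RNA mean with detected protein is excluded with a
#' warning.
#'
#' @param rna,protein [abundance_table()]s sharing the gene namespace.
#' @param cfg a [run_config()].
#' @return data.frame (`gene`, `species`, `rna_mean`, `protein_mean`, `ptr`,
#'   `log10_ptr`, `ptr_class`) of class `ptr_table`, with attributes
#'   `thresholds` (per-species class boundaries) and `n_excluded`.
#' @export
compute_ptr <- function(rna, protein, cfg = run_config()) {
  stopifnot(rna$role == "rna", protein$role == "protein")
  ar <- aggregate_replicates(rna, min_detect = cfg$min_tpm)
  ap <- aggregate_replicates(protein, min_detect = 0)
  species <- intersect(colnames(ar$mean), colnames(ap$mean))
  if (length(species) == 0L) stop("no shared species between RNA and protein tables")
  genes <- intersect(rownames(ar$mean), rownames(ap$mean))
  rows <- list()
  n_excluded <- 0L
  n_zero_rna <- 0L
  for (sp in species) {
    rm_ <- ar$mean[genes, sp]
    pm_ <- ap$mean[genes, sp]
    det_r <- ar$detected[genes, sp]
    det_p <- !is.na(pm_) & pm_ > 0
    zero_guard <- det_p & !is.na(rm_) & rm_ == 0
    n_zero_rna <- n_zero_rna + sum(zero_guard & det_r)
    keep <- det_r & det_p & rm_ > 0
    n_excluded <- n_excluded + sum(!keep)
    if (!any(keep)) next
    rows[[sp]] <- data.frame(
      gene = genes[keep], species = sp,
      rna_mean = rm_[keep], protein_mean = pm_[keep],
      ptr = pm_[keep] / rm_[keep],
      stringsAsFactors = FALSE
    )
  }
  if (n_zero_rna > 0L) {
    warning(n_zero_rna, " gene(s) with zero RNA mean but detected protein excluded")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no (gene, species) pair passed detection")
  rownames(out) <- NULL
  out$log10_ptr <- log10(out$ptr)
  out$ptr_class <- NA_character_
  thresholds <- list()
  for (sp in unique(out$species)) {
    sel <- out$species == sp
    v <- if (cfg$ptr_log_scale) out$log10_ptr[sel] else out$ptr[sel]
    if (sum(is.finite(v)) < 2L) next  # species too sparse to set thresholds
    cls <- classify_by_sd(v, cfg$sd_multiplier)
    out$ptr_class[sel] <- as.character(cls)
    thresholds[[sp]] <- attributes(cls)
  }
  structure(out, class = c("ptr_table", "data.frame"),
            thresholds = thresholds, n_excluded = n_excluded)
}

#' ANOVA-gated pairwise rank-sum comparison of groups
#'
#' One-way ANOVA across all groups, followed by two-tailed Wilcoxon rank-sum
#' tests for every pair of groups, with Benjamini-Hochberg adjustment over
#' the pairwise family. Pairwise results are flagged `gated` when the ANOVA
#' p-value is not below `cfg$anova_alpha` (they are still reported).
#' Significance stars use 0.05 / 0.01 / 0.001 on the adjusted p.
#'
#' @param values_by_group named list of numeric vectors, one per group, each
#'   with at least 2 observations.
#' @param cfg a [run_config()].
#' @return Object of class `group_comparison`: list with `anova_p` and
#'   `pairs` (data.frame `group1`, `group2`, `n1`, `n2`, `W`, `p`, `p_adj`,
#'   `gated`, `stars`).
#' @export
compare_groups <- function(values_by_group, cfg = run_config()) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L,
            !is.null(names(values_by_group)))
  small <- vapply(values_by_group, length, 1L) < 2L
  if (any(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(values_by_group)[small], collapse = ", "))
  }
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group),
                       vapply(values_by_group, length, 1L)))
  )
  anova_p <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)$p.value
  prs <- utils::combn(names(values_by_group), 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    g1 <- prs[1L, i]; g2 <- prs[2L, i]
    wt <- suppressWarnings(
      stats::wilcox.test(values_by_group[[g1]], values_by_group[[g2]],
                         alternative = "two.sided")
    )
    data.frame(group1 = g1, group2 = g2,
               n1 = length(values_by_group[[g1]]),
               n2 = length(values_by_group[[g2]]),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  pairs$gated <- !is.na(anova_p) && anova_p >= cfg$anova_alpha
  pairs$stars <- cut(pairs$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                     labels = c("***", "**", "*", "ns"))
  structure(list(anova_p = anova_p, pairs = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> ANOVA p = %.3g%s\n", x$anova_p,
              if (any(x$pairs$gated)) " (pairwise tests gated)" else ""))
  print(x$pairs)
  invisible(x)
}

#' Resampling null for gene-set PTR comparisons
#'
#' The control for gene-set comparisons: repeatedly draws `n_genes` genes
#' without replacement per species from the classified PTR table, records
#' each draw's mean log10 PTR, and compares the per-species resampled-mean
#' distributions with [compare_groups()]. A real gene-set effect should be
#' absent from these size-matched random sets.
#'
#' @param ptr a `ptr_table` from [compute_ptr()].
#' @param n_genes genes per draw (default 14).
#' @param n_resamples number of draws per species (default 100).
#' @param seed integer seed.
#' @param cfg a [run_config()].
#' @return list with `draws` (data.frame `species`, `draw`, `mean_log10_ptr`)
#'   and `comparison` (a `group_comparison`).
#' @export
resample_null <- function(ptr, n_genes = 14L, n_resamples = 100L, seed = 1L,
                          cfg = run_config()) {
  stopifnot(inherits(ptr, "ptr_table"))
  set.seed(seed)
  species <- unique(ptr$species)
  draws <- do.call(rbind, lapply(species, function(sp) {
    v <- ptr$log10_ptr[ptr$species == sp & !is.na(ptr$ptr_class)]
    if (length(v) < n_genes) {
      stop("species ", sp, " has only ", length(v),
           " classified genes (< ", n_genes, ")")
    }
    means <- vapply(seq_len(n_resamples),
                    function(i) mean(sample(v, n_genes)), numeric(1))
    data.frame(species = sp, draw = seq_len(n_resamples),
               mean_log10_ptr = means, stringsAsFactors = FALSE)
  }))
  cmp <- compare_groups(split(draws$mean_log10_ptr, draws$species), cfg)
  list(draws = draws, comparison = cmp)
}

#' Row-wise Z-score normalization
#'
#' Centres and scales each row (gene) of a gene-by-species matrix to mean 0
#' and SD 1, as used for relative-abundance heatmaps. Rows with zero SD are
#' flagged and emitted as zeros.
#'
#' @param m numeric matrix, genes x species.
#' @return Matrix of the same shape with attribute `flagged` (rownames of
#'   constant rows).
#' @export
zscore_matrix <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  flagged <- rownames(m)[s == 0]
  s[s == 0] <- 1
  structure(sweep(sweep(m, 1L, mu), 1L, s, "/"), flagged = flagged)
}

#' Pearson correlation on the log10 scale
#'
#' Correlation between two abundance vectors after log10 transformation of
#' paired, positive, finite entries (both roles detected).
#'
#' @param x,y paired numeric vectors.
#' @return list with `r` and `n` (pairs used).
#' @export
correlate_log <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(keep) < 3L) stop("need at least 3 detected pairs")
  list(r = stats::cor(log10(x[keep]), log10(y[keep])), n = sum(keep))
}
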