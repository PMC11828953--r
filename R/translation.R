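#' Deterministic extreme-fraction classification
#'
#' Ranks values and labels exactly `floor(frac * n)` entries `low` (smallest)
#' and the same number `high` (largest); everything else is `moderate`. Ties
#' at a rank cutoff are broken by ascending identifier so repeated runs give
#' identical classes.
#'
#' @param values numeric vector.
#' @param frac tail fraction in (0, 0.5), default 0.05.
#' @param ids identifiers used for deterministic tie-breaking; defaults to
#'   `names(values)` or the index.
#' @return Character vector in `{"low","moderate","high"}`.
#' @export
classify_extremes <- function(values, frac = 0.05, ids = NULL) {
  if (!(frac > 0 && frac < 0.5)) stop("frac must be in (0, 0.5)")
  n <- length(values)
  stopifnot(n >= 2L)
  if (is.null(ids)) ids <- if (is.null(names(values))) seq_len(n) else names(values)
  n_tail <- floor(frac * n)
  cls <- rep("moderate", n)
  if (n_tail > 0L) {
    o <- order(values, ids)
    cls[o[seq_len(n_tail)]] <- "low"
    cls[o[(n - n_tail + 1L):n]] <- "high"
  }
  cls
}

#' Translation efficiency with photosynthesis-set normalization
#'
#' Per species, translation efficiency is the ratio of ribosome-protected
#' fragment (RPF) abundance to RNA abundance for genes detected in both
#' roles. To make species comparable, raw efficiencies are divided by the
#' mean (or median, per `cfg$te_normalizer`) raw efficiency of the
#' photosynthesis gene set excluding C4 genes; by construction the mean
#' normalized efficiency over that set is 1 in every species. Classes are
#' the top/bottom `cfg$extreme_frac` per species.
#'
#' @param rna,rpf [abundance_table()]s.
#' @param photo_set,c4_set [gene_set()]s; the normalizer set is
#'   `photo_set` minus `c4_set`.
#' @param cfg a [run_config()].
#' @return data.frame (`gene`, `species`, `rna_mean`, `rpf_mean`, `te_raw`,
#'   `te_norm`, `te_class`) of class `translation_table` with attribute
#'   `normalizer` (per-species value).
#' @export
compute_te_normalized <- function(rna, rpf, photo_set, c4_set,
                                  cfg = run_config()) {
  stopifnot(rna$role == "rna", rpf$role == "rpf",
            inherits(photo_set, "gene_set"), inherits(c4_set, "gene_set"))
  ar <- aggregate_replicates(rna, min_detect = cfg$min_tpm)
  af <- aggregate_replicates(rpf, min_detect = cfg$min_tpm)
  species <- intersect(colnames(ar$mean), colnames(af$mean))
  genes <- intersect(rownames(ar$mean), rownames(af$mean))
  norm_set <- setdiff(photo_set$members, c4_set$members)
  summ <- if (cfg$te_normalizer == "median") stats::median else mean
  rows <- list()
  normalizer <- c()
  for (sp in species) {
    keep <- ar$detected[genes, sp] & af$detected[genes, sp]
    g <- genes[keep]
    te_raw <- af$mean[g, sp] / ar$mean[g, sp]
    nn <- intersect(g, norm_set)
    if (length(nn) == 0L) {
      stop("empty normalization set after detection filtering in ", sp)
    }
    nv <- summ(te_raw[match(nn, g)])
    stopifnot(nv > 0)
    normalizer[sp] <- nv
    te_norm <- te_raw / nv
    rows[[sp]] <- data.frame(
      gene = g, species = sp,
      rna_mean = ar$mean[g, sp], rpf_mean = af$mean[g, sp],
      te_raw = te_raw, te_norm = te_norm,
      te_class = classify_extremes(te_norm, cfg$extreme_frac, ids = g),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("translation_table", "data.frame"),
            normalizer = normalizer)
}

#' Protein-to-RPF ratios with extreme-fraction classes
#'
#' Per species, the ratio of protein abundance (iBAQ) to ribosome-protected
#' fragment abundance for genes detected in both roles, classified with the
#' same top/bottom-fraction rule as translation efficiency.
#'
#' @param protein,rpf [abundance_table()]s.
#' @param cfg a [run_config()].
#' @return data.frame (`gene`, `species`, `protein_mean`, `rpf_mean`,
#'   `protein_rpf`, `ratio_class`).
#' @export
compute_protein_rpf <- function(protein, rpf, cfg = run_config()) {
  stopifnot(protein$role == "protein", rpf$role == "rpf")
  ap <- aggregate_replicates(protein, min_detect = 0)
  af <- aggregate_replicates(rpf, min_detect = cfg$min_tpm)
  species <- intersect(colnames(ap$mean), colnames(af$mean))
  genes <- intersect(rownames(ap$mean), rownames(af$mean))
  rows <- list()
  for (sp in species) {
    pm <- ap$mean[genes, sp]
    keep <- !is.na(pm) & pm > 0 & af$detected[genes, sp]
    g <- genes[keep]
    if (length(g) == 0L) next
    ratio <- pm[keep] / af$mean[g, sp]
    rows[[sp]] <- data.frame(
      gene = g, species = sp,
      protein_mean = pm[keep], rpf_mean = af$mean[g, sp],
      protein_rpf = ratio,
      ratio_class = classify_extremes(ratio, cfg$extreme_frac, ids = g),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no (gene, species) pair passed detection")
  rownames(out) <- NULL
  out
}

#' Two-species gene-set comparison of a per-gene measure
#'
#' Two-tailed Wilcoxon rank-sum test of a measure (normalized translation
#' efficiency, or the protein-to-RPF ratio) between two species, restricted
#' to a gene set, with Benjamini-Hochberg adjustment across the sets tested.
#'
#' @param tab long data.frame with columns `gene`, `species`, and the
#'   measure column (e.g. a `translation_table`).
#' @param sets named list of [gene_set()]s to test.
#' @param species character(2): the two species to compare.
#' @param measure column name to test (e.g. `"te_norm"`, `"protein_rpf"`).
#' @return data.frame (`set`, `n1`, `n2`, `W`, `p`, `p_adj`).
#' @export
compare_between_species <- function(tab, sets, species, measure) {
  stopifnot(length(species) == 2L, measure %in% names(tab),
            all(species %in% tab$species))
  res <- do.call(rbind, lapply(sets, function(s) {
    g1 <- tab[tab$species == species[1L] & tab$gene %in% s$members, ]
    g2 <- tab[tab$species == species[2L] & tab$gene %in% s$members, ]
    shared <- intersect(g1$gene, g2$gene)
    if (length(shared) < 3L) {
      stop("fewer than 3 shared genes for set '", s$name, "'")
    }
    v1 <- g1[[measure]][match(shared, g1$gene)]
    v2 <- g2[[measure]][match(shared, g2$gene)]
    wt <- suppressWarnings(stats::wilcox.test(v1, v2, alternative = "two.sided"))
    data.frame(set = s$name, n1 = length(v1), n2 = length(v2),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
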