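#' Map ACR-relative motif occurrences to genomic coordinates
#'
#' Motif scans run on ACR sequences report coordinates relative to each ACR;
#' this shifts them onto the genome using the ACR intervals.
#'
#' @param occ occurrence data.frame from [read_fimo()] (`acr_id`-relative).
#' @param acrs ACR data.frame from [read_acr_bed()].
#' @return The occurrence data.frame with genomic `chrom`, `start`, `end`.
#' @export
occurrences_to_genomic <- function(occ, acrs) {
  i <- match(occ$acr_id, acrs$acr_id)
  if (anyNA(i)) {
    stop("occurrence(s) reference unknown ACR id(s): ",
         paste(utils::head(unique(occ$acr_id[is.na(i)]), 5), collapse = ", "))
  }
  occ$chrom <- acrs$chrom[i]
  occ$start <- occ$start + acrs$start[i]
  occ$end <- occ$end + acrs$start[i]
  occ
}

#' Assign genomic context labels to occurrences
#'
#' Labels each occurrence with zero or more (context, gene) pairs: `gACR`
#' when it overlaps a gene body, `upACR` when it overlaps the `window` bp
#' upstream of a gene's start codon, and `downACR` when it overlaps the
#' `window` bp downstream of a gene's stop codon. Upstream/downstream are
#' strand-aware (measured from the codon anchors along the gene's strand).
#' An occurrence may label multiple genes; unassigned occurrences are
#' retained with no labels. Genes without CDS anchors are skipped for
#' up/down labels.
#'
#' @param occ occurrence data.frame with genomic `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes gene-model data.frame from [read_gene_models()].
#' @param window window width in bp (default 3000).
#' @return data.frame (`occ_idx`, `cre_id`, `gene_id`, `context`), one row
#'   per (occurrence, gene, context) assignment.
#' @export
assign_context <- function(occ, genes, window = 3000L) {
  occ_gr <- GenomicRanges::GRanges(
    occ$chrom, IRanges::IRanges(occ$start + 1L, occ$end))
  hits_for <- function(start0, end0, sel) {
    ok <- sel & (end0 > start0)
    gr <- GenomicRanges::GRanges(
      genes$chrom[ok], IRanges::IRanges(start0[ok] + 1L, end0[ok]))
    h <- GenomicRanges::findOverlaps(occ_gr, gr)
    data.frame(occ_idx = S4Vectors::queryHits(h),
               gene_id = genes$gene_id[ok][S4Vectors::subjectHits(h)],
               stringsAsFactors = FALSE)
  }
  all_g <- rep(TRUE, nrow(genes))
  g <- hits_for(genes$start, genes$end, all_g)
  if (nrow(g) > 0L) g$context <- "gACR"

  has_cds <- genes$has_cds
  plus <- genes$strand == "+"
  # upstream window: [sc - window, sc) on +, (sc, sc + window] on -
  up_s <- ifelse(plus, pmax(genes$start_codon - window, 0L), genes$start_codon + 1L)
  up_e <- ifelse(plus, genes$start_codon, genes$start_codon + 1L + window)
  u <- hits_for(as.integer(up_s), as.integer(up_e), has_cds)
  if (nrow(u) > 0L) u$context <- "upACR"
  # downstream window: (stop, stop + window] on +, [stop - window, stop) on -
  dn_s <- ifelse(plus, genes$stop_codon + 1L, pmax(genes$stop_codon - window, 0L))
  dn_e <- ifelse(plus, genes$stop_codon + 1L + window, genes$stop_codon)
  d <- hits_for(as.integer(dn_s), as.integer(dn_e), has_cds)
  if (nrow(d) > 0L) d$context <- "downACR"

  lab <- rbind(g, u, d)
  if (nrow(lab) == 0L) {
    return(data.frame(occ_idx = integer(0), cre_id = character(0),
                      gene_id = character(0), context = character(0)))
  }
  lab$cre_id <- occ$cre_id[lab$occ_idx]
  lab <- lab[order(lab$occ_idx, lab$gene_id, lab$context),
             c("occ_idx", "cre_id", "gene_id", "context")]
  rownames(lab) <- NULL
  lab
}

#' Build the enrichment occurrence pool from labeled occurrences
#'
#' N counts every occurrence (background); k counts occurrences carrying at
#' least one label to a gene in the target set, each occurrence counted once
#' even when multi-labeled. Per-CRE counts `n_c` and `k_c` follow the same
#' rule.
#'
#' @param occ occurrence data.frame (defines N and `n_c`).
#' @param labels label data.frame from [assign_context()].
#' @param target a [gene_set()].
#' @return An [occurrence_pool()].
#' @export
build_pool <- function(occ, labels, target) {
  stopifnot(inherits(target, "gene_set"))
  cres <- sort(unique(occ$cre_id))
  n_c <- table(factor(occ$cre_id, levels = cres))
  target_idx <- unique(labels$occ_idx[labels$gene_id %in% target$members])
  if (length(target_idx) == 0L) {
    stop("no occurrence is associated with the target gene set; nothing to test")
  }
  k_c <- table(factor(occ$cre_id[target_idx], levels = cres))
  occurrence_pool(stats::setNames(as.integer(n_c), cres),
                  stats::setNames(as.integer(k_c), cres))
}

#' Monte Carlo permutation test of per-CRE enrichment
#'
#' Each permutation draws k occurrences from the N-occurrence background
#' pool (without replacement by default, an exact multivariate
#' hypergeometric draw; `perm_mode = "multinomial"` draws with replacement)
#' and records the per-CRE counts. The default p-value is
#' `(1 + #\{count >= observed\}) / (B + 1)`; `p_mode = "strict_paper"` uses
#' the plain proportion of permutations whose count strictly exceeds the
#' observed value, which can return 0 and, in a degenerate single-CRE pool,
#' declares certainty from no evidence — hence not the default.
#'
#' @param pool an [occurrence_pool()].
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param p_mode,perm_mode see above; defaults from [run_config()].
#' @return data.frame (`cre_id`, `observed`, `expected`, `perm_mean`,
#'   `p_perm`) with the B x CRE permuted-count matrix as attribute
#'   `perm_counts`.
#' @export
permutation_enrichment <- function(pool, B = 1000L, seed = 1L,
                                   p_mode = c("ge_plus_one", "strict_paper"),
                                   perm_mode = c("without", "multinomial")) {
  stopifnot(inherits(pool, "occurrence_pool"), B >= 1L)
  p_mode <- match.arg(p_mode)
  perm_mode <- match.arg(perm_mode)
  if (pool$k > pool$N) stop("k exceeds N")
  set.seed(seed)
  M <- length(pool$n_c)
  counts <- matrix(0L, B, M, dimnames = list(NULL, names(pool$n_c)))
  if (perm_mode == "without") {
    # sequential conditional draws: exact multivariate hypergeometric
    n_rest <- pool$N
    k_rest <- rep.int(pool$k, B)
    for (c in seq_len(M)) {
      m <- pool$n_c[[c]]
      if (c == M) {
        counts[, c] <- k_rest
      } else {
        x <- stats::rhyper(B, m, n_rest - m, k_rest)
        counts[, c] <- x
        k_rest <- k_rest - x
        n_rest <- n_rest - m
      }
    }
  } else {
    counts <- t(stats::rmultinom(B, pool$k, prob = pool$n_c / pool$N))
    colnames(counts) <- names(pool$n_c)
  }
  obs <- pool$k_c
  p <- if (p_mode == "ge_plus_one") {
    (1 + colSums(counts >= rep(obs, each = B))) / (B + 1)
  } else {
    colSums(counts > rep(obs, each = B)) / B
  }
  structure(
    data.frame(
      cre_id = names(pool$n_c),
      observed = as.integer(obs),
      expected = pool$k * pool$n_c / pool$N,
      perm_mean = colMeans(counts),
      p_perm = unname(p),
      stringsAsFactors = FALSE
    ),
    perm_counts = counts
  )
}

#' Fisher's exact (hypergeometric) per-CRE enrichment
#'
#' One-sided (greater) exact test of each CRE's target-associated count
#' against the background pool, from the 2x2 table
#' `[k_c, k - k_c; n_c - k_c, (N - n_c) - (k - k_c)]`. The odds ratio is the
#' sample odds ratio, with 0.5 added to every cell (and flagged) when any
#' cell is zero.
#'
#' @param pool an [occurrence_pool()].
#' @return data.frame (`cre_id`, `observed`, `p_fisher`, `odds_ratio`,
#'   `continuity`).
#' @export
fisher_enrichment <- function(pool) {
  stopifnot(inherits(pool, "occurrence_pool"))
  a <- pool$k_c
  b <- pool$k - a
  cc <- pool$n_c - a
  d <- (pool$N - pool$n_c) - b
  if (any(c(a, b, cc, d) < 0)) stop("negative contingency cell: pool invariant breach")
  p <- stats::phyper(a - 1, pool$n_c, pool$N - pool$n_c, pool$k,
                     lower.tail = FALSE)
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)),
               (a * d) / (b * cc))
  data.frame(
    cre_id = names(pool$n_c),
    observed = as.integer(a),
    p_fisher = unname(p),
    odds_ratio = unname(or),
    continuity = unname(zero),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Combined per-CRE enrichment results
#'
#' Runs the permutation and Fisher tests on the same pool and merges them
#' with Benjamini-Hochberg q-values per method; a CRE is flagged enriched
#' when its permutation q is below `q_max`.
#'
#' @param pool an [occurrence_pool()].
#' @param cfg a [run_config()] (supplies B, seed, estimator modes).
#' @param q_max enrichment q-value ceiling (default 0.05).
#' @return data.frame (`cre_id`, `observed`, `expected`, `p_perm`,
#'   `p_fisher`, `odds_ratio`, `q_perm`, `q_fisher`, `enriched`).
#' @export
cre_enrichment <- function(pool, cfg = run_config(), q_max = 0.05) {
  pe <- permutation_enrichment(pool, B = cfg$B, seed = cfg$seed,
                               p_mode = cfg$p_mode, perm_mode = cfg$perm_mode)
  fe <- fisher_enrichment(pool)
  out <- merge(pe, fe[, c("cre_id", "p_fisher", "odds_ratio", "continuity")],
               by = "cre_id", sort = FALSE)
  out$q_perm <- adjust_bh(out$p_perm)
  out$q_fisher <- adjust_bh(out$p_fisher)
  out$enriched <- out$q_perm < q_max
  out
}

#' Frequency summary of enriched CREs
#'
#' For CREs passing the q-value ceiling: observed counts and their log2
#' frequency (the quantity behind enrichment word clouds), optionally
#' grouped by CRE family with each family's share.
#'
#' @param results data.frame from [cre_enrichment()].
#' @param family_map optional named character vector, CRE id -> family.
#' @param q_max q ceiling (default 0.05).
#' @param method `"perm"` or `"fisher"`: which q column selects CREs.
#' @return list with `cres` (data.frame `cre_id`, `observed`, `log2_freq`,
#'   and `family` if mapped) and `families` (share table or `NULL`).
#' @export
summarize_enriched <- function(results, family_map = NULL, q_max = 0.05,
                               method = c("perm", "fisher")) {
  method <- match.arg(method)
  qcol <- if (method == "perm") "q_perm" else "q_fisher"
  sel <- results[results[[qcol]] < q_max, , drop = FALSE]
  cres <- data.frame(
    cre_id = sel$cre_id,
    observed = sel$observed,
    log2_freq = log2(sel$observed),
    stringsAsFactors = FALSE
  )
  families <- NULL
  if (!is.null(family_map)) {
    cres$family <- unname(family_map[cres$cre_id])
    if (nrow(cres) > 0L) {
      tab <- sort(table(cres$family), decreasing = TRUE)
      families <- data.frame(family = names(tab),
                             n_enriched = as.integer(tab),
                             share = as.numeric(tab) / sum(tab),
                             stringsAsFactors = FALSE)
    } else {
      families <- data.frame(family = character(0), n_enriched = integer(0),
                             share = numeric(0))
    }
  }
  list(cres = cres, families = families)
}
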