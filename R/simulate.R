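#' Simulation configuration
#'
#' Defines the study conditions the synthetic generators emulate: five
#' species spanning C3, C3-C4 intermediate and C4 photosynthetic types, six
#' RNA/protein replicates and two Ribo-seq replicates, an approximately
#' 10-fold RNA increase of C4-pathway genes in the C4-type species with a
#' smaller protein increase (so the protein-to-mRNA ratio drops by G/F), a
#' pool of cis-regulatory-element (CRE) occurrences with optional spiked
#' enrichment near target genes, coding sequences with controlled
#' third-codon-position GC, genomic fragments with planted inverted-repeat +
#' target-site-duplication retroduplication signatures, and a TF-target
#' regulatory network with ERF edges over-represented on C4 genes.
#'
#' @param seed integer; all generators are pure functions of the config,
#'   seed included.
#' @param species data.frame with columns `code` and `type`
#'   (`C3`/`C3C4`/`C4`).
#' @param n_genes number of genes in the abundance tables.
#' @param n_replicates named integer vector, replicates per role.
#' @param rpf_species species codes profiled by Ribo-seq.
#' @param rna_mu,rna_sigma log10-scale mean and SD of gene RNA abundance
#'   (TPM).
#' @param c4_rna_fold fold-change F applied to RNA of C4-set genes in
#'   C4-type species.
#' @param c4_protein_fold fold-change G applied to protein of C4-set genes
#'   in C4-type species; the realized PTR ratio is G/F.
#' @param ptr_mu,ptr_sigma log10-scale mean and SD of the per-gene baseline
#'   protein-to-mRNA ratio.
#' @param te_mu,te_sigma log10-scale mean and SD of the per-gene baseline
#'   translation efficiency.
#' @param noise_sd named numeric, log10-scale replicate measurement noise SD
#'   per role.
#' @param n_c4,n_photo,n_photoresp sizes of the C4, photosynthesis
#'   (C4-excluded) and photorespiratory gene sets.
#' @param n_cre,n_occurrences,n_target_occ CRE pool dimensions: distinct CRE
#'   types, total background occurrences N, and target-associated draws k.
#' @param dirichlet_conc concentration of the Dirichlet prior on background
#'   CRE frequencies.
#' @param spike_cres,spike_mult CRE ids whose sampling weight among
#'   target-associated occurrences is multiplied by `spike_mult` (> 0).
#' @param n_cre_genes,n_distal_acrs,n_geom_occ coordinate-level CRE dataset:
#'   number of genes (each with genic/upstream/downstream ACRs), distal
#'   (unassociated) ACRs, and placed occurrences.
#' @param n_target_genes leading genes forming the target set of the
#'   coordinate-level CRE dataset.
#' @param n_cds,cds_codons,gc3_target CDS generator: sequence count, codons
#'   per CDS, target third-position G+C fraction.
#' @param n_fragments,fragment_len genomic fragments carrying one planted
#'   retroduplication signature each.
#' @param ir_len,tsd_len,spacer_range planted signature geometry (bp).
#' @param n_tfs,n_grn_targets,tf_families GRN generator dimensions; families
#'   must include `ERF`.
#' @param cognate_fraction fraction of TFs whose targets carry the TF's
#'   cognate promoter CRE family (these survive cognate filtering).
#' @param erf_factor over-representation factor of ERF edges onto C4 genes.
#'
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       species = data.frame(
                         code = c("Frob", "Fson", "Fram", "Flin", "Ftri"),
                         type = c("C3", "C3C4", "C3C4", "C3C4", "C4"),
                         stringsAsFactors = FALSE),
                       n_genes = 2000L,
                       n_replicates = c(rna = 6L, protein = 6L, rpf = 2L),
                       rpf_species = c("Frob", "Ftri"),
                       rna_mu = 1.5, rna_sigma = 0.5,
                       c4_rna_fold = 10, c4_protein_fold = 3,
                       ptr_mu = 0, ptr_sigma = 0.3,
                       te_mu = 0, te_sigma = 0.3,
                       noise_sd = c(rna = 0.1, protein = 0.1, rpf = 0.1),
                       n_c4 = 15L, n_photo = 80L, n_photoresp = 30L,
                       n_cre = 50L, n_occurrences = 100000L,
                       n_target_occ = 2000L,
                       dirichlet_conc = 10,
                       spike_cres = character(0), spike_mult = 1,
                       n_cre_genes = 60L, n_distal_acrs = 30L,
                       n_geom_occ = 6000L, n_target_genes = 12L,
                       n_cds = 50L, cds_codons = 100L, gc3_target = 0.5,
                       n_fragments = 5L, fragment_len = 500L,
                       ir_len = 9L, tsd_len = 4L,
                       spacer_range = c(50L, 200L),
                       n_tfs = 100L, n_grn_targets = 2000L,
                       tf_families = c("ERF", "bHLH", "MYB", "NAC", "C2H2"),
                       cognate_fraction = 0.6, erf_factor = 20) {
  stopifnot(
    all(c("code", "type") %in% names(species)),
    all(species$type %in% c("C3", "C3C4", "C4")),
    c4_rna_fold > 0, c4_protein_fold > 0, spike_mult > 0,
    rna_sigma > 0, ptr_sigma >= 0, te_sigma >= 0,
    all(noise_sd >= 0), all(c("rna", "protein", "rpf") %in% names(noise_sd)),
    n_target_occ <= n_occurrences,
    gc3_target >= 0, gc3_target <= 1,
    ir_len >= 1, tsd_len >= 1, length(spacer_range) == 2L,
    spacer_range[1] <= spacer_range[2],
    "ERF" %in% tf_families,
    cognate_fraction >= 0, cognate_fraction <= 1, erf_factor > 0,
    all(rpf_species %in% species$code)
  )
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(n, conc) {
  g <- stats::rgamma(n, shape = conc, rate = 1)
  g / sum(g)
}

#' Generate the multi-species multi-omics abundance bundle
#'
#' Gene-level log10-normal RNA abundance shared across species; protein is
#' coupled to the species-level RNA mean through a per-gene protein-to-mRNA
#' ratio, and ribosome-protected-fragment (RPF) abundance through a per-gene
#' translation efficiency. In C4-type species, C4-set genes get RNA (and
#' hence RPF) multiplied by `c4_rna_fold` and protein by `c4_protein_fold`,
#' so the true PTR shrinks by G/F while true TE is unchanged. Replicates are
#' independent log10-normal measurement-noise draws.
#'
#' @param cfg a [sim_config()].
#' @return list with `tables` (named [abundance_table()] list), `sets`
#'   (named [gene_set()] list: `c4`, `photosynthesis`, `photorespiratory`),
#'   and `truth` (noise-free per-gene per-species matrices `rna`, `protein`,
#'   `rpf`, `ptr`, `te`, plus the config echo).
#' @export
gen_multiomics <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  stopifnot(cfg$n_c4 + cfg$n_photo + cfg$n_photoresp <= cfg$n_genes)
  sets <- list(
    c4 = gene_set("c4", genes[seq_len(cfg$n_c4)]),
    photosynthesis = gene_set("photosynthesis",
                              genes[cfg$n_c4 + seq_len(cfg$n_photo)]),
    photorespiratory = gene_set("photorespiratory",
                                genes[cfg$n_c4 + cfg$n_photo + seq_len(cfg$n_photoresp)])
  )
  sp <- cfg$species
  mu_g <- stats::rnorm(cfg$n_genes, cfg$rna_mu, cfg$rna_sigma)
  lptr <- stats::rnorm(cfg$n_genes, cfg$ptr_mu, cfg$ptr_sigma)
  lte <- stats::rnorm(cfg$n_genes, cfg$te_mu, cfg$te_sigma)

  is_c4_gene <- genes %in% sets$c4$members
  fold_rna <- outer(is_c4_gene, sp$type == "C4",
                    function(g, s) ifelse(g & s, cfg$c4_rna_fold, 1))
  fold_prot <- outer(is_c4_gene, sp$type == "C4",
                     function(g, s) ifelse(g & s, cfg$c4_protein_fold, 1))
  base <- matrix(10^mu_g, cfg$n_genes, nrow(sp))
  true_rna <- base * fold_rna
  true_protein <- base * fold_prot * 10^lptr
  true_rpf <- true_rna * 10^lte
  dimnames(true_rna) <- dimnames(true_protein) <- dimnames(true_rpf) <-
    list(genes, sp$code)

  make_table <- function(truth, role, sp_codes) {
    nrep <- cfg$n_replicates[[role]]
    sdlog <- cfg$noise_sd[[role]]
    cols <- as.vector(outer(sp_codes, seq_len(nrep),
                            function(s, r) paste0(s, "_R", r)))
    vals <- matrix(NA_real_, cfg$n_genes, length(cols),
                   dimnames = list(genes, cols))
    for (s in sp_codes) for (r in seq_len(nrep)) {
      noise <- if (sdlog > 0) 10^stats::rnorm(cfg$n_genes, 0, sdlog) else 1
      vals[, paste0(s, "_R", r)] <- truth[, s] * noise
    }
    abundance_table(vals, role = role)
  }
  tables <- list(
    rna = make_table(true_rna, "rna", sp$code),
    protein = make_table(true_protein, "protein", sp$code),
    rpf = make_table(true_rpf, "rpf", cfg$rpf_species)
  )
  truth <- list(
    rna = true_rna, protein = true_protein, rpf = true_rpf,
    ptr = true_protein / true_rna, te = true_rpf / true_rna,
    species = sp, cfg = cfg
  )
  list(tables = tables, sets = sets, truth = truth)
}

#' Per-CRE occurrence pool
#'
#' Counting container for enrichment testing: per-CRE background occurrence
#' counts `n_c` summing to N (all occurrences in accessible chromatin), and
#' per-CRE target-associated counts `k_c` summing to k.
#'
#' @param n_c named integer vector of background counts per CRE.
#' @param k_c named integer vector of target-associated counts per CRE
#'   (same names as `n_c`; missing CREs count 0).
#' @return An `occurrence_pool` object with fields `N`, `n_c`, `k`, `k_c`.
#' @export
occurrence_pool <- function(n_c, k_c) {
  stopifnot(!is.null(names(n_c)), !anyDuplicated(names(n_c)))
  k_full <- stats::setNames(integer(length(n_c)), names(n_c))
  if (length(k_c) > 0) {
    stopifnot(!is.null(names(k_c)), all(names(k_c) %in% names(n_c)))
    k_full[names(k_c)] <- as.integer(k_c)
  }
  n_c <- as.integer(round(n_c))
  names(n_c) <- names(k_full)
  if (any(k_full > n_c) || any(k_full < 0) || any(n_c < 0)) {
    stop("pool invariant violated: need 0 <= k_c <= n_c for every CRE")
  }
  structure(list(N = sum(n_c), n_c = n_c, k = sum(k_full), k_c = k_full),
            class = "occurrence_pool")
}

#' @export
print.occurrence_pool <- function(x, ...) {
  cat(sprintf("<occurrence_pool> %d occurrences of %d CREs; %d target-associated (%d CREs)\n",
              x$N, length(x$n_c), x$k, sum(x$k_c > 0)))
  invisible(x)
}

# Weighted sampling without replacement (Efraimidis-Spirakis exponential
# keys): O(N log N), exact, unlike sample(prob=, replace=FALSE) which is
# O(N*k).
sample_wor_weighted <- function(n, k, w) {
  if (length(unique(w)) == 1L) return(sample.int(n, k))
  order(stats::rexp(n) / w)[seq_len(k)]
}

#' Generate a count-level CRE occurrence pool
#'
#' Background frequencies are Dirichlet-distributed over `n_cre` CRE types;
#' `n_occurrences` background occurrences are allocated multinomially, and
#' `n_target_occ` of them are selected without replacement as
#' target-associated, with selection weight `spike_mult` for spiked CREs.
#' With `spike_mult = 1` the target subset is an unbiased draw from the
#' background, giving a valid permutation null.
#'
#' @param cfg a [sim_config()].
#' @return list with `pool` (an [occurrence_pool()]) and `truth`
#'   (frequencies, spiked CRE ids, per-CRE counts).
#' @export
gen_occurrence_pool <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  cres <- sprintf("%s_like_%d",
                  rep_len(cfg$tf_families, cfg$n_cre),
                  seq_len(cfg$n_cre))
  freq <- rdirichlet1(cfg$n_cre, cfg$dirichlet_conc)
  n_c <- as.integer(stats::rmultinom(1L, cfg$n_occurrences, freq))
  names(n_c) <- cres
  stopifnot(all(cfg$spike_cres %in% cres))
  labels <- rep(cres, n_c)
  w <- ifelse(labels %in% cfg$spike_cres, cfg$spike_mult, 1)
  sel <- sample_wor_weighted(cfg$n_occurrences, cfg$n_target_occ, w)
  k_tab <- table(factor(labels[sel], levels = cres))
  k_c <- stats::setNames(as.integer(k_tab), cres)
  pool <- occurrence_pool(n_c, k_c)
  list(pool = pool,
       truth = list(freq = stats::setNames(freq, cres),
                    spiked = cfg$spike_cres, n_c = n_c, k_c = k_c,
                    cre_family = stats::setNames(sub("_like_.*$", "", cres), cres)))
}

#' Generate a coordinate-level CRE dataset
#'
#' Lays out genes on five chromosomes 10 kb apart (alternating strand), each
#' with three accessible chromatin regions (ACRs): one in the gene body, one
#' inside the 3 kb window upstream of the start codon, one inside the 3 kb
#' window downstream of the stop codon, plus unassociated distal ACRs.
#' Occurrences are placed uniformly across ACRs with Dirichlet CRE
#' frequencies; occurrences landing in ACRs of target-set genes use
#' frequencies re-weighted by `spike_mult` for spiked CREs. The geometry
#' guarantees each ACR associates with exactly one gene, so exact expected
#' pool counts are recorded as ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `occurrences` (genomic, 0-based half-open), `genes`
#'   (gene models), `acrs`, `target_set` (a [gene_set()]), and `truth`
#'   (per-CRE `n_c`/`k_c`, ACR-to-gene map, spiked CREs).
#' @export
gen_cre_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ng <- cfg$n_cre_genes
  gid <- sprintf("g%04d", seq_len(ng))
  chrom <- paste0("chr", ((seq_len(ng) - 1L) %% 5L) + 1L)
  idx <- ave(seq_len(ng), chrom, FUN = seq_along)
  gstart <- 10000L * idx
  gend <- gstart + 1000L
  strand <- rep_len(c("+", "-"), ng)
  genes <- data.frame(
    gene_id = gid, chrom = chrom, start = gstart, end = gend,
    strand = strand,
    start_codon = ifelse(strand == "+", gstart, gend - 1L),
    stop_codon = ifelse(strand == "+", gend - 1L, gstart),
    has_cds = TRUE, stringsAsFactors = FALSE
  )
  # gACR inside the body; upACR/downACR centred ~2.3 kb out on the proper side
  up_off <- ifelse(strand == "+", -2500L, 2200L + 1000L)  # relative to gstart
  acr_one <- function(kind, s) {
    data.frame(acr_id = paste0(gid, "_", kind), chrom = chrom,
               start = s, end = s + 300L, gene_id = gid, context = kind,
               stringsAsFactors = FALSE)
  }
  acrs <- rbind(
    acr_one("gACR", gstart + 200L),
    acr_one("upACR", ifelse(strand == "+", gstart - 2500L, gend + 2200L)),
    acr_one("downACR", ifelse(strand == "+", gend + 2200L, gstart - 2500L))
  )
  distal <- data.frame(
    acr_id = sprintf("distal%03d", seq_len(cfg$n_distal_acrs)),
    chrom = paste0("chr", ((seq_len(cfg$n_distal_acrs) - 1L) %% 5L) + 1L),
    start = 10000L * ave(seq_len(cfg$n_distal_acrs),
                         ((seq_len(cfg$n_distal_acrs) - 1L) %% 5L),
                         FUN = seq_along) + 6000L,
    gene_id = NA_character_, context = "distal", stringsAsFactors = FALSE
  )
  distal$end <- distal$start + 300L
  acrs <- rbind(acrs, distal[, names(acrs)])

  target <- gene_set("c4", gid[seq_len(cfg$n_target_genes)])
  cres <- sprintf("%s_like_%d", rep_len(cfg$tf_families, cfg$n_cre),
                  seq_len(cfg$n_cre))
  stopifnot(all(cfg$spike_cres %in% cres))
  freq_bg <- rdirichlet1(cfg$n_cre, cfg$dirichlet_conc)
  w <- ifelse(cres %in% cfg$spike_cres, cfg$spike_mult, 1)
  freq_sp <- freq_bg * w / sum(freq_bg * w)

  acr_i <- sample.int(nrow(acrs), cfg$n_geom_occ, replace = TRUE)
  in_target <- !is.na(acrs$gene_id[acr_i]) & acrs$gene_id[acr_i] %in% target$members
  cre_lab <- character(cfg$n_geom_occ)
  cre_lab[!in_target] <- sample(cres, sum(!in_target), TRUE, prob = freq_bg)
  cre_lab[in_target] <- sample(cres, sum(in_target), TRUE, prob = freq_sp)
  pos <- acrs$start[acr_i] + sample.int(300L - 8L, cfg$n_geom_occ, replace = TRUE) - 1L
  occurrences <- data.frame(
    cre_id = cre_lab,
    acr_id = acrs$acr_id[acr_i],
    chrom = acrs$chrom[acr_i],
    start = pos, end = pos + 8L,
    strand = sample(c("+", "-"), cfg$n_geom_occ, TRUE),
    score = round(stats::runif(cfg$n_geom_occ, 8, 20), 3),
    p_value = stats::runif(cfg$n_geom_occ, 1e-8, 1e-4),
    q_value = stats::runif(cfg$n_geom_occ, 0, 0.05),
    stringsAsFactors = FALSE
  )
  n_c <- table(factor(cre_lab, levels = cres))
  k_c <- table(factor(cre_lab[in_target], levels = cres))
  list(
    occurrences = occurrences, genes = genes,
    acrs = acrs[, c("acr_id", "chrom", "start", "end")],
    target_set = target,
    truth = list(
      n_c = stats::setNames(as.integer(n_c), cres),
      k_c = stats::setNames(as.integer(k_c), cres),
      acr_gene = stats::setNames(acrs$gene_id, acrs$acr_id),
      acr_context = stats::setNames(acrs$context, acrs$acr_id),
      spiked = cfg$spike_cres, freq_bg = stats::setNames(freq_bg, cres)
    )
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Plant a retroduplication signature into a background sequence
#'
#' Inserts `TSD + IR + spacer + revcomp(IR) + TSD` at `pos` (0-based offset
#' of the left TSD). To make the planted geometry exact ground truth (the
#' reported lengths, not just lower bounds), the spacer's terminal bases are
#' resampled so the inverted repeat cannot extend inward, and the background
#' bases immediately flanking the block are resampled so neither the IR nor
#' the TSD can extend outward.
#'
#' @param background character DNA string.
#' @param pos 0-based insertion offset of the left TSD copy.
#' @param ir left inverted-repeat unit (the right unit is its reverse
#'   complement).
#' @param tsd direct-repeat (target-site-duplication) unit, copied on both
#'   sides.
#' @param spacer spacer sequence, or an integer length to fill with random
#'   bases.
#' @return list `seq` (modified sequence) and `truth` (data.frame of planted
#'   coordinates, 0-based half-open).
#' @export
plant_retro_signature <- function(background, pos, ir, tsd, spacer) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (is.numeric(spacer)) spacer <- random_dna(spacer)
  sp <- strsplit(spacer, "")[[1L]]
  # forbid inward IR extension: first spacer base must not complement last
  while (length(sp) > 0L && sp[1L] == comp[[sp[length(sp)]]]) {
    sp[1L] <- sample(c("A", "C", "G", "T"), 1L)
  }
  spacer <- paste(sp, collapse = "")
  td <- strsplit(tsd, "")[[1L]]
  if (td[length(td)] == comp[[td[1L]]]) {
    stop("tsd ends with the complement of its first base; the planted IR ",
         "would extend outward into the duplications")
  }
  block <- paste0(tsd, ir, spacer, revcomp_chr(ir), tsd)
  s <- strsplit(background, "")[[1L]]
  if (pos < 1L || pos + nchar(block) + 1L > length(s)) {
    stop("fragment too short for planted block at pos ", pos)
  }
  s[(pos + 1L):(pos + nchar(block))] <- strsplit(block, "")[[1L]]
  # forbid outward TSD extension: guard bases just outside the block differ
  while (s[pos] == s[pos + nchar(block) + 1L]) {
    s[pos] <- sample(c("A", "C", "G", "T"), 1L)
  }
  L <- nchar(ir); t <- nchar(tsd); slen <- nchar(spacer)
  ir_left <- pos + t
  ir_right <- ir_left + L + slen
  list(
    seq = paste(s, collapse = ""),
    truth = data.frame(
      ir_left_start = ir_left, ir_left_end = ir_left + L,
      ir_right_start = ir_right, ir_right_end = ir_right + L,
      ir_len = L, tsd_len = t, spacer_len = slen,
      ir_seq = ir, tsd_seq = tsd, stringsAsFactors = FALSE
    )
  )
}

#' Generate CDS and genomic fragments with known sequence features
#'
#' CDS codons are sampled with third-position G/C probability equal to
#' `gc3_target` (G and C equally likely given G/C, likewise A/T). Genomic
#' fragments of `fragment_len` bp carry one planted inverted-repeat +
#' target-site-duplication block each at a recorded position (see
#' [plant_retro_signature()]); the rest is uniform random sequence.
#'
#' @param cfg a [sim_config()].
#' @return list with `cds` and `fragments` ([Biostrings::DNAStringSet]) and
#'   `truth` (planted-signature coordinate table and the GC3 target).
#' @export
gen_sequences <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  ncodon <- cfg$cds_codons
  cds <- vapply(seq_len(cfg$n_cds), function(i) {
    b12 <- sample(c("A", "C", "G", "T"), 2L * ncodon, replace = TRUE)
    gc <- stats::runif(ncodon) < cfg$gc3_target
    b3 <- ifelse(gc, sample(c("G", "C"), ncodon, replace = TRUE),
                 sample(c("A", "T"), ncodon, replace = TRUE))
    m <- matrix("", 3L, ncodon)
    m[1L, ] <- b12[seq_len(ncodon)]
    m[2L, ] <- b12[ncodon + seq_len(ncodon)]
    m[3L, ] <- b3
    paste(m, collapse = "")
  }, "")
  names(cds) <- sprintf("cds%03d", seq_len(cfg$n_cds))

  planted <- vector("list", cfg$n_fragments)
  frags <- character(cfg$n_fragments)
  block_len <- 2L * (cfg$ir_len + cfg$tsd_len) + cfg$spacer_range[2]
  if (cfg$fragment_len < block_len + 2L) {
    stop("fragment_len too short for the planted block")
  }
  for (i in seq_len(cfg$n_fragments)) {
    slen <- sample(seq(cfg$spacer_range[1], cfg$spacer_range[2]), 1L)
    blen <- 2L * (cfg$ir_len + cfg$tsd_len) + slen
    pos <- sample.int(cfg$fragment_len - blen - 2L, 1L)
    ir <- random_dna(cfg$ir_len)
    tsd <- random_dna(cfg$tsd_len)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    while (substr(tsd, cfg$tsd_len, cfg$tsd_len) ==
           comp[[substr(tsd, 1L, 1L)]]) {
      tsd <- random_dna(cfg$tsd_len)
    }
    pl <- plant_retro_signature(random_dna(cfg$fragment_len), pos, ir, tsd, slen)
    frags[i] <- pl$seq
    planted[[i]] <- cbind(seq_id = sprintf("frag%03d", i), pl$truth,
                          stringsAsFactors = FALSE)
  }
  names(frags) <- sprintf("frag%03d", seq_len(cfg$n_fragments))
  list(
    cds = Biostrings::DNAStringSet(cds),
    fragments = Biostrings::DNAStringSet(frags),
    truth = list(planted = do.call(rbind, planted), gc3_target = cfg$gc3_target)
  )
}

#' Default cognate TF-family to CRE-family map
#'
#' Small mapping used by the synthetic regulatory-network tests; in real
#' analyses supply the mapping derived from motif-database annotations.
#'
#' @return data.frame with columns `tf_family`, `cre_family`.
#' @export
default_cognate_map <- function() {
  fam <- c("ERF", "bHLH", "MYB", "NAC", "C2H2", "WRKY")
  data.frame(tf_family = fam, cre_family = paste0(fam, "_CRE"),
             stringsAsFactors = FALSE)
}

#' Generate a TF-target regulatory network with known structure
#'
#' A configurable fraction of TFs are "cognate": the promoters of their
#' target genes carry the CRE family cognate to the TF's family, so these
#' TFs survive cognate-CRE filtering. ERF TFs choose C4-set target genes
#' with sampling weight `erf_factor`, over-representing ERF edges in the C4
#' sub-network.
#'
#' @param cfg a [sim_config()].
#' @return list with `edges` (tf, target), `tf_families` (tf, family),
#'   `promoter_cres` (gene, cre_family), `target_set` (C4 [gene_set()]),
#'   `cognate_map`, and `truth` (cognate TF ids, expected retained edges,
#'   the constructed ERF-per-C4-gene metric).
#' @export
gen_grn <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_tfs < 1L) stop("need at least one TF")
  set.seed(cfg$seed + 3L)
  tfs <- sprintf("tf%03d", seq_len(cfg$n_tfs))
  fam <- sample(cfg$tf_families, cfg$n_tfs, replace = TRUE)
  names(fam) <- tfs
  genes <- sprintf("g%04d", seq_len(cfg$n_grn_targets))
  c4 <- gene_set("c4", genes[seq_len(min(15L, cfg$n_grn_targets))])
  w_base <- ifelse(genes %in% c4$members, 1, 1)
  edges <- do.call(rbind, lapply(tfs, function(tf) {
    w <- w_base
    if (fam[[tf]] == "ERF") w[genes %in% c4$members] <- cfg$erf_factor
    n_t <- sample(5:15, 1L)
    data.frame(tf = tf,
               target = sample(genes, n_t, prob = w / sum(w)),
               stringsAsFactors = FALSE)
  }))
  n_cog <- round(cfg$cognate_fraction * cfg$n_tfs)
  cognate_tfs <- if (n_cog > 0) sample(tfs, n_cog) else character(0)
  cmap <- default_cognate_map()
  cre_of <- stats::setNames(cmap$cre_family, cmap$tf_family)
  pc <- unique(do.call(rbind, lapply(cognate_tfs, function(tf) {
    tg <- edges$target[edges$tf == tf]
    if (length(tg) == 0L) return(NULL)
    data.frame(gene = tg, cre_family = cre_of[[fam[[tf]]]],
               stringsAsFactors = FALSE)
  })))
  if (is.null(pc)) pc <- data.frame(gene = character(0),
                                    cre_family = character(0))
  # bookkeeping: which edges survive cognate filtering, and the resulting
  # ERF-per-C4-gene metric, computed directly from the construction records
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    f <- cre_of[[fam[[edges$tf[i]]]]]
    any(pc$gene == edges$target[i] & pc$cre_family == f)
  }, logical(1))
  sub <- edges[keep & edges$target %in% c4$members, , drop = FALSE]
  erf_tfs <- unique(sub$tf[fam[sub$tf] == "ERF"])
  n_reg <- length(unique(sub$target))
  erf_per_gene <- if (n_reg > 0) length(erf_tfs) / n_reg else NA_real_
  list(
    edges = edges,
    tf_families = data.frame(tf = tfs, family = unname(fam),
                             stringsAsFactors = FALSE),
    promoter_cres = pc,
    target_set = c4,
    cognate_map = cmap,
    truth = list(cognate_tfs = cognate_tfs, kept_edges = keep,
                 erf_per_c4_gene = erf_per_gene)
  )
}

#' Generate paralog groups with a designated functional copy
#'
#' Each group has 1-3 member genes per species with log-normal transcript
#' abundance; one member in a C4-type species is designated functional by
#' boosting its abundance above both its within-group C4 competitors and all
#' C3-species counterparts, mirroring the two-criterion functional-copy
#' rule.
#'
#' @param cfg a [sim_config()].
#' @param n_groups number of paralog groups.
#' @return list with `groups` (data.frame `group_id`, `gene`, `species`,
#'   `tpm`) and `truth` (designated functional gene per group).
#' @export
gen_paralog_groups <- function(cfg = sim_config(), n_groups = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  sp <- cfg$species
  out <- vector("list", n_groups)
  designated <- character(n_groups)
  for (g in seq_len(n_groups)) {
    rows <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
      n_m <- sample(1:3, 1L)
      data.frame(
        group_id = sprintf("grp%03d", g),
        gene = sprintf("grp%03d_%s_p%d", g, sp$code[i], seq_len(n_m)),
        species = sp$code[i], type = sp$type[i],
        tpm = 10^stats::rnorm(n_m, cfg$rna_mu, cfg$rna_sigma),
        stringsAsFactors = FALSE
      )
    }))
    c4_rows <- which(rows$type == "C4")
    pick <- c4_rows[sample.int(length(c4_rows), 1L)]
    rows$tpm[pick] <- max(rows$tpm) * 2
    designated[g] <- rows$gene[pick]
    out[[g]] <- rows[, c("group_id", "gene", "species", "tpm")]
  }
  list(groups = do.call(rbind, out),
       truth = list(functional = stats::setNames(
         designated, sprintf("grp%03d", seq_len(n_groups)))))
}

#' Write a complete synthetic dataset directory
#'
#' Emits every file the loaders read: abundance TSVs per role, gene sets,
#' gene-model GFF3, ACR BED, FIMO-dialect occurrences, CDS and fragment
#' FASTA, and regulatory-network tables, plus `ground_truth` TSVs.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(cfg = sim_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  om <- gen_multiomics(cfg)
  for (r in names(om$tables)) {
    write_abundance_tsv(om$tables[[r]], file.path(outdir, paste0(r, ".tsv")))
  }
  write_gene_sets(om$sets, file.path(outdir, "gene_sets.tsv"))
  cre <- gen_cre_dataset(cfg)
  write_gene_models(cre$genes, file.path(outdir, "genes.gff3"))
  write_acr_bed(cre$acrs, file.path(outdir, "acrs.bed"))
  # FIMO coordinates are relative to the ACR sequence
  occ <- cre$occurrences
  occ_rel <- occ
  off <- stats::setNames(cre$acrs$start, cre$acrs$acr_id)
  occ_rel$start <- occ$start - off[occ$acr_id]
  occ_rel$end <- occ$end - off[occ$acr_id]
  write_fimo(occ_rel, file.path(outdir, "fimo.tsv"))
  sq <- gen_sequences(cfg)
  Biostrings::writeXStringSet(sq$cds, file.path(outdir, "cds.fasta"))
  Biostrings::writeXStringSet(sq$fragments, file.path(outdir, "fragments.fasta"))
  grn <- gen_grn(cfg)
  utils::write.table(grn$edges, file.path(outdir, "grn_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(grn$tf_families, file.path(outdir, "tf_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(grn$promoter_cres, file.path(outdir, "promoter_cres.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sq$truth$planted, file.path(outdir, "ground_truth_planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
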