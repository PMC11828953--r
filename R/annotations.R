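#' Read gene models from GFF3
#'
#' Parses gene and CDS features and derives the start- and stop-codon anchors
#' used for promoter/downstream windows. All internal coordinates are 0-based
#' half-open; GFF3's 1-based inclusive coordinates are converted at this
#' boundary. On the minus strand the start codon is the highest CDS
#' coordinate and "upstream" extends towards larger coordinates.
#'
#' Genes without any CDS feature are kept but flagged (`has_cds = FALSE`) and
#' excluded from context assignment, with a warning.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `start_codon`, `stop_codon` (0-based
#'   positions of the first base of each codon anchor), `has_cds`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  genes <- gr[is_gene]
  gid <- S4Vectors::mcols(genes)$ID
  if (anyDuplicated(gid)) stop("duplicate gene IDs in ", path)

  # Resolve each CDS to its gene through the Parent chain (CDS -> mRNA -> gene)
  id2parent <- stats::setNames(
    vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, ""),
    md$ID
  )
  # features without IDs (CDS commonly) still carry Parent
  cds <- gr[md$type == "CDS"]
  cds_parent <- vapply(S4Vectors::mcols(cds)$Parent,
                       function(p) if (length(p)) p[[1L]] else NA_character_, "")
  cds_gene <- ifelse(cds_parent %in% gid, cds_parent,
                     unname(id2parent[cds_parent]))

  out <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    stringsAsFactors = FALSE
  )
  if (any(!out$strand %in% c("+", "-"))) stop("gene with undefined strand in ", path)
  out$start_codon <- NA_integer_
  out$stop_codon <- NA_integer_
  out$has_cds <- FALSE
  for (i in seq_len(nrow(out))) {
    sel <- which(cds_gene == out$gene_id[i])
    if (length(sel) == 0L) next
    lo <- min(GenomicRanges::start(cds)[sel]) - 1L  # 0-based first base
    hi <- max(GenomicRanges::end(cds)[sel]) - 1L    # 0-based last base
    out$has_cds[i] <- TRUE
    if (out$strand[i] == "+") {
      out$start_codon[i] <- lo
      out$stop_codon[i] <- hi
    } else {
      out$start_codon[i] <- hi
      out$stop_codon[i] <- lo
    }
  }
  if (any(!out$has_cds)) {
    warning(sum(!out$has_cds), " gene(s) lack CDS features; excluded from context assignment")
  }
  bad <- out$has_cds &
    (pmin(out$start_codon, out$stop_codon) < out$start |
       pmax(out$start_codon, out$stop_codon) >= out$end)
  if (any(bad)) stop("codon anchors outside gene interval for: ",
                     paste(out$gene_id[bad], collapse = ", "))
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and a single CDS span per gene (covering the codon
#' anchors), converting internal 0-based half-open coordinates back to GFF3
#' 1-based inclusive. `read_gene_models(write_gene_models(x))` is the
#' identity on valid models.
#'
#' @param models data.frame as returned by [read_gene_models()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- character(0)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    gff <- function(type, s0, e0, id, parent = NULL) {
      attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
      sprintf("%s\tc4omics\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, s0 + 1L, e0, g$strand,
              if (type == "CDS") "0" else ".", attrs)
    }
    rows <- c(rows, gff("gene", g$start, g$end, g$gene_id))
    if (isTRUE(g$has_cds)) {
      mid <- paste0(g$gene_id, ".m1")
      lo <- min(g$start_codon, g$stop_codon)
      hi <- max(g$start_codon, g$stop_codon)
      rows <- c(rows,
                gff("mRNA", g$start, g$end, mid, g$gene_id),
                gff("CDS", lo, hi + 1L, paste0(mid, ".cds"), mid))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read accessible chromatin regions (ACRs) from BED
#'
#' BED is already 0-based half-open, so intervals pass through unchanged.
#' Interval names (column 4) become ACR ids; unnamed intervals get
#' `acr_<i>`.
#'
#' @param path BED3+ file.
#' @return data.frame `acr_id`, `chrom`, `start`, `end`.
#' @export
read_acr_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("acr_", seq_along(gr))
  data.frame(
    acr_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write ACR intervals to BED
#' @param acrs data.frame as from [read_acr_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acr_bed <- function(acrs, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", acrs$chrom, acrs$start, acrs$end,
                     acrs$acr_id), path)
  invisible(path)
}

#' Load genome annotations needed for context assignment
#'
#' @param gff3 gene-model GFF3 path.
#' @param acr_bed ACR BED path.
#' @param fasta optional genome FASTA path.
#' @return list with `genes`, `acrs`, and `seqs` (a
#'   [Biostrings::DNAStringSet] or `NULL`).
#' @export
load_genome_annotations <- function(gff3, acr_bed, fasta = NULL) {
  genes <- read_gene_models(gff3)
  acrs <- read_acr_bed(acr_bed)
  seqs <- NULL
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(unique(c(genes$chrom, acrs$chrom)), names(seqs))
    if (length(missing) > 0L) {
      stop("sequence id(s) in annotations absent from FASTA: ",
           paste(missing, collapse = ", "))
    }
  }
  list(genes = genes, acrs = acrs, seqs = seqs)
}

#' Read motif occurrences from a FIMO-dialect TSV
#'
#' Accepts the FIMO column layout (`motif_id`, `sequence_name`, `start`,
#' `stop`, `strand`, `score`, `p-value`, `q-value`, with or without
#' `motif_alt_id`). Rows above the q-value ceiling are dropped and counted;
#' FIMO's 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path TSV path.
#' @param q_max q-value ceiling; rows with `q > q_max` are dropped. Pass
#'   `NA` to disable filtering explicitly.
#' @return data.frame `cre_id`, `acr_id`, `start`, `end`, `strand`, `score`,
#'   `p_value`, `q_value`, with attribute `n_dropped`.
#' @export
read_fimo <- function(path, q_max = 0.05) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  names(df) <- tolower(gsub("[ .]", "_", names(df)))
  names(df)[names(df) == "p-value"] <- "p_value"
  names(df)[names(df) == "q-value"] <- "q_value"
  req <- c("motif_id", "sequence_name", "start", "stop")
  if (!all(req %in% names(df))) {
    stop("FIMO file ", path, " lacks required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (!"q_value" %in% names(df)) {
    if (is.na(q_max)) {
      df$q_value <- NA_real_
    } else {
      stop("no q-value column in ", path,
           "; pass q_max = NA to disable q-value filtering explicitly")
    }
  }
  n0 <- nrow(df)
  if (!is.na(q_max)) df <- df[df$q_value <= q_max, , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0L) message(n_dropped, " occurrence(s) dropped at q > ", q_max)
  out <- data.frame(
    cre_id = df$motif_id,
    acr_id = df$sequence_name,
    start = as.integer(df$start) - 1L,
    end = as.integer(df$stop),
    strand = if ("strand" %in% names(df)) df$strand else "+",
    score = if ("score" %in% names(df)) df$score else NA_real_,
    p_value = if ("p_value" %in% names(df)) df$p_value else NA_real_,
    q_value = df$q_value,
    stringsAsFactors = FALSE
  )
  if (any(out$end <= out$start)) stop("invalid interval in ", path)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write motif occurrences in the FIMO TSV dialect
#' @param occ data.frame as from [read_fimo()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fimo <- function(occ, path) {
  df <- data.frame(
    motif_id = occ$cre_id,
    sequence_name = occ$acr_id,
    start = occ$start + 1L,
    stop = occ$end,
    strand = occ$strand,
    score = occ$score,
    `p-value` = occ$p_value,
    `q-value` = occ$q_value,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write stage results with a manifest
#'
#' Each element of `results` (a named list of data.frames) is written as a
#' TSV with stable column order; a `manifest.tsv` records file names, row
#' counts, the configuration hash and the seed, so any output directory is
#' traceable to its settings.
#'
#' @param results named list of data.frames.
#' @param outdir output directory (created if needed).
#' @param cfg the [run_config()] used.
#' @param overwrite allow overwriting existing files.
#' @return The manifest data.frame, invisibly.
#' @export
write_results <- function(results, outdir, cfg = run_config(), overwrite = FALSE) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(cfg)
  files <- file.path(outdir, paste0(names(results), ".tsv"))
  exists <- file.exists(files)
  if (any(exists) && !overwrite) {
    stop("output file(s) exist (use overwrite = TRUE): ",
         paste(basename(files[exists]), collapse = ", "))
  }
  rows <- integer(length(files))
  for (i in seq_along(results)) {
    df <- as.data.frame(results[[i]])
    utils::write.table(df, files[i], sep = "\t", quote = FALSE, row.names = FALSE)
    rows[i] <- nrow(df)
  }
  manifest <- data.frame(
    file = basename(files), rows = rows, config_hash = h, seed = cfg$seed,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
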