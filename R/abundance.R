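#' Gene-by-sample abundance table
#'
#' The shared quantification container for the three omics roles: RNA-seq
#' transcript abundance (TPM), proteomics (iBAQ), and ribosome-protected
#' fragments from Ribo-seq (TPM). Rows are genes; columns are samples, each
#' tagged with a species code and replicate index. Missing measurements are
#' stored as `NA` ("absent"), never as zero: non-detection in label-free
#' proteomics is censoring, not absence of protein.
#'
#' @param values numeric matrix, genes x samples; finite non-negative or `NA`.
#' @param role one of `"rna"`, `"protein"`, `"rpf"`.
#' @param units `"TPM"` or `"iBAQ"`; defaults to `"iBAQ"` for the protein
#'   role and `"TPM"` otherwise.
#' @param samples optional data.frame with columns `sample`, `species`,
#'   `replicate`; parsed from `SPECIES_R<k>` column names when omitted.
#'
#' @return An `abundance_table` object.
#' @export
abundance_table <- function(values, role = c("rna", "protein", "rpf"),
                            units = NULL, samples = NULL) {
  role <- match.arg(role)
  if (is.null(units)) units <- if (role == "protein") "iBAQ" else "TPM"
  stopifnot(units %in% c("TPM", "iBAQ"))
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must carry gene identifiers as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  bad <- !is.na(values) & (!is.finite(values) | values < 0)
  if (any(bad)) stop("abundance values must be finite and non-negative")
  if (is.null(samples)) samples <- parse_sample_names(colnames(values))
  stopifnot(
    nrow(samples) == ncol(values),
    all(c("sample", "species", "replicate") %in% names(samples)),
    all(samples$replicate >= 1),
    !anyNA(samples$species)
  )
  structure(
    list(role = role, units = units, values = values,
         samples = as.data.frame(samples, stringsAsFactors = FALSE)),
    class = "abundance_table"
  )
}

# SPECIES_R<k> header dialect, e.g. "Ftri_R3" -> species Ftri, replicate 3
parse_sample_names <- function(x) {
  if (is.null(x)) stop("sample names required")
  m <- regmatches(x, regexec("^(.*)_R([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed sample header(s): ", paste(x[bad], collapse = ", "),
         " (expected SPECIES_R<k>)")
  }
  data.frame(
    sample = x,
    species = vapply(m, `[`, "", 2L),
    replicate = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> role=%s units=%s: %d genes x %d samples (%d species)\n",
              x$role, x$units, nrow(x$values), ncol(x$values),
              length(unique(x$samples$species))))
  invisible(x)
}

#' Read an abundance table from TSV
#'
#' Expects a header row `gene<TAB>SPECIES_R1<TAB>...` and one row per gene.
#' Empty fields and `NA` are kept as absent values. Negative or non-numeric
#' abundances are rejected with the offending file and line number.
#'
#' @param path TSV file path.
#' @inheritParams abundance_table
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path, role, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header in ", path, " (line 1): need gene + sample columns")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop("duplicate gene id '", dup, "' in ", path)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  bad <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative abundance in %s (line %d, column %s)",
                 path, bad[1L, 1L] + 1L, colnames(vals)[bad[1L, 2L]]))
  }
  abundance_table(vals, role = role, units = units)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_tsv()]: the round trip reproduces values
#' bit-exactly (numbers are written with full precision).
#'
#' @param x an [abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(gene = rownames(x$values),
                   as.data.frame(format(x$values, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1L][is.na(x$values)] <- NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the multi-omics bundle
#'
#' Reads one abundance TSV per role and aligns all tables on the union of
#' gene identifiers; genes missing from a file are recorded as absent (`NA`),
#' not zero.
#'
#' @param paths named character vector or list, names in
#'   `c("rna", "protein", "rpf")`, values file paths.
#' @param cfg a [run_config()] (reserved for format options).
#' @return Named list of [abundance_table()] objects, one per role.
#' @export
load_omics_bundle <- function(paths, cfg = run_config()) {
  roles <- names(paths)
  if (is.null(roles) || !all(roles %in% c("rna", "protein", "rpf"))) {
    stop("paths must be named with roles rna/protein/rpf")
  }
  tabs <- lapply(roles, function(r) read_abundance_tsv(paths[[r]], role = r))
  names(tabs) <- roles
  all_genes <- sort(unique(unlist(lapply(tabs, function(t) rownames(t$values)))))
  lapply(tabs, function(t) {
    v <- matrix(NA_real_, length(all_genes), ncol(t$values),
                dimnames = list(all_genes, colnames(t$values)))
    v[rownames(t$values), ] <- t$values
    abundance_table(v, role = t$role, units = t$units, samples = t$samples)
  })
}

#' Aggregate replicates to species-level summaries
#'
#' Arithmetic mean and SD per gene per species over replicate columns, plus a
#' detection flag (mean present and at least `min_detect`). A single
#' replicate yields SD 0. Absent replicates are dropped from the mean; a gene
#' absent in every replicate of a species has mean `NA` (undetected).
#'
#' @param x an [abundance_table()].
#' @param min_detect detection floor applied to the species mean (default the
#'   TPM floor of [run_config()]; use 0 with iBAQ where any detected value
#'   counts).
#' @return List with matrices `mean`, `sd` (genes x species) and logical
#'   `detected`.
#' @export
aggregate_replicates <- function(x, min_detect = 1) {
  stopifnot(inherits(x, "abundance_table"))
  species <- unique(x$samples$species)
  if (any(!species %in% x$samples$species)) stop("species with zero samples")
  agg <- function(f) {
    vapply(species, function(sp) {
      cols <- x$samples$sample[x$samples$species == sp]
      if (length(cols) == 0L) stop("species with zero samples: ", sp)
      f(x$values[, cols, drop = FALSE])
    }, numeric(nrow(x$values)))
  }
  m <- agg(function(v) rowMeans(v, na.rm = TRUE))
  m[is.nan(m)] <- NA_real_
  s <- agg(function(v) {
    n <- rowSums(!is.na(v))
    out <- apply(v, 1L, stats::sd, na.rm = TRUE)
    out[n == 1L] <- 0
    out[n == 0L] <- NA_real_
    out
  })
  m <- matrix(m, nrow(x$values), length(species))
  s <- matrix(s, nrow(x$values), length(species))
  dimnames(m) <- dimnames(s) <- list(rownames(x$values), species)
  list(mean = m, sd = s, detected = !is.na(m) & m >= min_detect)
}

#' Gene set
#'
#' A named, non-empty, duplicate-free set of gene identifiers (e.g. the C4
#' enzyme/transporter genes, photosynthesis genes, photorespiratory genes).
#'
#' @param name set label.
#' @param members character vector of gene ids.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' Read gene sets from a two-column TSV (set name, gene id)
#'
#' @param path TSV with columns `set` and `gene` (header required).
#' @return Named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set", "gene") %in% names(df)))
  sets <- split(df$gene, df$set)
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) gene_set(nm, sets[[nm]]))
}

#' Write gene sets to TSV
#' @param sets named list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set = s$name, gene = s$members, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
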