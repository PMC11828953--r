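#' Gene regulatory network container
#'
#' Holds TF-to-target edges together with the TF family annotation, the
#' per-gene promoter CRE-family predictions (from the upstream window), and
#' the cognate TF-family-to-CRE-family map used for filtering. Network
#' inference itself is an input; this package only refines and summarizes.
#'
#' @param edges data.frame with columns `tf`, `target` (and optional
#'   `weight`).
#' @param tf_families data.frame with columns `tf`, `family`.
#' @param promoter_cres data.frame with columns `gene`, `cre_family`.
#' @param cognate_map data.frame with columns `tf_family`, `cre_family`
#'   (default [default_cognate_map()]).
#' @param allow_self allow self-loop edges (default FALSE).
#' @return A `grn` object.
#' @export
grn <- function(edges, tf_families, promoter_cres,
                cognate_map = default_cognate_map(), allow_self = FALSE) {
  stopifnot(all(c("tf", "target") %in% names(edges)),
            all(c("tf", "family") %in% names(tf_families)),
            all(c("gene", "cre_family") %in% names(promoter_cres)),
            all(c("tf_family", "cre_family") %in% names(cognate_map)))
  if (!allow_self && any(edges$tf == edges$target)) {
    stop("self-loop edge(s) present; pass allow_self = TRUE to keep them")
  }
  structure(list(edges = edges, tf_families = tf_families,
                 promoter_cres = promoter_cres, cognate_map = cognate_map),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d edges, %d TFs, %d regulated genes\n",
              nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$target))))
  invisible(x)
}

#' Filter edges by cognate promoter CREs
#'
#' Keeps an edge TF -> gene only when the gene's predicted promoter
#' CRE-family set contains a family cognate to the TF's family, i.e. the
#' predicted regulation is supported by a binding site of the right family
#' in the target's promoter. Edges from TFs with no family annotation are
#' dropped with a warning. Idempotent.
#'
#' @param g a [grn()].
#' @return The filtered [grn()], with attribute `n_removed`.
#' @export
filter_tfs_by_cognate_cre <- function(g) {
  stopifnot(inherits(g, "grn"))
  fam <- stats::setNames(g$tf_families$family, g$tf_families$tf)
  cre_of <- stats::setNames(g$cognate_map$cre_family, g$cognate_map$tf_family)
  e <- g$edges
  unknown <- !(e$tf %in% names(fam)) | !(fam[e$tf] %in% names(cre_of))
  if (any(unknown)) {
    warning(sum(unknown), " edge(s) dropped: TF without (cognate-mapped) family")
  }
  key_have <- paste(g$promoter_cres$gene, g$promoter_cres$cre_family)
  need <- paste(e$target, cre_of[fam[e$tf]])
  keep <- !unknown & need %in% key_have
  out <- g
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  structure(out, n_removed = sum(!keep))
}

#' Extract the sub-network over a target gene set
#'
#' Restricts the network to edges whose target gene belongs to the set (the
#' C4 sub-network when given the C4 gene set); TFs without a retained edge
#' drop out.
#'
#' @param g a [grn()] (typically already cognate-filtered).
#' @param target a [gene_set()].
#' @return The sub-[grn()].
#' @export
extract_target_grn <- function(g, target) {
  stopifnot(inherits(g, "grn"), inherits(target, "gene_set"))
  out <- g
  out$edges <- g$edges[g$edges$target %in% target$members, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' TF-family composition of a sub-network
#'
#' Counts distinct TFs per family (descending, top five flagged) and
#' computes the ERF-per-target-gene rate: distinct ERF TFs in the
#' sub-network divided by the number of target-set genes it regulates.
#'
#' @param g a [grn()] (the sub-network to summarize).
#' @param target a [gene_set()] (denominator of the per-gene rate).
#' @return list with `families` (data.frame `family`, `n_tfs`, `top5`) and
#'   `erf_per_target_gene`.
#' @export
tf_family_summary <- function(g, target) {
  stopifnot(inherits(g, "grn"), inherits(target, "gene_set"))
  fam <- stats::setNames(g$tf_families$family, g$tf_families$tf)
  tfs <- unique(g$edges$tf)
  tab <- sort(table(fam[tfs]), decreasing = TRUE)
  families <- data.frame(
    family = names(tab), n_tfs = as.integer(tab),
    top5 = seq_along(tab) <= 5L,
    stringsAsFactors = FALSE
  )
  reg <- unique(g$edges$target[g$edges$target %in% target$members])
  erf_tfs <- unique(g$edges$tf[fam[g$edges$tf] == "ERF" &
                                 g$edges$target %in% target$members])
  list(
    families = families,
    erf_per_target_gene = if (length(reg) > 0L) {
      length(erf_tfs) / length(reg)
    } else NA_real_
  )
}
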