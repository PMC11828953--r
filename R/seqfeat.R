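#' GC content at third codon positions (GC3)
#'
#' Fraction of codons whose third base is G or C. Codons with N at the third
#' position are excluded from numerator and denominator; the excluded count
#' is reported. Sequences must be whole numbers of codons.
#'
#' @param x character vector of CDS, or a [Biostrings::DNAStringSet] /
#'   [Biostrings::DNAString].
#' @return Named numeric vector of GC3 fractions with attribute
#'   `n_excluded` (codons skipped for N at position 3, per sequence).
#' @export
gc3 <- function(x) {
  if (inherits(x, "DNAString")) x <- as.character(x)
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  x <- toupper(x)
  out <- numeric(length(x))
  excl <- integer(length(x))
  for (i in seq_along(x)) {
    n <- nchar(x[i])
    if (n == 0L) stop("empty CDS")
    if (n %% 3L != 0L) stop("CDS length not a multiple of 3 (", n, " nt)")
    b3 <- strsplit(x[i], "")[[1L]][seq(3L, n, by = 3L)]
    if (any(!b3 %in% c("A", "C", "G", "T", "N"))) {
      stop("CDS contains characters outside ACGTN")
    }
    use <- b3 != "N"
    excl[i] <- sum(!use)
    if (!any(use)) stop("no informative codons (all third positions are N)")
    out[i] <- mean(b3[use] %in% c("G", "C"))
  }
  names(out) <- names(x)
  structure(out, n_excluded = excl)
}

#' Scan a sequence for inverted repeats flanked by target-site duplications
#'
#' Detects the sequence signature of retrotransposon-mediated gene
#' duplication: a pair of inverted repeats (a segment followed downstream by
#' its reverse complement) immediately flanked on the outside by identical
#' direct repeats (the target-site duplication, TSD, created on insertion).
#'
#' Reports every maximal inverted-repeat pair `(i, j, L)` — `seq[i, i+L)`
#' reverse-complementing `seq[j, j+L)` within the mismatch budget, not
#' extendable in `L` — of length at least `min_ir` with spacer at most
#' `max_spacer`, that carries identical direct repeats of some length `t` in
#' `tsd_range` immediately outside the pair; the largest qualifying `t` is
#' reported. Bases `N` never match. Results are sorted by score
#' `L + t - 2 * mismatches` (descending), ties broken by leftmost position.
#'
#' @param seq a single DNA sequence (character or
#'   [Biostrings::DNAString]).
#' @param min_ir minimum inverted-repeat length in bp (default 6).
#' @param tsd_range length-2 integer range of direct-repeat lengths
#'   (default `c(3, 6)`).
#' @param max_spacer maximum distance between the repeats (default 5000).
#' @param max_mismatch mismatch budget inside the inverted repeat
#'   (default 0).
#' @return data.frame (`left_start`, `left_end`, `right_start`,
#'   `right_end` — 0-based half-open — `ir_len`, `spacer_len`, `tsd_len`,
#'   `mismatches`, `ir_seq`, `tsd_seq`, `score`), empty when nothing
#'   qualifies (including sequences too short to hold a signature).
#' @export
find_inverted_repeat_tsd <- function(seq, min_ir = 6L, tsd_range = c(3L, 6L),
                                     max_spacer = 5000L, max_mismatch = 0L) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L,
            min_ir >= 1L, length(tsd_range) == 2L,
            tsd_range[1] >= 1L, tsd_range[1] <= tsd_range[2],
            max_spacer >= 0L, max_mismatch >= 0L)
  s <- strsplit(toupper(seq), "")[[1L]]
  if (any(!s %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside ACGTN")
  }
  n <- length(s)
  empty <- data.frame(
    left_start = integer(0), left_end = integer(0),
    right_start = integer(0), right_end = integer(0),
    ir_len = integer(0), spacer_len = integer(0), tsd_len = integer(0),
    mismatches = integer(0), ir_seq = character(0), tsd_seq = character(0),
    score = numeric(0), stringsAsFactors = FALSE
  )
  if (n < 2L * min_ir + 2L * tsd_range[1]) return(empty)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  cs <- unname(comp[s])
  res <- list()
  # A complementary pairing (p, q), p < q (1-based), lies on anti-diagonal
  # D = p + q; contiguous pairings along one anti-diagonal form an inverted
  # repeat. Arms must not overlap, so p is confined below the centre D/2.
  for (D in seq(2L * (tsd_range[1] + 1L) + 1L, 2L * n - 1L)) {
    p_lo <- max(1L, D - n)
    p_hi <- (D - 1L) %/% 2L               # strictly below the centre
    if (p_hi - p_lo + 1L < min_ir) next
    pv <- p_lo:p_hi
    v <- s[pv] == cs[D - pv]
    if (!any(v)) next
    cand <- if (max_mismatch == 0L) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- r$values & r$lengths >= min_ir
      if (!any(ok)) NULL else cbind(starts[ok], ends[ok], rep(0L, sum(ok)))
    } else {
      windows_with_mismatch(v, min_ir, max_mismatch)
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    for (r_i in seq_len(nrow(cand))) {
      a <- pv[cand[r_i, 1L]]
      b <- pv[cand[r_i, 2L]]
      mm <- cand[r_i, 3L]
      L <- b - a + 1L
      i0 <- a - 1L                         # 0-based left IR start
      j0 <- (D - b) - 1L                   # 0-based right IR start
      spacer <- j0 - (i0 + L)
      if (spacer < 0L || spacer > max_spacer) next
      # largest TSD in range with identical, N-free direct repeats
      tsd_len <- NA_integer_
      for (t in seq(tsd_range[2], tsd_range[1])) {
        if (i0 - t < 0L || j0 + L + t > n) next
        left <- s[(i0 - t + 1L):i0]
        right <- s[(j0 + L + 1L):(j0 + L + t)]
        if (all(left == right) && !any(left == "N")) {
          tsd_len <- t
          break
        }
      }
      if (is.na(tsd_len)) next
      res[[length(res) + 1L]] <- data.frame(
        left_start = i0, left_end = i0 + L,
        right_start = j0, right_end = j0 + L,
        ir_len = L, spacer_len = spacer, tsd_len = tsd_len,
        mismatches = mm,
        ir_seq = paste(s[a:b], collapse = ""),
        tsd_seq = paste(s[(i0 - tsd_len + 1L):i0], collapse = ""),
        score = L + tsd_len - 2 * mm,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(-out$score, out$left_start, out$right_start), ]
  rownames(out) <- NULL
  out
}

# maximal windows over a logical vector with at most m FALSE entries,
# TRUE at both ends, length >= min_len; returns cbind(start, end, n_false)
windows_with_mismatch <- function(v, min_len, m) {
  n <- length(v)
  out <- NULL
  lo <- 1L
  nf <- 0L
  for (hi in seq_len(n)) {
    if (!v[hi]) nf <- nf + 1L
    while (nf > m) {
      if (!v[lo]) nf <- nf - 1L
      lo <- lo + 1L
    }
    # window [lo, hi] is the widest budget-respecting window ending at hi;
    # it is maximal iff it cannot extend right (hi == n or would bust budget)
    ext <- hi < n && (v[hi + 1L] || nf < m)
    if (!ext) {
      a <- lo; b <- hi
      while (a <= b && !v[a]) { a <- a + 1L; nf <- nf } # trim to TRUE ends
      bb <- b
      while (bb >= a && !v[bb]) bb <- bb - 1L
      if (bb - a + 1L >= min_len) {
        n_false <- sum(!v[a:bb])
        if (is.null(out) || !(out[nrow(out), 1L] <= a && out[nrow(out), 2L] >= bb)) {
          out <- rbind(out, c(a, bb, n_false))
        }
      }
    }
  }
  unique(out)
}

#' Scan a sequence set for retroduplication signatures
#'
#' Applies [find_inverted_repeat_tsd()] to each sequence of a set.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param ... passed to [find_inverted_repeat_tsd()].
#' @return data.frame with a leading `seq_id` column.
#' @export
scan_retro_signatures <- function(seqs, ...) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  do.call(rbind, lapply(seq_along(seqs), function(i) {
    df <- find_inverted_repeat_tsd(seqs[[i]], ...)
    if (nrow(df) == 0L) return(NULL)
    cbind(seq_id = ids[i], df, stringsAsFactors = FALSE)
  }))
}

#' Identify the functional copy within a paralog group
#'
#' Applies the two transcript-abundance criteria for calling a paralog the
#' functional copy of a C4-pathway gene: (1) it has the highest transcript
#' abundance among the group's members in C4-type species, and (2) that
#' abundance exceeds the abundance of every counterpart member in C3-type
#' species. A tie at criterion 1 returns no call with a tie flag.
#'
#' @param group data.frame with columns `gene`, `species`, `tpm` (one row
#'   per member per species; typically species-mean TPM).
#' @param c4_species,c3_species character vectors of species codes.
#' @return list with `gene` (identifier or `NA`), `tie` (logical), and
#'   `trace` (data.frame recording both criteria evaluations).
#' @export
identify_functional_copy <- function(group, c4_species, c3_species) {
  stopifnot(all(c("gene", "species", "tpm") %in% names(group)))
  if (nrow(group) == 0L || all(is.na(group$tpm))) stop("no expression data")
  c4 <- group[group$species %in% c4_species & !is.na(group$tpm), ]
  c3 <- group[group$species %in% c3_species & !is.na(group$tpm), ]
  if (nrow(c4) == 0L || nrow(c3) == 0L) {
    stop("group needs expression in at least one C4-type and one C3-type species")
  }
  mx <- max(c4$tpm)
  top <- c4$gene[c4$tpm == mx]
  tie <- length(top) > 1L
  c3_max <- max(c3$tpm)
  crit2 <- mx > c3_max
  trace <- data.frame(
    criterion = c("highest_in_c4_group", "exceeds_c3_counterpart"),
    value = c(mx, c3_max),
    passed = c(!tie, crit2),
    stringsAsFactors = FALSE
  )
  gene <- if (!tie && crit2) top else NA_character_
  list(gene = gene, tie = tie, trace = trace)
}
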