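# Independent brute-force oracles. These deliberately use different
# algorithms from the package implementations they check.

BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "?")

# Per-pair extension scan for inverted repeats with flanking direct repeats:
# O(n^2 * L * t), mismatch-free. Enumerates every (left-start i, right-end j)
# complementary pairing that cannot extend outward, extends inward while the
# arms stay disjoint, then looks for the largest qualifying direct repeat.
oracle_ir_tsd <- function(seq, min_ir = 6, tsd_range = c(3, 6),
                          max_spacer = 5000) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (s[j] != BASE_COMP[[s[i]]]) next
      if (i > 1 && j < n && s[i - 1] == BASE_COMP[[s[j + 1]]]) next  # not a run start
      L <- 1
      while (i + L < j - L && s[i + L] == BASE_COMP[[s[j - L]]]) L <- L + 1
      if (L < min_ir) next
      spacer <- (j - L + 1) - (i + L)
      if (spacer < 0 || spacer > max_spacer) next
      tl <- NA_integer_
      for (t in rev(seq(tsd_range[1], tsd_range[2]))) {
        if (i - t < 1 || j + t > n) next
        left <- s[(i - t):(i - 1)]
        right <- s[(j + 1):(j + t)]
        if (all(left == right) && !any(left == "N")) {
          tl <- t
          break
        }
      }
      if (is.na(tl)) next
      out <- rbind(out, data.frame(left_start = i - 1, right_start = j - L,
                                   ir_len = L, tsd_len = tl))
    }
  }
  out
}

# Definitional step-up BH: q_(i) = min_{j >= i} m * p_(j) / j on sorted p
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by direct summation of choose() terms
oracle_hyper_tail <- function(k_c, n_c, N, k) {
  xs <- k_c:min(n_c, k)
  sum(exp(lchoose(n_c, xs) + lchoose(N - n_c, k - xs) - lchoose(N, k)))
}

# Exact two-sided rank-sum p by enumerating all rank assignments
oracle_wilcox_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_null <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
}

# All-pairs interval/distance context oracle (no interval-tree machinery)
oracle_context <- function(occ, genes, window = 3000) {
  res <- list()
  ov <- function(o, s, e) occ$start[o] < e && occ$end[o] > s
  for (o in seq_len(nrow(occ))) {
    for (g in seq_len(nrow(genes))) {
      if (occ$chrom[o] != genes$chrom[g]) next
      if (ov(o, genes$start[g], genes$end[g])) {
        res[[length(res) + 1]] <- c(o, genes$gene_id[g], "gACR")
      }
      if (!isTRUE(genes$has_cds[g])) next
      sc <- genes$start_codon[g]
      st <- genes$stop_codon[g]
      if (genes$strand[g] == "+") {
        up <- c(max(sc - window, 0), sc)
        dn <- c(st + 1, st + 1 + window)
      } else {
        up <- c(sc + 1, sc + 1 + window)
        dn <- c(max(st - window, 0), st)
      }
      if (up[2] > up[1] && ov(o, up[1], up[2])) {
        res[[length(res) + 1]] <- c(o, genes$gene_id[g], "upACR")
      }
      if (dn[2] > dn[1] && ov(o, dn[1], dn[2])) {
        res[[length(res) + 1]] <- c(o, genes$gene_id[g], "downACR")
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(occ_idx = integer(0), gene_id = character(0),
                      context = character(0)))
  }
  m <- do.call(rbind, res)
  data.frame(occ_idx = as.integer(m[, 1]), gene_id = m[, 2], context = m[, 3],
             stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# small abundance table straight from a matrix
tiny_table <- function(values, role) {
  c4omics::abundance_table(values, role = role)
}
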