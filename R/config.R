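#' Analysis run configuration
#'
#' Bundles every tunable threshold of the pipeline so that each stage can be
#' re-run reproducibly from a single object. Defaults follow the study design
#' the package emulates: 1000 Monte Carlo permutations, 3 kb promoter and
#' downstream windows, a FIMO q-value ceiling of 0.05, mean +/- 1 SD
#' protein-to-mRNA classes and top/bottom 5% translation-efficiency classes.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param B number of Monte Carlo permutations (>= 1).
#' @param sd_multiplier multiplier m for the mean +/- m*SD abundance-ratio
#'   classification.
#' @param extreme_frac tail fraction for extreme-value classification,
#'   in (0, 0.5).
#' @param min_tpm detection floor: a gene counts as detected in a TPM role
#'   when its species-mean abundance is at least this value.
#' @param fimo_q_max maximum motif-occurrence q-value retained at load time;
#'   `NA` disables the filter explicitly.
#' @param window_bp width in bp of the upstream (from the start codon) and
#'   downstream (from the stop codon) windows used for context assignment.
#' @param anova_alpha gate: pairwise tests are flagged "gated" when the
#'   one-way ANOVA p-value is not below this.
#' @param ptr_log_scale logical; classify protein-to-mRNA ratios on the log10
#'   scale (default) rather than the linear scale.
#' @param te_normalizer `"mean"` (default) or `"median"` summary of the
#'   normalization gene set's raw translation efficiency.
#' @param p_mode permutation p-value estimator: `"ge_plus_one"` (default,
#'   `(1 + #{count >= observed}) / (B + 1)`) or `"strict_paper"`
#'   (`#{count > observed} / B`).
#' @param perm_mode `"without"` (default; draws without replacement, exact
#'   multivariate hypergeometric) or `"multinomial"` (with replacement).
#' @param outdir default output directory for [write_results()].
#'
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(seed = 1L,
                       B = 1000L,
                       sd_multiplier = 1,
                       extreme_frac = 0.05,
                       min_tpm = 1,
                       fimo_q_max = 0.05,
                       window_bp = 3000L,
                       anova_alpha = 0.05,
                       ptr_log_scale = TRUE,
                       te_normalizer = c("mean", "median"),
                       p_mode = c("ge_plus_one", "strict_paper"),
                       perm_mode = c("without", "multinomial"),
                       outdir = ".") {
  te_normalizer <- match.arg(te_normalizer)
  p_mode <- match.arg(p_mode)
  perm_mode <- match.arg(perm_mode)
  stopifnot(
    is.numeric(seed), length(seed) == 1L, is.finite(seed),
    is.numeric(B), length(B) == 1L, B >= 1,
    is.numeric(sd_multiplier), sd_multiplier > 0,
    is.numeric(extreme_frac), extreme_frac > 0, extreme_frac < 0.5,
    is.numeric(min_tpm), min_tpm >= 0,
    is.numeric(window_bp), window_bp > 0,
    is.numeric(anova_alpha), anova_alpha > 0, anova_alpha < 1
  )
  if (!is.na(fimo_q_max)) {
    stopifnot(is.numeric(fimo_q_max), fimo_q_max >= 0, fimo_q_max <= 1)
  }
  structure(
    list(
      seed = as.integer(seed), B = as.integer(B),
      sd_multiplier = sd_multiplier, extreme_frac = extreme_frac,
      min_tpm = min_tpm, fimo_q_max = fimo_q_max,
      window_bp = as.integer(window_bp), anova_alpha = anova_alpha,
      ptr_log_scale = ptr_log_scale, te_normalizer = te_normalizer,
      p_mode = p_mode, perm_mode = perm_mode, outdir = outdir
    ),
    class = "run_config"
  )
}

#' Stable fingerprint of a configuration
#'
#' Serializes the configuration deterministically and returns its MD5 digest.
#' Any change to any field changes the hash; the hash is recorded in output
#' manifests so results can be traced back to the settings that produced them.
#'
#' @param cfg a [run_config()] (or any list of simple values).
#' @return A length-1 character MD5 hex digest.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(cfg[order(names(cfg))]), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> hash", substr(config_hash(x), 1, 8), "\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}
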