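# Normalisation (FPKM for long RNAs, TPM for small-RNA tags) and the
# differential-expression surrogate.
#
# The DE caller is deliberately simple and fully documented: Welch's two
# sample t-test on log2(abundance + pseudocount), BH adjustment within the
# contrast, and class-specific status rules (mRNA/lncRNA: q < alpha and
# |log2FC| >= 1; miRNA: raw p below its own cutoff and |log2FC| >= 1).
# "fold change >= 2" and "|log2FC| > 1" are treated as the same rule, applied
# boundary-inclusive as |log2FC| >= 1.

#' FPKM normalisation
#'
#' FPKM_i = count_i / ((length_i / 1e3) * (library_total / 1e6)) per sample.
#' The transformation is exactly invertible, which yields the conservation
#' identity `sum_i FPKM_i * (length_i/1e3) * (total/1e6) = total` used as a
#' self-check in the test suite.
#'
#' @param counts Wide tibble: feature column first, one count column per sample.
#' @param lengths Tibble with columns `feature_id`, `length` (bp, > 0), or a
#'   named numeric vector.
#' @return A wide tibble of FPKM values with the same shape as `counts`.
#' @export
fpkm <- function(counts, lengths) {
  m <- expr_to_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$feature_id)
  }
  len <- lengths[rownames(m)]
  if (anyNA(len)) abort("missing transcript length for some features")
  if (any(len <= 0)) abort("transcript lengths must be positive")
  totals <- colSums(m)
  if (any(totals <= 0)) abort("zero library size in at least one sample")
  out <- sweep(m / (len / 1e3), 2, totals / 1e6, `/`)
  res <- matrix_to_expr(out, id_col = names(counts)[1])
  cf_log("fpkm", "%d features x %d samples normalised to FPKM", nrow(m), ncol(m))
  res
}

#' TPM normalisation for small-RNA tag counts
#'
#' TPM_i = count_i * 1e6 / library_total; column sums are exactly 1e6 (to
#' floating-point rounding).
#'
#' @param counts Wide tibble of per-miRNA tag counts.
#' @return A wide tibble of TPM values.
#' @export
tpm_small <- function(counts) {
  m <- expr_to_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) abort("zero library total in at least one sample")
  out <- sweep(m, 2, totals / 1e6, `/`)
  matrix_to_expr(out, id_col = names(counts)[1])
}

#' Enumerate the study design's pairwise contrasts
#'
#' For the 2 genotypes x 3 leaf positions design this produces the nine
#' standard comparisons: the three between-genotype contrasts at matched leaf
#' position, and the three within-genotype leaf contrasts for each genotype.
#'
#' @param samples Sample-metadata tibble with columns `sample`, `genotype`,
#'   `leaf`.
#' @return A tibble with columns `contrast`, `type` (`between_genotype` /
#'   `within_genotype`), and list-columns `a` and `b` of sample ids
#'   (`b` is the numerator group of the fold change).
#' @export
enumerate_contrasts <- function(samples) {
  leaves <- unique(samples$leaf)
  genos <- unique(samples$genotype)
  rows <- list()
  grab <- function(g, l) samples$sample[samples$genotype == g & samples$leaf == l]
  if (all(c("wild", "mutant") %in% genos)) {
    for (l in leaves) {
      rows[[length(rows) + 1]] <- tibble(
        contrast = paste0("wild_", l, "_vs_mutant_", l),
        type = "between_genotype",
        a = list(grab("wild", l)), b = list(grab("mutant", l))
      )
    }
  }
  for (g in genos) {
    if (length(leaves) >= 2) {
      cmb <- utils::combn(leaves, 2)
      for (j in seq_len(ncol(cmb))) {
        rows[[length(rows) + 1]] <- tibble(
          contrast = paste0(g, "_", cmb[1, j], "_vs_", g, "_", cmb[2, j]),
          type = "within_genotype",
          a = list(grab(g, cmb[1, j])), b = list(grab(g, cmb[2, j]))
        )
      }
    }
  }
  bind_rows(rows)
}

#' Differential-expression surrogate (Welch's t on log2 abundance)
#'
#' Calls differential expression between two sample groups on a normalised
#' abundance matrix. The log2 fold change is
#' `log2((mean_B + c) / (mean_A + c))` with pseudocount `c`; the p-value is
#' Welch's two-sample t on `log2(x + c)`; q is BH-adjusted within the
#' contrast. Status rules by feature class: `mRNA` and `lncRNA` require
#' `q < alpha` and `|log2FC| >= lfc_cutoff`; `miRNA` requires raw
#' `p < p_mirna` and `|log2FC| >= lfc_cutoff`.
#'
#' Swapping the two groups negates every log2FC and leaves p unchanged.
#'
#' @param expr Wide abundance tibble (FPKM/TPM scale).
#' @param group_a,group_b Character vectors of sample ids (disjoint, >= 2 each).
#' @param feature_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param contrast Label stored in the result (default built from the groups).
#' @param alpha FDR threshold for mRNA/lncRNA status (default 0.05).
#' @param lfc_cutoff Absolute log2FC threshold, boundary inclusive (default 1).
#' @param p_mirna Raw p-value threshold for the miRNA class (default 0.05; the
#'   0.07 variant used in some reports can be passed here).
#' @param pseudocount Pseudocount `c` on the normalised scale (default 1).
#' @return A tibble with columns `feature_id`, `contrast`, `log2fc`, `p`,
#'   `q`, `status` (`up`/`down`/`ns`), class `cerna_de`.
#' @export
call_de <- function(expr, group_a, group_b, feature_class = c("mRNA", "lncRNA", "miRNA"),
                    contrast = NULL, alpha = 0.05, lfc_cutoff = 1,
                    p_mirna = 0.05, pseudocount = 1) {
  feature_class <- match.arg(feature_class)
  m <- expr_to_matrix(expr)
  if (length(intersect(group_a, group_b)) > 0) abort("sample groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 replicates")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0) {
    abort(paste0("samples absent from matrix: ", paste(missing, collapse = ", ")))
  }
  contrast <- contrast %||% paste0(paste(group_a, collapse = "+"), "_vs_",
                                   paste(group_b, collapse = "+"))
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  lfc <- log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))
  res <- welch_t_rows(log2(a + pseudocount), log2(b + pseudocount))
  q <- bh_fdr(res$p)
  sig <- if (feature_class == "miRNA") res$p < p_mirna else q < alpha
  status <- case_when(
    sig & lfc >= lfc_cutoff ~ "up",
    sig & lfc <= -lfc_cutoff ~ "down",
    .default = "ns"
  )
  cf_log("de", "%s %s: %d features, thresholds |log2FC|>=%g %s, %d up / %d down",
         feature_class, contrast, nrow(m), lfc_cutoff,
         if (feature_class == "miRNA") sprintf("p<%g", p_mirna) else sprintf("q<%g", alpha),
         sum(status == "up"), sum(status == "down"))
  out <- tibble(
    feature_id = rownames(m),
    contrast = contrast,
    log2fc = unname(lfc),
    p = res$p,
    q = q,
    status = status
  )
  class(out) <- c("cerna_de", class(out))
  out
}

# Row-wise Welch two-sample t-test, vectorised over features. Verified against
# stats::t.test in the unit tests. Degenerate rows (zero variance in both
# groups) get p = 1 when the means agree and p = 0 when they differ.
welch_t_rows <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(mb[degen] == ma[degen], 1, 0)
    tstat[degen] <- ifelse(mb[degen] == ma[degen], 0, Inf)
  }
  list(t = unname(tstat), df = unname(df), p = unname(p))
}

#' Run a DE contrast table over a metadata-driven design
#'
#' Convenience wrapper applying [call_de()] to every row of
#' [enumerate_contrasts()] output.
#'
#' @param expr Wide abundance tibble.
#' @param samples Sample metadata.
#' @param feature_class Feature class forwarded to [call_de()].
#' @param contrasts Optional contrast tibble; defaults to the full enumeration.
#' @param ... Further arguments to [call_de()].
#' @return A `cerna_de` tibble with one block of rows per contrast.
#' @export
call_de_all <- function(expr, samples, feature_class = "mRNA",
                        contrasts = NULL, ...) {
  contrasts <- contrasts %||% enumerate_contrasts(samples)
  out <- pmap(
    list(contrasts$contrast, contrasts$a, contrasts$b),
    function(lbl, a, b) call_de(expr, a, b, feature_class = feature_class,
                                contrast = lbl, ...)
  ) %>% bind_rows()
  class(out) <- c("cerna_de", class(out))
  out
}
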