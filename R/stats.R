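# Statistical primitives invoked throughout the pipeline: Pearson and
# Spearman correlation, Benjamini-Hochberg adjustment, the hypergeometric
# upper tail, term enrichment, and the chi-square segregation test.
#
# These wrap base R's well-tested routines behind the pipeline's contracts
# (argument checks, the undefined-correlation marker, strict thresholds);
# the test suite compares each against an independent brute-force oracle.

check_cor_args <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("correlation needs at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("correlation inputs must be finite")
  invisible(TRUE)
}

#' Pearson correlation with an undefined marker for constant input
#'
#' Returns `NA_real_` (rather than a spurious +/-1) when either vector is
#' constant; downstream ceRNA filters treat the undefined marker as failing
#' their threshold.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @return Correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
cor_pearson <- function(x, y) {
  check_cor_args(x, y)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' Spearman rank correlation (mid-ranks for ties)
#'
#' Equals [cor_pearson()] applied to average-ranked data; ties receive
#' mid-ranks, the standard definition of the rank correlation coefficient.
#'
#' @inheritParams cor_pearson
#' @return Rank correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
cor_spearman <- function(x, y) {
  check_cor_args(x, y)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length; elementwise `q >= p`, order
#'   preserving, and thresholding `q <= alpha` selects exactly the classical
#'   step-up rejection set.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric upper-tail probability P[X >= k]
#'
#' Drawing `n` balls without replacement from an urn of `N` with `K` marked,
#' the probability of seeing `k` or more marked balls. Computed exactly via
#' the log-space hypergeometric tail, so small probabilities do not underflow.
#'
#' @param k Observed overlap.
#' @param K Marked population size.
#' @param n Draw size.
#' @param N Population size.
#' @return Probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  ok <- K >= 0 && K <= N && n >= 0 && n <= N && k >= 0 && k <= min(K, n)
  if (!ok) abort("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric term enrichment with BH correction
#'
#' Tests each term for over-representation in `geneset` against the
#' `universe` background (the annotation's full gene complement, i.e. the
#' genome background, unless the caller narrows it). One row per term with at
#' least one universe gene; a term is flagged significant iff its BH-adjusted
#' q-value is at or below `alpha`.
#'
#' @param geneset Character vector, a subset of `universe`.
#' @param universe Character vector of background gene ids.
#' @param term_map Tibble with columns `term`, `gene`.
#' @param alpha Significance threshold on q (default 0.05).
#' @return A tibble with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, sorted by `p` then term id.
#' @export
enrich_terms <- function(geneset, universe, term_map, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  geneset <- unique(geneset)
  if (length(setdiff(geneset, universe)) > 0) {
    abort("geneset contains genes absent from the universe")
  }
  tm <- term_map %>%
    filter(.data$gene %in% universe) %>%
    distinct(.data$term, .data$gene)
  if (nrow(tm) == 0) {
    return(tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(), q = numeric(),
                  significant = logical()))
  }
  n <- length(geneset)
  N <- length(universe)
  res <- tm %>%
    group_by(.data$term) %>%
    summarise(
      K = n_distinct(.data$gene),
      k = sum(.data$gene %in% geneset),
      .groups = "drop"
    ) %>%
    arrange(.data$term)          # iteration-order independence
  res$n <- n
  res$N <- N
  res$p <- vapply(seq_len(nrow(res)),
                  function(i) hypergeom_upper(res$k[i], res$K[i], n, N),
                  numeric(1))
  res$q <- bh_fdr(res$p)
  res %>%
    mutate(significant = .data$q <= alpha) %>%
    select("term", "k", "K", "n", "N", "p", "q", "significant") %>%
    arrange(.data$p, .data$term)
}

#' Chi-square goodness-of-fit test against an expected segregation ratio
#'
#' The classical test for Mendelian segregation: observed category counts are
#' compared with an expected ratio (3:1 by default, the F2 expectation for a
#' single recessive locus). The critical value at alpha = 0.05 with one
#' degree of freedom is 3.84 (2 d.p.).
#'
#' @param observed Integer vector of category counts (>= 2 categories).
#' @param ratio Expected proportions (normalised internally; default `c(3, 1)`).
#' @return A list of class `cerna_gof` with `observed`, `expected`,
#'   `statistic`, `df`, `p_value` and `critical_05` (the 0.95 chi-square
#'   quantile at the test's df).
#' @export
chisq_segregation <- function(observed, ratio = c(3, 1)) {
  if (length(observed) < 2) abort("need at least two categories")
  if (sum(observed) <= 0) abort("total count must be positive")
  if (length(ratio) != length(observed)) abort("ratio and observed lengths differ")
  p <- ratio / sum(ratio)
  if (any(p * sum(observed) == 0)) abort("zero expected count")
  ht <- chisq.test(x = observed, p = p)
  structure(
    list(
      observed = observed,
      expected = unname(ht$expected),
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = unname(ht$p.value),
      critical_05 = qchisq(0.95, df = unname(ht$parameter))
    ),
    class = "cerna_gof"
  )
}

#' @export
print.cerna_gof <- function(x, ...) {
  cat("Chi-square goodness of fit\n")
  cat("  observed:", paste(x$observed, collapse = ":"), "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g (critical value at 0.05: %.2f)\n",
              x$statistic, x$df, x$p_value, x$critical_05))
  invisible(x)
}
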