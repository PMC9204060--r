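# Rule-based miRNA target prediction: ungapped antiparallel duplex alignment
# of a miRNA against every transcript window of equal length, wobble-aware
# mismatch scoring, position-window constraints, and a duplex energy-ratio
# test.
#
# Position i of the miRNA (1..L from the 5' end) pairs with window position
# L+1-i; Watson-Crick pairs are A:U, U:A, G:C, C:G, wobbles are G:U and U:G.
# The mismatch score weighs a wobble 0.5 and a true mismatch 1.0. Two rule
# variants are supported:
#   ruleset A: total score <= 4; no run of more than two mismatch events;
#              no adjacent mismatch pair within positions 2-12; positions
#              10-11 paired; score over positions 1-12 <= 2.5; duplex energy
#              >= 74% of the perfect-complement energy.
#   ruleset B: as A but no two consecutive mismatch events anywhere, no
#              mismatch event at positions 2-12 at all, and an energy ratio
#              threshold of 60%.
# Whether a wobble counts as a "mismatch event" for the positional rules
# (r2-r4) is the `gu_positional` switch (default TRUE); the weighted scores
# of r1/r5 always count wobbles at 0.5.
#
# The energy model is a simple additive per-pair model (G:C -3, A:U -2,
# G:U -1, mismatch 0, arbitrary units) applied identically to the duplex and
# to the perfect complement, so the ratio test is model-consistent; the
# constants are configurable and a nearest-neighbour model could be plugged
# in behind the same contract.

WC_PAIRS <- c("AU", "UA", "GC", "CG")
GU_PAIRS <- c("GU", "UG")

#' Default additive duplex energy model
#'
#' @return Named list of per-pair energies: `GC`, `AU`, `GU`, `MM` (all
#'   non-positive; mismatches contribute 0).
#' @export
default_energy_model <- function() list(GC = -3, AU = -2, GU = -1, MM = 0)

as_rna <- function(seq) chartr("T", "U", toupper(seq))

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA (or DNA; `T` is normalised to `U`) sequence string.
#' @return The reverse complement as an RNA string.
#' @export
reverse_complement_rna <- function(seq) {
  x <- rev(strsplit(as_rna(seq), "")[[1]])
  paste(chartr("ACGU", "UGCA", x), collapse = "")
}

#' Align a miRNA against an equal-length transcript window
#'
#' Gapless antiparallel alignment: miRNA position `i` (5'->3') pairs with
#' window position `L+1-i`. Each position is classified `WC`, `GU`, or `MM`,
#' and the mismatch score is `0.5 * #GU + 1.0 * #MM`.
#'
#' @param mirna miRNA sequence (RNA alphabet; `T` accepted and normalised).
#' @param window Transcript window of the same length.
#' @param model Energy model, see [default_energy_model()].
#' @return A list of class `duplex_alignment`: `states` (character vector
#'   over `{WC, GU, MM}` indexed by miRNA position), `score`, `energy`,
#'   `perfect_energy`, `mfe_ratio`.
#' @export
duplex_align <- function(mirna, window, model = default_energy_model()) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  w <- strsplit(as_rna(window), "")[[1]]
  if (length(m) != length(w)) abort("miRNA and window lengths differ")
  pairs <- paste0(m, rev(w))
  states <- ifelse(pairs %in% WC_PAIRS, "WC", ifelse(pairs %in% GU_PAIRS, "GU", "MM"))
  e <- duplex_energy(states, m, model)
  ep <- perfect_energy(mirna, model)
  structure(
    list(
      states = states,
      score = mismatch_score(states),
      energy = e,
      perfect_energy = ep,
      mfe_ratio = if (ep < 0) e / ep else NA_real_
    ),
    class = "duplex_alignment"
  )
}

mismatch_score <- function(states) sum(states == "GU") * 0.5 + sum(states == "MM")

#' Additive duplex energy
#'
#' Sums per-position pair energies: a Watson-Crick pair contributes the
#' `GC` or `AU` energy according to the miRNA base, a wobble the `GU`
#' energy, and a mismatch the `MM` energy (0).
#'
#' @param states Per-position states from [duplex_align()].
#' @param mirna_chars miRNA sequence as a character vector.
#' @param model Energy model.
#' @return Total energy (<= 0).
#' @export
duplex_energy <- function(states, mirna_chars, model = default_energy_model()) {
  wc_e <- ifelse(mirna_chars %in% c("G", "C"), model$GC, model$AU)
  sum(ifelse(states == "WC", wc_e,
             ifelse(states == "GU", model$GU, model$MM)))
}

#' Energy of a miRNA bound to its perfect complement
#'
#' @param mirna miRNA sequence string.
#' @param model Energy model.
#' @return Total energy with every base Watson-Crick paired.
#' @export
perfect_energy <- function(mirna, model = default_energy_model()) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  sum(ifelse(m %in% c("G", "C"), model$GC, model$AU))
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Evaluate the target-prediction rules on a duplex alignment
#'
#' @param aln A `duplex_alignment` from [duplex_align()].
#' @param ruleset `"A"` or `"B"` (see the module header for the two variants).
#' @param mfe_ratio Energy-ratio threshold; defaults to 0.74 (A) / 0.60 (B).
#' @param gu_positional Do wobbles count as mismatch events for the
#'   positional rules r2-r4? Default `TRUE`.
#' @return A list of class `rule_verdict` with logicals `r1`..`r6`, `pass`
#'   (their conjunction), plus `score` and `mfe_ratio`.
#' @export
evaluate_rules <- function(aln, ruleset = c("A", "B"), mfe_ratio = NULL,
                           gu_positional = TRUE) {
  ruleset <- match.arg(ruleset)
  mfe_ratio <- mfe_ratio %||% if (ruleset == "A") 0.74 else 0.60
  states <- aln$states
  L <- length(states)
  sc <- ifelse(states == "GU", 0.5, ifelse(states == "MM", 1, 0))
  mism <- if (gu_positional) states != "WC" else states == "MM"

  r1 <- sum(sc) <= 4
  r2 <- if (ruleset == "A") max_run(mism) <= 2 else max_run(mism) <= 1
  five_prime <- seq_len(min(12L, L))
  r3 <- if (ruleset == "A") {
    hi <- min(11L, L - 1L)
    !any(mism[seq(2L, hi)] & mism[seq(3L, hi + 1L)])
  } else {
    !any(mism[five_prime[five_prime >= 2L]])
  }
  r4 <- if (L >= 11L) !mism[10L] && !mism[11L] else TRUE
  r5 <- sum(sc[five_prime]) <= 2.5
  r6 <- !is.na(aln$mfe_ratio) && aln$mfe_ratio >= mfe_ratio

  structure(
    list(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6,
         pass = r1 && r2 && r3 && r4 && r5 && r6,
         score = sum(sc), mfe_ratio = aln$mfe_ratio),
    class = "rule_verdict"
  )
}

#' Score one candidate site and name any violated rules
#'
#' Diagnostic helper combining [duplex_align()] and [evaluate_rules()] at a
#' stated transcript position.
#'
#' @param mirna,transcript Sequence strings (RNA alphabet).
#' @param start 0-based window start on the transcript.
#' @inheritParams evaluate_rules
#' @param model Energy model.
#' @return The `rule_verdict` with an extra `violated` character vector.
#' @export
site_verdict <- function(mirna, transcript, start, ruleset = "A",
                         mfe_ratio = NULL, gu_positional = TRUE,
                         model = default_energy_model()) {
  L <- nchar(mirna)
  window <- substr(as_rna(transcript), start + 1L, start + L)
  if (nchar(window) < L) abort("window extends past transcript end")
  v <- evaluate_rules(duplex_align(mirna, window, model), ruleset = ruleset,
                      mfe_ratio = mfe_ratio, gu_positional = gu_positional)
  v$violated <- paste0("r", 1:6)[!unlist(v[paste0("r", 1:6)])]
  v
}

# Candidate windows via an exact inexact-matching scan (Biostrings). Any
# window passing rule 1 (weighted score <= 4) has at most 8 raw mismatches
# against the miRNA's reverse complement (worst case: 8 wobbles), so scanning
# with max.mismatch = 8 is a lossless prefilter for both rulesets.
candidate_starts <- function(mirna_rna, transcript_dna_set) {
  pat <- Biostrings::DNAString(chartr("U", "T", reverse_complement_rna(mirna_rna)))
  hits <- Biostrings::vmatchPattern(pat, transcript_dna_set, max.mismatch = 8,
                                    with.indels = FALSE, fixed = TRUE)
  lapply(hits, function(h) BiocGenerics::start(h) - 1L)
}

#' Scan transcripts for miRNA target sites
#'
#' Every window of miRNA length is evaluated against the selected ruleset;
#' windows passing all six rules are reported (overlapping hits included),
#' sorted by miRNA, transcript and position. Transcripts shorter than a
#' miRNA yield no hits for it (with a warning).
#'
#' @param mirnas Tibble with columns `id`, `seq` (miRNA catalog).
#' @param transcripts Tibble with columns `id`, `seq`.
#' @inheritParams evaluate_rules
#' @param model Energy model.
#' @return A tibble with columns `mirna_id`, `transcript_id`, `start`
#'   (0-based), `score`, `mfe_ratio`, and logical flags `r1`..`r6`.
#' @export
predict_targets <- function(mirnas, transcripts, ruleset = c("A", "B"),
                            mfe_ratio = NULL, gu_positional = TRUE,
                            model = default_energy_model()) {
  ruleset <- match.arg(ruleset)
  tx_rna <- as_rna(transcripts$seq)
  subj <- Biostrings::DNAStringSet(chartr("U", "T", tx_rna))
  names(subj) <- transcripts$id
  rows <- list()
  for (k in seq_len(nrow(mirnas))) {
    mir <- as_rna(mirnas$seq[k])
    L <- nchar(mir)
    short <- nchar(tx_rna) < L
    if (any(short)) {
      warn(paste0("transcript(s) shorter than miRNA ", mirnas$id[k],
                  ": ", paste(transcripts$id[short], collapse = ", ")))
    }
    ok <- which(!short)
    if (length(ok) == 0) next
    cand_ok <- candidate_starts(mir, subj[ok])
    cand <- vector("list", length(tx_rna))
    cand[ok] <- cand_ok
    for (j in ok) {
      for (s in cand[[j]]) {
        if (s < 0 || s + L > nchar(tx_rna[j])) next
        window <- substr(tx_rna[j], s + 1L, s + L)
        aln <- duplex_align(mir, window, model)
        v <- evaluate_rules(aln, ruleset = ruleset, mfe_ratio = mfe_ratio,
                            gu_positional = gu_positional)
        if (v$pass) {
          rows[[length(rows) + 1]] <- tibble(
            mirna_id = mirnas$id[k], transcript_id = transcripts$id[j],
            start = as.integer(s), score = v$score, mfe_ratio = v$mfe_ratio,
            r1 = v$r1, r2 = v$r2, r3 = v$r3, r4 = v$r4, r5 = v$r5, r6 = v$r6
          )
        }
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(mirna_id = character(), transcript_id = character(),
                  start = integer(), score = numeric(), mfe_ratio = numeric(),
                  r1 = logical(), r2 = logical(), r3 = logical(),
                  r4 = logical(), r5 = logical(), r6 = logical())
  }
  cf_log("predict_targets", "%d miRNAs x %d transcripts, ruleset %s: %d hits",
         nrow(mirnas), nrow(transcripts), ruleset, nrow(out))
  arrange(out, .data$mirna_id, .data$transcript_id, .data$start)
}

#' Scan a single transcript with a single miRNA
#'
#' @param mirna,transcript Single-row tibbles (`id`, `seq`) or plain lists
#'   with those fields.
#' @inheritParams predict_targets
#' @return The hit tibble of [predict_targets()] for this pair.
#' @export
scan_transcript <- function(mirna, transcript, ruleset = "A",
                            mfe_ratio = NULL, gu_positional = TRUE,
                            model = default_energy_model()) {
  predict_targets(as_tibble(mirna[c("id", "seq")]),
                  as_tibble(transcript[c("id", "seq")]),
                  ruleset = ruleset, mfe_ratio = mfe_ratio,
                  gu_positional = gu_positional, model = model)
}
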