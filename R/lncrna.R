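# Length screening and positional classification of lncRNA candidates
# relative to protein-coding genes, plus the cis-neighbour search.
#
# Five classes, assigned with a fixed precedence so every candidate gets
# exactly one label:
#   sense_overlapping: exon-level overlap with a coding exon, same strand
#   antisense:         exon-level overlap with a coding exon, opposite strand
#   intronic:          fully contained in a coding intron, no exon overlap
#   bidirectional:     no overlap; divergent head-to-head promoter within
#                      `bidir_window` bp of an opposite-strand coding TSS
#   intergenic:        none of the above
# The class names follow the standard lncRNA taxonomy; the bidirectional
# window (1 kb) is a declared convention, configurable.

LNC_CLASSES <- c("intergenic", "bidirectional", "intronic", "antisense",
                 "sense_overlapping")

# split an annotation tibble into per-transcript structures
annot_transcripts <- function(annot, biotype = NULL) {
  tx <- filter(annot, .data$type == "transcript")
  if (!is.null(biotype)) tx <- filter(tx, .data$biotype == !!biotype)
  tx
}

annot_exons <- function(annot, tx_ids) {
  filter(annot, .data$type == "exon", .data$parent %in% tx_ids)
}

spliced_lengths <- function(annot, tx) {
  ex <- annot_exons(annot, tx$id)
  if (nrow(ex) == 0) {
    return(setNames(tx$end - tx$start, tx$id))
  }
  len <- ex %>%
    group_by(.data$parent) %>%
    summarise(len = sum(.data$end - .data$start), .groups = "drop")
  out <- setNames(tx$end - tx$start, tx$id)  # exonless transcripts: span
  out[len$parent] <- len$len
  out
}

#' Screen lncRNA candidates by spliced length
#'
#' Removes candidate transcripts whose spliced length (sum of exon widths)
#' falls below `min_length`; the 200-nt floor is the conventional definition
#' of a long non-coding RNA, applied boundary inclusive (a 200-nt transcript
#' is retained).
#'
#' @param annot Annotation tibble (see [validate_annotation()]).
#' @param min_length Minimum spliced length in nt (default 200).
#' @return A tibble with columns `lncrna_id`, `spliced_length`, `retained`.
#' @export
screen_lncrna <- function(annot, min_length = 200) {
  validate_annotation(annot)
  tx <- annot_transcripts(annot, biotype = "lncRNA_candidate")
  len <- spliced_lengths(annot, tx)
  out <- tibble(
    lncrna_id = tx$id,
    spliced_length = unname(len[tx$id]),
    retained = unname(len[tx$id]) >= min_length
  )
  cf_log("screen_lncrna", "%d candidates, min_length=%d: %d retained, %d removed",
         nrow(out), as.integer(min_length), sum(out$retained), sum(!out$retained))
  out
}

# interval overlap on 0-based half-open coordinates
iv_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
iv_contains <- function(outer_s, outer_e, inner_s, inner_e) {
  outer_s <= inner_s & inner_e <= outer_e
}

# introns of one transcript given its exon rows (base R: called in a loop)
tx_introns <- function(exon_start, exon_end) {
  if (length(exon_start) < 2) {
    return(list(start = integer(0), end = integer(0)))
  }
  o <- order(exon_start)
  s <- exon_end[o][-length(o)]
  e <- exon_start[o][-1]
  ok <- s < e
  list(start = s[ok], end = e[ok])
}

classify_one <- function(lnc_tx, lnc_ex, coding_tx, coding_ex, bidir_window) {
  # only coding transcripts within reach (overlap or the bidirectional
  # window) can influence the label
  near <- coding_tx$seqid == lnc_tx$seqid &
    coding_tx$start <= lnc_tx$end + bidir_window &
    coding_tx$end >= lnc_tx$start - bidir_window
  ctx <- coding_tx[near, , drop = FALSE]
  if (nrow(ctx) == 0) return("intergenic")
  cex <- coding_ex[coding_ex$parent %in% ctx$id, , drop = FALSE]
  if (nrow(lnc_ex) == 0) {
    lnc_ex <- tibble(start = lnc_tx$start, end = lnc_tx$end, parent = lnc_tx$id)
  }

  # exon-level overlap, split by strand of the host transcript
  if (nrow(cex) > 0) {
    host_strand <- setNames(ctx$strand, ctx$id)
    for (i in seq_len(nrow(lnc_ex))) {
      ov <- iv_overlaps(lnc_ex$start[i], lnc_ex$end[i], cex$start, cex$end)
      if (any(ov)) {
        strands <- host_strand[cex$parent[ov]]
        if (any(strands == lnc_tx$strand)) return("sense_overlapping")
        return("antisense")
      }
    }
  }

  # fully inside a coding intron (either strand), no exon overlap by now
  for (j in seq_len(nrow(ctx))) {
    sel <- cex$parent == ctx$id[j]
    introns <- tx_introns(cex$start[sel], cex$end[sel])
    if (length(introns$start) > 0 &&
        any(iv_contains(introns$start, introns$end, lnc_tx$start, lnc_tx$end))) {
      return("intronic")
    }
  }

  # bidirectional: no span overlap anywhere, divergent head-to-head promoter
  span_ov <- iv_overlaps(lnc_tx$start, lnc_tx$end, ctx$start, ctx$end)
  if (!any(span_ov)) {
    opp <- ctx[ctx$strand != lnc_tx$strand, , drop = FALSE]
    if (nrow(opp) > 0) {
      if (lnc_tx$strand == "-") {
        # lncRNA transcribes leftward from its right end; partner gene sits to
        # the right transcribing rightward
        gap <- opp$start - lnc_tx$end
        if (any(opp$strand == "+" & gap >= 0 & gap <= bidir_window)) {
          return("bidirectional")
        }
      } else {
        gap <- lnc_tx$start - opp$end
        if (any(opp$strand == "-" & gap >= 0 & gap <= bidir_window)) {
          return("bidirectional")
        }
      }
    }
  }
  "intergenic"
}

#' Classify lncRNA candidates into five positional classes
#'
#' Applies the precedence sense_overlapping > antisense > intronic >
#' bidirectional > intergenic so each candidate receives exactly one label.
#' Class labels are strand-flip covariant: inverting a lncRNA's strand swaps
#' sense_overlapping with antisense.
#'
#' @param annot Annotation tibble holding both coding transcripts (biotype
#'   `"coding"`) and candidates (biotype `"lncRNA_candidate"`), with exon rows.
#' @param bidir_window Head-to-head promoter distance in bp (default 1000).
#' @return A tibble with columns `lncrna_id`, `class`, `spliced_length`.
#' @export
classify_lncrna <- function(annot, bidir_window = 1000) {
  validate_annotation(annot)
  lnc_tx <- annot_transcripts(annot, biotype = "lncRNA_candidate")
  coding_tx <- annot_transcripts(annot, biotype = "coding")
  coding_ex <- annot_exons(annot, coding_tx$id)
  lnc_ex_all <- annot_exons(annot, lnc_tx$id)
  len <- spliced_lengths(annot, lnc_tx)
  cls <- vapply(seq_len(nrow(lnc_tx)), function(i) {
    classify_one(lnc_tx[i, ],
                 lnc_ex_all[lnc_ex_all$parent == lnc_tx$id[i], , drop = FALSE],
                 coding_tx, coding_ex, bidir_window)
  }, character(1))
  out <- tibble(
    lncrna_id = lnc_tx$id,
    class = cls,
    spliced_length = unname(len[lnc_tx$id])
  )
  cf_log("classify_lncrna", "%d lncRNAs classified; classes present: %s",
         nrow(out), paste(sort(unique(cls)), collapse = ", "))
  out
}

#' Find cis-neighbour coding genes of lncRNAs
#'
#' Returns the coding genes whose span intersects the window
#' `[lnc_start - window, lnc_end + window)` around each lncRNA, either
#' strand — the conventional 10-kb cis-regulation neighbourhood.
#' Monotone in `window`: enlarging the window never removes a pair.
#'
#' @param annot Annotation tibble.
#' @param window Flank size in bp (default 10000; 0 keeps only overlaps).
#' @return A tibble with columns `lncrna_id`, `gene_id`, `distance` (0 for
#'   overlapping pairs, else the gap in bp).
#' @export
cis_targets <- function(annot, window = 10000) {
  if (window < 0) abort("window must be >= 0")
  validate_annotation(annot)
  lnc_tx <- annot_transcripts(annot, biotype = "lncRNA_candidate")
  coding_tx <- annot_transcripts(annot, biotype = "coding")
  rows <- map(seq_len(nrow(lnc_tx)), function(i) {
    l <- lnc_tx[i, ]
    cand <- coding_tx[coding_tx$seqid == l$seqid, , drop = FALSE]
    hit <- cand$start < l$end + window & cand$end > l$start - window
    cand <- cand[hit, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    gap <- pmax(0, pmax(cand$start - l$end, l$start - cand$end))
    tibble(lncrna_id = l$id, gene_id = cand$id, distance = as.integer(gap))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(lncrna_id = character(), gene_id = character(),
                  distance = integer())
  }
  arrange(out, .data$lncrna_id, .data$distance, .data$gene_id)
}
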