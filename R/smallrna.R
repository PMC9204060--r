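# Small-RNA clean-tag filter cascade and miRNA quantification.
#
# Rules are applied per read in a fixed order, and a read is attributed to
# the FIRST rule that removes it, so the report satisfies the conservation
# identity input = output + sum(removals) exactly:
#   1. low_quality         > 50% of bases with Phred quality <= 20
#   2. no_3prime_adapter   3' adapter not found (longest-prefix match,
#                          >= min_overlap nt, exact); found adapters are
#                          trimmed before any length test
#   3. has_5prime_adapter  5' adapter sequence present in the insert
#   4. short / long        trimmed insert outside the [min_len, max_len]
#                          tag window (18-30 nt)
#   5. polya               run of >= polya_min consecutive A in the insert
#
# The length window is applied after adapter trimming. The "low quality"
# definition mirrors the mRNA-seq rule (bases with Q <= 20 making up more
# than 50% of the read). Because clean tags are adapter-trimmed, re-running
# the cascade on its own output removes nothing only with
# `require_adapter3 = FALSE`; all content rules (quality, 5' adapter, length,
# polyA) pass unchanged on clean tags.

phred_scores <- function(qual) {
  lapply(qual, function(s) utf8ToInt(s) - 33L)
}

# leftmost occurrence of the longest matching adapter prefix; 0 if none
locate_adapter3 <- function(seq, adapter, min_overlap) {
  n <- nchar(adapter)
  for (k in seq(from = min(n, nchar(seq)), to = min_overlap)) {
    pos <- regexpr(substr(adapter, 1, k), seq, fixed = TRUE)
    if (pos > 0) return(as.integer(pos))
  }
  0L
}

#' Small-RNA clean-tag filter cascade
#'
#' @param reads Read tibble with columns `id`, `seq`, `qual` (Phred+33);
#'   see [read_fastq()]. An empty input yields an empty output and a zeroed
#'   report, not an error.
#' @param adapter3 3' adapter sequence (DNA alphabet); required when
#'   `require_adapter3 = TRUE`.
#' @param adapter5 5' adapter sequence; reads containing it are removed.
#' @param min_len,max_len Tag length window after trimming (default 18-30 nt).
#' @param min_overlap Minimum 3' adapter prefix match (default 6 nt, exact).
#' @param polya_min Minimum A-run length counted as polyA (default 8).
#' @param low_quality_q,low_quality_frac A read is low quality when more than
#'   `low_quality_frac` of its bases have Phred quality <= `low_quality_q`.
#' @param require_adapter3 Remove reads whose 3' adapter cannot be located?
#'   Default `TRUE` (the filter's published behaviour); set `FALSE` when
#'   re-filtering already-trimmed tags.
#' @return A list with `reads` (clean-tag tibble: `id`, `seq`, `qual`, the
#'   sequence now adapter-trimmed) and `report` (a `smallrna_report`: input
#'   count, named removal counts, output count).
#' @export
filter_smallrna <- function(reads,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            min_len = 18, max_len = 30, min_overlap = 6,
                            polya_min = 8, low_quality_q = 20,
                            low_quality_frac = 0.5,
                            require_adapter3 = TRUE) {
  bins <- c("low_quality", "no_3prime_adapter", "has_5prime_adapter",
            "short", "long", "polya")
  removed <- setNames(integer(length(bins)), bins)
  n_in <- nrow(reads)
  if (n_in == 0) {
    report <- new_smallrna_report(0L, removed, 0L)
    return(list(reads = reads, report = report))
  }
  if (require_adapter3 && !nzchar(adapter3)) {
    abort("adapter3 must be non-empty when require_adapter3 = TRUE")
  }
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  seqs <- toupper(chartr("U", "T", reads$seq))
  quals <- phred_scores(reads$qual)
  polya_re <- paste0("A{", polya_min, ",}")

  keep <- logical(n_in)
  out_seq <- character(n_in)
  out_qual <- character(n_in)
  for (i in seq_len(n_in)) {
    q <- quals[[i]]
    if (mean(q <= low_quality_q) > low_quality_frac) {
      removed["low_quality"] <- removed["low_quality"] + 1L
      next
    }
    pos <- if (nzchar(adapter3)) locate_adapter3(seqs[i], adapter3, min_overlap) else 0L
    if (pos == 0L) {
      if (require_adapter3) {
        removed["no_3prime_adapter"] <- removed["no_3prime_adapter"] + 1L
        next
      }
      insert <- seqs[i]
      iq <- reads$qual[i]
    } else {
      insert <- substr(seqs[i], 1, pos - 1L)
      iq <- substr(reads$qual[i], 1, pos - 1L)
    }
    if (nzchar(adapter5) && grepl(adapter5, insert, fixed = TRUE)) {
      removed["has_5prime_adapter"] <- removed["has_5prime_adapter"] + 1L
      next
    }
    len <- nchar(insert)
    if (len < min_len) {
      removed["short"] <- removed["short"] + 1L
      next
    }
    if (len > max_len) {
      removed["long"] <- removed["long"] + 1L
      next
    }
    if (grepl(polya_re, insert)) {
      removed["polya"] <- removed["polya"] + 1L
      next
    }
    keep[i] <- TRUE
    out_seq[i] <- insert
    out_qual[i] <- iq
  }
  clean <- tibble(id = reads$id[keep], seq = out_seq[keep], qual = out_qual[keep])
  report <- new_smallrna_report(n_in, removed, nrow(clean))
  cf_log("filter_smallrna",
         "%d reads in, %d clean tags out (Q<=%d frac>%.2f, len %d-%d, polyA>=%d); removed: %s",
         n_in, nrow(clean), low_quality_q, low_quality_frac,
         as.integer(min_len), as.integer(max_len), as.integer(polya_min),
         paste(names(removed), removed, sep = "=", collapse = " "))
  list(reads = clean, report = report)
}

new_smallrna_report <- function(input, removed, output) {
  stopifnot(input == output + sum(removed))
  structure(list(input = as.integer(input), removed = removed,
                 output = as.integer(output)),
            class = "smallrna_report")
}

#' @export
print.smallrna_report <- function(x, ...) {
  cat("Small-RNA filter report\n")
  cat("  input:", x$input, "\n")
  for (nm in names(x$removed)) cat(sprintf("  removed %-18s %d\n", nm, x$removed[[nm]]))
  cat("  output:", x$output, "\n")
  invisible(x)
}

#' Tidy a small-RNA filter report
#'
#' @param x A `smallrna_report`.
#' @param ... Unused.
#' @return A tibble with columns `rule`, `count`.
#' @export
tidy.smallrna_report <- function(x, ...) {
  tibble(
    rule = c("input", names(x$removed), "output"),
    count = c(x$input, unname(x$removed), x$output)
  )
}

#' Quantify miRNAs from clean tags by exact sequence match
#'
#' A tag increments a catalog miRNA's count iff the trimmed sequence equals
#' the catalog sequence exactly (T/U-insensitive); everything else is counted
#' under `"unassigned"`. Exact matching is the strictest reproducible policy
#' for tag-to-miRNA assignment.
#'
#' @param tags Clean-tag tibble (or a list of them, one per sample, named by
#'   sample id).
#' @param mirnas miRNA catalog tibble with columns `id`, `seq`; sequences
#'   must be unique.
#' @return A wide count tibble: `mirna_id` column followed by one count
#'   column per sample (a single unnamed tibble yields column `count`),
#'   including the `unassigned` row.
#' @export
quantify_mirna <- function(tags, mirnas) {
  catalog <- toupper(chartr("U", "T", mirnas$seq))
  if (anyDuplicated(catalog)) abort("duplicate catalog sequences")
  lookup <- setNames(mirnas$id, catalog)
  one_sample <- function(tg) {
    seqs <- toupper(chartr("U", "T", tg$seq))
    assigned <- lookup[seqs]
    counts <- table(factor(assigned[!is.na(assigned)], levels = mirnas$id))
    c(as.integer(counts), sum(is.na(assigned)))
  }
  if (is.data.frame(tags)) tags <- list(count = tags)
  mat <- vapply(tags, one_sample, integer(nrow(mirnas) + 1L))
  out <- as_tibble(mat)
  out <- bind_cols(tibble(mirna_id = c(mirnas$id, "unassigned")), out)
  out
}
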