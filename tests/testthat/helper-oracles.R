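# Independent brute-force oracles. These re-derive each quantity from first
# principles with deliberately different code paths from the package, so a
# shared bug cannot hide.

options(cernaforge.verbose = FALSE)

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# literal step-up formula: q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact combinatorial tail sum
oracle_hypergeom <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# triple-loop unsigned topological overlap
oracle_tom <- function(a) {
  g <- nrow(a)
  out <- matrix(0, g, g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i == j) {
        out[i, j] <- 1
        next
      }
      shared <- 0
      for (u in seq_len(g)) {
        if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# exhaustive window scorer for the target engine (gu_positional semantics,
# default energy model), written as an explicit per-position loop
oracle_scan <- function(mirna, transcript, ruleset = "A", mfe_ratio = NULL) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  energy <- function(m, t) {
    if (comp[[m]] == t) {
      if (m %in% c("G", "C")) -3 else -2
    } else if ((m == "G" && t == "U") || (m == "U" && t == "G")) {
      -1
    } else {
      0
    }
  }
  thr <- if (!is.null(mfe_ratio)) mfe_ratio else if (ruleset == "A") 0.74 else 0.60
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  tx <- strsplit(chartr("T", "U", toupper(transcript)), "")[[1]]
  L <- length(m)
  hits <- integer(0)
  if (length(tx) < L) return(hits)
  perfect <- sum(vapply(m, function(b) if (b %in% c("G", "C")) -3 else -2,
                        numeric(1)))
  for (s0 in 0:(length(tx) - L)) {
    w <- tx[(s0 + 1):(s0 + L)]
    score <- 0
    score5 <- 0
    mism <- logical(L)
    e <- 0
    for (i in seq_len(L)) {
      t_base <- w[L + 1 - i]
      wobble <- (m[i] == "G" && t_base == "U") || (m[i] == "U" && t_base == "G")
      wc <- comp[[m[i]]] == t_base
      contr <- if (wc) 0 else if (wobble) 0.5 else 1
      score <- score + contr
      if (i <= 12) score5 <- score5 + contr
      mism[i] <- !wc
      e <- e + energy(m[i], t_base)
    }
    ok <- score <= 4
    run <- 0
    maxrun <- 0
    for (i in seq_len(L)) {
      run <- if (mism[i]) run + 1 else 0
      maxrun <- max(maxrun, run)
    }
    if (ruleset == "A") {
      if (maxrun > 2) ok <- FALSE
      for (i in 2:11) if (mism[i] && mism[i + 1]) ok <- FALSE
    } else {
      if (maxrun > 1) ok <- FALSE
      if (any(mism[2:12])) ok <- FALSE
    }
    if (mism[10] || mism[11]) ok <- FALSE
    if (score5 > 2.5) ok <- FALSE
    if (e / perfect < thr) ok <- FALSE
    if (ok) hits <- c(hits, s0)
  }
  hits
}

# straightforward re-derivation of the five-class lncRNA call
oracle_classify <- function(annot, lnc_id, bidir_window = 1000) {
  tx <- annot[annot$type == "transcript", ]
  ex <- annot[annot$type == "exon", ]
  l <- tx[tx$id == lnc_id, ]
  lex <- ex[ex$parent == lnc_id, ]
  if (nrow(lex) == 0) lex <- l
  coding <- tx[!is.na(tx$biotype) & tx$biotype == "coding" & tx$seqid == l$seqid, ]
  ov <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  same <- FALSE
  anti <- FALSE
  for (ci in seq_len(nrow(coding))) {
    cexi <- ex[ex$parent == coding$id[ci], ]
    for (a in seq_len(nrow(lex))) {
      for (b in seq_len(nrow(cexi))) {
        if (ov(lex$start[a], lex$end[a], cexi$start[b], cexi$end[b])) {
          if (coding$strand[ci] == l$strand) same <- TRUE else anti <- TRUE
        }
      }
    }
  }
  if (same) return("sense_overlapping")
  if (anti) return("antisense")
  for (ci in seq_len(nrow(coding))) {
    cexi <- ex[ex$parent == coding$id[ci], ]
    cexi <- cexi[order(cexi$start), ]
    if (nrow(cexi) >= 2) {
      for (b in seq_len(nrow(cexi) - 1)) {
        if (cexi$end[b] <= l$start && l$end <= cexi$start[b + 1]) {
          return("intronic")
        }
      }
    }
  }
  overlap_any <- any(vapply(seq_len(nrow(coding)), function(ci) {
    ov(l$start, l$end, coding$start[ci], coding$end[ci])
  }, logical(1)))
  if (!overlap_any) {
    for (ci in seq_len(nrow(coding))) {
      if (coding$strand[ci] == l$strand) next
      if (l$strand == "-" && coding$strand[ci] == "+") {
        gap <- coding$start[ci] - l$end
        if (gap >= 0 && gap <= bidir_window) return("bidirectional")
      }
      if (l$strand == "+" && coding$strand[ci] == "-") {
        gap <- l$start - coding$end[ci]
        if (gap >= 0 && gap <= bidir_window) return("bidirectional")
      }
    }
  }
  "intergenic"
}

# convenience builders ----------------------------------------------------

make_expr <- function(m, ids = NULL) {
  if (is.null(rownames(m))) rownames(m) <- ids %||% paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "feature_id")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# first miRNA position at/after `from` whose base can wobble (G or U)
first_wobble_pos <- function(mirna, from = 13) {
  ch <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  pos <- which(ch %in% c("G", "U"))
  pos <- pos[pos >= from & pos != 10 & pos != 11]
  if (length(pos) == 0) stop("no wobble-capable position")
  pos[1]
}

# build a target window: reverse complement of the miRNA with the stated
# modifications (independent of the package's site builder)
make_decoy_window <- function(mirna, pos, kind) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  w <- rev(unname(comp[m]))
  L <- length(m)
  for (p in pos) {
    wi <- L + 1 - p
    if (kind == "GU") {
      w[wi] <- if (m[p] == "G") "U" else if (m[p] == "U") "G" else
        stop("no wobble partner at position ", p)
    } else {
      w[wi] <- m[p]
    }
  }
  paste(w, collapse = "")
}
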