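# Synthetic-data generator: annotation, sequences, small-RNA reads and
# expression matrices carrying the statistical structure the analysis
# assumes, together with a machine-readable truth table, so that every
# downstream stage is testable without any download.
#
# The emulated design is 2 genotypes (wild, mutant) x 3 leaf positions
# (flag, second, third) x 3 biological replicates = 18 samples. Expression
# is log-normal around group means (log2 scale, multiplicative noise sigma
# 0.15 by default); a count mode (Poisson around the abundance-scale means)
# exists for testing the DE surrogate on count-like data. Planted structure:
#   * DE features with a genotype-wide log2 fold change (|log2FC| >= 1.5
#     required, default 2 — a margin above the calling threshold of 1);
#   * two co-expression modules driven by orthogonal sample patterns: a
#     senescence pattern (high only in mutant second/third leaves, the
#     phenotype-matched module) and a genotype-crossed leaf contrast;
#   * ceRNA triplets sharing a latent senescence-plus-jitter profile, the
#     miRNA carrying its negative (latent |correlation| ~ 0.97, comfortably
#     clearing the SCC < -0.7 and PCC > 0.9 thresholds under default noise);
#   * decoy pseudo-triplets with the full expression structure whose
#     binding sites each violate exactly one prediction rule, so the rule
#     engine is the only thing standing between them and the network.
# All randomness flows through a single integer seed (withr::with_seed).

DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
DEFAULT_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

rand_seqs <- function(lengths, alphabet = c("A", "C", "G", "T")) {
  if (length(lengths) == 0) return(character(0))
  chars <- sample(alphabet, sum(lengths), replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  vapply(seq_along(lengths),
         function(i) paste(chars[starts[i]:ends[i]], collapse = ""),
         character(1))
}

seq_is_clean <- function(seq, adapter3, adapter5, min_overlap = 6, polya_min = 8) {
  !grepl(substr(adapter3, 1, min_overlap), seq, fixed = TRUE) &&
    !grepl(adapter5, seq, fixed = TRUE) &&
    !grepl(paste0("A{", polya_min, ",}"), seq)
}

rand_clean_seq <- function(len, adapter3, adapter5, alphabet = c("A", "C", "G", "T")) {
  repeat {
    s <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    if (seq_is_clean(s, adapter3, adapter5)) return(s)
  }
}

#' The study's sample design
#'
#' @param n_reps Biological replicates per (genotype, leaf) group (default 3).
#' @return Sample-metadata tibble: `sample`, `genotype`, `leaf`, `replicate`
#'   (18 rows for the default design).
#' @export
study_design <- function(n_reps = 3) {
  tidyr::expand_grid(
    genotype = c("wild", "mutant"),
    leaf = c("flag", "second", "third"),
    replicate = seq_len(n_reps)
  ) %>%
    mutate(sample = paste(.data$genotype, .data$leaf, .data$replicate, sep = "_")) %>%
    select("sample", "genotype", "leaf", "replicate")
}

# -------------------------------------------------------------------------
# Annotation + transcript sequences

#' Generate a synthetic annotation with the five lncRNA archetypes
#'
#' Coding genes are laid out on one chromosome, 20 kb apart, each with three
#' exons (a large first intron hosts the intronic archetype); strands
#' alternate. The first five lncRNA candidates are placed as archetypes of
#' the five positional classes (sense_overlapping, antisense, intronic,
#' bidirectional, intergenic); any further candidates are intergenic,
#' placed in gene-free gaps away from promoters. Transcript sequences are
#' random (fixed seed).
#'
#' @param n_genes Number of coding genes (>= 6).
#' @param n_lncrna Number of lncRNA candidates (>= 5, one archetype each).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param gene_ids,lnc_ids Optional explicit feature ids.
#' @return A list with `annotation` (tibble, see [validate_annotation()]),
#'   `sequences` (tibble `id`, `seq`, `desc` for every transcript) and
#'   `archetypes` (tibble `lncrna_id`, `class` of the planted archetypes).
#' @export
simulate_annotation <- function(n_genes = 10, n_lncrna = 5, seed = 1,
                                gene_ids = NULL, lnc_ids = NULL) {
  if (n_lncrna < 5) abort("need n_lncrna >= 5 to cover the five positional classes")
  if (n_genes < 6) abort("need n_genes >= 6 to host the archetypes")
  gene_ids <- gene_ids %||% sprintf("mRNA_%04d", seq_len(n_genes))
  lnc_ids <- lnc_ids %||% sprintf("lnc_%03d", seq_len(n_lncrna))
  stopifnot(length(gene_ids) == n_genes, length(lnc_ids) == n_lncrna)

  withr::with_seed(seed, {
    spacing <- 20000L
    g_start <- 10000L + (seq_len(n_genes) - 1L) * spacing
    g_strand <- rep(c("+", "-"), length.out = n_genes)
    # exon offsets within each gene: 300 nt, [1800,2200), [3000,3500)
    exon_off <- list(c(0L, 300L), c(1800L, 2200L), c(3000L, 3500L))
    gene_rows <- tibble(
      seqid = "Chr1", type = "gene", start = g_start, end = g_start + 3500L,
      strand = g_strand, id = paste0("gene:", gene_ids),
      parent = NA_character_, biotype = NA_character_
    )
    tx_rows <- gene_rows %>%
      mutate(type = "transcript", id = gene_ids,
             parent = paste0("gene:", gene_ids), biotype = "coding")
    exon_rows <- bind_rows(lapply(seq_along(exon_off), function(k) {
      tibble(
        seqid = "Chr1", type = "exon",
        start = g_start + exon_off[[k]][1], end = g_start + exon_off[[k]][2],
        strand = g_strand, id = paste0(gene_ids, ".e", k),
        parent = gene_ids, biotype = NA_character_
      )
    }))

    lnc_len <- 400L
    arch <- c("sense_overlapping", "antisense", "intronic", "bidirectional",
              "intergenic")
    place_one <- function(i) {
      if (i == 1) {                               # same strand, over exon 1
        tibble(start = g_start[1] + 100L, strand = g_strand[1])
      } else if (i == 2) {                        # opposite strand, over exon 1
        tibble(start = g_start[2] + 100L,
               strand = if (g_strand[2] == "+") "-" else "+")
      } else if (i == 3) {                        # inside intron 1
        tibble(start = g_start[3] + 400L, strand = g_strand[3])
      } else if (i == 4) {                        # divergent head-to-head
        if (g_strand[4] == "-") {
          tibble(start = g_start[4] + 3500L + 500L, strand = "+")
        } else {
          tibble(start = g_start[4] - 500L - lnc_len, strand = "-")
        }
      } else if (i == 5) {                        # between genes 5 and 6
        tibble(start = g_start[5] + 3500L + 8000L, strand = "+")
      } else {                                    # extra: intergenic in a gap
        j <- ((i - 6L) %% (n_genes - 1L)) + 1L
        off <- 3000L + (i * 997L) %% 8000L
        tibble(start = g_start[j] + 3500L + off,
               strand = if (i %% 2 == 0) "+" else "-")
      }
    }
    placed <- bind_rows(lapply(seq_len(n_lncrna), place_one))
    lnc_tx <- tibble(
      seqid = "Chr1", type = "transcript",
      start = placed$start, end = placed$start + lnc_len,
      strand = placed$strand, id = lnc_ids, parent = NA_character_,
      biotype = "lncRNA_candidate"
    )
    lnc_exon <- lnc_tx %>%
      mutate(type = "exon", id = paste0(lnc_ids, ".e1"), parent = lnc_ids,
             biotype = NA_character_)

    annot <- bind_rows(gene_rows, tx_rows, exon_rows, lnc_tx, lnc_exon)
    validate_annotation(annot)
    tx_len <- 300L + 400L + 500L
    seqs <- tibble(
      id = c(gene_ids, lnc_ids),
      seq = rand_seqs(c(rep(tx_len, n_genes), rep(lnc_len, n_lncrna))),
      desc = c(rep("coding transcript", n_genes),
               rep("lncRNA candidate", n_lncrna))
    )
    list(
      annotation = annot,
      sequences = seqs,
      archetypes = tibble(lncrna_id = lnc_ids[1:5], class = arch)
    )
  })
}

# -------------------------------------------------------------------------
# miRNA catalog with decoy-carrier composition constraints

# Per-rule decoy templates (miRNA length 21): which miRNA positions carry
# which modification in the planted near-site, and which carrier bases those
# positions need. Designed so each decoy violates its named rule and no
# other (under ruleset A with the default energy model); feasibility is
# re-verified in the test suite against the rule engine and the brute-force
# oracle.
decoy_template <- function(rule) {
  switch(rule,
    r1 = list(pos = c(1, 3, 5, 7, 13, 15, 17, 19, 21), kind = "GU", base = "U",
              other = NULL),
    r2 = list(pos = 13:15, kind = "GU", base = "U", other = NULL),
    r3 = list(pos = 5:6, kind = "GU", base = "U", other = NULL),
    r4 = list(pos = 10, kind = "MM", base = NULL, other = NULL),
    r5 = list(pos = c(1, 3, 5), kind = "MM", base = "A", other = NULL),
    r6 = list(pos = c(1, 3, 5, 13, 15, 17, 19), kind = "GU", base = "G",
              other = c("A", "U")),
    abort(paste0("unknown decoy rule: ", rule))
  )
}

#' Generate a miRNA catalog (with decoy-carrier sequences)
#'
#' Random 21-nt RNA sequences, rejection-sampled so that none contains the
#' 3' adapter's seed prefix or a polyA run (which would confound the read
#' filter). The first `length(decoy_rules)` catalog entries are decoy
#' carriers whose base composition supports a near-site violating exactly
#' the named rule.
#'
#' @param n Catalog size.
#' @param length miRNA length in nt (>= 21 when decoys are requested).
#' @param seed Integer seed.
#' @param decoy_rules Character vector among `r1`..`r6` (default all six);
#'   use `character(0)` for a plain catalog.
#' @param adapter3,adapter5 Adapters the sequences must stay clear of.
#' @param ids Optional explicit ids.
#' @return Tibble `id`, `seq` (RNA alphabet), `decoy_rule` (`NA` for
#'   ordinary miRNAs).
#' @export
simulate_mirnas <- function(n, length = 21, seed = 1,
                            decoy_rules = paste0("r", 1:6),
                            adapter3 = DEFAULT_ADAPTER3,
                            adapter5 = DEFAULT_ADAPTER5,
                            ids = NULL) {
  if (length(decoy_rules) > 0 && length < 21) {
    abort("decoy templates need miRNA length >= 21")
  }
  if (n < length(decoy_rules)) abort("catalog smaller than the decoy rule list")
  ids <- ids %||% c(sprintf("miR_decoy_%s", decoy_rules),
                    sprintf("miR_%03d", seq_len(n - length(decoy_rules))))
  withr::with_seed(seed, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      rule <- if (i <= length(decoy_rules)) decoy_rules[i] else NA_character_
      repeat {
        if (is.na(rule)) {
          s <- paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
                     collapse = "")
        } else {
          tpl <- decoy_template(rule)
          pool <- tpl$other %||% c("A", "C", "G", "U")
          ch <- sample(pool, length, replace = TRUE)
          if (!is.null(tpl$base)) ch[tpl$pos] <- tpl$base
          s <- paste(ch, collapse = "")
        }
        if (seq_is_clean(chartr("U", "T", s), adapter3, adapter5)) break
      }
      seqs[i] <- s
    }
    tibble(id = ids, seq = seqs,
           decoy_rule = c(decoy_rules, rep(NA_character_, n - length(decoy_rules))))
  })
}

# -------------------------------------------------------------------------
# Binding-site planting

# build the target window for a miRNA: reverse complement with the given
# modifications (GU wobble or true mismatch) at the stated miRNA positions
make_site_window <- function(mirna_seq, mods = NULL) {
  m <- strsplit(as_rna(mirna_seq), "")[[1]]
  L <- length(m)
  w <- strsplit(reverse_complement_rna(mirna_seq), "")[[1]]
  if (!is.null(mods) && nrow(mods) > 0) {
    for (i in seq_len(nrow(mods))) {
      p <- mods$pos[i]
      wi <- L + 1L - p                      # window index pairing miRNA pos p
      if (mods$kind[i] == "GU") {
        if (m[p] == "G") w[wi] <- "U"
        else if (m[p] == "U") w[wi] <- "G"
        else abort(paste0("cannot place a G:U wobble at miRNA position ", p,
                          " (base ", m[p], ")"))
      } else {                              # MM: pair the base with itself
        w[wi] <- m[p]
      }
    }
  }
  paste(w, collapse = "")
}

#' Plant miRNA binding sites (and rule-violating decoys) into transcripts
#'
#' Each planned site overwrites a random window of the transcript with the
#' miRNA's reverse complement; `type = "site"` windows are perfect
#' complements (optionally with benign wobbles), `type = "decoy"` windows
#' carry the modification set of `rule`, violating exactly that rule under
#' ruleset A. Windows on the same transcript never overlap.
#'
#' @param mirnas miRNA tibble (`id`, `seq`).
#' @param transcripts Transcript tibble (`id`, `seq`); each edited
#'   transcript must be longer than the miRNA by at least 10 nt.
#' @param plan Tibble `mirna_id`, `transcript_id`, `type` (`site`/`decoy`),
#'   `rule` (`r1`..`r6` for decoys, `NA` otherwise).
#' @param seed Integer seed (site placement).
#' @param n_wobble Number of benign G:U wobbles in true sites (0-2, placed
#'   at positions 15/17 when the miRNA base allows; default 0).
#' @return A list with `transcripts` (edited tibble) and `sites` (truth
#'   tibble: `transcript_id`, `mirna_id`, `start`, `type`, `rule`).
#' @export
plant_binding_sites <- function(mirnas, transcripts, plan, seed = 1,
                                n_wobble = 0) {
  stopifnot(all(plan$mirna_id %in% mirnas$id),
            all(plan$transcript_id %in% transcripts$id))
  seqs <- setNames(transcripts$seq, transcripts$id)
  mir_seq <- setNames(mirnas$seq, mirnas$id)
  occupied <- setNames(vector("list", length(seqs)), names(seqs))
  sites <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(plan))) {
      mid <- plan$mirna_id[i]
      tid <- plan$transcript_id[i]
      mir <- mir_seq[[mid]]
      L <- nchar(mir)
      tlen <- nchar(seqs[[tid]])
      if (tlen < L + 10) {
        abort(paste0("transcript ", tid, " too short to host a site for ", mid))
      }
      mods <- NULL
      if (plan$type[i] == "decoy") {
        tpl <- decoy_template(plan$rule[i])
        mods <- tibble(pos = tpl$pos, kind = tpl$kind)
      } else if (n_wobble > 0) {
        m <- strsplit(as_rna(mir), "")[[1]]
        cand <- intersect(c(15L, 17L), which(m %in% c("G", "U")))
        cand <- head(cand, n_wobble)
        if (length(cand) > 0) mods <- tibble(pos = cand, kind = "GU")
      }
      window <- chartr("U", "T", make_site_window(mir, mods))
      placed <- FALSE
      for (try in 1:50) {
        s0 <- sample.int(tlen - L + 1L, 1L) - 1L   # 0-based
        clash <- any(vapply(occupied[[tid]],
                            function(iv) s0 < iv[2] && iv[1] < s0 + L,
                            logical(1)))
        if (!clash) {
          placed <- TRUE
          break
        }
      }
      if (!placed) abort(paste0("could not place a non-overlapping site on ", tid))
      substr(seqs[[tid]], s0 + 1L, s0 + L) <- window
      occupied[[tid]] <- c(occupied[[tid]], list(c(s0, s0 + L)))
      sites[[length(sites) + 1]] <- tibble(
        transcript_id = tid, mirna_id = mid, start = s0,
        type = plan$type[i], rule = plan$rule[i]
      )
    }
  })
  out_tx <- transcripts
  out_tx$seq <- unname(seqs[out_tx$id])
  list(transcripts = out_tx, sites = bind_rows(sites))
}

# -------------------------------------------------------------------------
# Expression

# sample-level pattern vectors used by the planted structure
design_patterns <- function(samples) {
  list(
    geno = as.numeric(samples$genotype == "mutant"),
    # senescence: high only in the mutant's second/third leaves
    sen = as.numeric(samples$genotype == "mutant" &
                       samples$leaf %in% c("second", "third")),
    # genotype-crossed leaf contrast, orthogonal to `sen` after centring
    leafx = c(flag = 1, second = -1, third = 0)[samples$leaf] *
      ifelse(samples$genotype == "wild", 1, 0) +
      c(flag = 0, second = 1, third = -1)[samples$leaf] *
      ifelse(samples$genotype == "mutant", 1, 0)
  )
}

#' Generate the study's expression matrices with planted structure
#'
#' See the module header for the generative model. Feature roles are
#' assigned positionally within each id vector: mRNAs are
#' `[DE | module1 | module2 | triplet | decoy | null]`, lncRNAs
#' `[DE | triplet | decoy | null]`, miRNAs `[decoy | triplet | DE | null]`.
#'
#' @param mrna_ids,lnc_ids,mirna_ids Feature id vectors (defaults sized
#'   300 / 60 / 30).
#' @param n_de_mrna,n_de_lnc,n_de_mirna Planted genotype-wide DE features.
#' @param n_triplets Planted ceRNA triplets.
#' @param n_decoy Decoy pseudo-triplets (default 6, one per rule).
#' @param module_sizes Planted module sizes (default `c(60, 60)`).
#' @param de_lfc Planted |log2FC| for DE features (>= 1.5; default 2).
#' @param noise_sigma Log2-scale noise sd (default 0.15).
#' @param module_noise_sd Per-gene noise of module members (default 0.5,
#'   giving within-module pairwise correlation about 0.9).
#' @param triplet_amp Amplitude of the triplet senescence profile (default 3).
#' @param triplet_jitter_sd Per-sample jitter shared within a triplet
#'   (default 0.35): the graded component that keeps rank correlations high
#'   while leaving the members' group contrasts strong enough to be called
#'   differentially expressed.
#' @param module_amp Amplitudes of the two module patterns (default `c(3, 2)`).
#' @param n_reps Replicates per group (>= 2; default 3).
#' @param count_mode Return Poisson counts around the abundance means?
#' @param seed Integer seed.
#' @return A list with `expr` (list of wide tibbles `mrna`, `lnc`, `mirna`),
#'   `samples`, and `truth` (class `cerna_truth`: `de`, `modules`,
#'   `triplets`, `decoy_triplets`, `params`, `seed`).
#' @export
simulate_expression <- function(mrna_ids = sprintf("mRNA_%04d", 1:300),
                                lnc_ids = sprintf("lnc_%03d", 1:60),
                                mirna_ids = NULL,
                                n_de_mrna = 30, n_de_lnc = 10, n_de_mirna = 5,
                                n_triplets = 5, n_decoy = 6,
                                module_sizes = c(60, 60),
                                de_lfc = 2, noise_sigma = 0.15,
                                module_noise_sd = 0.5,
                                triplet_amp = 3, triplet_jitter_sd = 0.35,
                                module_amp = c(3, 2),
                                n_reps = 3, count_mode = FALSE, seed = 1) {
  if (n_reps < 2) abort("the DE test is undefined with fewer than 2 replicates")
  if (n_de_mrna + n_triplets + n_decoy > 0 && abs(de_lfc) < 1.5) {
    abort("planted |log2FC| must be >= 1.5 (margin above the calling threshold)")
  }
  mirna_ids <- mirna_ids %||%
    c(paste0("miR_decoy_r", seq_len(n_decoy)) %0% character(0),
      sprintf("miR_%03d", seq_len(30 - n_decoy)))
  need_mrna <- n_de_mrna + sum(module_sizes) + n_triplets + n_decoy
  need_lnc <- n_de_lnc + n_triplets + n_decoy
  need_mir <- n_decoy + n_triplets + n_de_mirna
  if (length(mrna_ids) < need_mrna) abort("too few mRNA ids for the planted roles")
  if (length(lnc_ids) < need_lnc) abort("too few lncRNA ids for the planted roles")
  if (length(mirna_ids) < need_mir) abort("too few miRNA ids for the planted roles")

  samples <- study_design(n_reps)
  n_s <- nrow(samples)
  pat <- design_patterns(samples)

  # positional role assignment
  mrna_de <- mrna_ids[seq_len(n_de_mrna)] %0% character(0)
  off <- n_de_mrna
  mod1 <- mrna_ids[off + seq_len(module_sizes[1])] %0% character(0)
  off <- off + module_sizes[1]
  mod2 <- mrna_ids[off + seq_len(module_sizes[2])] %0% character(0)
  off <- off + module_sizes[2]
  mrna_trip <- mrna_ids[off + seq_len(n_triplets)] %0% character(0)
  off <- off + n_triplets
  mrna_dec <- mrna_ids[off + seq_len(n_decoy)] %0% character(0)

  lnc_de <- lnc_ids[seq_len(n_de_lnc)] %0% character(0)
  lnc_trip <- lnc_ids[n_de_lnc + seq_len(n_triplets)] %0% character(0)
  lnc_dec <- lnc_ids[n_de_lnc + n_triplets + seq_len(n_decoy)] %0% character(0)

  mir_dec <- mirna_ids[seq_len(n_decoy)] %0% character(0)
  mir_trip <- mirna_ids[n_decoy + seq_len(n_triplets)] %0% character(0)
  mir_de <- mirna_ids[n_decoy + n_triplets + seq_len(n_de_mirna)] %0% character(0)

  withr::with_seed(seed, {
    build <- function(ids, base_lo, base_hi, sigma_default) {
      logm <- matrix(rep(runif(length(ids), base_lo, base_hi), n_s),
                     nrow = length(ids), dimnames = list(ids, samples$sample))
      logm
    }
    lm_mrna <- build(mrna_ids, 3, 8)
    lm_lnc <- build(lnc_ids, 3, 8)
    lm_mir <- build(mirna_ids, 3, 6)
    # triplet/decoy miRNAs are well-expressed (as ceRNA-network miRNAs are),
    # so Poisson read sampling leaves their profiles rank-coherent
    hot <- c(mir_dec, mir_trip)
    lm_mir[hot, ] <- matrix(rep(runif(length(hot), 7, 8), n_s),
                            nrow = length(hot))

    de_sign <- function(k) rep_len(c(1, -1), k)
    add_geno <- function(lm, ids, signs) {
      for (i in seq_along(ids)) {
        lm[ids[i], ] <- lm[ids[i], ] + signs[i] * de_lfc * pat$geno
      }
      lm
    }
    lm_mrna <- add_geno(lm_mrna, mrna_de, de_sign(length(mrna_de)))
    lm_lnc <- add_geno(lm_lnc, lnc_de, de_sign(length(lnc_de)))
    lm_mir <- add_geno(lm_mir, mir_de, de_sign(length(mir_de)))

    for (g in mod1) lm_mrna[g, ] <- lm_mrna[g, ] + module_amp[1] * pat$sen
    for (g in mod2) lm_mrna[g, ] <- lm_mrna[g, ] + module_amp[2] * pat$leafx

    latent <- function() triplet_amp * pat$sen + rnorm(n_s, 0, triplet_jitter_sd)
    trip_z <- lapply(seq_len(n_triplets), function(i) latent())
    dec_z <- lapply(seq_len(n_decoy), function(i) latent())
    for (i in seq_len(n_triplets)) {
      lm_mrna[mrna_trip[i], ] <- lm_mrna[mrna_trip[i], ] + trip_z[[i]]
      lm_lnc[lnc_trip[i], ] <- lm_lnc[lnc_trip[i], ] + trip_z[[i]]
      lm_mir[mir_trip[i], ] <- lm_mir[mir_trip[i], ] - trip_z[[i]]
    }
    for (i in seq_len(n_decoy)) {
      lm_mrna[mrna_dec[i], ] <- lm_mrna[mrna_dec[i], ] + dec_z[[i]]
      lm_lnc[lnc_dec[i], ] <- lm_lnc[lnc_dec[i], ] + dec_z[[i]]
      lm_mir[mir_dec[i], ] <- lm_mir[mir_dec[i], ] - dec_z[[i]]
    }

    noise_sd <- function(ids, module_ids) {
      ifelse(ids %in% module_ids, module_noise_sd, noise_sigma)
    }
    add_noise <- function(lm, sds) {
      lm + matrix(rnorm(length(lm), 0, rep(sds, ncol(lm))), nrow = nrow(lm))
    }
    lm_mrna <- add_noise(lm_mrna, noise_sd(mrna_ids, c(mod1, mod2)))
    lm_lnc <- add_noise(lm_lnc, rep(noise_sigma, length(lnc_ids)))
    lm_mir <- add_noise(lm_mir, rep(noise_sigma, length(mirna_ids)))

    to_expr <- function(lm) {
      ab <- 2^lm
      if (count_mode) {
        ab <- matrix(rpois(length(ab), ab), nrow = nrow(ab), dimnames = dimnames(ab))
      }
      matrix_to_expr(ab)
    }
    expr <- list(mrna = to_expr(lm_mrna), lnc = to_expr(lm_lnc),
                 mirna = to_expr(lm_mir))
  })

  truth <- structure(
    list(
      de = bind_rows(
        tibble(feature_id = mrna_de, class = "mRNA",
               log2fc = rep_len(c(1, -1), length(mrna_de)) * de_lfc),
        tibble(feature_id = lnc_de, class = "lncRNA",
               log2fc = rep_len(c(1, -1), length(lnc_de)) * de_lfc),
        tibble(feature_id = mir_de, class = "miRNA",
               log2fc = rep_len(c(1, -1), length(mir_de)) * de_lfc)
      ),
      modules = bind_rows(
        tibble(feature_id = mod1, module = "module1"),
        tibble(feature_id = mod2, module = "module2"),
        tibble(feature_id = mrna_trip, module = "module1")
      ),
      triplets = tibble(lncrna_id = lnc_trip, mirna_id = mir_trip,
                        mrna_id = mrna_trip),
      decoy_triplets = tibble(lncrna_id = lnc_dec, mirna_id = mir_dec,
                              mrna_id = mrna_dec,
                              rule = paste0("r", seq_len(n_decoy)) %0% character(0)),
      params = list(n_de_mrna = n_de_mrna, n_de_lnc = n_de_lnc,
                    n_de_mirna = n_de_mirna, n_triplets = n_triplets,
                    n_decoy = n_decoy, module_sizes = module_sizes,
                    de_lfc = de_lfc, noise_sigma = noise_sigma,
                    module_noise_sd = module_noise_sd,
                    triplet_amp = triplet_amp,
                    triplet_jitter_sd = triplet_jitter_sd,
                    module_amp = module_amp, n_reps = n_reps,
                    count_mode = count_mode),
      seed = seed
    ),
    class = "cerna_truth"
  )
  list(expr = expr, samples = samples, truth = truth)
}

# -------------------------------------------------------------------------
# Small-RNA reads

#' Generate a small-RNA library with controlled contaminants
#'
#' Clean reads are miRNA sequences flanked by the 3' adapter at Phred
#' quality 40; contaminant counts are exactly as specified, each built to
#' fail exactly its filter rule, so the filter report is checkable against
#' the specification.
#'
#' @param mirnas miRNA tibble (`id`, `seq`).
#' @param copy_numbers Named integer vector of clean-read counts per miRNA
#'   (names matching `mirnas$id`).
#' @param contaminants Named list/vector with any of `low_quality`, `short`,
#'   `no_3prime_adapter`, `has_5prime_adapter`, `polya` (default all 0).
#' @param adapter3,adapter5 Adapter sequences.
#' @param seed Integer seed.
#' @return A list with `reads` (tibble `id`, `seq`, `qual`) and `truth`
#'   (the copy numbers and contaminant spec).
#' @export
simulate_smallrna_reads <- function(mirnas, copy_numbers,
                                    contaminants = list(),
                                    adapter3 = DEFAULT_ADAPTER3,
                                    adapter5 = DEFAULT_ADAPTER5,
                                    seed = 1) {
  spec <- list(low_quality = 0, short = 0, no_3prime_adapter = 0,
               has_5prime_adapter = 0, polya = 0)
  bad <- setdiff(names(contaminants), names(spec))
  if (length(bad) > 0) abort(paste0("unknown contaminant class: ", paste(bad, collapse = ", ")))
  spec[names(contaminants)] <- contaminants
  stopifnot(all(names(copy_numbers) %in% mirnas$id))
  mir_dna <- setNames(chartr("U", "T", toupper(mirnas$seq)), mirnas$id)
  for (s in mir_dna[names(copy_numbers)]) {
    if (!seq_is_clean(s, adapter3, adapter5)) {
      abort("a catalog miRNA contains the adapter seed or a polyA run; regenerate the catalog")
    }
  }
  withr::with_seed(seed, {
    reads <- list()
    push <- function(seq, qual) {
      reads[[length(reads) + 1]] <<- tibble(seq = seq, qual = qual)
    }
    q40 <- function(n) strrep("I", n)
    for (mid in names(copy_numbers)) {
      k <- copy_numbers[[mid]]
      if (k > 0) {
        s <- paste0(mir_dna[[mid]], adapter3)
        push(rep(s, k), rep(q40(nchar(s)), k))
      }
    }
    for (i in seq_len(spec$low_quality)) {
      ins <- rand_clean_seq(21, adapter3, adapter5)
      s <- paste0(ins, adapter3)
      n <- nchar(s)
      n_bad <- ceiling(0.6 * n)
      push(s, paste0(strrep("#", n_bad), strrep("I", n - n_bad)))
    }
    for (i in seq_len(spec$short)) {
      s <- paste0(rand_clean_seq(15, adapter3, adapter5), adapter3)
      push(s, q40(nchar(s)))
    }
    for (i in seq_len(spec$no_3prime_adapter)) {
      s <- rand_clean_seq(40, adapter3, adapter5)
      push(s, q40(nchar(s)))
    }
    for (i in seq_len(spec$has_5prime_adapter)) {
      s <- paste0(adapter5, rand_clean_seq(10, adapter3, adapter5), adapter3)
      push(s, q40(nchar(s)))
    }
    for (i in seq_len(spec$polya)) {
      s <- paste0(strrep("A", 20), adapter3)
      push(s, q40(nchar(s)))
    }
    out <- bind_rows(reads)
    if (nrow(out) == 0) {
      out <- tibble(seq = character(), qual = character())
    }
    out <- tibble(id = sprintf("read_%06d", seq_len(nrow(out))),
                  seq = out$seq, qual = out$qual)
    list(reads = out, truth = list(copy_numbers = copy_numbers,
                                   contaminants = spec))
  })
}

# -------------------------------------------------------------------------
# Focused generator for DE operating characteristics

#' Simulate a two-group matrix with planted fold changes
#'
#' The focused generator for measuring the DE surrogate's type-I error and
#' sensitivity: `n_null` features identical in both groups, `n_de` features
#' with a planted log2 fold change of alternating sign, log-normal noise,
#' and (by default) Poisson counts around the abundance-scale means.
#'
#' @param n_null,n_de Feature counts.
#' @param lfc Planted |log2FC| (default 2).
#' @param sigma Log2-scale noise sd (default 0.15).
#' @param n_per_group Replicates per group (default 3).
#' @param base_range Log2 baseline range (default `c(5, 10)`, i.e. roughly
#'   30-1000 counts — the range of detectably expressed genes at typical
#'   sequencing depth).
#' @param count_mode Poisson counts? Default `TRUE`.
#' @param seed Integer seed.
#' @return A list with `expr` (wide tibble), `group_a`, `group_b`, `truth`
#'   (tibble `feature_id`, `log2fc`; 0 for nulls).
#' @export
simulate_de_matrix <- function(n_null = 200, n_de = 50, lfc = 2, sigma = 0.15,
                               n_per_group = 3, base_range = c(5, 10),
                               count_mode = TRUE, seed = 1) {
  ids <- c(sprintf("de_%03d", seq_len(n_de)) %0% character(0),
           sprintf("null_%03d", seq_len(n_null)) %0% character(0))
  group_a <- paste0("A_", seq_len(n_per_group))
  group_b <- paste0("B_", seq_len(n_per_group))
  signs <- c(rep_len(c(1, -1), n_de), rep(0, n_null))
  withr::with_seed(seed, {
    base <- runif(length(ids), base_range[1], base_range[2])
    lm <- cbind(
      matrix(rep(base, n_per_group), ncol = n_per_group),
      matrix(rep(base + signs * lfc, n_per_group), ncol = n_per_group)
    )
    lm <- lm + matrix(rnorm(length(lm), 0, sigma), nrow = nrow(lm))
    ab <- 2^lm
    if (count_mode) ab <- matrix(rpois(length(ab), ab), nrow = nrow(ab))
    dimnames(ab) <- list(ids, c(group_a, group_b))
    list(
      expr = matrix_to_expr(ab),
      group_a = group_a, group_b = group_b,
      truth = tibble(feature_id = ids, log2fc = signs * lfc)
    )
  })
}

# -------------------------------------------------------------------------
# Whole-study bundle

#' Simulate a complete ceRNA study
#'
#' Bundles annotation, transcript sequences with planted binding sites,
#' a miRNA catalog with decoy carriers, expression matrices, per-sample
#' small-RNA libraries, and the truth table. `preset = "full"`
#' reproduces the full-scale study design (2,000 mRNAs, 300 lncRNAs,
#' 100 miRNAs, 18 libraries); the default `"small"` preset keeps unit tests
#' fast.
#'
#' @param preset `"small"` or `"full"`.
#' @param seed Integer seed driving every stage.
#' @param reads Generate the 18 small-RNA libraries? (default `TRUE`).
#' @param ... Overrides forwarded to [simulate_expression()].
#' @return A list: `annotation`, `transcripts` (sequence tibble with sites
#'   planted), `mirnas`, `expr`, `samples`, `reads` (named list of read
#'   tibbles or `NULL`), `truth`.
#' @export
simulate_cerna_study <- function(preset = c("small", "full"), seed = 1,
                                 reads = TRUE, ...) {
  preset <- match.arg(preset)
  dims <- if (preset == "full") {
    list(n_mrna = 2000, n_lnc = 300, n_mirna = 100,
         n_de_mrna = 200, n_de_lnc = 40, n_de_mirna = 10, n_triplets = 10)
  } else {
    list(n_mrna = 300, n_lnc = 60, n_mirna = 30,
         n_de_mrna = 30, n_de_lnc = 10, n_de_mirna = 5, n_triplets = 5)
  }
  n_decoy <- 6
  mrna_ids <- sprintf("mRNA_%04d", seq_len(dims$n_mrna))
  lnc_ids <- sprintf("lnc_%03d", seq_len(dims$n_lnc))
  mirnas <- simulate_mirnas(dims$n_mirna, seed = seed + 101L)
  sim <- simulate_expression(
    mrna_ids = mrna_ids, lnc_ids = lnc_ids, mirna_ids = mirnas$id,
    n_de_mrna = dims$n_de_mrna, n_de_lnc = dims$n_de_lnc,
    n_de_mirna = dims$n_de_mirna, n_triplets = dims$n_triplets,
    n_decoy = n_decoy, seed = seed, ...
  )
  ann <- simulate_annotation(dims$n_mrna, dims$n_lnc, seed = seed + 202L,
                             gene_ids = mrna_ids, lnc_ids = lnc_ids)
  truth <- sim$truth
  plan <- bind_rows(
    tibble(mirna_id = truth$triplets$mirna_id,
           transcript_id = truth$triplets$mrna_id, type = "site",
           rule = NA_character_),
    tibble(mirna_id = truth$triplets$mirna_id,
           transcript_id = truth$triplets$lncrna_id, type = "site",
           rule = NA_character_),
    tibble(mirna_id = truth$decoy_triplets$mirna_id,
           transcript_id = truth$decoy_triplets$mrna_id, type = "decoy",
           rule = truth$decoy_triplets$rule),
    tibble(mirna_id = truth$decoy_triplets$mirna_id,
           transcript_id = truth$decoy_triplets$lncrna_id, type = "decoy",
           rule = truth$decoy_triplets$rule)
  )
  planted <- plant_binding_sites(mirnas, ann$sequences, plan, seed = seed + 303L)
  truth$sites <- planted$sites
  truth$archetypes <- ann$archetypes

  read_libs <- NULL
  if (reads) {
    mir_ab <- expr_to_matrix(sim$expr$mirna)
    read_libs <- list()
    for (j in seq_len(ncol(mir_ab))) {
      copies <- withr::with_seed(seed + 400L + j,
                                 setNames(rpois(nrow(mir_ab), mir_ab[, j]),
                                          rownames(mir_ab)))
      lib <- simulate_smallrna_reads(
        mirnas, copies,
        contaminants = list(low_quality = 3, short = 5, no_3prime_adapter = 4,
                            has_5prime_adapter = 2, polya = 3),
        seed = seed + 500L + j
      )
      read_libs[[colnames(mir_ab)[j]]] <- lib$reads
    }
  }
  list(
    annotation = ann$annotation,
    transcripts = planted$transcripts,
    mirnas = mirnas,
    expr = sim$expr,
    samples = sim$samples,
    reads = read_libs,
    truth = truth
  )
}
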