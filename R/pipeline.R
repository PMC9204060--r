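# End-to-end driver: from a simulated (or user-assembled) study bundle to
# the ceRNA network, running every stage with the configured thresholds.

#' Run the full ceRNA inference pipeline
#'
#' Stages: lncRNA screening/classification and cis-target search; small-RNA
#' filtering, exact-match quantification and TPM (when read libraries are
#' present, otherwise the study's miRNA abundance matrix is used directly);
#' differential expression per class over the three between-genotype
#' contrasts (a feature is "DE" when called in at least one of them);
#' rule-based target prediction for DE miRNAs against DE mRNA/lncRNA
#' transcripts; co-expression module detection on the mRNA matrix with
#' module-trait association (the senescence module is the one whose
#' eigengene correlates best with the mutant second/third-leaf groups);
#' and ceRNA triplet assembly with module intersection, followed by a
#' self-audit re-verification of every emitted triplet.
#'
#' @param study A study bundle as returned by [simulate_cerna_study()]:
#'   `annotation`, `transcripts`, `mirnas`, `expr`, `samples`, optionally
#'   `reads`.
#' @param config A [cerna_config()] list.
#' @return A list of class `cerna_pipeline` with the per-stage results:
#'   `lnc_classes`, `cis`, `filter_reports`, `mirna_tpm`, `de` (tables per
#'   class), `de_sets`, `hits`, `fit`, `trait`, `senescence_module`,
#'   `triplets`, `config`.
#' @export
run_cerna_pipeline <- function(study, config = cerna_config()) {
  cfg <- config

  # --- lncRNA annotation ---------------------------------------------------
  screened <- screen_lncrna(study$annotation, min_length = cfg$lncrna$min_length)
  keep_lnc <- screened$lncrna_id[screened$retained]
  lnc_classes <- classify_lncrna(study$annotation,
                                 bidir_window = cfg$lncrna$bidir_window) %>%
    filter(.data$lncrna_id %in% keep_lnc)
  cis <- cis_targets(study$annotation, window = cfg$lncrna$cis_window)

  # --- miRNA quantification ------------------------------------------------
  filter_reports <- NULL
  if (!is.null(study$reads)) {
    filtered <- lapply(study$reads, filter_smallrna,
                       min_len = cfg$smallrna$min_len,
                       max_len = cfg$smallrna$max_len,
                       min_overlap = cfg$smallrna$min_overlap,
                       polya_min = cfg$smallrna$polya_min,
                       low_quality_q = cfg$smallrna$low_quality_q,
                       low_quality_frac = cfg$smallrna$low_quality_frac)
    filter_reports <- lapply(filtered, `[[`, "report")
    tags <- lapply(filtered, `[[`, "reads")
    counts <- quantify_mirna(tags, study$mirnas)
    counts <- filter(counts, .data$mirna_id != "unassigned")
    mirna_expr <- tpm_small(counts)
  } else {
    mirna_expr <- study$expr$mirna
  }

  # --- differential expression --------------------------------------------
  contrasts <- enumerate_contrasts(study$samples) %>%
    filter(.data$type == "between_genotype")
  de_args <- list(alpha = cfg$de$alpha, lfc_cutoff = cfg$de$lfc_cutoff,
                  p_mirna = cfg$de$p_mirna, pseudocount = cfg$de$pseudocount)
  de <- list(
    mrna = do.call(call_de_all, c(list(study$expr$mrna, study$samples,
                                       feature_class = "mRNA",
                                       contrasts = contrasts), de_args)),
    lnc = do.call(call_de_all, c(list(study$expr$lnc, study$samples,
                                      feature_class = "lncRNA",
                                      contrasts = contrasts), de_args)),
    mirna = do.call(call_de_all, c(list(mirna_expr, study$samples,
                                        feature_class = "miRNA",
                                        contrasts = contrasts), de_args))
  )
  de_set <- function(tbl) unique(tbl$feature_id[tbl$status != "ns"])
  de_sets <- lapply(de, de_set)

  # --- target prediction ---------------------------------------------------
  tx <- study$transcripts
  de_tx <- filter(tx, .data$id %in% c(de_sets$mrna, de_sets$lnc))
  de_mirnas <- filter(study$mirnas, .data$id %in% de_sets$mirna)
  hits <- predict_targets(de_mirnas, de_tx, ruleset = cfg$targets$ruleset,
                          mfe_ratio = if (cfg$targets$ruleset == "A")
                            cfg$targets$mfe_ratio_a else cfg$targets$mfe_ratio_b,
                          gu_positional = cfg$targets$gu_positional,
                          model = cfg$targets$energy)

  # --- co-expression modules ----------------------------------------------
  fit <- detect_coexpr_modules(study$expr$mrna,
                               beta = cfg$modules$beta,
                               drop_fraction = cfg$modules$drop_fraction,
                               min_size = cfg$modules$min_size,
                               merge_cut = cfg$modules$merge_cut,
                               cut_height = cfg$modules$cut_height)
  trait <- module_trait(fit, study$samples)
  sen_module <- NA_character_
  sen_tr <- trait %>%
    filter(.data$trait %in% c("mutant_second", "mutant_third"), !is.na(.data$r)) %>%
    group_by(.data$module) %>%
    summarise(r = mean(.data$r), .groups = "drop") %>%
    arrange(desc(.data$r))
  if (nrow(sen_tr) > 0) sen_module <- sen_tr$module[1]
  module_genes <- fit$membership$feature_id[fit$membership$module == sen_module]

  # --- ceRNA assembly ------------------------------------------------------
  pairs_mrna <- filter_target_pairs(hits, mirna_expr, study$expr$mrna,
                                    de_sets$mirna, de_sets$mrna,
                                    scc_threshold = cfg$cerna$scc_threshold)
  pairs_lnc <- filter_target_pairs(hits, mirna_expr, study$expr$lnc,
                                   de_sets$mirna, de_sets$lnc,
                                   scc_threshold = cfg$cerna$scc_threshold)
  triplets <- assemble_triplets(pairs_mrna, pairs_lnc,
                                study$expr$lnc, study$expr$mrna,
                                pcc_threshold = cfg$cerna$pcc_threshold,
                                module_genes = module_genes,
                                require_lnc_in_module = cfg$cerna$require_lnc_in_module)
  verify_triplets(triplets, study$expr$lnc, mirna_expr, study$expr$mrna,
                  scc_threshold = cfg$cerna$scc_threshold,
                  pcc_threshold = cfg$cerna$pcc_threshold)

  structure(
    list(
      lnc_screen = screened, lnc_classes = lnc_classes, cis = cis,
      filter_reports = filter_reports, mirna_tpm = mirna_expr,
      de = de, de_sets = de_sets, hits = hits,
      fit = fit, trait = trait, senescence_module = sen_module,
      pairs_mrna = pairs_mrna, pairs_lnc = pairs_lnc,
      triplets = triplets, config = cfg
    ),
    class = "cerna_pipeline"
  )
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("ceRNA pipeline result\n")
  cat("  DE features: ", length(x$de_sets$mrna), " mRNA, ",
      length(x$de_sets$lnc), " lncRNA, ", length(x$de_sets$mirna),
      " miRNA\n", sep = "")
  cat("  target hits:", nrow(x$hits), "\n")
  cat("  modules:", nrow(filter(x$fit$sizes, .data$module != "grey")),
      "(senescence-associated:", x$senescence_module, ")\n")
  cat("  triplets:", nrow(x$triplets), "\n")
  invisible(x)
}
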