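# ceRNA triplet assembly: miRNA-target pairs constrained by target
# prediction, differential expression and Spearman anticorrelation, joined
# into (lncRNA, miRNA, mRNA) triplets through shared miRNAs under a Pearson
# co-expression constraint, optionally intersected with a co-expression
# module, and exported as SIF / GraphML for Cytoscape-class viewers.
#
# Thresholds are strict inequalities (SCC < -0.7, PCC > 0.9, as printed);
# pairs whose correlation is undefined (constant profiles) are dropped —
# they are treated as failing the threshold rather than scoring +/-1.

#' Filter predicted miRNA-target pairs by DE status and anticorrelation
#'
#' A pair survives iff (a) the target was predicted for the miRNA, (b) both
#' members are differentially expressed, and (c) the Spearman correlation of
#' their expression profiles is strictly below `scc_threshold`.
#'
#' @param hits Target-hit tibble from [predict_targets()] (transcript ids
#'   must match the target expression matrix's feature ids).
#' @param expr_mirna,expr_target Wide abundance tibbles sharing sample columns.
#' @param de_mirna,de_target Character vectors of DE feature ids.
#' @param scc_threshold Strict Spearman threshold (default -0.7).
#' @return A tibble with columns `mirna_id`, `target_id`, `scc`.
#' @export
filter_target_pairs <- function(hits, expr_mirna, expr_target,
                                de_mirna, de_target, scc_threshold = -0.7) {
  if (!identical(colnames(expr_mirna)[-1], colnames(expr_target)[-1])) {
    abort("expression matrices must share identical sample columns")
  }
  pairs <- hits %>%
    distinct(.data$mirna_id, target_id = .data$transcript_id) %>%
    filter(.data$mirna_id %in% de_mirna, .data$target_id %in% de_target)
  mm <- expr_to_matrix(expr_mirna)
  tm <- expr_to_matrix(expr_target)
  if (nrow(pairs) == 0) {
    return(tibble(mirna_id = character(), target_id = character(), scc = numeric()))
  }
  pairs$scc <- vapply(seq_len(nrow(pairs)), function(i) {
    cor_spearman(mm[pairs$mirna_id[i], ], tm[pairs$target_id[i], ])
  }, numeric(1))
  out <- pairs %>%
    filter(!is.na(.data$scc), .data$scc < scc_threshold) %>%
    arrange(.data$mirna_id, .data$target_id)
  cf_log("filter_pairs", "%d predicted pairs, %d DE-consistent, SCC<%g: %d kept",
         nrow(distinct(hits, .data$mirna_id, .data$transcript_id)),
         nrow(pairs), scc_threshold, nrow(out))
  out
}

#' Assemble ceRNA triplets from the two pair lists
#'
#' For every (lncRNA, mRNA) pair sharing at least one common miRNA across
#' the miRNA-mRNA and miRNA-lncRNA pair lists, the Pearson correlation of
#' the lncRNA and mRNA profiles is computed; one triplet is emitted per
#' shared miRNA when PCC strictly exceeds `pcc_threshold`. With
#' `module_genes` given, triplets are kept when their mRNA belongs to the
#' module (lncRNA membership additionally required only with
#' `require_lnc_in_module`). Output is deduplicated and sorted by
#' (lncRNA, miRNA, mRNA).
#'
#' @param pairs_mrna Tibble from [filter_target_pairs()] with mRNA targets.
#' @param pairs_lnc Tibble from [filter_target_pairs()] with lncRNA targets.
#' @param expr_lnc,expr_mrna Wide abundance tibbles sharing sample columns.
#' @param pcc_threshold Strict Pearson threshold (default 0.9).
#' @param module_genes Optional character vector of module member ids.
#' @param require_lnc_in_module Require lncRNA module membership too?
#' @return A tibble of class `cerna_triplets` with columns `lncrna_id`,
#'   `mirna_id`, `mrna_id`, `scc_mirna_mrna`, `scc_mirna_lnc`, `pcc_lnc_mrna`.
#' @export
assemble_triplets <- function(pairs_mrna, pairs_lnc, expr_lnc, expr_mrna,
                              pcc_threshold = 0.9, module_genes = NULL,
                              require_lnc_in_module = FALSE) {
  if (!identical(colnames(expr_lnc)[-1], colnames(expr_mrna)[-1])) {
    abort("expression matrices must share identical sample columns")
  }
  joined <- inner_join(
    rename(pairs_mrna, mrna_id = "target_id", scc_mirna_mrna = "scc"),
    rename(pairs_lnc, lncrna_id = "target_id", scc_mirna_lnc = "scc"),
    by = "mirna_id", relationship = "many-to-many"
  )
  empty <- tibble(lncrna_id = character(), mirna_id = character(),
                  mrna_id = character(), scc_mirna_mrna = numeric(),
                  scc_mirna_lnc = numeric(), pcc_lnc_mrna = numeric())
  if (nrow(joined) == 0) return(structure(empty, class = c("cerna_triplets", class(empty))))
  lm <- expr_to_matrix(expr_lnc)
  gm <- expr_to_matrix(expr_mrna)
  lg <- distinct(joined, .data$lncrna_id, .data$mrna_id)
  lg$pcc_lnc_mrna <- vapply(seq_len(nrow(lg)), function(i) {
    cor_pearson(lm[lg$lncrna_id[i], ], gm[lg$mrna_id[i], ])
  }, numeric(1))
  out <- joined %>%
    inner_join(lg, by = c("lncrna_id", "mrna_id")) %>%
    filter(!is.na(.data$pcc_lnc_mrna), .data$pcc_lnc_mrna > pcc_threshold)
  if (!is.null(module_genes)) {
    out <- filter(out, .data$mrna_id %in% module_genes)
    if (require_lnc_in_module) out <- filter(out, .data$lncrna_id %in% module_genes)
  }
  out <- out %>%
    select("lncrna_id", "mirna_id", "mrna_id", "scc_mirna_mrna",
           "scc_mirna_lnc", "pcc_lnc_mrna") %>%
    distinct() %>%
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  cf_log("assemble_triplets",
         "PCC>%g%s: %d triplets (%d lncRNAs, %d miRNAs, %d mRNAs)",
         pcc_threshold,
         if (is.null(module_genes)) "" else " + module intersection",
         nrow(out), n_distinct(out$lncrna_id), n_distinct(out$mirna_id),
         n_distinct(out$mrna_id))
  structure(out, class = c("cerna_triplets", class(out)))
}

#' Re-verify every emitted triplet against its defining thresholds
#'
#' Self-audit pass: recomputes all three correlations from the expression
#' matrices and checks the strict thresholds. Any violation is an error —
#' the invariants are part of the triplet's definition.
#'
#' @param triplets A `cerna_triplets` tibble.
#' @param expr_lnc,expr_mirna,expr_mrna Wide abundance tibbles.
#' @param scc_threshold,pcc_threshold The thresholds the triplets claim.
#' @return `TRUE`, invisibly, or an error naming the offending triplet.
#' @export
verify_triplets <- function(triplets, expr_lnc, expr_mirna, expr_mrna,
                            scc_threshold = -0.7, pcc_threshold = 0.9) {
  lm <- expr_to_matrix(expr_lnc)
  mm <- expr_to_matrix(expr_mirna)
  gm <- expr_to_matrix(expr_mrna)
  for (i in seq_len(nrow(triplets))) {
    t <- triplets[i, ]
    s1 <- cor_spearman(mm[t$mirna_id, ], gm[t$mrna_id, ])
    s2 <- cor_spearman(mm[t$mirna_id, ], lm[t$lncrna_id, ])
    p1 <- cor_pearson(lm[t$lncrna_id, ], gm[t$mrna_id, ])
    ok <- !is.na(s1) && !is.na(s2) && !is.na(p1) &&
      s1 < scc_threshold && s2 < scc_threshold && p1 > pcc_threshold
    if (!ok) {
      abort(paste0("triplet violates its thresholds: ",
                   t$lncrna_id, " / ", t$mirna_id, " / ", t$mrna_id))
    }
  }
  invisible(TRUE)
}

triplets_to_edges <- function(triplets) {
  bind_rows(
    triplets %>% distinct(from = .data$lncrna_id, to = .data$mirna_id) %>%
      mutate(interaction = "sponges"),
    triplets %>% distinct(from = .data$mirna_id, to = .data$mrna_id) %>%
      mutate(interaction = "targets")
  ) %>% arrange(.data$interaction, .data$from, .data$to)
}

triplets_to_nodes <- function(triplets) {
  bind_rows(
    tibble(id = unique(triplets$lncrna_id), type = "lncRNA"),
    tibble(id = unique(triplets$mirna_id), type = "miRNA"),
    tibble(id = unique(triplets$mrna_id), type = "mRNA")
  ) %>% arrange(.data$type, .data$id)
}

#' Export a ceRNA network as SIF and GraphML
#'
#' Writes the bipartite-style edge structure (lncRNA-miRNA and miRNA-mRNA)
#' with a node attribute `type` in {lncRNA, miRNA, mRNA}. An empty triplet
#' table yields valid empty files.
#'
#' @param triplets A `cerna_triplets` tibble.
#' @param path_prefix Output prefix; writes `<prefix>.sif` and
#'   `<prefix>.graphml`.
#' @return Invisibly, a list with `nodes` and `edges` tibbles.
#' @export
export_cerna_network <- function(triplets, path_prefix) {
  edges <- triplets_to_edges(triplets)
  nodes <- triplets_to_nodes(triplets)
  sif_path <- paste0(path_prefix, ".sif")
  graphml_path <- paste0(path_prefix, ".graphml")
  readr::write_lines(
    sprintf("%s\t%s\t%s", edges$from, edges$interaction, edges$to),
    sif_path
  )
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges) > 0) edges[, c("from", "to", "interaction")] else
      data.frame(from = character(), to = character(), interaction = character()),
    directed = TRUE,
    vertices = if (nrow(nodes) > 0) as.data.frame(nodes) else
      data.frame(id = character(), type = character())
  )
  igraph::write_graph(g, graphml_path, format = "graphml")
  cf_log("export_network", "%d nodes (%s), %d edges -> %s / %s",
         nrow(nodes), paste(table(nodes$type), collapse = "/"), nrow(edges),
         sif_path, graphml_path)
  invisible(list(nodes = nodes, edges = edges))
}

#' One-row summary of a triplet table
#'
#' @param x A `cerna_triplets` tibble.
#' @param ... Unused.
#' @return Tibble with `n_triplets`, `n_lncrna`, `n_mirna`, `n_mrna`.
#' @export
glance.cerna_triplets <- function(x, ...) {
  tibble(
    n_triplets = nrow(x),
    n_lncrna = n_distinct(x$lncrna_id),
    n_mirna = n_distinct(x$mirna_id),
    n_mrna = n_distinct(x$mrna_id)
  )
}
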