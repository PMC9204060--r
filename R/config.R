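# Pipeline configuration: one document, one section per module. Thresholds
# default to the study's printed constants and are validated against their
# legal ranges at construction time.

#' Build a validated pipeline configuration
#'
#' Returns the nested configuration list driving [run_cerna_pipeline()]. All
#' defaults are the analysis constants of the underlying study design: FDR
#' 0.05 with |log2FC| >= 1 for mRNA/lncRNA differential expression, miRNA
#' p-value 0.05 (a 0.07 variant exists in the literature and can be set),
#' Spearman threshold -0.7 for miRNA-target pairs, Pearson threshold 0.9 for
#' lncRNA-mRNA pairs, soft-threshold power 8 with unsigned TOM, module merge
#' cut height 0.85, minimum module size 50, and duplex energy-ratio cutoffs
#' of 0.74 (ruleset A) and 0.60 (ruleset B).
#'
#' @param ... Named overrides, e.g. `de = list(alpha = 0.01)`. Unknown keys
#'   or out-of-range values raise an error.
#' @return A named list of sections with class `cerna_config`.
#' @export
cerna_config <- function(...) {
  cfg <- list(
    seed = 1L,
    de = list(alpha = 0.05, lfc_cutoff = 1, p_mirna = 0.05, pseudocount = 1),
    lncrna = list(min_length = 200L, bidir_window = 1000L, cis_window = 10000L),
    smallrna = list(min_len = 18L, max_len = 30L, min_overlap = 6L,
                    polya_min = 8L, low_quality_q = 20L, low_quality_frac = 0.5),
    targets = list(ruleset = "A", mfe_ratio_a = 0.74, mfe_ratio_b = 0.60,
                   gu_positional = TRUE,
                   energy = list(GC = -3, AU = -2, GU = -1, MM = 0)),
    modules = list(beta = 8, drop_fraction = 0.45, min_size = 50L,
                   merge_cut = 0.85, cut_height = 0.95),
    cerna = list(scc_threshold = -0.7, pcc_threshold = 0.9,
                 require_lnc_in_module = FALSE),
    enrich = list(alpha = 0.05)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) abort(paste0("unknown config section/key: ", nm))
    if (is.list(cfg[[nm]])) {
      sub <- overrides[[nm]]
      bad <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(bad) > 0) abort(paste0("unknown key(s) in '", nm, "': ",
                                        paste(bad, collapse = ", ")))
      cfg[[nm]][names(sub)] <- sub
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  in_range <- function(x, lo, hi, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      abort(sprintf("config: %s must be a number in [%s, %s]", what, lo, hi))
    }
  }
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    abort("config: seed must be an integer")
  }
  in_range(cfg$de$alpha, 0, 1, "de$alpha")
  in_range(cfg$de$p_mirna, 0, 1, "de$p_mirna")
  in_range(cfg$de$lfc_cutoff, 0, Inf, "de$lfc_cutoff")
  in_range(cfg$lncrna$min_length, 1, Inf, "lncrna$min_length")
  in_range(cfg$lncrna$cis_window, 0, Inf, "lncrna$cis_window")
  in_range(cfg$modules$beta, 1, Inf, "modules$beta")
  in_range(cfg$modules$drop_fraction, 0, 1 - 1e-12, "modules$drop_fraction")
  in_range(cfg$modules$merge_cut, 0, 2, "modules$merge_cut")
  in_range(cfg$cerna$scc_threshold, -1, 0, "cerna$scc_threshold")
  in_range(cfg$cerna$pcc_threshold, 0, 1, "cerna$pcc_threshold")
  in_range(cfg$targets$mfe_ratio_a, 0, 1, "targets$mfe_ratio_a")
  in_range(cfg$targets$mfe_ratio_b, 0, 1, "targets$mfe_ratio_b")
  if (!cfg$targets$ruleset %in% c("A", "B")) abort("config: targets$ruleset must be 'A' or 'B'")
  structure(cfg, class = "cerna_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds one section per module mirroring [cerna_config()]; values
#' given in the file override the defaults, and anything passed through `...`
#' overrides the file in turn (the precedence used for command-style runs).
#'
#' @param path Path to a YAML configuration file.
#' @param ... Final overrides, as in [cerna_config()].
#' @return A validated `cerna_config` list.
#' @export
read_config <- function(path, ...) {
  file_cfg <- yaml::read_yaml(path) %||% list()
  cfg <- do.call(cerna_config, file_cfg)
  overrides <- list(...)
  if (length(overrides) > 0) {
    merged <- unclass(cfg)
    for (nm in names(overrides)) {
      if (is.list(merged[[nm]])) {
        merged[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else {
        merged[[nm]] <- overrides[[nm]]
      }
    }
    cfg <- do.call(cerna_config, merged[names(merged) != "class"])
  }
  cfg
}
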