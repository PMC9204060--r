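# Weighted co-expression module detection: variance pre-filter,
# soft-threshold adjacency, unsigned topological overlap, average-linkage
# clustering with a static cut, eigengene-based module merging, and
# module-trait association.
#
# The TOM is the standard unsigned topological overlap
#   TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),
# with k_i = sum_{u != i} a_iu and TOM_ii = 1. Clustering uses a static cut
# at a fixed dissimilarity height (uncorrelated genes sit near 1 - TOM = 1,
# so a cut just below that isolates genuine topological structure and is
# deterministic across instance sizes); clusters below the minimum size are
# pooled into the reserved "grey" label, and modules whose eigengenes are
# closer than the merge cut height (dissimilarity 1 - cor) are merged
# iteratively.

MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

#' Drop the lowest-variance genes before network construction
#'
#' Removes the `drop_fraction` lowest-variance features (variance taken on
#' the log2(x+1) scale), with a deterministic tie-break by feature id.
#' Dropping 45% of 100 genes retains exactly 55.
#'
#' @param expr Wide abundance tibble.
#' @param drop_fraction Fraction of genes to remove, in `[0, 1)` (default 0.45).
#' @return The filtered wide tibble (original row order preserved).
#' @export
variance_prefilter <- function(expr, drop_fraction = 0.45) {
  if (drop_fraction < 0 || drop_fraction >= 1) abort("drop_fraction must be in [0, 1)")
  m <- expr_to_matrix(expr)
  v <- apply(log2(m + 1), 1, var)
  if (all(v == 0)) abort("all features are constant; nothing to rank")
  n_drop <- floor(drop_fraction * nrow(m))
  ord <- order(v, rownames(m))          # ties broken by id
  drop_ids <- rownames(m)[ord][seq_len(n_drop)] %0% character(0)
  keep <- !(expr[[1]] %in% drop_ids)
  cf_log("variance_prefilter", "%d features in, drop_fraction=%.2f: %d retained",
         nrow(m), drop_fraction, sum(keep))
  expr[keep, , drop = FALSE]
}

#' Soft-threshold (unsigned) adjacency matrix
#'
#' `a_ij = |pearson(x_i, x_j)|^beta` with unit diagonal. Constant features
#' are excluded with a warning (their correlation is undefined).
#'
#' @param expr Wide abundance tibble (features x samples, >= 3 samples).
#' @param beta Soft-threshold power (default 8).
#' @param log2_transform Correlate on the log2(x+1) scale? Default `TRUE`.
#' @return A symmetric gene x gene matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(expr, beta = 8, log2_transform = TRUE) {
  if (beta < 1) abort("beta must be >= 1")
  m <- expr_to_matrix(expr)
  if (ncol(m) < 3) abort("need at least 3 samples")
  if (log2_transform) m <- log2(m + 1)
  constant <- apply(m, 1, sd) == 0
  if (any(constant)) {
    warn(paste0("excluding ", sum(constant), " constant feature(s) from the network"))
    m <- m[!constant, , drop = FALSE]
  }
  r <- cor(t(m))
  a <- abs(r)^beta
  diag(a) <- 1
  a
}

#' Unsigned topological overlap matrix
#'
#' @param adjacency Symmetric adjacency with unit diagonal, entries in `[0,1]`.
#' @return The TOM (same shape), with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) abort("adjacency must be square")
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a            # sum_{u != i,j} a_iu a_uj, off-diagonal
  num <- shared + a                    # plus the direct edge a_ij
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module eigengene (first principal component of member expression)
#'
#' Member features are standardised across samples; the eigengene is the
#' first left singular vector of the samples x features matrix, oriented so
#' that its correlation with the mean member profile is non-negative (the
#' PCA sign is otherwise arbitrary).
#'
#' @param expr Wide abundance tibble.
#' @param members Feature ids of the module.
#' @param log2_transform Standardise on the log2(x+1) scale? Default `TRUE`.
#' @return A named per-sample numeric vector (unit norm).
#' @export
module_eigengene <- function(expr, members, log2_transform = TRUE) {
  m <- expr_to_matrix(expr)[members, , drop = FALSE]
  if (log2_transform) m <- log2(m + 1)
  sds <- apply(m, 1, sd)
  m <- m[sds > 0, , drop = FALSE]
  if (nrow(m) == 0) abort("module has no non-constant members")
  z <- t(scale(t(m)))                  # standardise each feature
  sv <- svd(t(z))                      # samples x features
  me <- sv$u[, 1]
  avg <- rowMeans(t(z))
  if (sd(avg) > 0 && cor(me, avg) < 0) me <- -me
  setNames(me, colnames(m))
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`, a
#' static cut at `cut_height`, pooling of clusters smaller than `min_size`
#' into `"grey"`, then iterative merging of module pairs whose eigengene
#' dissimilarity `1 - cor(ME_i, ME_j)` falls below `merge_cut`. Modules are
#' labelled by size rank with conventional colour names (largest =
#' `"turquoise"`); detection is invariant to the gene order of the input.
#'
#' @param tom TOM from [tom_similarity()] (dimnames = feature ids).
#' @param expr Wide abundance tibble covering the TOM's features (used for
#'   eigengenes).
#' @param min_size Minimum module size (default 50).
#' @param merge_cut Eigengene dissimilarity below which modules merge
#'   (default 0.85).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.95).
#' @return An object of class `coexpr_fit`: a list with `membership`
#'   (tibble `feature_id`, `module`), `eigengenes` (tibble `sample` +
#'   one column per module), `sizes`, and `params`.
#' @export
detect_modules <- function(tom, expr, min_size = 50, merge_cut = 0.85,
                           cut_height = 0.95) {
  genes <- rownames(tom)
  if (is.null(genes)) abort("TOM must carry feature ids as dimnames")
  if (length(genes) < min_size) {
    warn("fewer features than min_size; everything is grey")
    labels <- setNames(rep("grey", length(genes)), genes)
    return(new_coexpr_fit(labels, expr, min_size, merge_cut, cut_height))
  }
  ord <- order(genes)                   # gene-order invariance
  tom <- tom[ord, ord]
  genes <- genes[ord]
  tree <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  labels <- ifelse(cl %in% as.integer(big), paste0("cl", cl), "grey")
  names(labels) <- genes

  # iterative eigengene merging
  n_samp <- ncol(expr) - 1L
  repeat {
    mods <- sort(setdiff(unique(labels), "grey"))
    if (length(mods) < 2) break
    me <- vapply(mods, function(mod) {
      unname(module_eigengene(expr, names(labels)[labels == mod]))
    }, numeric(n_samp))
    d <- 1 - cor(me)
    diag(d) <- Inf
    min_d <- min(d)
    if (min_d >= merge_cut) break
    idx <- which(d == min_d, arr.ind = TRUE)[1, ]
    pair <- sort(c(mods[idx[1]], mods[idx[2]]))
    labels[labels == pair[2]] <- pair[1]
  }
  new_coexpr_fit(labels, expr, min_size, merge_cut, cut_height)
}

new_coexpr_fit <- function(labels, expr, min_size, merge_cut, cut_height) {
  mods <- setdiff(unique(labels), "grey")
  # rank modules by size (desc), tie-break by first member id, then colour
  if (length(mods) > 0) {
    info <- tibble(
      old = mods,
      size = vapply(mods, function(m) sum(labels == m), integer(1)),
      first_gene = vapply(mods, function(m) min(names(labels)[labels == m]), character(1))
    ) %>% arrange(desc(.data$size), .data$first_gene)
    new_names <- c(MODULE_COLORS, paste0("module", seq_len(max(0, nrow(info) - length(MODULE_COLORS)))))
    remap <- setNames(new_names[seq_len(nrow(info))], info$old)
    labels[labels != "grey"] <- remap[labels[labels != "grey"]]
  }
  membership <- tibble(feature_id = names(labels), module = unname(labels)) %>%
    arrange(.data$feature_id)
  mods <- setdiff(unique(membership$module), "grey")
  eigengenes <- NULL
  if (length(mods) > 0) {
    me_list <- lapply(mods, function(m) {
      module_eigengene(expr, membership$feature_id[membership$module == m])
    })
    eigengenes <- bind_cols(
      tibble(sample = names(me_list[[1]])),
      as_tibble(setNames(lapply(me_list, unname), mods))
    )
  } else {
    eigengenes <- tibble(sample = colnames(expr)[-1])
  }
  sizes <- membership %>% count(.data$module, name = "size") %>% arrange(desc(.data$size))
  cf_log("detect_modules",
         "min_size=%d merge_cut=%.2f cut_height=%.2f: %d modules (+%d grey genes)",
         as.integer(min_size), merge_cut, cut_height, length(mods),
         sum(membership$module == "grey"))
  structure(
    list(membership = membership, eigengenes = eigengenes, sizes = sizes,
         params = list(min_size = min_size, merge_cut = merge_cut,
                       cut_height = cut_height)),
    class = "coexpr_fit"
  )
}

#' @export
print.coexpr_fit <- function(x, ...) {
  cat("Co-expression module fit:", nrow(x$sizes), "label(s)\n")
  print(x$sizes, n = 12)
  invisible(x)
}

#' Tidy a co-expression fit into its gene-module map
#'
#' @param x A `coexpr_fit`.
#' @param ... Unused.
#' @return Tibble with columns `feature_id`, `module`.
#' @export
tidy.coexpr_fit <- function(x, ...) x$membership

#' One-row summary of a co-expression fit
#'
#' @param x A `coexpr_fit`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_modules`, `n_grey`, `largest_module`.
#' @export
glance.coexpr_fit <- function(x, ...) {
  mods <- filter(x$sizes, .data$module != "grey")
  tibble(
    n_features = nrow(x$membership),
    n_modules = nrow(mods),
    n_grey = sum(x$membership$module == "grey"),
    largest_module = if (nrow(mods) > 0) mods$module[1] else NA_character_
  )
}

#' Module-trait association table
#'
#' Correlates each module eigengene with indicator traits derived from the
#' sample metadata: one indicator per (genotype, leaf) group, one per leaf
#' position, and the mutant-genotype indicator. The p-value uses the
#' t-approximation for a Pearson correlation. Constant traits give the
#' undefined marker `NA`.
#'
#' @param fit A `coexpr_fit`.
#' @param samples Sample metadata tibble (`sample`, `genotype`, `leaf`).
#' @return Tibble with columns `module`, `trait`, `r`, `p`.
#' @export
module_trait <- function(fit, samples) {
  eg <- fit$eigengenes
  mods <- setdiff(names(eg), "sample")
  if (length(mods) == 0) {
    return(tibble(module = character(), trait = character(),
                  r = numeric(), p = numeric()))
  }
  meta <- samples[match(eg$sample, samples$sample), ]
  traits <- list(mutant = as.numeric(meta$genotype == "mutant"))
  for (l in unique(meta$leaf)) {
    traits[[paste0("leaf_", l)]] <- as.numeric(meta$leaf == l)
  }
  for (g in unique(meta$genotype)) {
    for (l in unique(meta$leaf)) {
      traits[[paste0(g, "_", l)]] <- as.numeric(meta$genotype == g & meta$leaf == l)
    }
  }
  n <- nrow(eg)
  rows <- list()
  for (m in mods) {
    for (tr in names(traits)) {
      x <- eg[[m]]
      y <- traits[[tr]]
      if (sd(y) == 0 || sd(x) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- cor(x, y)
        tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
        p <- 2 * pt(-abs(tt), n - 2)
      }
      rows[[length(rows) + 1]] <- tibble(module = m, trait = tr, r = r, p = p)
    }
  }
  bind_rows(rows)
}

#' Full module-detection pipeline from an abundance matrix
#'
#' Variance pre-filter, soft adjacency, TOM, and [detect_modules()] in one
#' call — the module-detection stage used by [run_cerna_pipeline()].
#'
#' @param expr Wide abundance tibble.
#' @param beta Soft-threshold power (default 8).
#' @param drop_fraction Variance pre-filter fraction (default 0.45).
#' @inheritParams detect_modules
#' @return A `coexpr_fit` (see [detect_modules()]).
#' @export
detect_coexpr_modules <- function(expr, beta = 8, drop_fraction = 0.45,
                                  min_size = 50, merge_cut = 0.85,
                                  cut_height = 0.95) {
  kept <- variance_prefilter(expr, drop_fraction)
  adj <- soft_adjacency(kept, beta = beta)
  kept <- kept[kept[[1]] %in% rownames(adj), , drop = FALSE]
  tom <- tom_similarity(adj)
  detect_modules(tom, kept, min_size = min_size, merge_cut = merge_cut,
                 cut_height = cut_height)
}
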