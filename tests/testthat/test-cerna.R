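# small helper: wide tibble from named list of per-sample profiles
profiles <- function(lst, samples = paste0("s", seq_along(lst[[1]]))) {
  m <- do.call(rbind, lst)
  dimnames(m) <- list(names(lst), samples)
  make_expr(m)
}

test_that("pair filtering enforces prediction, DE status and strict SCC", {
  n <- 10
  withr::with_seed(71, {
    z <- rnorm(n)
    e_mir <- profiles(list(m1 = 2^(5 - z), m2 = 2^rnorm(n, 5)))
    e_tgt <- profiles(list(g1 = 2^(6 + z), g2 = 2^(6 + z), g3 = 2^rnorm(n, 6)))
  })
  hits <- tibble::tibble(mirna_id = c("m1", "m1", "m1", "m2"),
                         transcript_id = c("g1", "g2", "g3", "g1"))
  # g2 is predicted and anticorrelated but not DE; g3 is DE but uncorrelated
  pairs <- filter_target_pairs(hits, e_mir, e_tgt,
                               de_mirna = c("m1", "m2"),
                               de_target = c("g1", "g3"))
  expect_equal(pairs$target_id, "g1")
  expect_equal(pairs$mirna_id, "m1")
  expect_lt(pairs$scc, -0.7)
})

test_that("the SCC threshold is strict: a correlation of exactly -0.7 is dropped", {
  # permutation (5,4,1,3,2) of ranks 1..5 gives rho = 1 - 6*34/120 = -0.7
  e_mir <- profiles(list(m1 = c(1, 2, 3, 4, 5)), paste0("s", 1:5))
  e_tgt <- profiles(list(g1 = c(5, 4, 1, 3, 2)), paste0("s", 1:5))
  hits <- tibble::tibble(mirna_id = "m1", transcript_id = "g1")
  expect_equal(cor_spearman(c(1, 2, 3, 4, 5), c(5, 4, 1, 3, 2)), -0.7)
  pairs <- filter_target_pairs(hits, e_mir, e_tgt, "m1", "g1")
  expect_equal(nrow(pairs), 0L)
  # -0.5 is likewise dropped; a steeper anticorrelation passes
  e_tgt2 <- profiles(list(g1 = c(5, 4, 3, 2, 1)), paste0("s", 1:5))
  expect_equal(nrow(filter_target_pairs(hits, e_mir, e_tgt2, "m1", "g1")), 1L)
})

test_that("undefined correlations are treated as failing the threshold", {
  e_mir <- profiles(list(m1 = rep(3, 6)))
  e_tgt <- profiles(list(g1 = 2^rnorm(6)))
  hits <- tibble::tibble(mirna_id = "m1", transcript_id = "g1")
  expect_equal(nrow(filter_target_pairs(hits, e_mir, e_tgt, "m1", "g1")), 0L)
})

test_that("triplets require a shared miRNA and strict PCC", {
  n <- 12
  withr::with_seed(73, {
    z <- rnorm(n)
    e_lnc <- profiles(list(L1 = 2^(5 + z), L2 = 2^rnorm(n, 5)))
    e_mrna <- profiles(list(G1 = 2^(6 + z), G2 = 2^(6 + rnorm(n))))
  })
  pm <- tibble::tibble(mirna_id = c("mA", "mB"), target_id = c("G1", "G2"),
                       scc = c(-0.9, -0.9))
  pl <- tibble::tibble(mirna_id = c("mA", "mC"), target_id = c("L1", "L2"),
                       scc = c(-0.9, -0.9))
  tr <- assemble_triplets(pm, pl, e_lnc, e_mrna)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$mirna_id, "mA")      # mB/mC do not share partners
  expect_gt(tr$pcc_lnc_mrna, 0.9)

  # same pair lists but no shared miRNA at all -> no triplet
  pl2 <- dplyr::mutate(pl, mirna_id = c("mX", "mC"))
  expect_equal(nrow(assemble_triplets(pm, pl2, e_lnc, e_mrna)), 0L)
})

test_that("module intersection applies to the mRNA (and optionally the lncRNA)", {
  n <- 12
  withr::with_seed(74, {
    z <- rnorm(n)
    e_lnc <- profiles(list(L1 = 2^(5 + z)))
    e_mrna <- profiles(list(G1 = 2^(6 + z)))
  })
  pm <- tibble::tibble(mirna_id = "mA", target_id = "G1", scc = -0.9)
  pl <- tibble::tibble(mirna_id = "mA", target_id = "L1", scc = -0.9)
  in_mod <- assemble_triplets(pm, pl, e_lnc, e_mrna, module_genes = c("G1"))
  expect_equal(nrow(in_mod), 1L)
  out_mod <- assemble_triplets(pm, pl, e_lnc, e_mrna, module_genes = c("other"))
  expect_equal(nrow(out_mod), 0L)
  lnc_req <- assemble_triplets(pm, pl, e_lnc, e_mrna, module_genes = c("G1"),
                               require_lnc_in_module = TRUE)
  expect_equal(nrow(lnc_req), 0L)
})

test_that("assembly equals a brute-force triple loop on a random toy instance", {
  n_l <- 20; n_m <- 5; n_g <- 20; n_s <- 10
  withr::with_seed(77, {
    lat <- replicate(n_m, rnorm(n_s), simplify = FALSE)
    e_lnc <- profiles(setNames(lapply(1:n_l, function(i) {
      k <- ((i - 1) %% n_m) + 1
      2^(5 + 0.9 * lat[[k]] + rnorm(n_s, 0, 0.4))
    }), paste0("L", 1:n_l)))
    e_mrna <- profiles(setNames(lapply(1:n_g, function(i) {
      k <- ((i - 1) %% n_m) + 1
      2^(6 + 0.9 * lat[[k]] + rnorm(n_s, 0, 0.4))
    }), paste0("G", 1:n_g)))
    e_mir <- profiles(setNames(lapply(1:n_m, function(k) 2^(4 - lat[[k]])),
                               paste0("m", 1:n_m)))
    pm <- tidyr::expand_grid(mirna_id = paste0("m", 1:n_m),
                             target_id = paste0("G", sample(n_g, 12)))
    pl <- tidyr::expand_grid(mirna_id = paste0("m", 1:n_m),
                             target_id = paste0("L", sample(n_l, 12)))
  })
  mm <- as.matrix(e_mir[, -1]); rownames(mm) <- e_mir[[1]]
  scc_of <- function(mir, tgt, e) {
    tm <- as.matrix(e[, -1]); rownames(tm) <- e[[1]]
    cor(mm[mir, ], tm[tgt, ], method = "spearman")
  }
  pm$scc <- mapply(scc_of, pm$mirna_id, pm$target_id, MoreArgs = list(e = e_mrna))
  pl$scc <- mapply(scc_of, pl$mirna_id, pl$target_id, MoreArgs = list(e = e_lnc))
  pm <- pm[pm$scc < -0.7, ]
  pl <- pl[pl$scc < -0.7, ]

  got <- assemble_triplets(pm, pl, e_lnc, e_mrna, pcc_threshold = 0.8)

  lm <- as.matrix(e_lnc[, -1]); rownames(lm) <- e_lnc[[1]]
  gm <- as.matrix(e_mrna[, -1]); rownames(gm) <- e_mrna[[1]]
  brute <- list()
  for (i in seq_len(nrow(pl))) {
    for (j in seq_len(nrow(pm))) {
      if (pl$mirna_id[i] != pm$mirna_id[j]) next
      pcc <- cor(lm[pl$target_id[i], ], gm[pm$target_id[j], ])
      if (pcc > 0.8) {
        brute[[length(brute) + 1]] <- paste(pl$target_id[i], pl$mirna_id[i],
                                            pm$target_id[j])
      }
    }
  }
  expect_setequal(paste(got$lncrna_id, got$mirna_id, got$mrna_id),
                  unlist(brute))

  # relaxing both thresholds never removes a triplet
  relaxed <- assemble_triplets(pm, pl, e_lnc, e_mrna, pcc_threshold = 0.5)
  expect_true(all(paste(got$lncrna_id, got$mirna_id, got$mrna_id) %in%
                    paste(relaxed$lncrna_id, relaxed$mirna_id, relaxed$mrna_id)))

  # self-audit accepts the emitted set at its thresholds
  expect_true(verify_triplets(got, e_lnc, e_mir, e_mrna,
                              scc_threshold = -0.7, pcc_threshold = 0.8))
})

test_that("network export writes consistent SIF and GraphML", {
  tr <- structure(
    tibble::tibble(lncrna_id = "L1", mirna_id = "m1", mrna_id = "G1",
                   scc_mirna_mrna = -0.9, scc_mirna_lnc = -0.85,
                   pcc_lnc_mrna = 0.95),
    class = c("cerna_triplets", class(tibble::tibble()))
  )
  prefix <- withr::local_tempfile()
  out <- export_cerna_network(tr, prefix)
  expect_equal(nrow(out$nodes), 3L)
  expect_equal(nrow(out$edges), 2L)
  sif <- readLines(paste0(prefix, ".sif"))
  expect_equal(length(sif), 2L)
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  expect_setequal(igraph::vertex_attr(g, "type"), c("lncRNA", "miRNA", "mRNA"))

  gl <- generics::glance(tr)
  expect_equal(gl$n_triplets, 1L)

  # empty network still produces valid files
  empty <- tr[0, ]
  out0 <- export_cerna_network(empty, prefix)
  expect_equal(nrow(out0$edges), 0L)
  g0 <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::gorder(g0), 0)
})
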