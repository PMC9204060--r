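test_that("generation is deterministic for a fixed seed", {
  a1 <- simulate_annotation(8, 6, seed = 5)
  a2 <- simulate_annotation(8, 6, seed = 5)
  expect_identical(a1, a2)

  e1 <- simulate_expression(seed = 7)
  e2 <- simulate_expression(seed = 7)
  expect_identical(e1, e2)
  e3 <- simulate_expression(seed = 8)
  expect_false(identical(e1$expr$mrna, e3$expr$mrna))

  m1 <- simulate_mirnas(10, seed = 3)
  m2 <- simulate_mirnas(10, seed = 3)
  expect_identical(m1, m2)

  lib1 <- simulate_smallrna_reads(m1, setNames(rep(5, 10), m1$id), seed = 4)
  lib2 <- simulate_smallrna_reads(m1, setNames(rep(5, 10), m1$id), seed = 4)
  expect_identical(lib1, lib2)
})

test_that("generator argument contracts hold", {
  expect_error(simulate_annotation(10, 4), "five positional classes")
  expect_error(simulate_expression(n_reps = 1), "2 replicates")
  expect_error(simulate_expression(de_lfc = 1), ">= 1.5")
  expect_error(simulate_expression(mrna_ids = paste0("g", 1:10)), "too few mRNA ids")
})

test_that("a planted fold change of +2 shows up as a ~4x mutant/wild mean ratio", {
  sim <- simulate_expression(n_de_mrna = 10, n_triplets = 0, n_decoy = 0,
                             module_sizes = c(0, 0), seed = 11)
  up_gene <- sim$truth$de$feature_id[sim$truth$de$class == "mRNA" &
                                       sim$truth$de$log2fc == 2][1]
  m <- as.matrix(sim$expr$mrna[, -1])
  rownames(m) <- sim$expr$mrna[[1]]
  mut <- sim$samples$sample[sim$samples$genotype == "mutant"]
  wld <- sim$samples$sample[sim$samples$genotype == "wild"]
  ratio <- mean(m[up_gene, mut]) / mean(m[up_gene, wld])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.4)
})

test_that("a null configuration gives the DE caller its nominal false-positive rate", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    sim <- simulate_de_matrix(n_null = 200, n_de = 0, seed = 100 + s)
    de <- call_de(sim$expr, sim$group_a, sim$group_b)
    hits <- hits + sum(de$p < 0.05)
    total <- total + nrow(de)
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
})

test_that("planted triplet correlations clear the network thresholds at seed 42", {
  study <- simulate_cerna_study("small", seed = 42, reads = FALSE)
  em <- as.matrix(study$expr$mirna[, -1]); rownames(em) <- study$expr$mirna[[1]]
  eg <- as.matrix(study$expr$mrna[, -1]); rownames(eg) <- study$expr$mrna[[1]]
  el <- as.matrix(study$expr$lnc[, -1]); rownames(el) <- study$expr$lnc[[1]]
  for (i in seq_len(nrow(study$truth$triplets))) {
    tr <- study$truth$triplets[i, ]
    expect_lt(cor_spearman(em[tr$mirna_id, ], eg[tr$mrna_id, ]), -0.7)
    expect_lt(cor_spearman(em[tr$mirna_id, ], el[tr$lncrna_id, ]), -0.7)
    expect_gt(cor_pearson(el[tr$lncrna_id, ], eg[tr$mrna_id, ]), 0.9)
  }
})

test_that("planted correlations hold across most generator runs at default noise", {
  ok <- 0; total <- 0
  for (s in 1:10) {
    sim <- simulate_expression(seed = 200 + s)
    em <- as.matrix(sim$expr$mirna[, -1]); rownames(em) <- sim$expr$mirna[[1]]
    eg <- as.matrix(sim$expr$mrna[, -1]); rownames(eg) <- sim$expr$mrna[[1]]
    el <- as.matrix(sim$expr$lnc[, -1]); rownames(el) <- sim$expr$lnc[[1]]
    for (i in seq_len(nrow(sim$truth$triplets))) {
      tr <- sim$truth$triplets[i, ]
      total <- total + 1
      if (cor_spearman(em[tr$mirna_id, ], eg[tr$mrna_id, ]) < -0.7 &&
          cor_spearman(em[tr$mirna_id, ], el[tr$lncrna_id, ]) < -0.7 &&
          cor_pearson(el[tr$lncrna_id, ], eg[tr$mrna_id, ]) > 0.9) {
        ok <- ok + 1
      }
    }
  }
  expect_gte(ok / total, 0.95)

  # non-planted pairs are centred on zero
  sim <- simulate_expression(seed = 300)
  eg <- as.matrix(sim$expr$mrna[, -1]); rownames(eg) <- sim$expr$mrna[[1]]
  null_ids <- setdiff(sim$expr$mrna[[1]],
                      c(sim$truth$de$feature_id, sim$truth$modules$feature_id,
                        sim$truth$triplets$mrna_id, sim$truth$decoy_triplets$mrna_id))
  withr::with_seed(301, {
    cors <- replicate(200, {
      p <- sample(null_ids, 2)
      cor(eg[p[1], ], eg[p[2], ])
    })
  })
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("planted sites are hits and plant/decoy labels agree with the oracle", {
  mirnas <- simulate_mirnas(8, seed = 21)
  tx <- tibble::tibble(
    id = paste0("t", 1:8),
    seq = withr::with_seed(22, vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
      character(1)))
  )
  plan <- tibble::tibble(
    mirna_id = mirnas$id,
    transcript_id = tx$id,
    type = c(rep("decoy", 6), "site", "site"),
    rule = c(mirnas$decoy_rule[1:6], NA, NA)
  )
  planted <- plant_binding_sites(mirnas, tx, plan, seed = 23)
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    mir <- mirnas$seq[mirnas$id == s$mirna_id]
    tx_seq <- planted$transcripts$seq[planted$transcripts$id == s$transcript_id]
    oracle_hits <- oracle_scan(mir, tx_seq, "A")
    if (s$type == "site") {
      expect_true(s$start %in% oracle_hits)
      got <- predict_targets(mirnas[mirnas$id == s$mirna_id, ],
                             planted$transcripts[planted$transcripts$id == s$transcript_id, ])
      expect_true(any(got$start == s$start & got$score == 0))
    } else {
      expect_false(s$start %in% oracle_hits)
    }
  }
  # too-short transcripts are refused
  expect_error(
    plant_binding_sites(mirnas[7, ], tibble::tibble(id = "short", seq = "ACGUACGUAC"),
                        tibble::tibble(mirna_id = mirnas$id[7],
                                       transcript_id = "short",
                                       type = "site", rule = NA)),
    "too short")
})

test_that("the study bundle is internally consistent", {
  study <- simulate_cerna_study("small", seed = 3, reads = FALSE)
  truth <- study$truth
  # every planted triplet member exists in the generated data
  expect_true(all(truth$triplets$mrna_id %in% study$expr$mrna[[1]]))
  expect_true(all(truth$triplets$lncrna_id %in% study$expr$lnc[[1]]))
  expect_true(all(truth$triplets$mirna_id %in% study$expr$mirna[[1]]))
  expect_true(all(truth$sites$transcript_id %in% study$transcripts$id))
  # every decoy names exactly one violated rule
  expect_true(all(truth$decoy_triplets$rule %in% paste0("r", 1:6)))
  expect_equal(anyDuplicated(truth$decoy_triplets$rule), 0L)
  # 18 libraries in the design
  expect_equal(nrow(study$samples), 18L)
  expect_equal(ncol(study$expr$mrna) - 1L, 18L)
})
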