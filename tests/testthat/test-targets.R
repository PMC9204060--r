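test_that("duplex alignment classifies pairs and scores wobbles at one half", {
  mir <- "GGGGGGGG"
  expect_equal(duplex_align(mir, reverse_complement_rna(mir))$states,
               rep("WC", 8))
  # every G across a U gives a wobble worth 0.5
  aln <- duplex_align(mir, "UUUUUUUU")
  expect_equal(aln$states, rep("GU", 8))
  expect_equal(aln$score, 4)
  expect_error(duplex_align("AC", "ACG"), "lengths differ")
})

test_that("an 8-nt toy duplex matches a position-by-position hand evaluation", {
  mir <- "AUGCGUAC"                       # positions 1..8 from the 5' end
  # window read 5'->3'; miRNA position i pairs window position 9-i
  win <- "GUACGCAU"
  # hand pairing: m1 A : w8 U -> WC; m2 U : w7 A -> WC; m3 G : w6 C -> WC;
  # m4 C : w5 G -> WC; m5 G : w4 C -> WC; m6 U : w3 A -> WC; m7 A : w2 U WC;
  # m8 C : w1 G WC
  expect_equal(duplex_align(mir, win)$states, rep("WC", 8))
  # flip window base pairing miRNA position 5 (w4: C -> U) -> G:U wobble,
  # and the base pairing position 2 (w7: A -> C) -> U:C mismatch
  win2 <- "GUAUGCCU"
  aln <- duplex_align(mir, win2)
  expect_equal(aln$states, c("WC", "MM", "WC", "WC", "GU", "WC", "WC", "WC"))
  expect_equal(aln$score, 1.5)
})

test_that("rule verdicts implement both printed variants", {
  mir <- strrep("G", 21)
  perfect <- duplex_align(mir, reverse_complement_rna(mir))
  vA <- evaluate_rules(perfect, "A")
  expect_true(vA$pass)
  expect_equal(vA$mfe_ratio, 1.0)

  # single mismatch at duplex position 10 fails r4 under both rulesets
  win10 <- make_decoy_window(mir, 10, "MM")
  v10a <- evaluate_rules(duplex_align(mir, win10), "A")
  v10b <- evaluate_rules(duplex_align(mir, win10), "B")
  expect_false(v10a$r4)
  expect_false(v10b$r4)
  expect_true(v10a$r1 && v10a$r2 && v10a$r5)

  # nine wobbles score 4.5 and break the four-mismatch budget
  mir_u <- strrep("U", 21)
  win9 <- make_decoy_window(mir_u, c(1, 3, 5, 7, 13, 15, 17, 19, 21), "GU")
  v9 <- evaluate_rules(duplex_align(mir_u, win9), "A")
  expect_equal(v9$score, 4.5)
  expect_false(v9$r1)

  # two adjacent mismatch events: legal under A (run of 2), illegal under B
  win2r <- make_decoy_window(mir_u, c(14, 15), "GU")
  expect_true(evaluate_rules(duplex_align(mir_u, win2r), "A")$r2)
  expect_false(evaluate_rules(duplex_align(mir_u, win2r), "B")$r2)
  # ...and any 5'-region mismatch at all is illegal under B
  win5p <- make_decoy_window(mir_u, 5, "GU")
  expect_true(evaluate_rules(duplex_align(mir_u, win5p), "A")$r3)
  expect_false(evaluate_rules(duplex_align(mir_u, win5p), "B")$r3)
})

test_that("additive energies and the ratio test follow the model constants", {
  mir10 <- strrep("G", 10)
  expect_equal(perfect_energy(mir10), -30)
  aln <- duplex_align(mir10, reverse_complement_rna(mir10))
  expect_equal(aln$energy, -30)
  expect_equal(aln$mfe_ratio, 1)
  # converting one G:C pair to a mismatch drops 3 units: ratio 27/30
  win <- make_decoy_window(mir10, 4, "MM")
  aln2 <- duplex_align(mir10, win)
  expect_equal(aln2$energy, -27)
  expect_equal(aln2$mfe_ratio, 0.9)
})

test_that("scanning finds a planted perfect site and nothing in poly-A noise", {
  withr::with_seed(31, {
    mir <- tibble::tibble(id = "m1", seq = rand_rna(21))
    tx_seq <- rand_rna(200)
  })
  site <- reverse_complement_rna(mir$seq)
  substr(tx_seq, 81, 101) <- site
  hits <- predict_targets(mir, tibble::tibble(id = "t1", seq = tx_seq))
  expect_true(any(hits$start == 80 & hits$score == 0))

  polya <- tibble::tibble(id = "t2", seq = strrep("A", 100))
  mir_a <- tibble::tibble(id = "ma", seq = strrep("A", 21))
  expect_equal(nrow(predict_targets(mir_a, polya)), 0L)

  expect_warning(
    out <- predict_targets(mir, tibble::tibble(id = "t3", seq = "ACGU")),
    "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("every generator decoy violates exactly its named rule and is never hit", {
  mirnas <- simulate_mirnas(6, seed = 17)       # six decoy carriers
  tx <- tibble::tibble(id = paste0("t", 1:6),
                       seq = withr::with_seed(18, vapply(1:6, function(i)
                         paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                               collapse = ""), character(1))))
  plan <- tibble::tibble(mirna_id = mirnas$id, transcript_id = tx$id,
                         type = "decoy", rule = mirnas$decoy_rule)
  planted <- plant_binding_sites(mirnas, tx, plan, seed = 19)
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    mir_seq <- mirnas$seq[mirnas$id == s$mirna_id]
    v <- site_verdict(mir_seq, planted$transcripts$seq[planted$transcripts$id == s$transcript_id],
                      s$start, ruleset = "A")
    expect_equal(v$violated, s$rule, info = s$rule)
    hits <- predict_targets(mirnas[mirnas$id == s$mirna_id, ],
                            planted$transcripts[planted$transcripts$id == s$transcript_id, ])
    expect_false(any(hits$start == s$start), info = s$rule)
  }
})

test_that("ruleset B hits are a subset of ruleset A hits at a common energy cutoff", {
  withr::with_seed(23, {
    mirnas <- tibble::tibble(id = paste0("m", 1:4),
                             seq = vapply(1:4, function(i) rand_rna(21), character(1)))
    tx <- tibble::tibble(id = paste0("t", 1:6),
                         seq = vapply(1:6, function(i) rand_rna(120), character(1)))
  })
  # seed sites so there is something to find: one perfect, one near-perfect
  for (k in 1:4) {
    substr(tx$seq[k], 10, 30) <- reverse_complement_rna(mirnas$seq[k])
  }
  hits_a <- predict_targets(mirnas, tx, ruleset = "A", mfe_ratio = 0.6)
  hits_b <- predict_targets(mirnas, tx, ruleset = "B", mfe_ratio = 0.6)
  key <- function(h) paste(h$mirna_id, h$transcript_id, h$start)
  expect_true(all(key(hits_b) %in% key(hits_a)))
})

test_that("the weighted score decomposes over the 5' region and the rest", {
  withr::with_seed(27, {
    for (i in 1:25) {
      mir <- rand_rna(21)
      win <- rand_rna(21)
      aln <- duplex_align(mir, win)
      sc <- ifelse(aln$states == "GU", 0.5, ifelse(aln$states == "MM", 1, 0))
      expect_equal(aln$score, sum(sc[1:12]) + sum(sc[13:21]))
    }
  })
})

test_that("scan_transcript agrees with the exhaustive window oracle", {
  withr::with_seed(29, {
    mirnas <- vapply(1:3, function(i) rand_rna(21), character(1))
    txs <- vapply(1:10, function(i) rand_rna(90), character(1))
  })
  # implant assorted sites: perfect, single wobble, near-miss
  substr(txs[1], 5, 25) <- reverse_complement_rna(mirnas[1])
  substr(txs[2], 40, 60) <- make_decoy_window(mirnas[2],
                                              first_wobble_pos(mirnas[2]), "GU")
  substr(txs[3], 20, 40) <- make_decoy_window(mirnas[3], 10, "MM")
  for (rs in c("A", "B")) {
    for (m in seq_along(mirnas)) {
      for (t in seq_along(txs)) {
        got <- scan_transcript(list(id = "m", seq = mirnas[m]),
                               list(id = "t", seq = txs[t]), ruleset = rs)
        expect_equal(got$start, oracle_scan(mirnas[m], txs[t], rs),
                     info = paste(rs, m, t))
      }
    }
  }
})
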