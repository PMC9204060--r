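test_that("variance pre-filter keeps the stated fraction with a deterministic ranking", {
  withr::with_seed(41, {
    m <- matrix(2^rnorm(100 * 6, 6, sd = rep(runif(100, 0.05, 1), 6)), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  })
  expr <- make_expr(m)
  expect_equal(variance_prefilter(expr, 0), expr)
  kept <- variance_prefilter(expr, 0.45)
  expect_equal(nrow(kept), 55L)
  v <- apply(log2(m + 1), 1, var)
  brute <- names(sort(v, decreasing = TRUE))[1:55]
  expect_setequal(kept$feature_id, brute)
  expect_error(variance_prefilter(make_expr(matrix(1, 4, 4)), 0.5), "constant")
  expect_error(variance_prefilter(expr, 1), "drop_fraction")
})

test_that("soft adjacency is the beta-power of absolute correlation", {
  withr::with_seed(43, {
    m <- matrix(2^rnorm(50 * 10, 6), 50, 10,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  })
  a <- soft_adjacency(make_expr(m), beta = 8)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(unname(diag(a)), rep(1, 50))
  r <- cor(t(log2(m + 1)))
  expect_equal(a[2, 7], abs(r[2, 7])^8, tolerance = 1e-12)
  expect_equal(0.5^8, 0.00390625)   # the arithmetic the power rule implies

  # a perfectly correlated pair keeps adjacency 1 at any power
  m2 <- rbind(x = 2^(1:6), y = 2^(1:6))
  colnames(m2) <- paste0("s", 1:6)
  a2 <- suppressWarnings(soft_adjacency(make_expr(m2), beta = 12,
                                        log2_transform = FALSE))
  expect_equal(a2["x", "y"], 1)
})

test_that("TOM matches hand arithmetic on toys and the triple-loop oracle", {
  a2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(tom_similarity(a2)["a", "b"], 1)

  a3 <- matrix(0.5, 3, 3)
  diag(a3) <- 1
  dimnames(a3) <- list(letters[1:3], letters[1:3])
  # (0.25 + 0.5) / (min(1,1) + 1 - 0.5) = 0.5
  expect_equal(tom_similarity(a3)["a", "b"], 0.5)

  withr::with_seed(47, {
    r <- cor(matrix(rnorm(30 * 12), 12, 30))
    a <- abs(r)^6
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:30), paste0("g", 1:30))
  })
  expect_equal(tom_similarity(a), oracle_tom(a), tolerance = 1e-12)
})

test_that("the eigengene of a coherent module tracks every member", {
  withr::with_seed(53, {
    base <- rnorm(12)
    m <- t(vapply(1:8, function(i) 2^(6 + base + rnorm(12, 0, 1e-6)),
                  numeric(12)))
    dimnames(m) <- list(paste0("g", 1:8), paste0("s", 1:12))
  })
  expr <- make_expr(m)
  me <- module_eigengene(expr, paste0("g", 1:8))
  for (i in 1:8) {
    expect_equal(abs(cor(me, log2(m[i, ] + 1))), 1, tolerance = 1e-6)
  }
  # sign convention: positively oriented to the mean member profile
  expect_gt(cor(me, rowMeans(scale(t(log2(m + 1))))), 0)
})

test_that("two planted blocks are recovered and background stays grey", {
  sim <- simulate_expression(
    mrna_ids = sprintf("g%03d", 1:180), lnc_ids = sprintf("l%02d", 1:10),
    n_de_mrna = 0, n_de_lnc = 0, n_de_mirna = 0, n_triplets = 0, n_decoy = 0,
    module_sizes = c(60, 60), seed = 57
  )
  fit <- detect_coexpr_modules(sim$expr$mrna, drop_fraction = 0)
  truth <- sim$truth$modules
  memb <- fit$membership
  mods <- setdiff(unique(memb$module), "grey")
  expect_equal(length(mods), 2L)
  for (mod in c("module1", "module2")) {
    planted <- truth$feature_id[truth$module == mod]
    detected <- memb$module[memb$feature_id %in% planted]
    top <- names(sort(table(detected), decreasing = TRUE))[1]
    expect_gte(mean(detected == top), 0.95)
  }
  # average linkage absorbs a few background genes into block clusters;
  # the large majority must stay grey
  null_genes <- setdiff(memb$feature_id, truth$feature_id)
  expect_gte(mean(memb$module[memb$feature_id %in% null_genes] == "grey"), 0.8)
})

test_that("module detection is invariant to gene order and respects min_size", {
  sim <- simulate_expression(
    mrna_ids = sprintf("g%03d", 1:150), lnc_ids = sprintf("l%02d", 1:10),
    n_de_mrna = 0, n_de_lnc = 0, n_de_mirna = 0, n_triplets = 0, n_decoy = 0,
    module_sizes = c(60, 60), seed = 59
  )
  expr <- sim$expr$mrna
  adj <- soft_adjacency(expr, beta = 8)
  tom <- tom_similarity(adj)
  fit1 <- detect_modules(tom, expr)
  perm <- withr::with_seed(60, sample(nrow(expr)))
  fit2 <- detect_modules(tom[perm, perm], expr[perm, ])
  expect_equal(fit2$membership, fit1$membership)

  expect_warning(all_grey <- detect_modules(tom, expr, min_size = 1000), "grey")
  expect_true(all(all_grey$membership$module == "grey"))

  expect_warning(
    tiny <- detect_modules(tom[1:5, 1:5], expr[1:5, ], min_size = 50),
    "grey")
  expect_true(all(tiny$membership$module == "grey"))
})

test_that("module-trait association recovers the planted phenotype link", {
  sim <- simulate_expression(
    mrna_ids = sprintf("g%03d", 1:160), lnc_ids = sprintf("l%02d", 1:10),
    n_de_mrna = 0, n_de_lnc = 0, n_de_mirna = 0, n_triplets = 0, n_decoy = 0,
    module_sizes = c(60, 60), seed = 61
  )
  fit <- detect_coexpr_modules(sim$expr$mrna, drop_fraction = 0)
  trait <- module_trait(fit, sim$samples)
  expect_true(all(abs(trait$r[!is.na(trait$r)]) <= 1))
  # module1 genes are high only in mutant second/third leaves: its module's
  # top trait must be the mutant genotype or one of those two groups
  m1_genes <- sim$truth$modules$feature_id[sim$truth$modules$module == "module1"]
  memb <- fit$membership
  mod_label <- names(sort(table(memb$module[memb$feature_id %in% m1_genes]),
                          decreasing = TRUE))[1]
  tr_mod <- trait[trait$module == mod_label & !is.na(trait$r), ]
  top_trait <- tr_mod$trait[which.max(tr_mod$r)]
  expect_true(top_trait %in% c("mutant", "mutant_second", "mutant_third"))
})

test_that("tidy and glance summarise a fit", {
  sim <- simulate_expression(
    mrna_ids = sprintf("g%03d", 1:140), lnc_ids = sprintf("l%02d", 1:10),
    n_de_mrna = 0, n_de_lnc = 0, n_de_mirna = 0, n_triplets = 0, n_decoy = 0,
    module_sizes = c(60, 60), seed = 63
  )
  fit <- detect_coexpr_modules(sim$expr$mrna, drop_fraction = 0)
  td <- generics::tidy(fit)
  expect_equal(names(td), c("feature_id", "module"))
  expect_equal(nrow(td), 140L)
  gl <- generics::glance(fit)
  expect_equal(gl$n_features, 140L)
  expect_gte(gl$n_modules, 2L)
})
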