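test_that("genotype simulation is seed-deterministic and breed-structured", {
  br <- list(breed_spec("A", 20, fst = 0.2), breed_spec("B", 20, fst = 0.2))
  g1 <- simulate_genotypes(br, 300, seed = 5)
  g2 <- simulate_genotypes(br, 300, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  g3 <- simulate_genotypes(br, 300, seed = 6)
  expect_false(identical(g1$dosages, g3$dosages))
  # map is valid: strictly increasing positions within chromosomes
  for (ch in unique(g1$map$chrom)) {
    p <- g1$map$pos_bp[g1$map$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  # Balding-Nichols frequencies stay strictly inside (0, 1)
  fr <- attr(g1, "breed_freqs")
  expect_true(all(fr > 0 & fr < 1))
})

test_that("fst controls breed divergence in allele frequencies", {
  lowf <- list(breed_spec("A", 40, fst = 0.001),
               breed_spec("B", 40, fst = 0.001))
  g <- simulate_genotypes(lowf, 5000, seed = 7)
  fr <- attr(g, "breed_freqs")
  expect_lt(mean(abs(fr[1, ] - fr[2, ])), 0.02)
  # at fst = 0.2 the leading PC separates the two breeds
  hif <- list(breed_spec("A", 40, fst = 0.2), breed_spec("B", 40, fst = 0.2))
  gh <- simulate_genotypes(hif, 2000, seed = 8)
  Z <- scale(gh$dosages, scale = FALSE)
  pc1 <- svd(Z, nu = 1, nv = 0)$u[, 1]
  side <- pc1 > median(pc1)
  lab <- gh$samples$breed == "A"
  acc <- max(mean(side == lab), mean(side != lab))
  expect_gt(acc, 0.99)
})

test_that("trait simulation hits per-breed heritability and shares QTNs", {
  br <- list(breed_spec("A", 800, fst = 0.1), breed_spec("B", 800, fst = 0.1))
  g <- simulate_genotypes(br, 1000, seed = 9)
  y <- simulate_phenotype(g, trait_sim_spec(n_qtn = 20,
                                            heritability = "sample",
                                            seed = 10))
  tr <- attr(y, "truth")
  expect_length(tr$qtn_ids, 20L)
  expect_false(anyDuplicated(tr$qtn_ids) > 0)
  expect_true(all(tr$h2_by_breed >= 0.2 & tr$h2_by_breed <= 0.8))
  # realized within-breed h2 close to target at this sample size
  for (b in c("A", "B")) {
    rows <- g$samples$breed == b
    realized <- var(tr$g_true[rows]) / var(as.numeric(y)[rows])
    expect_lt(abs(realized - tr$h2_by_breed[[b]]), 0.05)
  }
  # degenerate residual: h2 = 1 means phenotype equals genetic value
  y1 <- simulate_phenotype(g, trait_sim_spec(heritability = 1, seed = 11))
  expect_equal(as.numeric(y1), unname(attr(y1, "truth")$g_true))
  expect_error(simulate_phenotype(g, trait_sim_spec(n_qtn = 5000)),
               "polymorphic")
})

test_that("binary trait case counts follow the prevalence quantile rule", {
  g <- sim_geno(456, 300, seed = 12)
  yb <- simulate_binary_trait(g, trait_sim_spec(heritability = 0.5,
                                                seed = 13),
                              prevalence = 0.44)
  expect_true(sum(yb == 1) >= 199 && sum(yb == 1) <= 201)
  g2 <- sim_geno(100, 100, seed = 14)
  yb2 <- simulate_binary_trait(g2, trait_sim_spec(heritability = 0.5,
                                                  seed = 15),
                               prevalence = 0.5)
  expect_equal(sum(yb2 == 1), 50)
  expect_error(simulate_binary_trait(g2, prevalence = 1.2), "prevalence")
})

test_that("a null trait gives no genotype-based signal", {
  g <- sim_geno(200, 200, seed = 16)
  y0 <- simulate_phenotype(g, trait_sim_spec(heritability = 0, seed = 17))
  r <- cor(attr(y0, "truth")$g_true, as.numeric(y0))
  expect_lt(abs(r), 2 / sqrt(200))
})

test_that("fixture bundle is complete, consistent, and byte-stable", {
  d1 <- withr::local_tempdir()
  paths <- write_fixture_bundle(d1, seed = 3, n_dogs = 60, L = 300)
  g <- read_plink(paths$plink)
  expect_equal(n_samples(g), 60L)
  expect_equal(n_markers(g), 300L)
  ph <- read_phenotypes(paths$pheno)
  expect_identical(align_phenotypes(ph, g)$id, g$samples$id)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  gi <- read_gene_intervals(paths$genes, extension_bp = 0)
  # every interval contains at least one true QTN by construction
  qpos <- g$map$pos_bp[match(truth$qtn_ids, g$map$marker_id)]
  qchr <- g$map$chrom[match(truth$qtn_ids, g$map$marker_id)]
  for (i in seq_len(nrow(gi$records))) {
    rec <- gi$records[i, ]
    expect_true(any(qchr == rec$chrom & qpos >= rec$start_bp &
                      qpos <= rec$end_bp))
  }
  # associated-marker selection finds the QTN-bearing regions
  sel <- select_associated_markers(g, gi)
  expect_true(any(truth$qtn_ids %in% sel$map$marker_id))
  # regeneration with the same seed is byte-identical
  d2 <- withr::local_tempdir()
  paths2 <- write_fixture_bundle(d2, seed = 3, n_dogs = 60, L = 300)
  for (f in c("pheno", "genes", "truth"))
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  expect_identical(readBin(paste0(paths$plink, ".bed"), "raw", 1e6),
                   readBin(paste0(paths2$plink, ".bed"), "raw", 1e6))
})
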