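test_that("random folds partition the population with near-equal sizes", {
  g <- sim_geno(10, 15, seed = 1)
  plan <- make_folds(g, "random", n_folds = 5, n_rounds = 3, seed = 2)
  for (r in 1:3) {
    a <- plan$assign[, r]
    expect_false(anyNA(a))
    expect_equal(as.integer(table(a)), rep(2L, 5))  # 10 dogs, five folds of 2
  }
  g11 <- sim_geno(11, 15, seed = 1)
  plan11 <- make_folds(g11, "random", n_folds = 5, n_rounds = 2, seed = 2)
  sizes <- table(plan11$assign[, 1])
  expect_lte(max(sizes) - min(sizes), 1L)
  # reproducibility
  plan_b <- make_folds(g, "random", n_folds = 5, n_rounds = 3, seed = 2)
  expect_identical(plan$assign, plan_b$assign)
})

test_that("single-breed strategies fold only the target breed", {
  g <- simulate_genotypes(list(breed_spec("Lab", 25), breed_spec("GSD", 10)),
                          30, seed = 3)
  aug <- make_folds(g, "single_breed_augmented", target_breed = "Lab",
                    n_folds = 5, n_rounds = 4, seed = 5)
  pure <- make_folds(g, "single_breed", target_breed = "Lab",
                     n_folds = 5, n_rounds = 4, seed = 5)
  is_lab <- g$samples$breed == "Lab"
  # validation sets are always within the target breed
  expect_true(all(aug$assign[!is_lab, ] == 0L))   # permanent reference
  expect_true(all(is.na(pure$assign[!is_lab, ]))) # excluded entirely
  # same seed -> identical fold labels for the target breed
  expect_identical(aug$assign[is_lab, ], pure$assign[is_lab, ])
  expect_error(make_folds(g, "single_breed", target_breed = "Poodle"),
               "unknown breed")
  expect_error(make_folds(g, "single_breed", target_breed = "GSD",
                          n_folds = 20), "eligible")
})

test_that("run_cv is deterministic and produces the expected table shape", {
  dat <- sim_trait_data(60, 100, h2 = 0.8, seed = 9)
  plan <- make_folds(dat$g, "random", n_folds = 5, n_rounds = 2, seed = 4)
  r1 <- run_cv(plan, dat$y, dat$g, "gblup", config = list(seed = 6))
  r2 <- run_cv(plan, dat$y, dat$g, "gblup", config = list(seed = 6))
  expect_identical(r1$folds, r2$folds)
  expect_equal(nrow(r1$folds), 10L)  # 2 rounds x 5 folds
  expect_equal(nrow(r1$rounds), 2L)
  expect_true(all(r1$folds$pearson_r >= -1 & r1$folds$pearson_r <= 1))
  # aggregation: per-round means first, then across rounds
  expect_equal(r1$summary$mean_r, mean(r1$rounds$pearson_r))
  expect_equal(r1$summary$sd_r, sd(r1$rounds$pearson_r))
  # tidy output has one aggregate row
  path <- file.path(withr::local_tempdir(), "cv.tsv")
  write_cv_result(r1, path, trait = "sim")
  tab <- read.delim(path)
  expect_equal(nrow(tab), 11L)
  expect_equal(sum(is.na(tab$round)), 1L)
})

test_that("missing phenotypes are excluded and small folds are skipped", {
  dat <- sim_trait_data(40, 60, h2 = 0.8, seed = 13)
  yv <- as.numeric(dat$y)
  yv[1:30] <- NA  # only 10 phenotyped dogs remain
  y <- phenotype_vector(yv, "continuous", "t", dat$g$samples$id)
  plan <- make_folds(dat$g, "random", n_folds = 5, n_rounds = 2, seed = 8)
  w <- testthat::capture_warnings(
    res <- run_cv(plan, y, dat$g, "gblup", config = list(seed = 1)))
  expect_true(any(grepl("skipping", w)))
  expect_gt(res$summary$n_skipped, 0)
  expect_true(all(res$folds$n_valid[!res$folds$skipped] >= 3))
})

test_that("binary traits get AUC; angle traits get cutoff labels with negation", {
  g <- sim_geno(80, 120, seed = 17)
  yb <- simulate_binary_trait(g, trait_sim_spec(n_qtn = 10,
                                                heritability = 0.8,
                                                seed = 18),
                              prevalence = 0.5)
  plan <- make_folds(g, "random", n_folds = 5, n_rounds = 2, seed = 19)
  res <- run_cv(plan, yb, g, "gblup", config = list(seed = 20))
  expect_true(all(!is.na(res$folds$auc)))
  expect_true(all(res$folds$auc >= 0 & res$folds$auc <= 1))
  # angle-like trait: case = below cutoff, so predictions are negated;
  # a strongly heritable trait must then score AUC above 0.5
  dat <- sim_trait_data(80, 120, h2 = 0.9, seed = 21)
  ang <- phenotype_vector(103 - 5 * scale(as.numeric(dat$y))[, 1],
                          "continuous", "angle", dat$g$samples$id)
  plan2 <- make_folds(dat$g, "random", n_folds = 5, n_rounds = 2, seed = 22)
  res2 <- run_cv(plan2, ang, dat$g, "gblup",
                 config = list(binarize_cutoff = 103, seed = 23))
  expect_gt(res2$summary$mean_auc, 0.5)
})
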