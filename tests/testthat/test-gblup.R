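test_that("fixed-effects design uses treatment coding with reference levels", {
  d <- build_design(c("Lab", "Lab", "GSD", "GSD"), c("M", "F", "M", "F"))
  expect_equal(ncol(d$X), 2L)  # (2-1) breeds + (2-1) sexes
  expect_identical(d$effect_names, c("breedLab", "sexM"))
  d0 <- build_design(rep("Lab", 3), rep("F", 3))
  expect_equal(ncol(d0$X), 0L)  # intercept-only model
  d6 <- build_design(rep(paste0("B", 1:6), each = 2),
                     rep(c("M", "F"), 6))
  expect_equal(ncol(d6$X), 6L)  # (6-1) + (2-1)
  # unseen level at prediction time
  expect_error(breedgp:::design_rows(d, "Poodle", "M"), "unseen")
})

test_that("closed-form GBLUP satisfies Henderson's equations on random instances", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(20:40, 1)
    dat <- sim_trait_data(n, n + 30, h2 = 0.5, seed = 200 + rep)
    # a VanRaden GRM is singular by construction (centered columns), so
    # blend with the identity to make Henderson's K^-1 form testable
    kin <- kinship_from_matrix(0.95 * compute_grm(dat$g)$K +
                                 diag(0.05, n))
    des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
    vc <- variance_components(runif(1, 0.3, 2), runif(1, 0.3, 2))
    fit <- fit_gblup_closed_form(as.numeric(dat$y), des, kin, vc)
    expect_lt(mme_residual(fit, as.numeric(dat$y), des, kin, vc), 1e-8)
    # linear predictor identity: eta = mu + X beta + g
    eta <- drop(cbind(1, des$X) %*% c(fit$mu, fit$beta)) + fit$g_hat
    expect_equal(fit$fitted, eta, ignore_attr = TRUE)
  }
})

test_that("GBLUP limits: ridge to OLS as sigma_g2 -> 0; K = I shrinkage form", {
  dat <- sim_trait_data(30, 60, h2 = 0.5, seed = 5)
  y <- as.numeric(dat$y)
  kin <- compute_grm(dat$g)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  fit0 <- fit_gblup_closed_form(y, des, kin,
                                variance_components(1e-10, 1))
  expect_lt(max(abs(fit0$g_hat)), 1e-6)
  ols <- coef(lm(y ~ des$X))
  expect_equal(unname(c(fit0$mu, fit0$beta)), unname(ols), tolerance = 1e-6)
  # K = identity, intercept only: g_hat = h2 * (y - ybar)
  kid <- kinship_from_matrix(diag(length(y)))
  d0 <- build_design(rep("Lab", length(y)), rep("F", length(y)))
  fit1 <- fit_gblup_closed_form(y, d0, kid, variance_components(1, 1))
  expect_equal(unname(fit1$g_hat), 0.5 * (y - mean(y)), tolerance = 1e-10)
})

test_that("REML recovers heritability on a large single-breed sample", {
  dat <- sim_trait_data(400, 800, h2 = 0.5, seed = 11)
  kin <- compute_grm(dat$g)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  fit <- fit_gblup_closed_form(as.numeric(dat$y), des, kin)
  expect_gt(fit$vc$h2, 0.3)
  expect_lt(fit$vc$h2, 0.7)
})

test_that("Gibbs GBLUP is seed-reproducible and matches the closed form", {
  dat <- sim_trait_data(100, 200, h2 = 0.5, seed = 21)
  y <- as.numeric(dat$y)
  kin <- compute_grm(dat$g)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  ch <- list(n_iter = 4000, burn_in = 1000, thin = 5)
  f1 <- fit_gblup_gibbs(y, des, kin, chain = ch, seed = 42)
  f2 <- fit_gblup_gibbs(y, des, kin, chain = ch, seed = 42)
  expect_identical(f1$g_hat, f2$g_hat)
  expect_identical(f1$trace, f2$trace)
  f3 <- fit_gblup_gibbs(y, des, kin, chain = ch, seed = 43)
  expect_false(identical(f1$g_hat, f3$g_hat))
  # oracle equivalence at the posterior-mean variance components
  cf <- fit_gblup_closed_form(y, des, kin, f1$vc)
  expect_gt(cor(f1$g_hat, cf$g_hat), 0.98)
  expect_error(fit_gblup_gibbs(rep(1, 100), des, kin, chain = ch, seed = 1),
               "degenerate phenotype")
  expect_error(fit_gblup_gibbs(y, des, kin,
                               chain = list(n_iter = 10, burn_in = 50,
                                            thin = 1), seed = 1),
               "burn-in")
})

test_that("GBLUP prediction is self-consistent and respects duplicates", {
  dat <- sim_trait_data(60, 120, h2 = 0.6, seed = 31)
  y <- as.numeric(dat$y)
  g <- dat$g
  kin <- compute_grm(g)
  des <- build_design(g$samples$breed, g$samples$sex)
  fit <- fit_gblup_closed_form(y, des, kin, variance_components(1, 1))
  # predicting the training samples recovers the fitted values
  pred_self <- predict(fit, K_cross = kin$K,
                       breed = g$samples$breed, sex = g$samples$sex)
  expect_equal(pred_self, fit$fitted, tolerance = 1e-4, ignore_attr = TRUE)
  # a validation dog genotypically identical to a training dog, same
  # covariates, gets (nearly) the same prediction
  newg <- genotype_matrix(g$dosages[c(1, 1), ], g$map$marker_id,
                          g$map$chrom, g$map$pos_bp, c("c1", "c2"),
                          g$samples$breed[c(1, 1)], g$samples$sex[c(1, 1)])
  p2 <- predict(fit, newg = newg, train_g = g,
                breed = g$samples$breed[c(1, 1)],
                sex = g$samples$sex[c(1, 1)])
  expect_equal(p2[1], p2[2], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("allele-coding flips leave GBLUP predictions unchanged", {
  dat <- sim_trait_data(50, 100, h2 = 0.5, seed = 41)
  y <- as.numeric(dat$y)
  g <- dat$g
  flip <- c(3, 10, 11, 40)
  g2 <- g
  g2$dosages[, flip] <- 2 - g2$dosages[, flip]
  expect_equal(compute_grm(g)$K, compute_grm(g2)$K, tolerance = 1e-10)
  des <- build_design(g$samples$breed, g$samples$sex)
  f1 <- fit_gblup_closed_form(y, des, compute_grm(g),
                              variance_components(1, 1))
  f2 <- fit_gblup_closed_form(y, des, compute_grm(g2),
                              variance_components(1, 1))
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})
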