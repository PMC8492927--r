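test_that("BayesC chains are reproducible under a seed", {
  dat <- sim_trait_data(50, 60, h2 = 0.5, seed = 51)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  ch <- list(n_iter = 800, burn_in = 200, thin = 2)
  f1 <- fit_bayesc(as.numeric(dat$y), des, dat$g, chain = ch, seed = 7)
  f2 <- fit_bayesc(as.numeric(dat$y), des, dat$g, chain = ch, seed = 7)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$trace, f2$trace)
  f3 <- fit_bayesc(as.numeric(dat$y), des, dat$g, chain = ch, seed = 8)
  expect_false(identical(f1$alpha, f3$alpha))
})

test_that("with pi = 1 and fixed variances BayesC collapses to ridge regression", {
  dat <- sim_trait_data(80, 50, h2 = 0.5, seed = 61)
  y <- as.numeric(dat$y)
  g <- dat$g
  des <- build_design(g$samples$breed, g$samples$sex)
  sa <- 0.05; se <- stats::var(y) / 2
  pri <- bayesc_priors(fix_pi = TRUE, pi_fixed = 1, fix_var = TRUE,
                       sigma_a2 = sa, sigma_e2 = se)
  fit <- fit_bayesc(y, des, g, priors = pri,
                    chain = list(n_iter = 12000, burn_in = 2000, thin = 2),
                    seed = 3)
  # closed-form ridge (random-effect) solution with the same lambda
  Mc <- sweep(g$dosages, 2, colMeans(g$dosages))
  W <- cbind(1, des$X)
  lam <- se / sa
  A <- rbind(cbind(crossprod(W), crossprod(W, Mc)),
             cbind(crossprod(Mc, W),
                   crossprod(Mc) + diag(lam, ncol(Mc))))
  sol <- solve(A, c(crossprod(W, y), crossprod(Mc, y)))
  alpha_cf <- sol[-seq_len(ncol(W))]
  expect_lt(max(abs(fit$alpha - alpha_cf)) / sqrt(se), 0.05)
  expect_equal(unname(fit$pi_mean), 1)
})

test_that("a single large-effect QTN gets the top inclusion probability", {
  g <- sim_geno(120, 201, seed = 71)
  # pick a common variant so the single-QTN signal is well powered
  qtn <- which.min(abs(colMeans(g$dosages) / 2 - 0.5))
  set.seed(9)
  y <- 2 * g$dosages[, qtn] + rnorm(n_samples(g), 0, 0.5)
  des <- build_design(g$samples$breed, g$samples$sex)
  fit <- fit_bayesc(y, des, g,
                    chain = list(n_iter = 2000, burn_in = 500, thin = 2),
                    seed = 5)
  expect_identical(unname(which.max(fit$inclusion_prob)), as.integer(qtn))
  expect_gt(fit$inclusion_prob[qtn], 0.9)
})

test_that("null marker effects reduce predictions to the fixed part", {
  dat <- sim_trait_data(40, 30, h2 = 0.5, seed = 81)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  fit <- fit_bayesc(as.numeric(dat$y), des, dat$g,
                    chain = list(n_iter = 400, burn_in = 100, thin = 2),
                    seed = 2)
  fit$alpha[] <- 0  # degenerate-effects fit
  p <- predict(fit, dat$g)
  W <- cbind(1, des$X)
  expect_equal(p, drop(W %*% c(fit$mu, fit$beta)), ignore_attr = TRUE)
})

test_that("BayesC validates its inputs", {
  dat <- sim_trait_data(20, 10, h2 = 0.5, seed = 91)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  expect_error(fit_bayesc(as.numeric(dat$y), des, dat$g,
                          chain = list(n_iter = 100, burn_in = 200,
                                       thin = 1), seed = 1),
               "burn-in")
  gna <- dat$g
  gna$dosages[1, 1] <- NA
  expect_error(fit_bayesc(as.numeric(dat$y), des, gna,
                          chain = list(n_iter = 300, burn_in = 100,
                                       thin = 1), seed = 1),
               "complete")
  # marker-panel mismatch at prediction time names the missing markers
  fit <- fit_bayesc(as.numeric(dat$y), des, dat$g,
                    chain = list(n_iter = 300, burn_in = 100, thin = 1),
                    seed = 1)
  expect_error(predict(fit, dat$g[, 1:5]), "missing from new data")
})

test_that("allele-coding flips leave BayesC predictions unchanged", {
  dat <- sim_trait_data(60, 40, h2 = 0.6, seed = 95)
  y <- as.numeric(dat$y)
  des <- build_design(dat$g$samples$breed, dat$g$samples$sex)
  g2 <- dat$g
  flip <- c(2, 9, 30)
  g2$dosages[, flip] <- 2 - g2$dosages[, flip]
  ch <- list(n_iter = 6000, burn_in = 1000, thin = 2)
  f1 <- fit_bayesc(y, des, dat$g, chain = ch, seed = 11)
  f2 <- fit_bayesc(y, des, g2, chain = ch, seed = 11)
  p1 <- predict(f1, dat$g)
  p2 <- predict(f2, g2)
  expect_gt(cor(p1, p2), 0.99)
  expect_lt(mean(abs(p1 - p2)) / sd(y), 0.05)
})
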