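# tiny deterministic genotype objects used across test files

tiny_geno <- function() {
  # 3 dogs x 4 markers, fully observed, mixed breeds/sexes
  d <- rbind(c(0, 1, 2, 1),
             c(1, 0, 2, 0),
             c(2, 1, 0, 1))
  genotype_matrix(d, c("m1", "m2", "m3", "m4"),
                  c("chr1", "chr1", "chr2", "chr2"),
                  c(100L, 200L, 150L, 900L),
                  c("dogA", "dogB", "dogC"),
                  c("Lab", "Lab", "GSD"), c("M", "F", "F"))
}

# one-breed random genotypes with all-polymorphic guarantee
sim_geno <- function(n, L, seed = 1, fst = 0.1, name = "Lab") {
  g <- simulate_genotypes(breed_spec(name, n, fst = fst), L, seed = seed)
  p <- colMeans(g$dosages) / 2
  keep <- which(p > 0 & p < 1)
  g[, keep]
}

# genotypes plus a gaussian trait with known h2 (single breed)
sim_trait_data <- function(n, L, h2, seed = 1) {
  g <- sim_geno(n, L, seed = seed)
  y <- simulate_phenotype(g, trait_sim_spec(n_qtn = min(20L, n_markers(g)),
                                            heritability = h2,
                                            seed = seed + 1000))
  list(g = g, y = y, truth = attr(y, "truth"))
}

# brute-force AUC over all case-control pairs (independent oracle)
auc_brute <- function(pred, labels) {
  cs <- pred[labels == 1]; ct <- pred[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Henderson MME residual for a gblup fit at given variance components
mme_residual <- function(fit, y, design, kin, vc) {
  W <- cbind(1, design$X)
  n <- length(y)
  lam <- vc$sigma_e2 / vc$sigma_g2
  Kinv <- solve(kin$K)
  C <- rbind(cbind(crossprod(W), t(W)),
             cbind(W, diag(n) + lam * Kinv))
  rhs <- c(crossprod(W, y), y)
  sol <- c(fit$mu, fit$beta, fit$g_hat)
  sqrt(sum((C %*% sol - rhs)^2))
}
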