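#' Variance components container
#'
#' @param sigma_g2 additive-genetic variance (>= 0), on the scale of the
#'   kinship matrix (for a VanRaden GRM with mean diagonal near 1 this is
#'   directly comparable to the residual variance).
#' @param sigma_e2 residual variance (> 0).
#' @return A `variance_components` list with `sigma_g2`, `sigma_e2`, `h2`.
#' @export
variance_components <- function(sigma_g2, sigma_e2) {
  if (sigma_g2 < 0) stop("sigma_g2 must be non-negative")
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2)),
            class = "variance_components")
}

# Rotate the model into the kinship eigenbasis. Returns the pieces every
# GBLUP path needs: ytil = U'y, Wtil = U'[1 X], d = eigenvalues.
rotate_model <- function(y, design, kin) {
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(kin$K) != n) stop("kinship dimension does not match phenotype")
  if (anyNA(y)) stop("closed-form GBLUP requires complete phenotypes")
  W <- cbind(`(Intercept)` = 1, design$X)
  U <- kin$eigen$vectors
  list(W = W, U = U, d = pmax(kin$eigen$values, 0),
       ytil = drop(crossprod(U, y)), Wtil = crossprod(U, W), n = n, y = y)
}

#' GBLUP by the closed-form mixed-model equations
#'
#' Solves `y = 1 mu + X beta + g + e`, `g ~ N(0, K sigma_g2)`,
#' `e ~ N(0, I sigma_e2)` exactly at the supplied variance components
#' (Henderson's BLUP, computed in the eigenbasis of `K` so a singular
#' kinship is handled without forming `K^-1`). When `vc` is omitted the
#' variance ratio is first estimated by REML (Brent search over h2 on the
#' rotated profile likelihood) — a deterministic path with no MCMC.
#'
#' @param y a `phenotype_vector` (or numeric vector), complete.
#' @param design a `fixed_design` from [build_design()].
#' @param kin a `kinship_matrix` covering the same samples in order.
#' @param vc optional `variance_components`; estimated by REML if `NULL`.
#' @return A `gblup_fit`: `mu`, `beta`, `g_hat`, `vc`, `fitted`,
#'   `design`, `kin`, `method = "closed_form"`.
#' @export
fit_gblup_closed_form <- function(y, design, kin, vc = NULL) {
  rm_ <- rotate_model(y, design, kin)
  if (is.null(vc)) vc <- reml_variance(rm_)
  sg <- vc$sigma_g2; se <- vc$sigma_e2
  v <- sg * rm_$d + se                       # eigenvalues of V
  Wv <- rm_$Wtil / v                          # V^-1 Wtil (columnwise)
  A <- crossprod(rm_$Wtil, Wv)
  qx <- qr(A)
  if (qx$rank < ncol(A))
    stop("singular mixed-model coefficient matrix; confounded columns: ",
         paste(colnames(rm_$W)[setdiff(seq_len(ncol(A)),
                                       qx$pivot[seq_len(qx$rank)])],
               collapse = ", "))
  b <- solve(qx, crossprod(Wv, rm_$ytil))
  rtil <- rm_$ytil - rm_$Wtil %*% b           # rotated GLS residual
  g_hat <- drop(rm_$U %*% (sg * rm_$d / v * rtil))
  names(g_hat) <- rownames(kin$K)
  fitted <- drop(rm_$W %*% b) + g_hat
  structure(list(mu = b[1L], beta = drop(b)[-1L], g_hat = g_hat, vc = vc,
                 fitted = fitted, design = design, kin = kin,
                 ids = rownames(kin$K), method = "closed_form"),
            class = "gblup_fit")
}

# REML over h2 on the rotated model; profile out total variance.
reml_variance <- function(rm_) {
  p <- ncol(rm_$Wtil)
  n <- rm_$n
  negll <- function(h) {
    v <- h * rm_$d + (1 - h)
    Wv <- rm_$Wtil / v
    A <- crossprod(rm_$Wtil, Wv)
    b <- tryCatch(solve(A, crossprod(Wv, rm_$ytil)),
                  error = function(e) NULL)
    if (is.null(b)) return(1e10)
    r <- rm_$ytil - rm_$Wtil %*% b
    S <- sum(r^2 / v)
    0.5 * (sum(log(v)) + determinant(A, logarithm = TRUE)$modulus +
             (n - p) * log(S))
  }
  opt <- stats::optimize(negll, c(1e-4, 1 - 1e-4), tol = 1e-7)
  h <- opt$minimum
  v <- h * rm_$d + (1 - h)
  Wv <- rm_$Wtil / v
  b <- solve(crossprod(rm_$Wtil, Wv), crossprod(Wv, rm_$ytil))
  S <- sum((rm_$ytil - rm_$Wtil %*% b)^2 / v)
  sp2 <- S / (n - p)
  variance_components(h * sp2, max((1 - h) * sp2, 1e-12))
}

#' GBLUP by Gibbs sampling in the kinship eigenbasis
#'
#' The reproducing-kernel parameterization: with `K = U D U'`, the model
#' is `y = W b + U gamma + e` with independent `gamma_i ~ N(0, d_i
#' sigma_g2)`. Full conditionals are Gaussian for `b` and `gamma` and
#' scaled-inverse-chi-square for both variances. The variance priors are
#' weakly informative (df 2) so posterior summaries are dominated by the
#' data once n reaches the hundreds; their scales still split the
#' phenotypic variance evenly a priori. Reported h2 samples use the
#' genomic heritability on the phenotypic scale,
#' `h2 = sg2 kbar / (sg2 kbar + se2)` with `kbar = mean(diag(K))`.
#'
#' @param y complete `phenotype_vector` or numeric vector.
#' @param design a `fixed_design`.
#' @param kin a `kinship_matrix`.
#' @param chain list with `n_iter`, `burn_in`, `thin`.
#' @param seed integer seed; chains are bitwise reproducible.
#' @param df_g,df_e prior degrees of freedom.
#' @param R2 prior proportion of variance assigned to the genetic term.
#' @return A `gblup_fit` with posterior means in `mu`, `beta`, `g_hat`,
#'   `vc`, plus `h2_mean`, `h2_sd` and a `trace` data.frame of thinned
#'   variance samples.
#' @export
fit_gblup_gibbs <- function(y, design, kin,
                            chain = list(n_iter = 12000, burn_in = 2000,
                                         thin = 5),
                            seed = 1L, df_g = 2, df_e = 2, R2 = 0.5) {
  rm_ <- rotate_model(y, design, kin)
  vy <- stats::var(rm_$y)
  if (!is.finite(vy) || vy <= 0)
    stop("degenerate phenotype: variance is zero")
  if (chain$n_iter <= chain$burn_in)
    stop("chain length must exceed burn-in")
  kbar <- mean(diag(kin$K))
  keep <- rm_$d > 1e-10 * max(rm_$d)
  d <- rm_$d[keep]
  m <- length(d)
  Wt <- rm_$Wtil                    # rotated design, n x p
  p <- ncol(Wt)
  WtW <- crossprod(Wt)
  cholWtW <- chol(WtW)
  # prior scales: mode of scaled-inv-chi2(df, S) is df*S/(df+2)
  S_e <- vy * (1 - R2) * (df_e + 2) / df_e
  S_g <- vy * R2 * (df_g + 2) / (df_g * mean(d))
  with_seed(seed, {
    gam <- numeric(m)
    b <- numeric(p)
    sg <- vy * R2 / mean(d); se <- vy * (1 - R2)
    nsave <- 0L
    b_sum <- numeric(p); g_sum <- numeric(rm_$n)
    sg_tr <- se_tr <- h2_tr <- numeric(0)
    ytil <- rm_$ytil
    ygam <- ytil; ygam[keep] <- ytil[keep] - gam
    for (it in seq_len(chain$n_iter)) {
      # b | rest  ~ N((W'W)^-1 W'(ytil - gamma*), se (W'W)^-1)
      rhs <- crossprod(Wt, ygam)
      bm <- backsolve(cholWtW, forwardsolve(t(cholWtW), rhs))
      b <- drop(bm + backsolve(cholWtW, stats::rnorm(p)) * sqrt(se))
      r <- ytil - drop(Wt %*% b)
      # gamma_i | rest, independent Gaussians
      cvar <- 1 / (1 / se + 1 / (d * sg))
      gam <- stats::rnorm(m, cvar * r[keep] / se, sqrt(cvar))
      ygam <- ytil; ygam[keep] <- ytil[keep] - gam
      # variances: scaled-inverse-chi-square full conditionals
      sg <- (sum(gam^2 / d) + df_g * S_g) / stats::rchisq(1L, m + df_g)
      ee <- sum((r[keep] - gam)^2) + sum(r[!keep]^2)
      se <- (ee + df_e * S_e) / stats::rchisq(1L, rm_$n + df_e)
      if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0L) {
        nsave <- nsave + 1L
        b_sum <- b_sum + b
        gfull <- numeric(rm_$n); gfull[keep] <- gam
        g_sum <- g_sum + drop(rm_$U %*% gfull)
        sg_tr <- c(sg_tr, sg); se_tr <- c(se_tr, se)
        h2_tr <- c(h2_tr, sg * kbar / (sg * kbar + se))
      }
    }
  })
  b_mean <- b_sum / nsave
  g_mean <- g_sum / nsave
  names(g_mean) <- rownames(kin$K)
  names(b_mean) <- colnames(rm_$W)
  vc <- variance_components(mean(sg_tr), mean(se_tr))
  structure(list(mu = b_mean[1L], beta = b_mean[-1L], g_hat = g_mean,
                 vc = vc, h2_mean = mean(h2_tr), h2_sd = stats::sd(h2_tr),
                 fitted = drop(rm_$W %*% b_mean) + g_mean,
                 trace = data.frame(sigma_g2 = sg_tr, sigma_e2 = se_tr,
                                    h2 = h2_tr),
                 design = design, kin = kin, ids = rownames(kin$K),
                 chain = chain, seed = seed, method = "gibbs"),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit (%s): n = %d, sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$method, length(x$g_hat), x$vc$sigma_g2, x$vc$sigma_e2,
              x$vc$h2))
  invisible(x)
}

#' Predict genetic merit of new samples from a GBLUP fit
#'
#' Held-out genetic values are the conditional expectation
#' `g_new = K_cross K_train^-1 g_hat`, with a small ridge
#' (`1e-6 tr(K)/n`) on the training block before inversion; fixed
#' effects are added under the training coding.
#'
#' @param object a `gblup_fit`.
#' @param K_cross `n_new x n_train` kinship block between new and
#'   training samples (e.g. a slice of a joint GRM). Alternatively pass
#'   `newg` and `train_g` to build the joint GRM from genotypes.
#' @param breed,sex covariates of the new samples.
#' @param newg,train_g optional `genotype_matrix` objects (new and
#'   training samples on an identical marker panel) used to compute the
#'   joint GRM when `K_cross` is not supplied.
#' @param ... ignored.
#' @return Numeric vector of predictions `mu + X beta + g_new`.
#' @export
predict.gblup_fit <- function(object, K_cross = NULL, breed = NULL,
                              sex = NULL, newg = NULL, train_g = NULL, ...) {
  if (is.null(K_cross)) {
    if (is.null(newg) || is.null(train_g))
      stop("supply either K_cross or both newg and train_g")
    if (!identical(newg$map$marker_id, train_g$map$marker_id))
      stop("marker panels of newg and train_g do not match")
    joint <- genotype_matrix(rbind(train_g$dosages, newg$dosages),
                             train_g$map$marker_id, train_g$map$chrom,
                             train_g$map$pos_bp,
                             c(train_g$samples$id, newg$samples$id),
                             c(train_g$samples$breed, newg$samples$breed),
                             c(train_g$samples$sex, newg$samples$sex),
                             train_g$map$a1, train_g$map$a2)
    Kj <- compute_grm(joint)$K
    ntr <- n_samples(train_g)
    K_cross <- Kj[-(seq_len(ntr)), seq_len(ntr), drop = FALSE]
    if (is.null(breed)) breed <- newg$samples$breed
    if (is.null(sex)) sex <- newg$samples$sex
  }
  Ktr <- object$kin$K
  ridge <- 1e-6 * sum(diag(Ktr)) / nrow(Ktr)
  g_new <- drop(K_cross %*% solve(Ktr + diag(ridge, nrow(Ktr)),
                                  object$g_hat))
  eta <- object$mu + g_new
  if (length(object$beta)) {
    if (is.null(breed) || is.null(sex))
      stop("breed and sex are required to apply the fixed effects")
    Xn <- design_rows(object$design, breed, sex)
    eta <- eta + drop(Xn %*% object$beta)
  }
  eta
}
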