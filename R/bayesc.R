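#' BayesC prior and hyperparameter settings
#'
#' Mirrors the common defaults of Bayesian whole-genome regression
#' software: prior inclusion probability 0.5 with a Beta prior of total
#' weight 10; scaled-inverse-chi-square priors with 5 degrees of freedom
#' on both variances; scales chosen so the prior splits the phenotypic
#' variance evenly between markers and residual (`R2 = 0.5`). Fixing
#' `pi = 1` with fixed variances turns the model into ridge regression
#' (SNP-BLUP), which is used as an oracle in the tests.
#'
#' @param pi0 prior mean inclusion probability.
#' @param pi_counts total weight of the Beta prior on `pi`.
#' @param df_e,df_a prior degrees of freedom for residual and
#'   marker-effect variance.
#' @param R2 prior proportion of phenotypic variance from markers.
#' @param fix_pi,pi_fixed fix the inclusion probability instead of
#'   sampling it.
#' @param fix_var,sigma_a2,sigma_e2 fix both variances (oracle mode).
#' @return A list of class `bayesc_priors`.
#' @export
bayesc_priors <- function(pi0 = 0.5, pi_counts = 10, df_e = 5, df_a = 5,
                          R2 = 0.5, fix_pi = FALSE, pi_fixed = 1,
                          fix_var = FALSE, sigma_a2 = NULL,
                          sigma_e2 = NULL) {
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]")
  structure(list(pi0 = pi0, pi_counts = pi_counts, df_e = df_e,
                 df_a = df_a, R2 = R2, fix_pi = fix_pi,
                 pi_fixed = pi_fixed, fix_var = fix_var,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2),
            class = "bayesc_priors")
}

#' Fit BayesC by single-site Gibbs sampling
#'
#' Spike-and-slab whole-genome regression: each marker effect is zero
#' with probability `1 - pi` and Gaussian with probability `pi`. Marker
#' columns are centered by their training means (stored for prediction);
#' sex and breed enter as fixed effects next to the intercept. The
#' sampler is compiled and uses R's RNG, so runs are reproducible under
#' the supplied seed.
#'
#' @param y complete `phenotype_vector` or numeric vector.
#' @param design a `fixed_design` for the training samples.
#' @param g a `genotype_matrix` of the training samples, no missing calls.
#' @param priors a [bayesc_priors()] list.
#' @param chain list with `n_iter`, `burn_in`, `thin`.
#' @param seed integer seed.
#' @return A `bayesc_fit`: posterior means `mu`, `beta`, `alpha`,
#'   `inclusion_prob`, `pi_mean`, `vc`, marker centers, and variance
#'   traces.
#' @export
fit_bayesc <- function(y, design, g, priors = bayesc_priors(),
                       chain = list(n_iter = 12000, burn_in = 2000,
                                    thin = 5),
                       seed = 1L) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("fit_bayesc requires complete phenotypes")
  M <- g$dosages
  if (ncol(M) == 0L) stop("empty marker panel")
  if (anyNA(M)) stop("fit_bayesc requires complete dosages")
  if (nrow(M) != length(y)) stop("genotype/phenotype dimension mismatch")
  if (chain$n_iter <= chain$burn_in)
    stop("chain length must exceed burn-in")
  centers <- colMeans(M)
  Mc <- sweep(M, 2L, centers)
  W <- cbind(`(Intercept)` = 1, design$X)
  vy <- stats::var(y)
  MSx <- sum(apply(Mc, 2L, stats::var))
  if (MSx <= 0) MSx <- 1
  S_e <- vy * (1 - priors$R2) * (priors$df_e + 2) / priors$df_e
  pi_eff <- if (priors$fix_pi) priors$pi_fixed else priors$pi0
  S_a <- vy * priors$R2 * (priors$df_a + 2) / (priors$df_a * MSx * pi_eff)
  res <- with_seed(seed, .bayesc_gibbs(
    y, W, Mc, as.integer(chain$n_iter), as.integer(chain$burn_in),
    as.integer(chain$thin), priors$df_e, S_e, priors$df_a, S_a,
    priors$pi0, priors$pi_counts, priors$fix_pi, priors$pi_fixed,
    priors$fix_var,
    if (priors$fix_var) priors$sigma_a2 else 0,
    if (priors$fix_var) priors$sigma_e2 else 0))
  bm <- drop(res$b)
  names(bm) <- colnames(W)
  alpha <- drop(res$alpha)
  names(alpha) <- g$map$marker_id
  vc <- variance_components(mean(res$sigma_a2_trace) * MSx,
                            mean(res$sigma_e2_trace))
  structure(list(mu = bm[1L], beta = bm[-1L], alpha = alpha,
                 inclusion_prob = stats::setNames(drop(res$inclusion_prob),
                                                  g$map$marker_id),
                 pi_mean = mean(res$pi_trace),
                 sigma_a2_mean = mean(res$sigma_a2_trace),
                 sigma_e2_mean = mean(res$sigma_e2_trace),
                 vc = vc,
                 trace = data.frame(sigma_a2 = res$sigma_a2_trace,
                                    sigma_e2 = res$sigma_e2_trace,
                                    pi = res$pi_trace),
                 centers = centers, marker_ids = g$map$marker_id,
                 design = design, chain = chain, seed = seed,
                 fitted = drop(W %*% bm) + drop(Mc %*% alpha)),
            class = "bayesc_fit")
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat(sprintf(
    "BayesC fit: L = %d markers, posterior mean pi = %.3f, sigma_e2 = %.4f\n",
    length(x$alpha), x$pi_mean, x$sigma_e2_mean))
  invisible(x)
}

#' Predict phenotypes of new samples from a BayesC fit
#'
#' `y_hat = mu + X beta + M_new alpha` with the new dosages centered by
#' the training-sample column means.
#'
#' @param object a `bayesc_fit`.
#' @param newg a `genotype_matrix` on the training marker panel.
#' @param breed,sex covariates of the new samples; default from `newg`.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
predict.bayesc_fit <- function(object, newg, breed = NULL, sex = NULL, ...) {
  if (!identical(newg$map$marker_id, object$marker_ids)) {
    missing_m <- setdiff(object$marker_ids, newg$map$marker_id)
    if (length(missing_m))
      stop("marker panel mismatch; missing from new data: ",
           paste(utils::head(missing_m, 5), collapse = ", "))
    newg <- newg[, object$marker_ids]  # same set, different order
  }
  if (is.null(breed)) breed <- newg$samples$breed
  if (is.null(sex)) sex <- newg$samples$sex
  Mc <- sweep(newg$dosages, 2L, object$centers)
  eta <- object$mu + drop(Mc %*% object$alpha)
  if (length(object$beta)) {
    Xn <- design_rows(object$design, breed, sex)
    eta <- eta + drop(Xn %*% object$beta)
  }
  eta
}
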