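#' Genomic relationship matrix (VanRaden method 1)
#'
#' Columns of the dosage matrix are centered by twice the observed allele
#' frequency, `W = M - 2p`, and the kinship is
#' `K = W W' / (2 * sum_j p_j (1 - p_j))`. Monomorphic markers contribute
#' neither to `W` nor to the denominator. The eigendecomposition of `K`
#' is computed once and cached on the object for the mixed-model solvers.
#'
#' @param g a `genotype_matrix` with no missing dosages (run
#'   [drop_incomplete_markers()] first).
#' @return An object of class `kinship_matrix`: list with `K` (n x n,
#'   dimnamed), `eigen` (`values`, `vectors`), `p_freq` (frequencies of
#'   the polymorphic markers used), `markers_used`, and `source`.
#' @export
compute_grm <- function(g) {
  M <- g$dosages
  if (anyNA(M))
    stop("compute_grm requires complete dosages; run drop_incomplete_markers()")
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("degenerate kinship: every marker is monomorphic")
  Mp <- M[, poly, drop = FALSE]
  pp <- p[poly]
  W <- sweep(Mp, 2L, 2 * pp)
  denom <- 2 * sum(pp * (1 - pp))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(g$samples$id, g$samples$id)
  kinship_from_matrix(K, source = "vanraden1",
                      p_freq = pp, markers_used = colnames(Mp))
}

#' Wrap a precomputed kinship matrix
#'
#' @param K symmetric n x n matrix.
#' @param source descriptor of how `K` was built.
#' @param p_freq,markers_used optional bookkeeping from [compute_grm()].
#' @return A `kinship_matrix` with cached eigendecomposition.
#' @export
kinship_from_matrix <- function(K, source = "user", p_freq = NULL,
                                markers_used = NULL) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kinship matrix must be square")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8 * max(1, max(abs(K))))
    stop("kinship matrix is not symmetric (max asymmetry ", asym, ")")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values, 1e-12))
    warning("kinship matrix has a markedly negative eigenvalue: ",
            min(e$values))
  structure(list(K = K, eigen = e, source = source,
                 p_freq = p_freq, markers_used = markers_used),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d x %d, mean diagonal %.3f\n",
              x$source, nrow(x$K), ncol(x$K), mean(diag(x$K))))
  invisible(x)
}

# subset a kinship object to samples idx, re-deriving the eigen cache
subset_kinship <- function(kin, idx) {
  kinship_from_matrix(kin$K[idx, idx, drop = FALSE], source = kin$source,
                      p_freq = kin$p_freq, markers_used = kin$markers_used)
}
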