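#' Build the fixed-effects design for sex and breed
#'
#' Treatment coding with the alphabetically first level of each factor as
#' reference; single-level factors contribute no column, so a one-breed,
#' one-sex population yields an intercept-only model (K = 0 columns).
#' The returned object remembers the training levels so that prediction
#' on a sample with an unseen breed or sex fails loudly.
#'
#' @param breed,sex character vectors of per-sample labels.
#' @return An object of class `fixed_design`: list with `X` (n x K dummy
#'   matrix, no intercept column), `effect_names`, and the level sets.
#' @export
build_design <- function(breed, sex) {
  if (length(breed) != length(sex)) stop("breed and sex differ in length")
  if (length(breed) < 1L) stop("at least one sample required")
  lev_b <- sort(unique(as.character(breed)))
  lev_s <- sort(unique(as.character(sex)))
  X <- design_columns(breed, sex, lev_b, lev_s)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    drop <- setdiff(seq_len(ncol(X) + 1L), qx$pivot[seq_len(qx$rank)]) - 1L
    stop("fixed-effects design is rank deficient; confounded columns: ",
         paste(colnames(X)[drop], collapse = ", "))
  }
  structure(list(X = X, effect_names = colnames(X),
                 breed_levels = lev_b, sex_levels = lev_s),
            class = "fixed_design")
}

design_columns <- function(breed, sex, lev_b, lev_s) {
  n <- length(breed)
  cols <- list()
  if (length(lev_b) > 1L)
    for (l in lev_b[-1L]) cols[[paste0("breed", l)]] <- as.numeric(breed == l)
  if (length(lev_s) > 1L)
    for (l in lev_s[-1L]) cols[[paste0("sex", l)]] <- as.numeric(sex == l)
  if (length(cols) == 0L)
    return(matrix(0, n, 0))
  do.call(cbind, cols)
}

# design rows for new samples under the training coding; unseen level -> error
design_rows <- function(d, breed, sex) {
  bad_b <- setdiff(unique(as.character(breed)), d$breed_levels)
  bad_s <- setdiff(unique(as.character(sex)), d$sex_levels)
  if (length(bad_b) || length(bad_s))
    stop("unseen factor level at prediction time: ",
         paste(c(bad_b, bad_s), collapse = ", "))
  design_columns(breed, sex, d$breed_levels, d$sex_levels)
}
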