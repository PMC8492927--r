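#' Construct a phenotype vector
#'
#' One trait's observed values, aligned with a companion `genotype_matrix`
#' by sample order. Binary traits are coded 0/1; `NA` marks missing.
#'
#' @param values numeric vector; for `trait_kind = "binary"` non-missing
#'   entries must be 0 or 1.
#' @param trait_kind "continuous" or "binary".
#' @param trait_name short trait label used in outputs.
#' @param ids optional sample ids used as names.
#' @return An object of class `phenotype_vector` (a named numeric vector
#'   with `trait_kind` and `trait_name` attributes).
#' @export
phenotype_vector <- function(values, trait_kind = c("continuous", "binary"),
                             trait_name = "trait", ids = NULL) {
  trait_kind <- match.arg(trait_kind)
  values <- as.numeric(values)
  if (trait_kind == "binary") {
    ok <- is.na(values) | values %in% c(0, 1)
    if (!all(ok)) stop("binary trait values must be 0, 1 or NA")
  }
  if (!is.null(ids)) names(values) <- as.character(ids)
  structure(values, trait_kind = trait_kind, trait_name = trait_name,
            class = c("phenotype_vector", "numeric"))
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector '%s' (%s): n = %d, missing = %d\n",
              attr(x, "trait_name"), attr(x, "trait_kind"),
              length(x), sum(is.na(x))))
  print(utils::head(as.numeric(x)))
  invisible(x)
}

trait_kind <- function(y) attr(y, "trait_kind")

#' Average the Norberg angle over both hips
#'
#' A dog receives the mean of its left and right hip angles; if either
#' side is missing the dog's value is missing.
#'
#' @param left,right numeric vectors of per-dog angles in degrees.
#' @param ids optional sample ids.
#' @return A continuous `phenotype_vector` named "norberg_angle".
#' @export
average_norberg <- function(left, right, ids = NULL) {
  if (length(left) != length(right))
    stop("left and right angle vectors differ in length")
  vals <- (left + right) / 2  # NA if either side NA
  phenotype_vector(vals, "continuous", "norberg_angle", ids)
}

#' Truncate low Norberg angles to a floor
#'
#' Angles below the floor are set to the floor, pulling in the long left
#' tail so the trait better approximates a normal distribution. Default
#' floor 75 degrees.
#'
#' @param y a continuous `phenotype_vector`.
#' @param floor angle in degrees.
#' @return The truncated `phenotype_vector`.
#' @export
truncate_norberg <- function(y, floor = 75) {
  if (trait_kind(y) != "continuous")
    stop("truncate_norberg expects a continuous trait")
  vals <- unclass(y)
  vals[!is.na(vals) & vals < floor] <- floor
  phenotype_vector(vals, "continuous", attr(y, "trait_name"), names(y))
}

#' Binarize the Norberg angle into case/control
#'
#' Angles below the cutoff (default 105 degrees) are cases (1): a lower
#' angle means poorer femoral-head coverage. The boundary value itself is
#' a control (0).
#'
#' @param y a continuous `phenotype_vector` of angles.
#' @param cutoff angle in degrees.
#' @return A binary `phenotype_vector`.
#' @export
binarize_norberg <- function(y, cutoff = 105) {
  if (trait_kind(y) != "continuous")
    stop("binarize_norberg expects a continuous trait")
  vals <- unclass(y)
  out <- ifelse(is.na(vals), NA_real_, as.numeric(vals < cutoff))
  phenotype_vector(out, "binary",
                   paste0(attr(y, "trait_name"), "_case"), names(y))
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with header columns `id`, `breed`, `sex`, `na_left`,
#' `na_right`, `rccl`, `weight_kg`. Empty fields and "NA" are missing.
#'
#' @param path TSV file path.
#' @return A data.frame with those columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("id", "breed", "sex", "na_left", "na_right", "rccl", "weight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df
}

#' Align a phenotype table row order to a genotype matrix
#'
#' @param pheno data.frame with an `id` column.
#' @param g a `genotype_matrix`.
#' @return `pheno` reordered to `g`'s sample order; errors if any
#'   genotyped sample is absent from the table.
#' @export
align_phenotypes <- function(pheno, g) {
  m <- match(g$samples$id, pheno$id)
  if (anyNA(m))
    stop("phenotype table is missing samples: ",
         paste(g$samples$id[is.na(m)][1:3], collapse = ", "))
  pheno[m, , drop = FALSE]
}
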