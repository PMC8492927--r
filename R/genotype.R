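#' Construct a genotype matrix object
#'
#' The central container of the package: an `n x L` allele-dosage matrix
#' (counts of the A1/ALT allele, values 0/1/2, `NA` for missing) together
#' with a marker map and per-sample breed/sex metadata.
#'
#' @param dosages numeric or integer matrix, samples in rows, markers in
#'   columns. Non-missing entries must be 0, 1 or 2.
#' @param marker_ids character vector of unique marker names (length `L`).
#' @param chrom character vector of chromosome labels per marker.
#' @param pos_bp integer vector of 1-based physical positions; must be
#'   strictly increasing within each chromosome.
#' @param sample_ids character vector of unique sample names (length `n`).
#' @param breed,sex character vectors of per-sample labels. `sex` uses
#'   "M"/"F"; unknown values are allowed and kept as-is.
#' @param a1,a2 allele labels per marker; `a1` is the counted allele.
#' @return An object of class `genotype_matrix` with components `dosages`
#'   (dimnamed matrix), `map` (data.frame: marker_id, chrom, pos_bp, a1, a2)
#'   and `samples` (data.frame: id, breed, sex).
#' @export
genotype_matrix <- function(dosages, marker_ids, chrom, pos_bp,
                            sample_ids, breed, sex,
                            a1 = NULL, a2 = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  L <- ncol(dosages)
  if (n < 2L) stop("genotype_matrix requires at least 2 samples")
  if (L < 1L) stop("genotype_matrix requires at least 1 marker")
  if (length(marker_ids) != L || length(chrom) != L || length(pos_bp) != L)
    stop("marker map length does not match number of dosage columns")
  if (length(sample_ids) != n || length(breed) != n || length(sex) != n)
    stop("sample metadata length does not match number of dosage rows")
  if (anyDuplicated(marker_ids)) stop("marker_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ", dosages[which(bad)[1L]])
  pos_bp <- as.integer(pos_bp)
  if (any(pos_bp < 1L, na.rm = TRUE)) stop("pos_bp must be positive (1-based)")
  for (ch in unique(chrom)) {
    p <- pos_bp[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("pos_bp must be strictly increasing within chromosome ", ch)
  }
  if (is.null(a1)) a1 <- rep("A", L)
  if (is.null(a2)) a2 <- rep("G", L)
  dimnames(dosages) <- list(as.character(sample_ids), as.character(marker_ids))
  structure(list(
    dosages = dosages,
    map = data.frame(marker_id = as.character(marker_ids),
                     chrom = as.character(chrom),
                     pos_bp = pos_bp,
                     a1 = as.character(a1), a2 = as.character(a2),
                     stringsAsFactors = FALSE),
    samples = data.frame(id = as.character(sample_ids),
                         breed = as.character(breed),
                         sex = as.character(sex),
                         stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers\n",
              nrow(x$dosages), ncol(x$dosages)))
  tb <- table(x$samples$breed)
  cat("breeds:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("missing dosages: %d\n", sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

n_samples <- function(g) nrow(g$dosages)
n_markers <- function(g) ncol(g$dosages)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (integer, logical or character).
#' @param j marker index (integer, logical or character).
#' @param ... ignored.
#' @return A `genotype_matrix` with metadata subset in step.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$map$marker_id)
  d <- x$dosages[i, j, drop = FALSE]
  map <- x$map[j, , drop = FALSE]
  smp <- x$samples[i, , drop = FALSE]
  genotype_matrix(d, map$marker_id, map$chrom, map$pos_bp,
                  smp$id, smp$breed, smp$sex, map$a1, map$a2)
}

# ---- PLINK binary (.bed/.bim/.fam) ------------------------------------------
# SNP-major v1.00 layout: magic bytes 0x6c 0x1b 0x01, then ceil(n/4) bytes per
# marker. Two-bit codes, least-significant pair first: 00 = hom A1 (dosage 2),
# 01 = missing, 10 = het, 11 = hom A2 (dosage 0).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype matrix as a PLINK bed/bim/fam triple
#'
#' The .fam family ID column carries the breed label and the sex column the
#' usual 1 = male / 2 = female code, so breed and sex survive a round trip.
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- n_samples(g); L <- n_markers(g)
  sexcode <- ifelse(g$samples$sex == "M", 1L, ifelse(g$samples$sex == "F", 2L, 0L))
  fam <- data.frame(g$samples$breed, g$samples$id, 0L, 0L, sexcode, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bim <- data.frame(g$map$chrom, g$map$marker_id, 0L, g$map$pos_bp,
                    g$map$a1, g$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # map dosage -> 2-bit code
  codes <- matrix(1L, n, L)  # default: missing (01)
  d <- g$dosages
  codes[!is.na(d) & d == 2] <- 0L
  codes[!is.na(d) & d == 1] <- 2L
  codes[!is.na(d) & d == 0] <- 3L
  bpm <- ceiling(n / 4)
  pad <- bpm * 4L - n
  if (pad > 0L) codes <- rbind(codes, matrix(0L, pad, L))
  # pack 4 samples per byte, low bits first
  i1 <- seq(1L, bpm * 4L, by = 4L)
  bytes <- codes[i1, , drop = FALSE] +
    codes[i1 + 1L, , drop = FALSE] * 4L +
    codes[i1 + 2L, , drop = FALSE] * 16L +
    codes[i1 + 3L, , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triple
#'
#' Dosages count the A1 allele (PLINK convention). Breed is taken from the
#' .fam family ID and sex from the .fam sex code; a `sample_info` table
#' (columns `id`, `breed`, `sex`) overrides both when supplied.
#'
#' @param prefix path without extension; `prefix.bed/.bim/.fam` must exist.
#' @param sample_info optional data.frame with per-sample metadata.
#' @return A `genotype_matrix`.
#' @export
read_plink <- function(prefix, sample_info = NULL) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  famdf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bimdf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "numeric",
                                            "integer", "character", "character"))
  n <- nrow(famdf); L <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("format error: ", bed, " lacks the PLINK v1.00 SNP-major magic bytes")
  bpm <- ceiling(n / 4)
  if (length(raw) - 3L != bpm * L)
    stop("consistency error: ", bed, " holds ", length(raw) - 3L,
         " genotype bytes but .bim/.fam imply ", bpm * L)
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, low bits first
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = bpm * 4L, ncol = L)[seq_len(n), ,
                                                               drop = FALSE]
  lut <- c(2, NA, 1, 0)  # code 0,1,2,3 -> dosage
  d <- matrix(lut[codes + 1L], n, L)
  breed <- as.character(famdf[[1L]])
  sex <- c("M", "F")[match(famdf[[5L]], c(1L, 2L))]
  sex[is.na(sex)] <- "U"
  ids <- as.character(famdf[[2L]])
  if (!is.null(sample_info)) {
    m <- match(ids, sample_info$id)
    if (anyNA(m)) stop("sample_info is missing ids: ",
                       paste(ids[is.na(m)][1:3], collapse = ", "))
    breed <- as.character(sample_info$breed[m])
    sex <- as.character(sample_info$sex[m])
  }
  genotype_matrix(d, bimdf[[2L]], bimdf[[1L]], bimdf[[4L]],
                  ids, breed, sex, bimdf[[5L]], bimdf[[6L]])
}

# ---- VCF --------------------------------------------------------------------

#' Write a genotype matrix as an uncompressed VCF
#'
#' REF is the A2 allele and ALT the counted A1 allele, so dosages keep the
#' same meaning in both supported formats. Genotypes are written unphased.
#'
#' @param g a `genotype_matrix`.
#' @param path output file ending in `.vcf`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  n <- n_samples(g); L <- n_markers(g)
  gt <- matrix("./.", L, n)
  d <- t(g$dosages)  # markers x samples
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples$id), collapse = "\t"))
  body <- paste(g$map$chrom, g$map$pos_bp, g$map$marker_id,
                g$map$a2, g$map$a1, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses `vcfR` for parsing. Dosages count the ALT allele. Multiallelic
#' records are rejected. Breed/sex metadata must come from `sample_info`
#' (VCF carries none); without it both are set to "U".
#'
#' @param path a VCF file (plain or bgzipped).
#' @param sample_info optional data.frame with columns `id`, `breed`, `sex`.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, sample_info = NULL) {
  if (!file.exists(path)) stop("missing VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multiallelic VCF record not supported: ",
         fix[multi, "CHROM"][1L], ":", fix[multi, "POS"][1L],
         " (", fix[multi, "ID"][1L], ")")
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles in a diploid GT string, tolerate phased separators
  cnt <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(z) {
      if (any(z == "." | is.na(z))) return(NA_real_)
      sum(z == "1")
    }, numeric(1))
  }
  d <- t(apply(gt, 1L, cnt))          # markers x samples
  if (ncol(gt) == 1L) d <- t(d)       # apply() drops dims for one sample
  d <- t(d)                           # samples x markers
  ids <- colnames(gt)
  breed <- rep("U", length(ids)); sex <- rep("U", length(ids))
  if (!is.null(sample_info)) {
    m <- match(ids, sample_info$id)
    if (anyNA(m)) stop("sample_info is missing ids: ",
                       paste(ids[is.na(m)][1:3], collapse = ", "))
    breed <- as.character(sample_info$breed[m])
    sex <- as.character(sample_info$sex[m])
  }
  ord <- order(fix[, "CHROM"], as.integer(fix[, "POS"]))
  genotype_matrix(d[, ord, drop = FALSE], fix[ord, "ID"], fix[ord, "CHROM"],
                  as.integer(fix[ord, "POS"]), ids, breed, sex,
                  fix[ord, "ALT"], fix[ord, "REF"])
}

#' Read genotypes from PLINK binary or VCF
#'
#' @param path PLINK prefix (no extension) or a `.vcf` file.
#' @param format "plink-bed" or "vcf"; inferred from `path` when missing.
#' @param sample_info optional data.frame with columns `id`, `breed`, `sex`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("plink-bed", "vcf"),
                           sample_info = NULL) {
  if (missing(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink-bed"
  format <- match.arg(format)
  switch(format,
         "plink-bed" = read_plink(sub("\\.bed$", "", path), sample_info),
         "vcf" = read_vcf(path, sample_info))
}

#' Write genotypes to PLINK binary or VCF
#'
#' @param g a `genotype_matrix`.
#' @param path PLINK prefix or `.vcf` path.
#' @param format "plink-bed" or "vcf"; inferred from `path` when missing.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("plink-bed", "vcf")) {
  if (missing(format))
    format <- if (grepl("\\.vcf$", path)) "vcf" else "plink-bed"
  format <- match.arg(format)
  switch(format,
         "plink-bed" = write_plink(g, sub("\\.bed$", "", path)),
         "vcf" = write_vcf(g, path))
}

#' Drop markers with any missing genotype call
#'
#' Mirrors the common array-QC step of keeping only completely observed
#' SNPs before model fitting. Column order is preserved.
#'
#' @param g a `genotype_matrix`.
#' @return A `genotype_matrix` with only fully observed markers.
#' @export
drop_incomplete_markers <- function(g) {
  keep <- colSums(is.na(g$dosages)) == 0L
  if (!any(keep))
    stop("empty panel: every marker has at least one missing genotype")
  if (all(keep)) return(g)
  g[, which(keep)]
}
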