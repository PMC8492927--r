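#' Construct a gene interval table
#'
#' Candidate-gene regions used to pick "associated" markers. Coordinates
#' are 1-based closed; each interval is widened by `extension_bp` on both
#' sides (clamped at position 1) before overlap.
#'
#' @param chrom,start_bp,end_bp,gene vectors describing the intervals.
#' @param extension_bp flank added to both boundaries, default 10 kb.
#' @return An object of class `gene_intervals`.
#' @export
gene_intervals <- function(chrom, start_bp, end_bp, gene,
                           extension_bp = 10000L) {
  start_bp <- as.integer(start_bp); end_bp <- as.integer(end_bp)
  if (any(start_bp > end_bp))
    stop("gene interval with start_bp > end_bp: ",
         gene[which(start_bp > end_bp)[1L]])
  if (extension_bp < 0) stop("extension_bp must be non-negative")
  structure(list(
    records = data.frame(chrom = as.character(chrom), start_bp = start_bp,
                         end_bp = end_bp, gene = as.character(gene),
                         stringsAsFactors = FALSE),
    extension_bp = as.integer(extension_bp)
  ), class = "gene_intervals")
}

#' Read a gene interval TSV
#'
#' Expects header columns `chrom`, `start`, `end`, `gene`. BED-style
#' half-open 0-based input is converted to 1-based closed coordinates
#' with `coords = "bed"`.
#'
#' @param path TSV file path.
#' @param extension_bp flank in bp, default 10 kb.
#' @param coords "1-based" (default) or "bed".
#' @return A `gene_intervals` object.
#' @export
read_gene_intervals <- function(path, extension_bp = 10000L,
                                coords = c("1-based", "bed")) {
  coords <- match.arg(coords)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene interval table lacks columns: ", paste(miss, collapse = ", "))
  start <- df$start; end <- df$end
  if (coords == "bed") start <- start + 1L
  gene_intervals(df$chrom, start, end, df$gene, extension_bp)
}

#' Select markers inside candidate-gene regions
#'
#' Keeps markers whose position falls in any extended gene interval
#' (closed interval `[start - ext, end + ext]`, union over genes, no
#' duplicates). Overlap is computed with GenomicRanges.
#'
#' @param g a `genotype_matrix`.
#' @param genes a `gene_intervals` object.
#' @return A `genotype_matrix` restricted to the associated panel.
#' @export
select_associated_markers <- function(g, genes) {
  rec <- genes$records
  ext <- genes$extension_bp
  gr_genes <- GenomicRanges::GRanges(
    rec$chrom,
    IRanges::IRanges(pmax(1L, rec$start_bp - ext), rec$end_bp + ext))
  gr_mark <- GenomicRanges::GRanges(
    g$map$chrom, IRanges::IRanges(g$map$pos_bp, g$map$pos_bp))
  # GenomicRanges warns on disjoint seqlevels; we raise our own clearer
  # warning below when no chromosome names are shared
  keep <- which(suppressWarnings(IRanges::overlapsAny(gr_mark, gr_genes)))
  if (length(keep) == 0L) {
    shared <- intersect(unique(g$map$chrom), unique(rec$chrom))
    if (length(shared) == 0L)
      warning("no chromosome names shared between markers and gene table")
    stop("empty panel: no marker overlaps any extended gene interval")
  }
  g[, keep]
}

#' Select a random marker panel
#'
#' Uniform sample of `k` markers without replacement, reproducible for a
#' given seed; the output keeps the original marker order.
#'
#' @param g a `genotype_matrix`.
#' @param k panel size.
#' @param seed integer seed.
#' @return A `genotype_matrix` with `k` markers.
#' @export
select_random_markers <- function(g, k, seed) {
  L <- n_markers(g)
  if (k > L) stop("requested ", k, " markers from a panel of ", L)
  idx <- with_seed(seed, sort(sample.int(L, k)))
  g[, idx]
}

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
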