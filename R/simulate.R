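#' Specify one breed for the genotype simulator
#'
#' @param name breed label.
#' @param n_dogs number of sampled dogs (>= 1).
#' @param fst divergence of the breed from the ancestral population,
#'   in (0, 0.5].
#' @param sex_ratio proportion of males.
#' @return A `breed_spec` list.
#' @export
breed_spec <- function(name, n_dogs, fst = 0.1, sex_ratio = 0.5) {
  if (n_dogs < 1L) stop("n_dogs must be >= 1")
  if (fst <= 0 || fst > 0.5) stop("fst must be in (0, 0.5]")
  structure(list(name = name, n_dogs = as.integer(n_dogs), fst = fst,
                 sex_ratio = sex_ratio), class = "breed_spec")
}

#' Default six-breed study population
#'
#' Breed census mirroring a multi-breed orthopedic cohort (Labrador
#' Retriever-dominated, five further breeds) at half scale for
#' desk-speed analyses, with a common divergence of Fst = 0.1 — a
#' typical between-breed value for domestic dogs.
#'
#' @param scale multiplier on the default breed sizes.
#' @param fst shared divergence parameter.
#' @return A list of six `breed_spec`s.
#' @export
default_breeds <- function(scale = 1, fst = 0.1) {
  sizes <- c(LabradorRetriever = 199L, GoldenRetriever = 69L,
             GermanShepherd = 49L, EnglishSetter = 40L,
             Newfoundland = 34L, Rottweiler = 31L)
  mapply(function(nm, n) breed_spec(nm, max(2L, round(n * scale)), fst),
         names(sizes), sizes, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Simulate multi-breed genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each breed's
#' frequency at a marker is Beta-distributed around the ancestral value
#' with spread set by the breed's Fst; dosages are Binomial(2, p_breed).
#' Markers are laid out on `n_chrom` chromosomes with strictly
#' increasing positions. No linkage disequilibrium is simulated.
#'
#' @param breeds list of [breed_spec()]s.
#' @param L number of markers.
#' @param seed integer seed.
#' @param n_chrom chromosomes to spread markers over (default 38
#'   autosomes, fewer if `L` is small).
#' @return A `genotype_matrix`; the per-breed frequencies are attached
#'   as attribute `breed_freqs` (breeds x markers).
#' @export
simulate_genotypes <- function(breeds, L, seed = 1L, n_chrom = 38L) {
  if (L < 1L) stop("L must be >= 1")
  if (inherits(breeds, "breed_spec")) breeds <- list(breeds)
  n_chrom <- max(1L, min(n_chrom, L))
  ntot <- sum(vapply(breeds, `[[`, integer(1), "n_dogs"))
  with_seed(seed, {
    p_anc <- stats::runif(L, 0.05, 0.95)
    chrom <- sort(rep_len(seq_len(n_chrom), L))
    pos <- integer(L)
    for (ch in seq_len(n_chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(1e8L, length(idx)))
    }
    dos <- matrix(NA_real_, ntot, L)
    breed_lab <- character(ntot); sex_lab <- character(ntot)
    ids <- character(ntot)
    freqs <- matrix(NA_real_, length(breeds), L)
    at <- 0L
    for (bi in seq_along(breeds)) {
      b <- breeds[[bi]]
      th <- (1 - b$fst) / b$fst
      pb <- stats::rbeta(L, p_anc * th, (1 - p_anc) * th)
      pb <- pmin(pmax(pb, 1e-6), 1 - 1e-6)
      freqs[bi, ] <- pb
      rows <- at + seq_len(b$n_dogs)
      dos[rows, ] <- matrix(
        stats::rbinom(b$n_dogs * L, 2L, rep(pb, each = b$n_dogs)),
        b$n_dogs, L)
      breed_lab[rows] <- b$name
      sex_lab[rows] <- ifelse(stats::runif(b$n_dogs) < b$sex_ratio, "M", "F")
      ids[rows] <- sprintf("%s_%03d", abbreviate(b$name, 4), seq_len(b$n_dogs))
      at <- at + b$n_dogs
    }
  })
  g <- genotype_matrix(dos, sprintf("snp%05d", seq_len(L)),
                       paste0("chr", chrom), pos, ids, breed_lab, sex_lab)
  attr(g, "breed_freqs") <- freqs
  g
}

#' Specify an additive QTN trait simulation
#'
#' @param n_qtn number of causal markers (default 20).
#' @param heritability `"sample"` (per-breed h2 drawn Uniform(0.2, 0.8)),
#'   a single value shared by all breeds, or a named per-breed vector.
#' @param sex_effect additive shift for males, in residual-SD-free trait
#'   units (default 0).
#' @param seed integer seed.
#' @return A `trait_sim_spec` list.
#' @export
trait_sim_spec <- function(n_qtn = 20L, heritability = "sample",
                           sex_effect = 0, seed = 1L) {
  if (n_qtn < 1L) stop("n_qtn must be >= 1")
  if (is.numeric(heritability) &&
      any(heritability < 0 | heritability > 1))
    stop("heritability must lie in [0, 1]")
  structure(list(n_qtn = as.integer(n_qtn), heritability = heritability,
                 sex_effect = sex_effect, seed = seed),
            class = "trait_sim_spec")
}

#' Simulate an additive quantitative trait
#'
#' A fixed set of QTNs is drawn uniformly from the polymorphic markers —
#' the same causal positions for every breed — with standard-normal
#' allele-substitution effects. Per-breed residual variance is scaled so
#' each breed's heritability (genetic variance over total, within breed)
#' matches its target; with `heritability = "sample"` targets are drawn
#' Uniform(0.2, 0.8) per breed.
#'
#' @param g a `genotype_matrix` (complete dosages).
#' @param spec a [trait_sim_spec()].
#' @return A continuous `phenotype_vector` with attribute `truth`: list
#'   with `qtn_ids`, `qtn_idx`, `effects`, `g_true` (genetic values),
#'   `h2_by_breed`, `sigma_e2_by_breed`.
#' @export
simulate_phenotype <- function(g, spec = trait_sim_spec()) {
  M <- g$dosages
  p <- colMeans(M) / 2
  poly <- which(p > 0 & p < 1)
  if (spec$n_qtn > length(poly))
    stop("n_qtn (", spec$n_qtn, ") exceeds the ", length(poly),
         " polymorphic markers")
  breeds <- unique(g$samples$breed)
  with_seed(spec$seed, {
    qtn <- sort(sample(poly, spec$n_qtn))
    eff <- stats::rnorm(spec$n_qtn)
    g_true <- drop(M[, qtn, drop = FALSE] %*% eff)
    h2tab <- if (identical(spec$heritability, "sample")) {
      stats::setNames(stats::runif(length(breeds), 0.2, 0.8), breeds)
    } else if (length(spec$heritability) == 1L && is.null(names(spec$heritability))) {
      stats::setNames(rep(spec$heritability, length(breeds)), breeds)
    } else {
      miss <- setdiff(breeds, names(spec$heritability))
      if (length(miss)) stop("heritability missing for breeds: ",
                             paste(miss, collapse = ", "))
      spec$heritability[breeds]
    }
    y <- numeric(nrow(M))
    se2 <- stats::setNames(numeric(length(breeds)), breeds)
    for (b in breeds) {
      rows <- which(g$samples$breed == b)
      vg <- if (length(rows) > 1L) stats::var(g_true[rows]) else 0
      h2 <- h2tab[[b]]
      if (h2 <= 0) {
        # pure-noise limit: no genetic contribution at all
        se2[b] <- max(vg, 1)
        y[rows] <- stats::rnorm(length(rows), 0, sqrt(se2[b]))
      } else {
        se2[b] <- if (h2 >= 1) 0 else vg * (1 - h2) / h2
        y[rows] <- g_true[rows] + stats::rnorm(length(rows), 0, sqrt(se2[b]))
      }
    }
    if (spec$sex_effect != 0)
      y <- y + spec$sex_effect * as.numeric(g$samples$sex == "M")
  })
  out <- phenotype_vector(y, "continuous", "simulated_trait", g$samples$id)
  attr(out, "truth") <- list(qtn_ids = g$map$marker_id[qtn], qtn_idx = qtn,
                             effects = eff, g_true = g_true,
                             h2_by_breed = h2tab, sigma_e2_by_breed = se2)
  out
}

#' Simulate a binary trait by thresholding a liability
#'
#' The continuous liability from [simulate_phenotype()] is dichotomized
#' at its empirical `(1 - prevalence)` quantile: the `round(n *
#' prevalence)` highest-liability dogs are cases (ties broken by sample
#' order).
#'
#' @param g a `genotype_matrix`.
#' @param spec a [trait_sim_spec()].
#' @param prevalence case fraction in (0, 1).
#' @return A binary `phenotype_vector` carrying the liability `truth`
#'   attribute.
#' @export
simulate_binary_trait <- function(g, spec = trait_sim_spec(),
                                  prevalence = 0.5) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  liab <- simulate_phenotype(g, spec)
  n <- length(liab)
  n_case <- round(n * prevalence)
  ord <- order(as.numeric(liab), decreasing = TRUE)
  lab <- numeric(n)
  lab[ord[seq_len(n_case)]] <- 1
  out <- phenotype_vector(lab, "binary", "simulated_binary", g$samples$id)
  attr(out, "truth") <- attr(liab, "truth")
  attr(out, "liability") <- as.numeric(liab)
  out
}

#' Write a miniature multi-breed study fixture
#'
#' Emits a complete, deterministic study in plain formats: PLINK
#' bed/bim/fam genotypes for 300 dogs of six breeds at 2,000 markers; a
#' phenotype TSV with a hip-angle-like continuous trait (left/right
#' measurements around a genetic liability, some missing), a binary
#' trait, and a weight-like trait; a gene-interval TSV whose intervals
#' each contain at least one true QTN; and a truth-record JSON.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed; regeneration is byte-identical.
#' @param n_dogs,L population and panel size of the bundle.
#' @return Named list of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, seed = 1L, n_dogs = 300L,
                                 L = 2000L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sizes <- round(n_dogs * c(0.45, 0.16, 0.12, 0.10, 0.09, 0.08))
  sizes[1L] <- n_dogs - sum(sizes[-1L])
  nm <- c("LabradorRetriever", "GoldenRetriever", "GermanShepherd",
          "EnglishSetter", "Newfoundland", "Rottweiler")
  breeds <- mapply(breed_spec, nm, sizes, MoreArgs = list(fst = 0.1),
                   SIMPLIFY = FALSE)
  g <- simulate_genotypes(breeds, L, seed = seed)
  liab <- simulate_phenotype(g, trait_sim_spec(n_qtn = 20,
                                               heritability = "sample",
                                               seed = seed + 1L))
  truth <- attr(liab, "truth")
  rccl <- simulate_binary_trait(g, trait_sim_spec(n_qtn = 20,
                                                  heritability = "sample",
                                                  seed = seed + 2L),
                                prevalence = 0.44)
  weight <- simulate_phenotype(g, trait_sim_spec(n_qtn = 20,
                                                 heritability = 0.6,
                                                 seed = seed + 3L))
  with_seed(seed + 4L, {
    z <- scale(as.numeric(liab))
    na_true <- 103 - 7 * drop(z)  # higher liability -> worse (lower) angle
    na_left <- round(na_true + stats::rnorm(n_dogs, 0, 1.5), 1)
    na_right <- round(na_true + stats::rnorm(n_dogs, 0, 1.5), 1)
    miss <- sample.int(n_dogs, max(3L, round(0.05 * n_dogs)))
    na_left[miss] <- NA
    wkg <- round(30 + 6 * drop(scale(as.numeric(weight))), 1)
    rccl_col <- as.numeric(rccl)
    rccl_col[sample.int(n_dogs, round(0.1 * n_dogs))] <- NA
  })
  paths <- list(plink = file.path(outdir, "study"),
                pheno = file.path(outdir, "phenotypes.tsv"),
                genes = file.path(outdir, "genes.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_plink(g, paths$plink)
  ph <- data.frame(id = g$samples$id, breed = g$samples$breed,
                   sex = g$samples$sex, na_left = na_left,
                   na_right = na_right, rccl = rccl_col,
                   weight_kg = wkg)
  utils::write.table(ph, paths$pheno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # intervals around the first 5 QTNs, 5 kb each side
  qi <- truth$qtn_idx[1:5]
  genes <- data.frame(chrom = g$map$chrom[qi],
                      start = pmax(1L, g$map$pos_bp[qi] - 5000L),
                      end = g$map$pos_bp[qi] + 5000L,
                      gene = sprintf("GENE%02d", seq_along(qi)))
  utils::write.table(genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, qtn_ids = truth$qtn_ids, effects = truth$effects,
         h2_by_breed = as.list(truth$h2_by_breed)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
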