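#' Build repeated k-fold cross-validation fold assignments
#'
#' Three sampling strategies:
#' * `"random"` — the whole population is shuffled and split into
#'   near-equal folds each round.
#' * `"single_breed"` — only dogs of `target_breed` are folded; all other
#'   dogs are excluded from the analysis entirely.
#' * `"single_breed_augmented"` — the target breed is folded exactly as
#'   in `"single_breed"` (identical validation sets for the same seed),
#'   but every other dog stays permanently in the reference panel.
#'
#' Folds are formed by shuffling then block-splitting; remainder samples
#' are spread one per fold, so fold sizes differ by at most one.
#'
#' @param samples a `genotype_matrix` or a data.frame with columns `id`
#'   and `breed`.
#' @param strategy one of the three strategy names above.
#' @param target_breed breed label, required for the single-breed
#'   strategies.
#' @param n_folds folds per round (default 5).
#' @param n_rounds repetitions (default 100).
#' @param seed integer seed; plans are reproducible.
#' @return A `cv_plan`: list with `assign` (n x n_rounds integer matrix;
#'   fold number, `0` = always-reference, `NA` = excluded), `strategy`,
#'   `target_breed`, `n_folds`, `n_rounds`, `seed`, `ids`.
#' @export
make_folds <- function(samples,
                       strategy = c("random", "single_breed",
                                    "single_breed_augmented"),
                       target_breed = NULL, n_folds = 5L, n_rounds = 100L,
                       seed = 1L) {
  strategy <- match.arg(strategy)
  if (inherits(samples, "genotype_matrix")) samples <- samples$samples
  n <- nrow(samples)
  if (strategy == "random") {
    eligible <- seq_len(n)
  } else {
    if (is.null(target_breed))
      stop("target_breed is required for single-breed strategies")
    if (!target_breed %in% samples$breed)
      stop("unknown breed label: ", target_breed)
    eligible <- which(samples$breed == target_breed)
  }
  if (length(eligible) < n_folds)
    stop("only ", length(eligible), " eligible samples for ", n_folds,
         " folds")
  assign <- matrix(NA_integer_, n, n_rounds)
  if (strategy == "single_breed_augmented") assign[-eligible, ] <- 0L
  with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      perm <- sample(eligible)
      assign[perm, r] <- balanced_fold_labels(length(perm), n_folds)
    }
  })
  rownames(assign) <- samples$id
  structure(list(assign = assign, strategy = strategy,
                 target_breed = target_breed, n_folds = as.integer(n_folds),
                 n_rounds = as.integer(n_rounds), seed = seed,
                 ids = samples$id),
            class = "cv_plan")
}

# fold labels for m shuffled samples: blocks of floor(m/f), remainder
# spread one per fold
balanced_fold_labels <- function(m, f) {
  base <- m %/% f; rem <- m %% f
  rep(seq_len(f), times = base + (seq_len(f) <= rem))
}

#' Run repeated cross-validation for a prediction model
#'
#' For every round and fold the model is fitted on the reference panel
#' and used to predict the validation panel; accuracy is the Pearson
#' correlation between predictions and observed phenotypes, plus AUC
#' against case/control labels where available. Folds whose validation
#' set has fewer than 3 phenotyped dogs, or a constant phenotype, are
#' skipped with a warning and excluded from aggregation. Per-round fold
#' means are computed first; the summary reports their mean and SD
#' across rounds.
#'
#' @param plan a `cv_plan` from [make_folds()].
#' @param y a `phenotype_vector` aligned with `g` (missing allowed;
#'   unphenotyped dogs are dropped from both panels).
#' @param g a `genotype_matrix` with complete dosages.
#' @param model "gblup" or "bayesc".
#' @param config list of model settings:
#'   * `gblup_method`: "closed_form" (REML per fold; default) or "gibbs";
#'   * `vc`: optional fixed `variance_components` (skips REML);
#'   * `chain`: MCMC settings for the samplers;
#'   * `priors`: [bayesc_priors()] for BayesC;
#'   * `binarize_cutoff`: for continuous angle traits, derive
#'     case/control labels at this cutoff (case = below) and score AUC on
#'     negated predictions (lower predicted angle = more likely case);
#'   * `seed`: base seed for per-fold model seeds.
#' @return A `cv_result`: `folds` data.frame (round, fold, n_train,
#'   n_valid, pearson_r, auc, skipped), `rounds` data.frame of per-round
#'   means, and a `summary` list (mean_r, sd_r, mean_auc, sd_auc,
#'   n_skipped).
#' @export
run_cv <- function(plan, y, g, model = c("gblup", "bayesc"),
                   config = list()) {
  model <- match.arg(model)
  cfg <- utils::modifyList(list(gblup_method = "closed_form", vc = NULL,
                                chain = NULL, priors = bayesc_priors(),
                                binarize_cutoff = NULL, seed = 1L),
                           config)
  if (is.null(cfg$chain))
    cfg$chain <- list(n_iter = 12000, burn_in = 2000, thin = 5)
  yv <- as.numeric(y)
  n <- length(yv)
  if (n != n_samples(g)) stop("phenotype/genotype dimension mismatch")
  if (nrow(plan$assign) != n) stop("plan does not match the data")
  binary <- trait_kind(y) == "binary"
  labels <- NULL; auc_sign <- 1
  if (binary) {
    labels <- yv
  } else if (!is.null(cfg$binarize_cutoff)) {
    labels <- as.numeric(yv < cfg$binarize_cutoff)
    auc_sign <- -1  # lower predicted angle scores higher case risk
  }
  kin <- if (model == "gblup") compute_grm(g) else NULL
  rows <- list()
  for (r in seq_len(plan$n_rounds)) {
    for (f in seq_len(plan$n_folds)) {
      a <- plan$assign[, r]
      valid <- which(a == f & !is.na(yv))
      train <- which(!is.na(a) & a != f & !is.na(yv))
      row <- data.frame(round = r, fold = f, n_train = length(train),
                        n_valid = length(valid), pearson_r = NA_real_,
                        auc = NA_real_, skipped = FALSE)
      if (length(valid) < 3L || length(train) < 3L ||
          stats::sd(yv[valid]) == 0 || stats::sd(yv[train]) == 0) {
        row$skipped <- TRUE
        warning("skipping round ", r, " fold ", f,
                ": validation too small or constant phenotype")
        rows[[length(rows) + 1L]] <- row
        next
      }
      fit_seed <- (cfg$seed * 1000L + r * 10L + f) %% .Machine$integer.max
      pred <- cv_fit_predict(model, cfg, yv, g, kin, train, valid, fit_seed)
      if (stats::sd(pred) > 0)
        row$pearson_r <- pearson(pred, yv[valid])
      if (!is.null(labels)) {
        lv <- labels[valid]
        if (length(unique(lv)) == 2L)
          row$auc <- auc(auc_sign * pred, lv)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  folds <- do.call(rbind, rows)
  ok <- !folds$skipped
  rounds <- stats::aggregate(cbind(pearson_r, auc) ~ round,
                             data = folds[ok, , drop = FALSE],
                             FUN = function(z) mean(z, na.rm = TRUE),
                             na.action = stats::na.pass)
  summ <- list(mean_r = mean(rounds$pearson_r, na.rm = TRUE),
               sd_r = stats::sd(rounds$pearson_r[!is.na(rounds$pearson_r)]),
               mean_auc = mean(rounds$auc, na.rm = TRUE),
               sd_auc = stats::sd(rounds$auc[!is.na(rounds$auc)]),
               n_skipped = sum(folds$skipped))
  structure(list(folds = folds, rounds = rounds, summary = summ,
                 model = model, strategy = plan$strategy),
            class = "cv_result")
}

cv_fit_predict <- function(model, cfg, yv, g, kin, train, valid, fit_seed) {
  smp <- g$samples
  d <- build_design(smp$breed[train], smp$sex[train])
  if (model == "gblup") {
    ktr <- subset_kinship(kin, train)
    fit <- if (cfg$gblup_method == "gibbs")
      fit_gblup_gibbs(yv[train], d, ktr, chain = cfg$chain, seed = fit_seed)
    else
      fit_gblup_closed_form(yv[train], d, ktr, vc = cfg$vc)
    predict(fit, K_cross = kin$K[valid, train, drop = FALSE],
            breed = smp$breed[valid], sex = smp$sex[valid])
  } else {
    fit <- fit_bayesc(yv[train], d, g[train, ], priors = cfg$priors,
                      chain = cfg$chain, seed = fit_seed)
    predict(fit, g[valid, ], breed = smp$breed[valid], sex = smp$sex[valid])
  }
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cv_result: %s / %s, %d rounds\n", x$model, x$strategy,
              nrow(x$rounds)))
  cat(sprintf("  mean r   = %.3f (SD %.3f)\n", s$mean_r, s$sd_r))
  if (!is.nan(s$mean_auc))
    cat(sprintf("  mean AUC = %.3f (SD %.3f)\n", s$mean_auc, s$sd_auc))
  if (s$n_skipped > 0) cat("  skipped folds:", s$n_skipped, "\n")
  invisible(x)
}

#' Write a cross-validation result as a tidy TSV
#'
#' One row per round x fold plus one aggregate row (`round = NA`).
#'
#' @param res a `cv_result`.
#' @param path output file.
#' @param model,trait,strategy labels recorded in the output columns.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(res, path, model = res$model, trait = "trait",
                            strategy = res$strategy) {
  df <- res$folds
  df$model <- model; df$trait <- trait; df$strategy <- strategy
  agg <- data.frame(round = NA_integer_, fold = NA_integer_,
                    n_train = NA_integer_, n_valid = NA_integer_,
                    pearson_r = res$summary$mean_r,
                    auc = res$summary$mean_auc, skipped = FALSE,
                    model = model, trait = trait, strategy = strategy)
  out <- rbind(df, agg)
  cols <- c("round", "fold", "model", "trait", "strategy", "n_train",
            "n_valid", "pearson_r", "auc", "skipped")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
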