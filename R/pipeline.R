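#' Read a pipeline run configuration
#'
#' A single YAML file describing one end-to-end analysis. Exactly one of
#' `genotypes` (paths to real data) or `simulate` (generator settings)
#' must be present. See [run_pipeline()] for the recognized keys.
#'
#' @param path YAML file.
#' @return The configuration list, validated.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  has_in <- !is.null(cfg$genotypes)
  has_sim <- !is.null(cfg$simulate)
  if (has_in == has_sim)
    stop("config error at top level: exactly one of 'genotypes' or ",
         "'simulate' must be present")
  if (is.null(cfg$seed)) stop("config error at 'seed': required")
  if (!is.null(cfg$panel) && !is.null(cfg$panel$type) &&
      !cfg$panel$type %in% c("all", "associated", "random"))
    stop("config error at 'panel.type': must be all, associated or random")
  if (!is.null(cfg$model) && !is.null(cfg$model$name) &&
      !cfg$model$name %in% c("gblup", "bayesc"))
    stop("config error at 'model.name': must be gblup or bayesc")
  invisible(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full genomic-prediction pipeline
#'
#' Orchestrates read-or-simulate, trait coding, marker-panel subsetting,
#' repeated cross-validation, and result/manifest output. Configuration
#' keys (all optional unless noted):
#'
#' * `seed` (required) — root seed; every stage derives its own from it.
#' * `genotypes`: `prefix` (PLINK) or `vcf`, plus `phenotypes` (TSV
#'   path) and optionally `genes` (interval TSV); **or** `simulate`:
#'   `n_dogs`, `L`, `n_qtn`, `heritability`.
#' * `trait`: `name` (`norberg_angle`, `rccl`, `weight_kg` or
#'   `simulated`), `truncate_floor` (default 75), `binarize_cutoff`
#'   (default 105; used for AUC labelling of angle traits).
#' * `panel`: `type` = `all` | `associated` | `random` (+ `k`, default
#'   808; `extension_bp`, default 10000).
#' * `model`: `name` = `gblup` | `bayesc`, `gblup_method`, `chain`
#'   (`n_iter`, `burn_in`, `thin`).
#' * `cv`: `strategy` (default `random`), `target_breed`, `n_folds`
#'   (default 5), `n_rounds` (default 100).
#'
#' @param config a configuration list or path to a YAML file.
#' @param outdir output directory for `results.tsv` and
#'   `manifest.json`.
#' @return Invisibly, a list with the `cv_result`, the marker ids used,
#'   and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  seed <- as.integer(config$seed)

  # ---- load or simulate -----------------------------------------------------
  sim_truth <- NULL
  if (!is.null(config$genotypes)) {
    gcf <- config$genotypes
    g <- stage("read-genotypes", {
      if (!is.null(gcf$prefix)) read_plink(gcf$prefix)
      else if (!is.null(gcf$vcf)) read_vcf(gcf$vcf)
      else stop("config error at 'genotypes': need 'prefix' or 'vcf'")
    })
    ph <- stage("read-phenotypes", {
      if (is.null(gcf$phenotypes))
        stop("config error at 'genotypes.phenotypes': required")
      align_phenotypes(read_phenotypes(gcf$phenotypes), g)
    })
  } else {
    scf <- config$simulate
    g <- stage("simulate-genotypes", {
      n_dogs <- if (is.null(scf$n_dogs)) 421L else scf$n_dogs
      L <- if (is.null(scf$L)) 2000L else scf$L
      simulate_genotypes(default_breeds(scale = n_dogs / 422), L,
                         seed = seed)
    })
    yspec <- trait_sim_spec(
      n_qtn = if (is.null(scf$n_qtn)) 20L else scf$n_qtn,
      heritability = if (is.null(scf$heritability)) "sample"
      else scf$heritability,
      seed = seed + 1L)
    ysim <- stage("simulate-phenotype", simulate_phenotype(g, yspec))
    sim_truth <- attr(ysim, "truth")
    ph <- NULL
  }

  # ---- trait coding ---------------------------------------------------------
  tcf <- utils::modifyList(list(name = "simulated", truncate_floor = 75,
                                binarize_cutoff = 105),
                           if (is.null(config$trait)) list() else config$trait)
  y <- stage("trait-coding", {
    if (!is.null(ph)) {
      switch(tcf$name,
             norberg_angle = truncate_norberg(
               average_norberg(ph$na_left, ph$na_right, ph$id),
               floor = tcf$truncate_floor),
             rccl = phenotype_vector(ph$rccl, "binary", "rccl", ph$id),
             weight_kg = phenotype_vector(ph$weight_kg, "continuous",
                                          "weight_kg", ph$id),
             stop("unknown trait name: ", tcf$name))
    } else ysim
  })

  # ---- marker panel ---------------------------------------------------------
  g <- stage("complete-markers", drop_incomplete_markers(g))
  pcf <- utils::modifyList(list(type = "all", k = 808L,
                                extension_bp = 10000L),
                           if (is.null(config$panel)) list() else config$panel)
  g <- stage("marker-subset", switch(
    pcf$type,
    all = g,
    random = select_random_markers(g, pcf$k, seed = seed + 2L),
    associated = {
      if (is.null(config$genotypes$genes))
        stop("panel type 'associated' needs a 'genotypes.genes' file")
      select_associated_markers(
        g, read_gene_intervals(config$genotypes$genes,
                               extension_bp = pcf$extension_bp))
    }))

  # ---- cross-validation -----------------------------------------------------
  ccf <- utils::modifyList(list(strategy = "random", target_breed = NULL,
                                n_folds = 5L, n_rounds = 100L),
                           if (is.null(config$cv)) list() else config$cv)
  mcf <- utils::modifyList(list(name = "gblup", gblup_method = "closed_form",
                                chain = NULL),
                           if (is.null(config$model)) list() else config$model)
  plan <- stage("cv-plan", make_folds(g, ccf$strategy, ccf$target_breed,
                                      ccf$n_folds, ccf$n_rounds,
                                      seed = seed + 3L))
  cut <- if (trait_kind(y) == "continuous" &&
             tcf$name %in% c("norberg_angle")) tcf$binarize_cutoff else NULL
  res <- stage("cv-run", run_cv(
    plan, y, g, model = mcf$name,
    config = list(gblup_method = mcf$gblup_method, chain = mcf$chain,
                  binarize_cutoff = cut, seed = seed + 4L)))

  # ---- outputs --------------------------------------------------------------
  res_path <- file.path(outdir, "results.tsv")
  write_cv_result(res, res_path, model = mcf$name, trait = tcf$name,
                  strategy = ccf$strategy)
  manifest <- list(
    config = config,
    seeds = list(root = seed, genotypes = seed, phenotype = seed + 1L,
                 panel = seed + 2L, cv_plan = seed + 3L, models = seed + 4L),
    markers_used = g$map$marker_id,
    n_samples = n_samples(g),
    version = as.character(utils::packageVersion("breedgp")),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    summary = res$summary)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cv = res, markers = g$map$marker_id, manifest = manifest,
                 truth = sim_truth))
}
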