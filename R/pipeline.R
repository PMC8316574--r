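## End-to-end orchestration: diffcall -> conservation -> features ->
## train -> score -> prioritize -> enrich, stages communicating only via
## files, with a deterministic run manifest (content hashes for every
## output; identical config + seed reproduces identical hashes).

#' Read a pipeline configuration
#'
#' YAML file naming the fixture/input directory, the output directory
#' and the analysis parameters (genotype labels, alpha, negative ratio,
#' number of benchmark sets, folds, prioritization fraction, seed,
#' reference species).
#'
#' @param path YAML config file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("input_dir", "output_dir", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("pipeline config missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg
}

pipeline_defaults <- function() {
  list(test_genotype = "mutant", control_genotype = "WT",
       auxiliary_genotypes = c("ctrlA", "ctrlB"),
       alpha = 0.05, min_quant = 3L, ratio = 5L, n_sets = 3L, k = 10L,
       fraction = 0.05, reference_species = "sp1",
       missing_policy = "impute-zero", normalize_ratios = FALSE)
}

#' Run the full prioritization pipeline
#'
#' Consumes a fixture/input directory (layout as written by
#' [simulate_fixture()]): differential calling on the quantitation
#' table, conservation scoring against the species tree, feature
#' assembly, benchmark construction and model selection, scoring and
#' normalization of all sites, top-fraction prioritization, intersection
#' with the regulated sites (the terminal LiRP table), and kinase
#' enrichment per direction. Every stage output is a TSV under
#' \code{output_dir}; the run manifest lists each file with its MD5
#' content hash. A failed stage aborts with the stage named; outputs of
#' completed stages are retained.
#'
#' @param config list from [read_pipeline_config()] or built in code;
#'   must contain \code{input_dir}, \code{output_dir}, \code{seed};
#'   other parameters default sensibly.
#' @return the run manifest (list), invisibly written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(pipeline_defaults(), config)
  ind <- cfg$input_dir; outd <- cfg$output_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, name) {
    p <- file.path(outd, name)
    write_tsv_table(df, p)
    outputs <<- c(outputs, p)
    p
  }

  ## --- load inputs ----------------------------------------------------
  st <- stage("load", {
    tab <- read_site_table(file.path(ind, "sites.tsv"))
    quant <- read_tsv_table(file.path(ind, "quant.tsv"))
    iso_map <- read_tsv_table(file.path(ind, "isoform_sites.tsv"))
    positives <- readLines(file.path(ind, "positives.txt"))
    bundle <- read_annotation_bundle(ind)
    tree <- read_newick(file.path(ind, "tree.nwk"))
    v <- validate_annotations(bundle, tab$proteins, tab$sites,
                              strict = TRUE)
    list(tab = tab, quant = quant, iso_map = iso_map,
         positives = positives, bundle = v$bundle, tree = tree)
  })

  ## --- differential calling -------------------------------------------
  diff <- stage("diffcall", {
    quant <- st$quant
    if (isTRUE(cfg$normalize_ratios)) quant <- normalize_quant_table(quant)
    call_differential(quant, cfg$test_genotype, cfg$control_genotype,
                      cfg$auxiliary_genotypes, cfg$min_quant, cfg$alpha)
  })
  emit(diff$calls, "diffcalls.tsv")
  regulated <- stage("diffcall", {
    expand_regulated_sites(diff$calls, st$iso_map)
  })
  emit(regulated, "regulated_sites.tsv")

  ## --- conservation ----------------------------------------------------
  cons <- stage("conserve", {
    score_conservation_table(st$tab$sites, file.path(ind, "msa"),
                             st$tree, cfg$reference_species)
  })
  emit(cons, "conservation.tsv")

  ## --- features --------------------------------------------------------
  feat <- stage("features", {
    assemble_feature_table(st$tab$sites, st$bundle, cons,
                           missing_policy = cfg$missing_policy)
  })
  emit(feat, "features.tsv")

  ## --- train -----------------------------------------------------------
  fit <- stage("train", {
    pool <- setdiff(st$tab$sites$site_id, st$positives)
    benchmarks <- build_benchmarks(st$positives, pool, cfg$ratio,
                                   cfg$n_sets,
                                   seed = derive_seed(cfg$seed, 11))
    select_final_model(feat, benchmarks, k = cfg$k,
                       seed = derive_seed(cfg$seed, 12))
  })
  emit(data.frame(set_index = seq_along(fit$cv_auc), cv_auc = fit$cv_auc),
       "cv_report.tsv")
  emit(fit$cv$roc, "roc.tsv")

  ## --- score and normalize ----------------------------------------------
  scored <- stage("score", {
    raw <- predict_raw_score(fit$model,
                             feat[, FEATURE_COLUMNS, drop = FALSE])
    nrm <- fit_normalizer(raw)
    data.frame(site_id = feat$site_id, raw_score = raw,
               score = normalize_scores(nrm, raw),
               stringsAsFactors = FALSE)
  })
  emit(scored, "scores.tsv")
  model_json <- file.path(outd, "model.json")
  write_json_sidecar(
    list(weights = as.list(fit$model$weights),
         intercept = fit$model$intercept,
         benchmark_index = fit$best_index,
         cv_auc = fit$cv_auc[fit$best_index]),
    model_json)
  outputs <- c(outputs, model_json)

  ## --- prioritize ---------------------------------------------------------
  lirp <- stage("prioritize", {
    top <- prioritize_top_fraction(
      setNames(scored$score, scored$site_id), cfg$fraction)
    intersect_lirp(top, regulated, setNames(scored$score, scored$site_id))
  })
  emit(lirp, "lirp.tsv")

  ## --- enrich -------------------------------------------------------------
  enr <- stage("enrich", {
    enrich_kinases(st$tab$sites$site_id, regulated,
                   st$bundle$kinase_edges, alpha = cfg$alpha)
  })
  emit(enr, "enrichment.tsv")

  ## --- manifest -------------------------------------------------------------
  manifest <- list(
    config = cfg[order(names(cfg))],
    seed = cfg$seed,
    spread = unclass(diff$spread),
    n_sites = nrow(st$tab$sites),
    n_regulated = nrow(regulated),
    n_lirp = nrow(lirp),
    outputs = lapply(sort(outputs), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  write_json_sidecar(manifest, file.path(outd, "manifest.json"))
  invisible(manifest)
}
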