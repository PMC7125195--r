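#' Read a dataset manifest
#'
#' A manifest is a YAML (or equivalent list) describing the profiling
#' datasets of a run: a `datasets` sequence of entries with fields `name`,
#' `path`, `orientation` (`wide`/`long`), `assay_kind`,
#' `assay_concentration_nM` (optional) and `mutant_flag_regex` (optional).
#' Paths are resolved relative to the manifest file.
#'
#' @param manifest path to a YAML manifest, or an already-parsed list.
#' @return named list of [profile_dataset()] objects.
#' @export
read_dataset_manifest <- function(manifest) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  entries <- manifest$datasets %||% manifest
  if (!length(entries)) stop("manifest declares no datasets")
  ds <- lapply(entries, function(e) {
    if (is.null(e$path) || is.null(e$assay_kind))
      stop("each dataset entry needs 'path' and 'assay_kind'")
    path <- if (file.exists(e$path)) e$path else file.path(base, e$path)
    if (!file.exists(path)) stop("dataset file not found: ", e$path)
    read_profile_table(path,
                       orientation = e$orientation %||% "wide",
                       assay_kind = e$assay_kind,
                       name = e$name %||% basename(path),
                       assay_concentration_nM = e$assay_concentration_nM,
                       mutant_flag_regex = e$mutant_flag_regex)
  })
  names(ds) <- vapply(ds, `[[`, character(1), "name")
  ds
}

validate_run_config <- function(config) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  config$.base <- base
  if (is.null(config$screen_id)) stop("config needs 'screen_id'")
  if (!length(config$plates)) stop("config needs >= 1 plate file")
  config$plates <- vapply(unlist(config$plates), function(p) {
    pp <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(pp)) stop("plate file not found: ", p)
    pp
  }, character(1))
  if (!length(config$datasets)) stop("config needs >= 1 dataset entry")
  config$datasets <- lapply(config$datasets, function(e) {
    p <- if (file.exists(e$path %||% "")) e$path
         else file.path(base, e$path %||% "")
    if (!file.exists(p)) stop("dataset file not found: ", e$path)
    e$path <- p
    e
  })
  opts <- config$options %||% list()
  if (is.null(opts$seed)) stop("config must provide options$seed explicitly")
  config$options <- list(min_overlap = opts$min_overlap %||% 10,
                         n_perm = opts$n_perm %||% 100,
                         seed = as.integer(opts$seed),
                         top_n = opts$top_n %||% 10,
                         null_scope = opts$null_scope %||% "per_dataset",
                         kd_concentration_nM = opts$kd_concentration_nM %||% 500)
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  if (!grepl("^(/|[A-Za-z]:)", config$out_dir))
    config$out_dir <- file.path(base, config$out_dir)
  config
}

#' Run a complete screen analysis from a configuration
#'
#' Orchestrates the full pipeline: plate files are normalized into the
#' screen fingerprint, correlated and ranked against every dataset in the
#' manifest with permutation z-scores and a confidence flag, and the
#' results are written to the output directory together with KinMap
#' annotations, optional downsampling curves and cluster trees, and a
#' JSON run manifest recording the configuration, input checksums, seeds
#' and per-stage timings. Identical configurations reproduce identical
#' data files.
#'
#' @param config path to a YAML run configuration or an equivalent list.
#'   Required fields: `screen_id`, `plates` (file list), `datasets`
#'   (manifest entries, see [read_dataset_manifest()]), `options$seed`,
#'   `out_dir`. Optional: `options` (`min_overlap`, `n_perm`, `top_n`,
#'   `null_scope`, `kd_concentration_nM`), `downsampling`
#'   (`enabled`, `dataset`, `target`, `n_values`, `k_values`, `reps`),
#'   `clustering` (`enabled`, `dataset`, `n_boot`, `multiscale`,
#'   `include_query`).
#' @return invisibly, the `"kipik"` fit; side effect: the report bundle
#'   under `out_dir`.
#' @export
run_screen_analysis <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  config <- validate_run_config(config)
  opts <- config$options
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- c(); warn <- character(0)
  stage <- function(name, expr) {
    t <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warn <<- c(warn, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[name] <<- round(proc.time()[["elapsed"]] - t, 3)
    res
  }

  datasets <- stage("load_datasets",
                    read_dataset_manifest(list(datasets = config$datasets)))
  plates <- stage("load_plates", lapply(config$plates, read_plate_table,
                                        screen_id = config$screen_id))
  fp <- stage("fingerprint", assemble_fingerprint(plates))
  fit <- stage("rank_and_null",
               kipik(fp, datasets, min_overlap = opts$min_overlap,
                     n_perm = opts$n_perm, seed = opts$seed,
                     null_scope = opts$null_scope,
                     kd_concentration_nM = opts$kd_concentration_nM,
                     top_n = opts$top_n))

  stage("write_core", {
    write_fingerprint(fp, file.path(out, "fingerprint.tsv"))
    write_hit_table(fit$hits, file.path(out, "hit_table.tsv"))
    write_null_summary(fit$nulls, file.path(out, "null_summary.tsv"))
    for (ds in unique(fit$hits$dataset))
      export_kinmap_annotation(fit$hits, ds,
                               file.path(out, paste0("kinmap_",
                                                     gsub("[^A-Za-z0-9._-]", "_", ds),
                                                     ".txt")))
  })

  dcfg <- config$downsampling
  if (isTRUE(dcfg$enabled)) {
    stage("downsampling", {
      dsname <- dcfg$dataset %||% names(fit$datasets)[1]
      curve <- downsample_recovery(fp, fit$datasets[[dsname]],
                                   target = dcfg$target,
                                   n_values = dcfg$n_values,
                                   k_values = unlist(dcfg$k_values) %||%
                                     c(1, 5, 10),
                                   reps = dcfg$reps %||% 10000,
                                   seed = opts$seed,
                                   min_overlap = opts$min_overlap)
      write_downsampling_curve(curve, file.path(out, "downsampling.tsv"))
    })
  }
  ccfg <- config$clustering
  if (isTRUE(ccfg$enabled)) {
    stage("clustering", {
      dsname <- ccfg$dataset %||% names(fit$datasets)[1]
      tree <- bootstrap_support(fit$datasets[[dsname]],
                                n_boot = ccfg$n_boot %||% 10000,
                                seed = opts$seed,
                                multiscale = isTRUE(ccfg$multiscale),
                                include_query = if (isTRUE(ccfg$include_query))
                                  fp else NULL)
      to_newick(tree, file.path(out, "cluster_tree.nwk"))
      write_support_table(tree, file.path(out, "cluster_support.tsv"))
    })
  }

  inputs <- c(config$plates,
              vapply(config$datasets, `[[`, character(1), "path"))
  manifest <- list(
    tool = paste("kipik", as.character(utils::packageVersion("kipik"))),
    screen_id = config$screen_id,
    config = config[setdiff(names(config), ".base")],
    input_checksums = as.list(tools::md5sum(inputs)),
    seed = opts$seed,
    confidence = fit$confidence,
    z_max = fit$z_max,
    top_hit = fit$hits$gene_symbol[fit$hits$rank_overall == 1],
    warnings = warn,
    timings_s = as.list(timings),
    total_s = round(proc.time()[["elapsed"]] - t0, 3))
  tmp <- file.path(out, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(out, "run_manifest.json"))
  invisible(fit)
}
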