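# End-to-end pipeline orchestration: validate -> descriptive statistics ->
# model selection plans -> parameter estimation, with per-stage outputs,
# caching and seed/config stamping.

#' Run configuration
#'
#' @param manifest Path to a dataset manifest (see [read_dataset()]).
#' @param out_dir Output directory.
#' @param plan `"plan1"`, `"plan2"`, `"estimate"` or `"all"`.
#' @param seed Master seed (recorded in every output).
#' @param scale `"desk"` (defaults of [abc_config()]) or `"paper"`
#'   (1e6 simulations, 5,000 retained, 2,000 pseudo-datasets).
#' @param abc Optional [abc_config()] overriding `scale`.
#' @param n_perm Permutations for the descriptive PhiST tests.
#' @param overwrite Recompute stages whose outputs already exist
#'   (default `FALSE`: cached intermediates are reused).
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, out_dir, plan = c("all", "plan1", "plan2",
                                                   "estimate"),
                       seed = 1, scale = c("desk", "paper"), abc = NULL,
                       n_perm = 999, overwrite = FALSE) {
  plan <- match.arg(plan)
  scale <- match.arg(scale)
  if (!file.exists(manifest))
    abort(sprintf("manifest not found: %s", manifest))
  if (is.null(abc)) {
    abc <- if (scale == "paper")
      abc_config(n_sims = 1e6, retain = 5000, n_pseudo = 2000)
    else abc_config()
  }
  structure(list(manifest = manifest, out_dir = out_dir, plan = plan,
                 seed = seed, scale = scale, abc = abc, n_perm = n_perm,
                 overwrite = overwrite),
            class = "run_config")
}

#' Read a run configuration from YAML/JSON
#'
#' @param path Path to a YAML or JSON file with the fields of [run_config()];
#'   relative paths are resolved against the file's directory.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(path)
  abc <- if (!is.null(raw$abc)) do.call(abc_config, raw$abc) else NULL
  run_config(manifest = file.path(base, raw$manifest),
             out_dir = raw$out_dir %||% file.path(base, "results"),
             plan = raw$plan %||% "all", seed = raw$seed %||% 1,
             scale = raw$scale %||% "desk", abc = abc,
             n_perm = raw$n_perm %||% 999,
             overwrite = isTRUE(raw$overwrite))
}

stage_log <- function(stage, msg)
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))

#' Run the full analysis pipeline
#'
#' Stages in order: dataset validation; descriptive statistics (diversity,
#' divergence, shared-polymorphism tables); model-selection plan 1 (SI vs IM
#' within each topology, then topologies under IM); parameter estimation under
#' the selected model; model-selection plan 2 (temporal patterns of migration
#' and expansion under the selected topology). Each stage writes TSV/JSON
#' outputs stamped with the seed and a configuration hash; existing outputs
#' are reused unless `overwrite`.
#'
#' @param config A [run_config()] or a path to one (YAML/JSON).
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  # hash of the analysis-defining settings (not the input/output locations)
  cfg_hash <- rlang::hash(config[c("plan", "seed", "scale", "abc", "n_perm")])
  stamp <- list(seed = config$seed, config_hash = cfg_hash)
  jsonlite::write_json(c(stamp, list(plan = config$plan, scale = config$scale)),
                       file.path(out, "run_info.json"), auto_unbox = TRUE)
  results <- list()

  stage_log("load", config$manifest)
  ds <- read_dataset(config$manifest)

  # -- validate ---------------------------------------------------------
  vfile <- file.path(out, "validation.tsv")
  rep <- validate_dataset(ds)
  readr::write_tsv(rep, vfile)
  results$validation <- rep
  if (!attr(rep, "usable"))
    abort("dataset failed hard validation rules; see validation.tsv")
  stage_log("validate", sprintf("%d loci pass", length(ds$loci)))

  # -- descriptive statistics ------------------------------------------
  sdir <- file.path(out, "sumstats")
  if (config$overwrite || !dir.exists(sdir)) {
    repstats <- summary_report(ds, n_perm = config$n_perm)
    write_summary_report(repstats, sdir)
    results$sumstats <- repstats
    stage_log("sumstats", sprintf("tables written to %s", sdir))
  } else stage_log("sumstats", "cached")
  obs <- stat_vector(ds, config$abc$stat_cfg)
  jsonlite::write_json(
    c(stamp, list(stats = as.list(setNames(as.numeric(obs), names(obs))),
                  n_imputed = attr(obs, "n_imputed"))),
    file.path(out, "observed_stats.json"), auto_unbox = TRUE, digits = NA)

  selected_top <- "top2"
  # -- plan 1 -----------------------------------------------------------
  if (config$plan %in% c("plan1", "all")) {
    f <- file.path(out, "plan1.tsv")
    if (config$overwrite || !file.exists(f)) {
      sel1 <- hierarchical_selection(obs, "plan1", config$abc,
                                     seed = seed_stream(config$seed, 1))
      readr::write_tsv(dplyr::mutate(sel1$steps, seed = config$seed,
                                     config_hash = cfg_hash), f)
      results$plan1 <- sel1
      selected_top <- sub(".*-(top[123]).*", "\\1", sel1$selected)
      stage_log("plan1", sprintf("selected %s", sel1$selected))
    } else stage_log("plan1", "cached")
  }

  # -- estimation under the selected IM model ---------------------------
  if (config$plan %in% c("estimate", "all")) {
    f <- file.path(out, "posterior_summary.tsv")
    if (config$overwrite || !file.exists(f)) {
      mod <- demographic_model(selected_top, "IM")
      est <- estimate_parameters(obs, mod, cfg = config$abc,
                                 seed = seed_stream(config$seed, 2))
      readr::write_tsv(dplyr::mutate(est$summary, seed = config$seed,
                                     config_hash = cfg_hash), f)
      readr::write_tsv(est$sample, file.path(out, "posterior_sample.tsv"))
      results$estimate <- est
      stage_log("estimate", sprintf("%d parameters summarised", nrow(est$summary)))
    } else stage_log("estimate", "cached")
  }

  # -- plan 2 -----------------------------------------------------------
  if (config$plan %in% c("plan2", "all")) {
    f <- file.path(out, "plan2.tsv")
    if (config$overwrite || !file.exists(f)) {
      sel2 <- hierarchical_selection(obs, "plan2", config$abc,
                                     seed = seed_stream(config$seed, 3),
                                     topology = selected_top)
      readr::write_tsv(dplyr::mutate(sel2$steps, seed = config$seed,
                                     config_hash = cfg_hash), f)
      results$plan2 <- sel2
      stage_log("plan2", sprintf("selected %s", sel2$selected))
    } else stage_log("plan2", "cached")
  }
  invisible(results)
}
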