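# One-config orchestration of the full analysis: obtain inputs (synthetic
# or from files), build nested families, sweep scoring functions, locate
# crossings and leaps, and write every artifact with a manifest. Everything
# is seeded, so re-running a config reproduces identical numeric outputs.

pipeline_config_keys <- c("seed", "synth", "inputs", "metrics", "directions",
                          "sf_names", "schedules", "out_dir", "plots",
                          "quiet")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a path to a JSON file holding one)
#' with keys: `seed` (integer), exactly one of `synth` (arguments for
#' [synth_config()]) or `inputs` (paths: `train_features`, `test_features`,
#' `train_index`, `test_index`, and at least one of `protein`, `ligand`,
#' `pocket`), `metrics` (which similarity channels to sweep), `directions`
#' (`"ds"`, `"sd"`), `sf_names` (see [sf_names()]), `schedules` (optional
#' per-metric `list(start, end, step)` overrides), `out_dir`, `plots`,
#' `quiet`. Unknown keys are rejected before any compute.
#'
#' @param config named list or JSON file path.
#' @return The validated config as a list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$synth)) config$synth <- as.list(config$synth)
    if (!is.null(config$inputs)) config$inputs <- as.list(config$inputs)
    if (!is.null(config$schedules)) {
      config$schedules <- lapply(config$schedules, as.list)
    }
  }
  if (!is.list(config)) abort("Config must be a named list or a JSON path")
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$directions <- config$directions %||% "ds"
  if (!all(config$directions %in% c("ds", "sd"))) {
    abort("`directions` must be a subset of c('ds', 'sd')")
  }
  config$sf_names <- config$sf_names %||% sf_names()
  bad <- setdiff(config$sf_names, sf_names())
  if (length(bad)) {
    abort(paste0("Unknown sf_name(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(config$synth) == is.null(config$inputs)) {
    abort("Config must contain exactly one of 'synth' or 'inputs'")
  }
  all_metrics <- c("protein_structure", "ligand_fingerprint", "pocket_topology")
  config$metrics <- config$metrics %||% all_metrics
  bad <- setdiff(config$metrics, all_metrics)
  if (length(bad)) {
    abort(paste0("Unknown metric(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(config$schedules)) {
    bad <- setdiff(names(config$schedules), all_metrics)
    if (length(bad)) {
      abort(paste0("Schedule override for unknown metric(s): ",
                   paste(bad, collapse = ", ")))
    }
    for (s in config$schedules) {
      if (!all(c("start", "end", "step") %in% names(s))) {
        abort("Each schedule override needs start, end and step")
      }
    }
  }
  config$plots <- isTRUE(config$plots)
  config$quiet <- isTRUE(config$quiet)
  config
}

pipeline_schedule <- function(config, metric) {
  ov <- config$schedules[[metric]]
  if (is.null(ov)) default_schedule(metric) else
    cutoff_schedule(ov$start, ov$end, ov$step)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synth)) {
    cfg <- do.call(synth_config, c(config$synth,
                                   if (is.null(config$synth$seed))
                                     list(seed = config$seed)))
    bench <- generate_benchmark(cfg)
    return(bench)
  }
  inp <- config$inputs
  need <- c("train_features", "test_features", "train_index", "test_index")
  missing <- setdiff(need, names(inp))
  if (length(missing)) {
    abort(paste0("Config 'inputs' lacks: ", paste(missing, collapse = ", ")))
  }
  feats <- feature_registry()$XVC16
  out <- list(
    train_features = read_feature_table(inp$train_features, feats),
    test_features = read_feature_table(inp$test_features, feats),
    train_affinities = read_pdbbind_index(inp$train_index),
    test_affinities = read_pdbbind_index(inp$test_index)
  )
  if (!is.null(inp$protein)) {
    out$protein <- read_similarity_matrix(inp$protein, "similarity",
                                          "protein_structure")
  }
  if (!is.null(inp$ligand)) {
    out$ligand <- read_similarity_matrix(inp$ligand, "similarity",
                                         "ligand_fingerprint")
  }
  if (!is.null(inp$pocket)) {
    out$pocket <- read_similarity_matrix(inp$pocket, "dissimilarity",
                                         "pocket_topology")
  }
  out
}

matrix_slot <- function(metric) {
  switch(metric, protein_structure = "protein",
         ligand_fingerprint = "ligand", pocket_topology = "pocket")
}

# RF/XGB scoring functions paired with the classical model they challenge
crossing_pairs <- function(names_present) {
  pairs <- list(
    c("RF::Xscore", "MLR::Xscore"), c("RF::Vina", "MLR::Vina"),
    c("RF::Cyscore", "MLR::Cyscore"),
    c("RF::XVC", "MLR::Xscore"), c("RF::XVC", "MLR::Vina"),
    c("XGB::XVC", "MLR::Xscore"), c("XGB::XVC", "MLR::Vina")
  )
  purrr::keep(pairs, function(p) all(p %in% names_present))
}

#' Run the full similarity-stratification pipeline
#'
#' Executes synth/load, stratify, sweep, crossings and report stages from
#' one validated config and writes every artifact under `out_dir`:
#' family-size and skew-histogram tables, the long-format performance
#' table, crossing and leap reports, measured-vs-predicted scatter exports
#' at the final cutoff, and a `manifest.txt` recording the config hash and
#' seed. Re-running the same config reproduces identical numeric outputs.
#'
#' @param config named list or JSON path; see [validate_config()].
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with `curves`, `crossings`, `leaps`,
#'   `families`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% abort("No output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!config$quiet) message("[sfstrat] ", ...)

  say("stage synth/load")
  data <- load_pipeline_inputs(config)
  if (!is.null(config$synth)) write_benchmark(data, file.path(out_dir, "benchmark"))

  metrics <- purrr::keep(config$metrics,
                         function(m) !is.null(data[[matrix_slot(m)]]))
  if (!length(metrics)) abort("No similarity matrix available for any requested metric")
  specs <- lapply(config$sf_names, sf_spec, seed = config$seed)

  say("stage stratify")
  dir.create(file.path(out_dir, "families"), showWarnings = FALSE)
  families <- list()
  for (metric in metrics) {
    m <- data[[matrix_slot(metric)]]
    schedule <- pipeline_schedule(config, metric)
    hist <- skew_histogram(m, schedule)
    readr::write_delim(hist, file.path(out_dir, "families",
                                       paste0(metric, "_skew.tsv")), delim = "\t")
    for (direction in config$directions) {
      fam <- build_family(m, schedule, direction)
      families[[paste(metric, direction, sep = "_")]] <- fam
      readr::write_delim(
        family_sizes(fam),
        file.path(out_dir, "families", paste0(metric, "_", direction,
                                              "_sizes.tsv")),
        delim = "\t")
      write_family_table(fam, file.path(out_dir, "families",
                                        paste0(metric, "_", direction,
                                               "_ids.tsv")))
    }
  }

  say("stage sweep (", length(specs), " scoring functions x ",
      length(families), " families)")
  curves <- purrr::map_dfr(families, function(fam) {
    sweep_scoring(specs, fam, data$train_features, data$train_affinities,
                  data$test_features, data$test_affinities,
                  seed = config$seed)
  })
  class(curves) <- c("sf_curves", class(curves))
  write_performance_table(curves, file.path(out_dir, "performance.tsv"))

  say("stage crossings")
  crossings <- purrr::map_dfr(
    split(curves, list(curves$metric, curves$direction), drop = TRUE),
    function(cv) {
      class(cv) <- c("sf_curves", class(cv))
      purrr::map_dfr(crossing_pairs(unique(cv$sf_name)), function(pr) {
        purrr::map_dfr(c("rp", "rs", "rmse"), function(met) {
          hit <- find_crossing(cv, pr[1], pr[2], met)
          if (nrow(hit)) {
            hit$metric_name <- cv$metric[1]
            hit$direction <- cv$direction[1]
          }
          hit
        })
      })
    })
  readr::write_delim(crossings, file.path(out_dir, "crossings.tsv"),
                     delim = "\t")
  leaps <- purrr::map_dfr(
    split(curves, list(curves$metric, curves$direction), drop = TRUE),
    function(cv) {
      ok <- vapply(split(cv$rp, cv$sf_name),
                   function(v) sum(!is.na(v)) >= 2, logical(1))
      cv <- cv[cv$sf_name %in% names(ok)[ok], , drop = FALSE]
      if (!nrow(cv)) return(tibble::tibble())
      out <- leap_deltas(cv, "rp")
      out$metric_name <- cv$metric[1]
      out$direction <- cv$direction[1]
      out
    })
  readr::write_delim(leaps, file.path(out_dir, "leaps.tsv"), delim = "\t")

  say("stage report")
  dir.create(file.path(out_dir, "scatter"), showWarnings = FALSE)
  fam1 <- families[[1]]
  final_ids <- fam1$sets[[length(fam1$sets)]]
  for (spec in specs) {
    if (length(final_ids) < min_trainable(spec)) next
    sub_X <- data$train_features[normalize_id(data$train_features$id) %in%
                                   final_ids, , drop = FALSE]
    spec_k <- spec
    spec_k$seed <- derive_point_seed(config$seed + spec$seed,
                                     length(fam1$cutoffs))
    fit <- fit_sf(spec_k, sub_X, data$train_affinities)
    export_scatter(predict(fit, data$test_features), data$test_affinities,
                   file.path(out_dir, "scatter",
                             paste0(gsub("::", "_", spec$sf_name), ".tsv")),
                   plot = config$plots)
  }
  if (config$plots) {
    ggplot2::ggsave(file.path(out_dir, "performance_rp.png"),
                    autoplot.sf_curves(curves, "rp"),
                    width = 8, height = 5, dpi = 150)
  }

  cfg_for_hash <- config[setdiff(names(config), c("quiet", "plots", "out_dir"))]
  manifest <- c(
    paste0("config_hash=", rlang::hash(cfg_for_hash)),
    paste0("seed=", config$seed),
    paste0("package_version=", as.character(utils::packageVersion("sfstrat"))),
    paste0("metrics=", paste(metrics, collapse = ",")),
    paste0("directions=", paste(config$directions, collapse = ",")),
    paste0("sf_names=", paste(config$sf_names, collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  say("done: ", out_dir)
  invisible(list(curves = curves, crossings = crossings, leaps = leaps,
                 families = families, out_dir = out_dir))
}
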