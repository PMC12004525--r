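# Config-driven orchestration: generate/load -> curate -> featurize ->
# aggregate -> model -> compare -> report.

.DESCRIPTOR_REGISTRY <- c("morse", "triplet3d", "triplet2d", "mbtr", "ecfp4")
.AGGREGATION_REGISTRY <- c("boltzmann", "mean", "global_min", "random",
                           "rmsd_max", "rmsd_min", "nonaggregation",
                           "ground_truth")
.MODEL_REGISTRY <- c("rf", "mlp", "enet", "lm")

.validation_error <- function(...) {
  stop(structure(class = c("confagg_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Validate a benchmark run configuration
#'
#' Checks every referenced descriptor, aggregation and model name against
#' the registries and the data-source block for completeness, before any
#' computation happens.
#'
#' @param config a run-configuration list (see [run_benchmark()]).
#' @return the config, invisibly, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$data) || is.null(config$data$type)) {
    .validation_error("config$data$type must be 'synthetic' or 'files'")
  }
  if (!config$data$type %in% c("synthetic", "files")) {
    .validation_error("unknown data type '", config$data$type, "'")
  }
  if (config$data$type == "files" &&
      (is.null(config$data$sdf) || is.null(config$data$table))) {
    .validation_error("file data source needs 'sdf' and 'table' paths")
  }
  if (is.null(config$descriptors) || length(config$descriptors) == 0L) {
    .validation_error("config$descriptors must list at least one descriptor")
  }
  for (d in config$descriptors) {
    nm <- if (is.character(d)) d else d$name
    if (is.null(nm) || !nm %in% .DESCRIPTOR_REGISTRY) {
      .validation_error("unknown descriptor '", nm %||% "<unnamed>",
                        "'; registered: ",
                        paste(.DESCRIPTOR_REGISTRY, collapse = ", "))
    }
  }
  if (is.null(config$aggregations) || length(config$aggregations) == 0L) {
    .validation_error("config$aggregations must list at least one method")
  }
  bad <- setdiff(config$aggregations, .AGGREGATION_REGISTRY)
  if (length(bad) > 0L) {
    .validation_error("unknown aggregation method(s): ",
                      paste(bad, collapse = ", "))
  }
  model_name <- config$model$name %||% "rf"
  if (!model_name %in% .MODEL_REGISTRY) {
    .validation_error("unknown model '", model_name, "'; registered: ",
                      paste(.MODEL_REGISTRY, collapse = ", "))
  }
  if (is.null(config$split)) config$split <- list()
  config$split$scheme <- config$split$scheme %||% "repeated_kfold"
  if (!config$split$scheme %in% c("repeated_kfold", "loocv")) {
    .validation_error("unknown split scheme '", config$split$scheme, "'")
  }
  invisible(config)
}

#' Read and validate a YAML run configuration
#' @param path YAML file.
#' @return validated config list.
#' @export
load_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

.build_descriptor_spec <- function(d, dataset) {
  nm <- if (is.character(d)) d else d$name
  if (nm == "mbtr") {
    els <- if (!is.character(d) && !is.null(d$element_set)) d$element_set else {
      sort(unique(unlist(lapply(dataset$ensembles,
                                function(e) e$molecule$elements))))
    }
    descriptor_spec("mbtr", config = mbtr_config(element_set = els))
  } else if (is.character(d)) {
    descriptor_spec(nm)
  } else if (nm == "morse" && !is.null(d$s_values)) {
    descriptor_spec("morse", config = morse_config(
      s_values = d$s_values,
      weight_schemes = d$weight_schemes %||% c("unit", "mass", "vdw_volume",
                                               "sanderson_en", "polarizability")))
  } else if (nm == "ecfp4") {
    descriptor_spec("ecfp4", n_bits = d$n_bits %||% 2048L,
                    counts = isTRUE(d$counts))
  } else {
    descriptor_spec(nm)
  }
}

#' Run the full benchmark pipeline from one configuration
#'
#' Generates (or loads) the dataset, applies optional curation, computes
#' every configured descriptor, evaluates every (descriptor x aggregation)
#' cell with the shared split plan and one model, runs the pairwise
#' signed-rank comparisons of aggregation methods per descriptor, and, when
#' `out_dir` is given, writes `results.csv`, `comparisons.csv`,
#' `curation_log.csv` and a `manifest.yaml` sufficient to reproduce the run.
#' All cells share the identical split plan, so the paired comparisons are
#' valid by construction.
#'
#' @param config nested list (or YAML via [load_run_config()]) with blocks
#'   `data` (type "synthetic" with `generator`/`property` blocks, or
#'   "files" with `sdf`/`table`/`property_name`), optional `curation`,
#'   `descriptors` (names or lists with a `name`), `aggregations`, `model`
#'   (`name` + hyperparameters), `split` (`scheme`, `k`, `repeats`), `seed`.
#' @param out_dir optional output directory for the report files.
#' @return list with `results` (per-fold data.frame), `comparisons`,
#'   `summaries`, `curation_log`, `manifest`.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  seed <- config$seed %||% 1L

  dataset <- if (config$data$type == "synthetic") {
    gen_args <- config$data$generator %||% list()
    gen_args$seed <- gen_args$seed %||% derive_seed(seed, "generator")
    prop_args <- config$data$property %||% list()
    generate_benchmark(do.call(generator_config, gen_args),
                       do.call(property_spec, prop_args))
  } else {
    load_dataset(config$data$sdf, config$data$table,
                 property_name = config$data$property_name %||% "property",
                 id_tag = config$data$id_tag %||% "compound_id",
                 energy_tag = config$data$energy_tag %||% "energy_kcal_mol",
                 energy_unit = config$data$energy_unit %||% "kcal/mol")
  }

  curation_log <- NULL
  if (!is.null(config$curation)) {
    cur <- curate(dataset, do.call(curation_rules, config$curation))
    dataset <- cur$dataset
    curation_log <- cur$log
  }
  if (length(dataset) < 2L) stop("fewer than two compounds after curation")

  split_cfg <- config$split
  splits <- make_splits(names(dataset$ensembles),
                        scheme = split_cfg$scheme,
                        k = split_cfg$k %||% 5L,
                        repeats = split_cfg$repeats %||% 5L,
                        seed = derive_seed(seed, "splits"))
  model <- do.call(model_spec, c(list(name = config$model$name %||% "rf"),
                                 config$model$params %||% list()))

  results <- list()
  comparisons <- list()
  summaries <- list()
  for (d in config$descriptors) {
    spec <- .build_descriptor_spec(d, dataset)
    matrices <- featurize_dataset(dataset, spec)
    gt_matrices <- if ("ground_truth" %in% config$aggregations) {
      featurize_dataset(dataset, spec, ground_truth = TRUE)
    } else NULL
    cell_res <- list()
    for (method in config$aggregations) {
      res <- evaluate_cell(dataset, matrices, method, model, splits,
                           seed = derive_seed(seed, paste0("cell_", spec$name,
                                                           "_", method)),
                           gt_matrices = gt_matrices)
      cell_res[[method]] <- res
      results[[length(results) + 1L]] <- cbind(
        descriptor = spec$name, method = method, res)
      summaries[[length(summaries) + 1L]] <- cbind(
        descriptor = spec$name, method = method, summarize_eval(res))
    }
    methods <- names(cell_res)
    if (length(methods) >= 2L) {
      for (i in seq_len(length(methods) - 1L)) {
        for (j in seq((i + 1L), length(methods))) {
          cmp <- paired_signed_rank(cell_res[[i]]$mae, cell_res[[j]]$mae,
                                    labels = methods[c(i, j)])
          comparisons[[length(comparisons) + 1L]] <- data.frame(
            descriptor = spec$name, method_a = methods[i],
            method_b = methods[j], metric = "mae",
            statistic = cmp$statistic, p_value = cmp$p_value,
            significant = cmp$significant, degenerate = cmp$degenerate,
            median_diff = cmp$median_diff)
        }
      }
    }
  }
  results <- do.call(rbind, results)
  comparisons <- if (length(comparisons) > 0L) do.call(rbind, comparisons)
  summaries <- do.call(rbind, summaries)
  manifest <- list(
    config = config,
    seed = seed,
    n_compounds = length(dataset),
    package = "confagg",
    version = as.character(utils::packageVersion("confagg")),
    config_hash = string_hash(yaml::as.yaml(config)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    if (!is.null(curation_log)) {
      utils::write.csv(curation_log, file.path(out_dir, "curation_log.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(results = results, comparisons = comparisons, summaries = summaries,
       curation_log = curation_log, manifest = manifest)
}
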