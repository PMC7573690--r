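# End-to-end analysis runs: simulate or load data, compute distributions,
# fit power laws and the resource-precision model, and write a
# machine-readable report bundle with a reproducibility manifest.

#' Read a run configuration
#'
#' Configurations are plain lists; on disk they may be JSON (always
#' supported) or YAML (if the yaml package is installed). See
#' [run_proteome_analysis()] and [run_ppi_analysis()] for the recognized
#' fields.
#'
#' @param path config file (`.json`, `.yaml`/`.yml`).
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format_error("config not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_format_error("YAML config requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# Resolve the proteome data source: exactly one of `proteome` (a TSV path)
# or `simulate` (proteome_sim_params arguments) must be present.
resolve_records <- function(config) {
  has_path <- !is.null(config$proteome)
  has_sim <- !is.null(config$simulate)
  if (has_path == has_sim) {
    stop_invalid_parameter(
      "config must contain exactly one of 'proteome' (path) or 'simulate'")
  }
  if (has_path) {
    read_proteome_table(config$proteome)
  } else {
    params <- do.call(proteome_sim_params, as.list(config$simulate))
    generate_proteome(params)
  }
}

write_manifest <- function(config, out_dir, seed) {
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed,
    package = "homomer",
    package_version = as.character(utils::packageVersion("homomer")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest
}

#' Run the proteome homo-oligomer analysis
#'
#' Simulate-or-load a proteome, compute its homo-oligomer distribution,
#' fit the log-log OLS power law and the resource-precision model on the
#' even support, compute the capacity curve, and write every artifact plus
#' a `summary.json` and reproducibility manifest to `out_dir`. Fits
#' needing at least three positive support points are skipped with a note
#' rather than failing the run.
#'
#' @param config list or config-file path with fields: one of `proteome`
#'   (TSV path) or `simulate` (list of [proteome_sim_params()] arguments);
#'   optional `parity` ("all"), `denominator` ("all-known"), `weighting`
#'   ("count"), `support` (c(2,4,6,8)), `fit_mode` ("scaled"), `k_max`
#'   (24), `label`, `seed`, `out_dir` (required).
#' @return the report bundle, invisibly: `distribution`, `ols_fit`,
#'   `model_fit`, `capacity`, `notes`, `manifest`.
#' @export
run_proteome_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||%
    stop_invalid_parameter("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed) && !is.null(config$simulate) &&
      is.null(config$simulate$seed)) {
    config$simulate$seed <- config$seed
  }

  records <- resolve_records(config)
  parity <- config$parity %||% "all"
  denominator <- config$denominator %||% "all-known"
  weighting <- config$weighting %||% "count"
  support <- as.numeric(config$support %||% c(2, 4, 6, 8))
  fit_mode <- config$fit_mode %||% "scaled"
  notes <- character(0)

  dist <- oligomer_frequency(records, parity = parity,
                             denominator = denominator,
                             weighting = weighting,
                             k_max = config$k_max %||% 24,
                             label = config$label)
  write_distribution(dist, file.path(out_dir, "distribution"))

  # even-k distribution feeds both fits regardless of the headline parity
  even_dist <- tryCatch(
    oligomer_frequency(records, parity = "even", denominator = denominator,
                       weighting = weighting, k_max = config$k_max %||% 24,
                       label = config$label),
    homomer_error = function(e) NULL)

  sup_chr <- as.character(support)
  ols_fit <- NULL
  model_fit <- NULL
  if (!is.null(even_dist) &&
      sum(sup_chr %in% names(even_dist$freqs) &
          even_dist$freqs[sup_chr] > 0, na.rm = TRUE) >= 3) {
    pts <- even_dist$freqs[intersect(sup_chr, names(even_dist$freqs))]
    pts <- pts[pts > 0]
    ols_fit <- loglog_ols_fit(pts)
    write_powerlaw_fit(ols_fit, file.path(out_dir, "ols_fit.json"))
  } else {
    notes <- c(notes, "ols_fit skipped: insufficient points")
  }
  if (!is.null(even_dist) && all(sup_chr %in% names(even_dist$freqs))) {
    model_fit <- fit_resource_model(even_dist, support = support,
                                    mode = fit_mode)
    jsonlite::write_json(unclass(model_fit),
                         file.path(out_dir, "resource_model_fit.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    notes <- c(notes, "resource model skipped: insufficient points")
  }

  cap <- capacity(dist)
  utils::write.table(cap, file.path(out_dir, "capacity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- write_manifest(config, out_dir, config$seed %||% NULL)
  summary <- list(
    n_records = nrow(records),
    n_known = sum(!is.na(records$oligomer_k)),
    n_distributions = 1L,
    distribution = list(label = dist$label, total = dist$total,
                        freqs = as.list(dist$freqs)),
    ols_fit = if (!is.null(ols_fit))
      list(exponent = ols_fit$exponent, r_squared = ols_fit$r.squared,
           p_slope = ols_fit$p_slope, n_points = ols_fit$n_points),
    resource_model = if (!is.null(model_fit))
      list(scale = model_fit$scale, r_squared = model_fit$r.squared,
           mode = model_fit$mode),
    notes = notes
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(distribution = dist, ols_fit = ols_fit,
                 model_fit = model_fit, capacity = cap, notes = notes,
                 manifest = manifest))
}

#' Run the interaction-network degree analysis
#'
#' Simulate-or-load an interaction graph, summarize degrees, fit the
#' discrete power law with cutoff scan (and bootstrap when `n_boot > 0`),
#' and — if proteome records are supplied — the per-oligomer-class degree
#' table. Artifacts, `summary.json` and a manifest land in `out_dir`.
#'
#' @param config list or config-file path with fields: one of `edges`
#'   (STRING-style TSV path) or `simulate_network` (list of
#'   [network_sim_params()] arguments); optional `proteome` (TSV path for
#'   class annotation), `score_min` (0), `min_tail` (10), `n_boot` (0),
#'   `classes` (c(2,4,6,8)), `seed`, `out_dir` (required).
#' @return the report bundle, invisibly: `degree_summary`, `powerlaw_fit`,
#'   `class_table`, `notes`, `manifest`.
#' @export
run_ppi_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||%
    stop_invalid_parameter("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% NULL
  notes <- character(0)

  has_path <- !is.null(config$edges)
  has_sim <- !is.null(config$simulate_network)
  if (has_path == has_sim) {
    stop_invalid_parameter(
      "config must contain exactly one of 'edges' or 'simulate_network'")
  }
  if (has_path) {
    graph <- read_string_edges(config$edges,
                               score_min = config$score_min %||% 0)
  } else {
    sim <- as.list(config$simulate_network)
    if (is.null(sim$seed)) sim$seed <- seed
    params <- do.call(network_sim_params, sim)
    deg <- generate_degree_sequence(params)
    graph <- realize_edges(deg, seed = if (!is.null(params$seed))
      params$seed + 1L else NULL)
  }

  records <- if (!is.null(config$proteome)) {
    read_proteome_table(config$proteome)
  } else NULL

  ds <- summarize_degrees(graph)
  write_degree_summary(ds, file.path(out_dir, "degree_summary"),
                       records = records)

  values <- ds$degree_of[ds$degree_of > 0]
  pl_fit <- tryCatch(
    fit_degree_powerlaw(values, min_tail = config$min_tail %||% 10,
                        n_boot = config$n_boot %||% 0, seed = seed),
    homomer_error = function(e) {
      notes <<- c(notes, paste("powerlaw fit skipped:", conditionMessage(e)))
      NULL
    })
  if (!is.null(pl_fit)) {
    write_powerlaw_fit(pl_fit, file.path(out_dir, "powerlaw_fit.json"))
  }

  class_table <- NULL
  if (!is.null(records)) {
    class_table <- tryCatch(
      degree_by_oligomer_class(graph, records,
                               classes = as.numeric(config$classes %||%
                                                      c(2, 4, 6, 8))),
      homomer_error = function(e) {
        notes <<- c(notes, paste("class table skipped:", conditionMessage(e)))
        NULL
      })
    if (!is.null(class_table)) {
      utils::write.table(class_table, file.path(out_dir, "class_degree.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    notes <- c(notes, "class table absent: no oligomer annotations supplied")
  }

  manifest <- write_manifest(config, out_dir, seed)
  summary <- list(
    n_nodes = ds$n_nodes, n_edges = ds$n_edges,
    mean_degree = ds$mean_degree,
    powerlaw_fit = if (!is.null(pl_fit))
      list(gamma = pl_fit$gamma, k_min = pl_fit$k_min,
           n_tail = pl_fit$n_tail, ks_D = pl_fit$ks_D,
           p_boot = pl_fit$p_boot, n_boot = pl_fit$n_boot),
    class_table = if (!is.null(class_table))
      lapply(seq_len(nrow(class_table)), function(i)
        as.list(class_table[i, ])),
    notes = notes
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(degree_summary = ds, powerlaw_fit = pl_fit,
                 class_table = class_table, notes = notes,
                 manifest = manifest))
}
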