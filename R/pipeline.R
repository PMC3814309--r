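#' Read a full run configuration from YAML
#'
#' A run configuration collects everything one analysis run needs: the
#' genome source, the simulation parameters, caller thresholds, classifier
#' options, statistics options and the root seed.  Every field has a
#' documented default, so an empty file is a valid configuration.
#'
#' @param path YAML file (optional; omit for all defaults)
#' @param ... named overrides applied after the file
#' @return object of class `run_config`
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example-config.yaml",
#'                                    package = "uvloh"))
#' cfg$sim$dose
#' @export
read_run_config <- function(path = NULL, ...) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, list(...))
  defaults <- list(
    genome = list(source = "default", seed = 1, snp_map = NULL),
    sim = list(),
    caller = list(min_run = 2, thresholds = list()),
    classifier = list(gap_kb = 15, tol_snps = 1),
    stats = list(n_perm = 1000),
    n_cells = 50,
    seed = 1)
  cfg <- utils::modifyList(defaults, vals)
  if (!is.null(cfg$sim$pathway_probs))
    cfg$sim$pathway_probs <- unlist(cfg$sim$pathway_probs)
  cfg$sim <- do.call(sim_config, cfg$sim)
  structure(cfg, class = "run_config")
}

#' Run the full simulate-call-classify-summarize pipeline
#'
#' Simulates `n_cells` irradiated cells, pushes every colony's two sectors
#' through array simulation, state calling, segmentation and event
#' classification, and writes per-stage outputs plus a JSON summary into
#' `out_dir`.  The run is deterministic given the config seed.
#'
#' @param config a `run_config` (see [read_run_config()])
#' @param out_dir output directory (created if needed); `NULL` skips writing
#' @return list (invisible when writing): `experiment`, `events` (all
#'   colonies pooled, with a `colony` column), `summary`
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = NULL) {
  genome <- if (identical(config$genome$source, "default"))
    make_default_genome(config$genome$seed)
  else {
    map <- load_snp_map(config$genome$snp_map)
    list(map = map, marker = do.call(marker_config, config$genome$marker),
         annotations = NULL)
  }
  exp <- simulate_experiment(config$sim, genome, config$n_cells,
                             seed = config$seed, ratios = TRUE)
  events <- list()
  for (i in seq_along(exp$colonies)) {
    col <- exp$colonies[[i]]
    ev <- classify_colony(col$ratio_a, col$ratio_b,
                          thresholds = config$caller$thresholds,
                          min_run = config$caller$min_run,
                          gap_kb = config$classifier$gap_kb,
                          tol_snps = config$classifier$tol_snps)
    if (nrow(ev)) { ev$colony <- i; events[[length(events) + 1]] <- ev }
  }
  events <- if (length(events)) do.call(rbind, events) else {
    e <- .empty_events(); e$colony <- integer(); e
  }
  summary <- list(
    n_cells = config$n_cells, dose = config$sim$dose, seed = config$seed,
    n_sectored = exp$n_sectored,
    n_selected_sectored = exp$n_selected_sectored,
    sector_frequency = exp$sector_frequency,
    n_events = if (nrow(events)) nrow(events) else 0L,
    events_per_cell = (if (nrow(events)) nrow(events) else 0L) /
      config$n_cells,
    kind_counts = if (nrow(events))
      as.list(table(events$kind)) else list())
  out <- list(experiment = exp, events = events, summary = summary,
              genome = genome)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.yaml")
    cfg_out <- unclass(config)
    cfg_out$sim <- unclass(cfg_out$sim)
    cfg_out$sim$pathway_probs <- as.list(cfg_out$sim$pathway_probs)
    yaml::write_yaml(cfg_out, cfg_path)
    summary$config_hash <- unname(tools::md5sum(cfg_path))
    if (nrow(events))
      write_events(events, file.path(out_dir, "run"))
    write_snp_map(genome$map, file.path(out_dir, "snp_map.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$summary <- summary
    invisible(out)
  } else out
}
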