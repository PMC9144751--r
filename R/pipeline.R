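#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]. In `simulate`
#' mode the scenario defaults reproduce the full screen design: 7
#' treatments x 3 conditions x 48 plants imaged at 14 twice-daily
#' timepoints, plus a metabolite table with 4 replicates per group. In
#' `ingest` mode, paths to plate images, a layout JSON and a well-map CSV
#' must be supplied.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param scenario Named list of overrides passed to [growth_scenario()].
#' @param metabolites Named list of overrides passed to
#'   [simulate_metabolites()] (simulate mode) or a `path` to a metabolite
#'   CSV (either mode).
#' @param segmentation List: `threshold`, `min_object_px`.
#' @param traits List: `auc_mode`.
#' @param pbci List: `bootstrap` (logical), `n_boot`.
#' @param stats List: `posthoc`, `alpha`, `pca_mode`.
#' @param paths List for ingest mode: `images` (character vector),
#'   `times` (days, one per image), `layout` (JSON path), `well_map`
#'   (CSV path with well, plant_id, treatment, concentration, condition).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"), seed = 1L,
                            scenario = list(), metabolites = list(),
                            segmentation = list(threshold = 40, min_object_px = 25),
                            traits = list(auc_mode = "trapezoid"),
                            pbci = list(bootstrap = FALSE, n_boot = 1000),
                            stats = list(posthoc = "tukey", alpha = 0.05,
                                         pca_mode = "group_means"),
                            paths = list()) {
  mode <- match.arg(mode)
  alpha <- stats$alpha %||% 0.05
  if (!(alpha > 0 && alpha < 1)) {
    stop_invalid("pipeline_config", "alpha must lie in (0, 1)")
  }
  structure(
    list(mode = mode, seed = as.integer(seed), scenario = scenario,
         metabolites = metabolites, segmentation = segmentation,
         traits = traits, pbci = pbci, stats = stats, paths = paths),
    class = "pipeline_config"
  )
}

#' Write a pipeline config to JSON / read it back
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname config_io
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("pipeline_config", sprintf("config file not found: %s", path))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j[intersect(names(j), names(formals(pipeline_config)))])
}

run_stage <- function(out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          parent = e)
  })
}

write_matrix_csv <- function(m, path, rowname_col = "row") {
  df <- tibble::as_tibble(m, rownames = rowname_col)
  readr::write_csv(df, path)
}

#' Run the full phenotyping pipeline
#'
#' Executes simulate (or ingest + segment) -> traits -> PBCI -> statistics
#' and writes every table plus a JSON run manifest and a plain-text summary
#' report to `out_dir`. All randomness derives from the config seed, so two
#' runs with the same config produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`series`,
#'   `traits`, `pbci`, `kruskal`, `metabolites`, `anova`, `pca`,
#'   `correlation`, `heatmap`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  seeds <- derive_seeds(config$seed, 3)

  series <- run_stage(out_dir, "simulate", {
    if (config$mode == "simulate") {
      sc <- do.call(growth_scenario, c(config$scenario, list(seed = seeds[1])))
      simulate_growth(sc)
    } else {
      p <- config$paths
      if (is.null(p$layout) || !file.exists(p$layout)) {
        stop_invalid("pipeline_config",
                     sprintf("layout file not found: %s", p$layout %||% "<missing>"))
      }
      layout <- read_layout_json(p$layout)
      well_map <- readr::read_csv(p$well_map, show_col_types = FALSE)
      scenes <- purrr::map2(p$images, p$times, ~ read_scene(.x, layout, .y))
      extract_time_series(scenes, well_map,
                          threshold = config$segmentation$threshold %||% 40,
                          min_object_px = config$segmentation$min_object_px %||% 25)
    }
  })
  write_series_csv(series, file.path(out_dir, "series.csv"))

  traits <- run_stage(out_dir, "traits",
    trait_table(series, auc_mode = config$traits$auc_mode %||% "trapezoid"))
  write_trait_csv(traits, file.path(out_dir, "traits.csv"))

  alpha <- config$stats$alpha %||% 0.05
  records <- run_stage(out_dir, "pbci", pbci_table(traits))
  readr::write_csv(records, file.path(out_dir, "pbci.csv"))
  pc_tab <- parallel_coordinates_table(
    dplyr::filter(records, .data$treatment != "control"))
  readr::write_csv(pc_tab, file.path(out_dir, "parallel_coordinates.csv"))

  kw <- run_stage(out_dir, "stats", {
    purrr::map_dfr(unique(traits$condition),
                   ~ kruskal_auc(traits, .x, alpha = alpha))
  })
  readr::write_csv(kw, file.path(out_dir, "kruskal_auc.csv"))

  metab <- run_stage(out_dir, "metabolites", {
    if (!is.null(config$metabolites$path)) {
      read_metabolite_csv(config$metabolites$path)
    } else {
      args <- config$metabolites
      args$path <- NULL
      do.call(simulate_metabolites, c(args, list(seed = seeds[2])))
    }
  })
  write_metabolite_csv(metab, file.path(out_dir, "metabolites.csv"))

  results <- run_stage(out_dir, "stats", {
    an <- metabolite_anova(metab, posthoc = config$stats$posthoc %||% "tukey",
                           alpha = alpha)
    pca <- metabolite_pca(metab, mode = config$stats$pca_mode %||% "group_means")
    cm <- pearson_matrix(metabolite_matrix(metab))
    hm <- heatmap_matrix(metab, anova = an)
    list(anova = an, pca = pca, correlation = cm, heatmap = hm)
  })
  readr::write_csv(results$anova, file.path(out_dir, "metabolite_anova.csv"))
  write_matrix_csv(results$pca$scores, file.path(out_dir, "pca_scores.csv"))
  write_matrix_csv(results$pca$loadings, file.path(out_dir, "pca_loadings.csv"),
                   rowname_col = "variable")
  readr::write_csv(
    tibble::tibble(component = paste0("PC", seq_along(results$pca$variance_explained)),
                   variance_explained = results$pca$variance_explained),
    file.path(out_dir, "pca_variance.csv"))
  write_matrix_csv(results$correlation$r, file.path(out_dir, "correlation_r.csv"),
                   rowname_col = "variable")
  write_matrix_csv(results$correlation$p, file.path(out_dir, "correlation_p.csv"),
                   rowname_col = "variable")
  write_matrix_csv(results$heatmap$matrix, file.path(out_dir, "heatmap_matrix.csv"),
                   rowname_col = "metabolite")

  manifest <- list(
    package = "phenoprime",
    version = as.character(utils::packageVersion("phenoprime")),
    config = unclass(config),
    stage_seeds = as.list(setNames(seeds, c("growth", "metabolites", "reserved")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  report <- c(
    "Plant Biostimulant Characterization Index summary",
    sprintf("%-12s %-14s %-10s %8s  %s",
            "treatment", "concentration", "condition", "PBCI", "label"),
    sprintf("%-12s %-14s %-10s %8.3f  %s",
            records$treatment, paste0(records$concentration, " mM"),
            records$condition, records$pbci, records$label)
  )
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(series = series, traits = traits, pbci = records,
                 parallel_coordinates = pc_tab, kruskal = kw,
                 metabolites = metab, anova = results$anova,
                 pca = results$pca, correlation = results$correlation,
                 heatmap = results$heatmap, out_dir = out_dir))
}
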