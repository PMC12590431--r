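# End-to-end driver: calibrated oracle -> active learning -> region
# search -> survival maps, with CSV/JSON artefacts and a markdown report.

.write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full study pipeline and write a report
#'
#' Chains the package end to end with the packaged calibrated oracle: an
#' active-learning run (30 Sobol + 78 acquisitions by default, validated
#' on 100 Sobol points), the 5000-candidate near-optimal region search
#' restricted to the laboratory press window, and survival maps at fixed
#' main pressures of 250/300/350/400 MPa. Artefacts (`train.csv`,
#' `val.csv`, `history.csv`, `model.json`, `candidates.csv`,
#' `retained.csv`, `shape.json`, `map_<P>MPa.csv`, `report.md`,
#' `config.yaml`) are written under `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [load_config()] result (defaults).
#' @param verbose print per-iteration progress.
#' @return list with `al` (the [run_al()] state), `region`, `maps` and
#'   the path of the markdown report.
#' @export
run_pipeline <- function(out_dir, config = load_config(), verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- resolve_config(config)
  write_config(config, file.path(out_dir, "config.yaml"))

  failure <- NULL
  al <- region <- maps <- NULL
  tryCatch({
    al <- run_al(res$space, res$al, res$params, verbose = verbose)
    .write_points_csv(al$train, file.path(out_dir, "train.csv"))
    .write_points_csv(al$validation, file.path(out_dir, "val.csv"))
    .write_points_csv(al$history, file.path(out_dir, "history.csv"))
    gp_save(al$model, file.path(out_dir, "model.json"))

    cand_space <- if (isTRUE(config$region$lab_space)) design_space_lab()
    else res$space
    region <- find_optimal_region(al$model, res$space,
                                  n_candidates = config$region$n_candidates,
                                  frac = config$region$frac,
                                  alpha = config$region$alpha,
                                  seed = config$seed + 40000L,
                                  candidate_space = cand_space)
    .write_points_csv(region$candidates, file.path(out_dir, "candidates.csv"))
    .write_points_csv(region$retained, file.path(out_dir, "retained.csv"))
    if (!is.null(region$shape))
      jsonlite::write_json(
        list(alpha = region$shape$alpha, volume = region$shape$volume,
             vertices = region$shape$points, facets = region$shape$facets),
        file.path(out_dir, "shape.json"), auto_unbox = TRUE, digits = NA)

    maps <- lapply(config$maps$main, function(mp) {
      m <- survival_map(res$params, res$space, mp,
                        speed_range = config$maps$speed,
                        pre_range = config$maps$pre,
                        n_speed = config$maps$n_speed,
                        n_pre = config$maps$n_pre)
      utils::write.csv(as.data.frame(m$values,
                                     row.names = sprintf("%g", m$speed)),
                       file.path(out_dir, sprintf("map_%gMPa.csv", mp)))
      m
    })
    names(maps) <- sprintf("%gMPa", config$maps$main)
  }, error = function(e) failure <<- conditionMessage(e))

  report <- file.path(out_dir, "report.md")
  lines <- c("# Probiotic tabletting optimisation run", "")
  if (!is.null(al)) {
    last <- al$history[nrow(al$history), ]
    lines <- c(lines,
      sprintf("- training-set size: %d", nrow(al$train)),
      sprintf("- final validation R2: %.4f (reference: >= 0.96)", last$r2),
      sprintf("- final validation RMSE: %.4f (reference: <= 0.06)",
              last$rmse))
  }
  if (!is.null(region) && nrow(region$retained) > 0) {
    lines <- c(lines,
      sprintf("- near-optimal region: %d points, main %.0f-%.0f MPa, pre %.0f-%.0f MPa (reference: main ~70-150, pre ~0-75)",
              nrow(region$retained), min(region$retained$main_MPa),
              max(region$retained$main_MPa), min(region$retained$pre_MPa),
              max(region$retained$pre_MPa)))
  }
  if (!is.null(maps)) {
    for (nm in names(maps)) {
      m <- maps[[nm]]
      lines <- c(lines, sprintf("- map %s: survival %.3f-%.3f", nm,
                                min(m$values), max(m$values)))
    }
  }
  if (!is.null(failure))
    lines <- c(lines, "", paste("**PIPELINE FAILURE:**", failure))
  writeLines(lines, report)
  list(al = al, region = region, maps = maps, report = report,
       failure = failure)
}
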