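#' Pipeline configuration
#'
#' All tunables of the end-to-end run in one serializable list. A single
#' master seed fans out to fixed per-stage sub-seeds (sampling: seed;
#' landmarks/clustering: seed + 1) so stages can be re-run independently.
#'
#' @param start,goal paths to endpoint PDB files, or \code{calpha}
#'   structures.
#' @param chain optional chain selector applied to both files.
#' @param method reduction method, \code{"isomap"} or \code{"sphpca"}.
#' @param dim embedding dimension (default 3).
#' @param max_iterations,rotation_limit,scaling_factor_a,energy_threshold,
#'   skip_angle_tolerance,goal_rmsd_stop see \code{\link{search_params}}.
#' @param gap,min_size,max_levels see \code{\link{topo_cluster}}.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(start, goal, chain = NULL,
                            method = c("isomap", "sphpca"), dim = 3L,
                            max_iterations = 60000L, rotation_limit = 5,
                            scaling_factor_a = 1.0, energy_threshold = NULL,
                            skip_angle_tolerance = 1, goal_rmsd_stop = 1.5,
                            gap = 0.1, min_size = 2L, max_levels = 20L,
                            out_dir = "pathtopo_results", seed = 1L) {
  structure(list(start = start, goal = goal, chain = chain,
                 method = match.arg(method), dim = as.integer(dim),
                 max_iterations = as.integer(max_iterations),
                 rotation_limit = rotation_limit,
                 scaling_factor_a = scaling_factor_a,
                 energy_threshold = energy_threshold,
                 skip_angle_tolerance = skip_angle_tolerance,
                 goal_rmsd_stop = goal_rmsd_stop,
                 gap = gap, min_size = as.integer(min_size),
                 max_levels = as.integer(max_levels),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_structure <- function(x, chain = NULL, what = "input") {
  if (inherits(x, "calpha")) return(x)
  if (!is.character(x) || !file.exists(x))
    stop("pipeline stage 0 (inputs): ", what, " file not found: ", x)
  read_calpha_pdb(x, chain = chain)
}

#' Run the full detection pipeline
#'
#' Executes sample -> embed -> landmarks -> barcode -> cluster count ->
#' levels -> outlier pruning -> hierarchy -> report, writing every stage's
#' artifact plus the resolved configuration into \code{config$out_dir}:
#' \code{traj.pdb}/\code{traj.csv}, \code{cloud.csv}/\code{cloud.json},
#' \code{barcode.csv}, \code{clusters.csv}, \code{hierarchy.json},
#' \code{report.csv}, \code{representative_*.pdb}, \code{config.json} and
#' \code{log.txt}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the \code{topo_clustering} fit, invisibly; its \code{traj} and
#'   output paths are attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  note <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }

  start <- resolve_structure(config$start, config$chain, "start")
  goal <- resolve_structure(config$goal, config$chain, "goal")

  params <- search_params(max_iterations = config$max_iterations,
                          rotation_limit = config$rotation_limit,
                          scaling_factor_a = config$scaling_factor_a,
                          energy_threshold = config$energy_threshold,
                          skip_angle_tolerance = config$skip_angle_tolerance,
                          goal_rmsd_stop = config$goal_rmsd_stop,
                          seed = config$seed)
  traj <- run_search(start, goal, params)
  note("sampling: %d proposals, %d accepted (%.1f%%), best RMSD %.3f A",
       traj$iterations, traj$accepted,
       if (traj$iterations > 0) 100 * traj$accepted / traj$iterations else 0,
       min(traj$rmsd_to_goal))
  write_trajectory(traj, file.path(config$out_dir, "traj.pdb"),
                   file.path(config$out_dir, "traj.csv"))

  cloud <- embed_trajectory(traj, method = config$method, d = config$dim)
  note("embedding (%s): %d points, explained variance %s%s",
       cloud$method, nrow(cloud$points),
       paste(sprintf("%.3f", cloud$explained_variance), collapse = " "),
       if (!is.null(cloud$k)) sprintf(", K = %d", cloud$k) else "")
  write_cloud(cloud, file.path(config$out_dir, "cloud.csv"),
              file.path(config$out_dir, "cloud.json"))

  fit <- topo_cluster(cloud, traj = traj, endpoints = list(start, goal),
                      seed = config$seed + 1L, gap = config$gap,
                      min_size = config$min_size,
                      max_levels = config$max_levels)
  note("landmarks: %d (coverage R = %.4g); %d retained after pruning",
       length(fit$landmarks$indices), fit$landmarks$coverage_radius,
       length(fit$retained))
  note("clusters: %d by the bar-gap rule; per-level scales: %s",
       fit$n_clusters,
       paste(sprintf("%.4g", vapply(fit$levels, `[[`, numeric(1), "scale")),
             collapse = ", "))

  write_barcode(fit$barcode, file.path(config$out_dir, "barcode.csv"))
  utils::write.csv(data.frame(landmark_index = fit$retained,
                              cluster = fit$membership),
                   file.path(config$out_dir, "clusters.csv"),
                   row.names = FALSE)
  hier_json <- list(levels = lapply(fit$levels, function(lv) {
    list(level = lv$level, scale = lv$scale, membership = lv$membership)
  }), nodes = fit$hierarchy$nodes, landmarks = fit$retained)
  jsonlite::write_json(hier_json, file.path(config$out_dir, "hierarchy.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(fit$report)) {
    utils::write.csv(as.data.frame(fit$report),
                     file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
    for (r in seq_len(nrow(fit$report))) {
      write_calpha_pdb(trajectory_structure(traj, fit$report$representative[r]),
                       file.path(config$out_dir,
                                 sprintf("representative_%02d.pdb", r)))
    }
  }
  cfg <- config
  cfg$start <- if (inherits(config$start, "calpha")) config$start$id else config$start
  cfg$goal <- if (inherits(config$goal, "calpha")) config$goal$id else config$goal
  jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  fit$out_dir <- config$out_dir
  invisible(fit)
}
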