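#' Pipeline configuration
#'
#' Bundles the full protocol — steered runs to seed a path, frameset
#' extraction, metadynamics on (S, Z), and analysis — for the funnel-pocket
#' toy system. All seeds are explicit; rerunning with the same
#' configuration reproduces every output bitwise.
#'
#' @param system A [toy_pocket_spec()].
#' @param params [langevin_params()] shared by all stages.
#' @param smd_seeds Seeds for the steering realisations (default 5 runs).
#' @param smd An [smd_config()]; selections default to the pocket groups.
#' @param frameset_P Number of frameset configurations (default 18).
#' @param metad A [metad_config()].
#' @param max_metad_steps Safety cap for the metadynamics stage.
#' @param smd_traj_stride,metad_traj_stride Frame-recording strides.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(system = toy_pocket_spec(),
                            params = langevin_params(),
                            smd_seeds = 1:5,
                            smd = smd_config("ligand_heavy",
                                             "pocket_bottom_ref",
                                             target_extension = 7.5),
                            frameset_P = 18,
                            metad = metad_config(),
                            max_metad_steps = 2e6,
                            smd_traj_stride = 200,
                            metad_traj_stride = 500) {
  structure(list(system = system, params = params, smd_seeds = smd_seeds,
                 smd = smd, frameset_P = frameset_P, metad = metad,
                 max_metad_steps = max_metad_steps,
                 smd_traj_stride = smd_traj_stride,
                 metad_traj_stride = metad_traj_stride),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; top-level keys mirror the [pipeline_config()]
#'   arguments (`system`, `params`, `smd`, ...).
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  if (!is.null(y$system)) cfg$system <- do.call(toy_pocket_spec, y$system)
  if (!is.null(y$params)) cfg$params <- do.call(langevin_params, y$params)
  if (!is.null(y$smd_seeds)) cfg$smd_seeds <- as.integer(y$smd_seeds)
  if (!is.null(y$smd)) cfg$smd <- do.call(smd_config, modifyList(
    list(group_a = "ligand_heavy", group_b = "pocket_bottom_ref"), y$smd))
  if (!is.null(y$frameset_P)) cfg$frameset_P <- y$frameset_P
  if (!is.null(y$metad)) cfg$metad <- do.call(metad_config, y$metad)
  for (k in c("max_metad_steps", "smd_traj_stride", "metad_traj_stride"))
    if (!is.null(y[[k]])) cfg[[k]] <- y[[k]]
  cfg
}

#' Run the full (un)binding pipeline
#'
#' Stages, each reading its inputs from and writing its outputs to the run
#' directory (so any suffix of stages can be rerun against existing
#' artifacts): `smd` (steered realisations, one per seed, plus selection of
#' the lowest-work run), `path` (frameset extraction from the selected
#' run), `metad` (path-CV metadynamics until recrossing or the step cap),
#' `analysis` (FES, basins, hydration map). A manifest with the package
#' version, seeds, configuration and output checksums goes to
#' `logs/manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @param stages Character subset of `c("smd", "path", "metad",
#'   "analysis")`, in order.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("smd", "path", "metad", "analysis")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("smd", "path", "metad", "analysis"),
                      several.ok = TRUE)
  for (d in c("pulls", "path", "hills", "fes", "analysis", "logs"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "logs", "pipeline.log"), "a")
  on.exit(close(log_con))
  say <- function(...) writeLines(sprintf(...), log_con)

  stage_wrap <- function(name, expr) {
    say("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sys <- build_toy_pocket(config$system)

  if ("smd" %in% stages) stage_wrap("smd", {
    recs <- lapply(seq_along(config$smd_seeds), function(i) {
      p <- config$params
      p$seed <- config$smd_seeds[i]
      rec <- run_smd(sys$potential, sys$configuration, p, config$smd,
                     run_id = i, traj_stride = config$smd_traj_stride)
      write_pull_record(rec, file.path(out_dir, "pulls",
                                       sprintf("run%d.tsv", i)))
      write_xyz(attr(rec, "trajectory"),
                file.path(out_dir, "pulls", sprintf("run%d.xyz", i)))
      rec
    })
    best <- select_lowest_work(recs)
    writeLines(as.character(attr(best, "run_id")),
               file.path(out_dir, "pulls", "selected.txt"))
    say("[smd] selected run %s (work %.3f kcal/mol)",
        attr(best, "run_id"), final_work(best))
  })

  if ("path" %in% stages) stage_wrap("path", {
    sel <- as.integer(readLines(file.path(out_dir, "pulls", "selected.txt")))
    traj <- read_xyz(file.path(out_dir, "pulls", sprintf("run%d.xyz", sel)))
    tmpl <- sys$configuration
    traj$frames <- lapply(traj$frames, function(f) {
      tmpl$coords <- f$coords
      tmpl
    })
    fs <- extract_frameset(traj, config$frameset_P, "pocket_ref",
                           "ligand_heavy")
    write_frameset(fs, file.path(out_dir, "path", "frameset"))
    say("[path] P = %d, lambda = %.4g", length(fs$frames), fs$lambda)
  })

  if ("metad" %in% stages) stage_wrap("metadynamics", {
    fs <- read_frameset(file.path(out_dir, "path", "frameset"))
    run <- run_metadynamics(sys$potential, sys$configuration, config$params,
                            fs, config$metad,
                            max_steps = config$max_metad_steps,
                            traj_stride = config$metad_traj_stride)
    write_hills(run$hills, file.path(out_dir, "hills", "hills.dat"))
    write.table(run$series, file.path(out_dir, "hills", "series.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_xyz(run$trajectory, file.path(out_dir, "hills", "traj.xyz"))
    say("[metadynamics] %d hills, recrossing at %s ps", nrow(run$hills),
        format(run$recross_time))
  })

  if ("analysis" %in% stages) stage_wrap("analysis", {
    hills <- read_hills(file.path(out_dir, "hills", "hills.dat"))
    fes <- reconstruct_fes(hills)
    write_fes_table(fes, file.path(out_dir, "fes", "fes.tsv"))
    basins <- find_basins(fes)
    write.table(as.data.frame(basins),
                file.path(out_dir, "analysis", "basins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    series <- read.table(file.path(out_dir, "hills", "series.tsv"),
                         header = TRUE, sep = "\t")
    traj <- read_xyz(file.path(out_dir, "hills", "traj.xyz"))
    tmpl <- sys$configuration
    traj$frames <- lapply(traj$frames, function(f) {
      tmpl$coords <- f$coords
      tmpl
    })
    s_at <- approx(series$time, series$s, xout = traj$times, rule = 2)$y
    axis <- segment_axis(c(0, 0, -1.5), c(0, 0, config$system$channel_length / 2 + 1))
    hyd <- hydration_map(traj, s_at, axis)
    write.table(as.data.frame.matrix(unclass(hyd)),
                file.path(out_dir, "analysis", "hydration.tsv"),
                sep = "\t", quote = FALSE)
    say("[analysis] %d basins", nrow(basins))
  })

  cfg_yaml <- file.path(out_dir, "logs", "config.yaml")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "list"), cfg_yaml)
  files <- list.files(file.path(out_dir, c("pulls", "path", "hills")),
                      full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  manifest <- list(
    package = as.character(utils::packageVersion("pathmeta")),
    seeds = list(smd = config$smd_seeds, dynamics = config$params$seed,
                 system = config$system$seed),
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(out_dir, "logs", "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

#' @importFrom stats approx
NULL
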