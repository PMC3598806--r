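# End-to-end analysis orchestration from a config: pocket metrics, site
# expansion, prong distances, beta scaffold, RMSF, virtual dihedrals and the
# hydrophobic panel, each emitting CSV plus a machine-readable JSON summary.
# A failure in one stage is recorded in the stage-status table and does not
# silently skip the others.

#' Analysis run configuration
#'
#' @param structure path to the reference structure (PDB); optional when the
#'   trajectory is a multi-MODEL PDB (its first model is the topology).
#' @param trajectory path to the trajectory (multi-MODEL PDB or xyz-table).
#' @param trajectory_format \code{"pdb"} or \code{"xyz"}.
#' @param chains a \code{\link{chain_map}} (or a list with a \code{tnc}
#'   entry, e.g. parsed from YAML).
#' @param pocket_residues the two pocket anchor residues, default
#'   \code{c(16, 48)}.
#' @param sites list of \code{\link{ef_site}}s; default sites I and II.
#' @param virtual_dihedrals list of \code{\link{virtual_dihedral}}s; default
#'   VD1 and VD2.
#' @param thresholds named list: \code{closed_max}, \code{semi_closed_max},
#'   \code{hbond_formed_max}, \code{prong_contact_max}, \code{contact_cutoff},
#'   \code{event_min_dwell}.
#' @param window window for state classification, as in
#'   \code{\link{window_stats}}.
#' @param rmsf_range residue range analysed for RMSF, default \code{c(5, 80)}.
#' @param out_dir output directory for \code{\link{write_report}}.
#' @param seed seed recorded for any stochastic step.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(structure = NULL, trajectory, trajectory_format = "pdb",
                       chains, pocket_residues = c(16L, 48L),
                       sites = NULL, virtual_dihedrals = NULL,
                       thresholds = list(), window = "all",
                       rmsf_range = c(5L, 80L), out_dir = NULL, seed = 1L,
                       log_level = "info") {
  if (is.list(chains) && !inherits(chains, "chain_map"))
    chains <- chain_map(tnc = chains$tnc, tni = chains$tni, tnt = chains$tnt)
  def <- list(closed_max = 14.5, semi_closed_max = 18.0,
              hbond_formed_max = 2.5, prong_contact_max = 3.5,
              contact_cutoff = 4.5, event_min_dwell = 5L)
  thresholds <- utils::modifyList(def, thresholds)
  if (is.null(sites))
    sites <- list(ef_site("I", chain = chains$tnc),
                  ef_site("II", chain = chains$tnc))
  if (is.null(virtual_dihedrals))
    virtual_dihedrals <- list(virtual_dihedral("VD1", chain = chains$tnc),
                              virtual_dihedral("VD2", chain = chains$tnc))
  structure(list(structure = structure, trajectory = trajectory,
                 trajectory_format = trajectory_format, chains = chains,
                 pocket_residues = as.integer(pocket_residues), sites = sites,
                 virtual_dihedrals = virtual_dihedrals,
                 thresholds = thresholds, window = window,
                 rmsf_range = as.integer(rmsf_range), out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path path to a YAML config.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  cm <- chain_map(tnc = y$chains$tnc, tni = y$chains$tni, tnt = y$chains$tnt)
  sites <- NULL
  if (!is.null(y$sites))
    sites <- lapply(y$sites, function(s)
      ef_site(s$site_id, chain = cm$tnc, loop_start = s$loop_start))
  run_config(structure = y$structure, trajectory = y$trajectory,
             trajectory_format = y$trajectory_format %||% "pdb",
             chains = cm,
             pocket_residues = y$pocket_residues %||% c(16L, 48L),
             sites = sites,
             thresholds = y$thresholds %||% list(),
             window = y$window %||% "all",
             rmsf_range = y$rmsf_range %||% c(5L, 80L),
             out_dir = y$out_dir, seed = y$seed %||% 1L,
             log_level = y$log_level %||% "info")
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  problems <- character(0)
  if (is.null(config$trajectory) || !file.exists(config$trajectory))
    problems <- c(problems, paste0("trajectory file not found: ",
                                   config$trajectory))
  if (!is.null(config$structure) && !file.exists(config$structure))
    problems <- c(problems, paste0("structure file not found: ",
                                   config$structure))
  if (identical(config$trajectory_format, "xyz") && is.null(config$structure))
    problems <- c(problems, "xyz trajectories need a reference structure")
  th <- config$thresholds
  for (nm in c("closed_max", "semi_closed_max", "hbond_formed_max",
               "prong_contact_max", "contact_cutoff"))
    if (!is_scalar_number(th[[nm]]) || th[[nm]] <= 0)
      problems <- c(problems, paste0("threshold ", nm, " must be > 0"))
  if (is_scalar_number(th$closed_max) && is_scalar_number(th$semi_closed_max) &&
      th$closed_max >= th$semi_closed_max)
    problems <- c(problems, "closed_max must be below semi_closed_max")
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

config_as_plain_list <- function(config) {
  list(structure = config$structure, trajectory = config$trajectory,
       trajectory_format = config$trajectory_format,
       chains = list(tnc = config$chains$tnc, tni = config$chains$tni,
                     tnt = config$chains$tnt),
       pocket_residues = config$pocket_residues,
       sites = lapply(config$sites, function(s)
         list(site_id = s$site_id, loop_start = s$loop_residues[1L])),
       virtual_dihedrals = lapply(config$virtual_dihedrals, function(v)
         list(label = v$label, residues = v$residues)),
       thresholds = config$thresholds,
       window = config$window, rmsf_range = config$rmsf_range,
       seed = config$seed, log_level = config$log_level)
}

series_frame <- function(series_list) {
  if (inherits(series_list, "metric_series"))
    series_list <- stats::setNames(list(series_list), series_list$name)
  out <- data.frame(frame = series_list[[1L]]$frames)
  for (nm in names(series_list)) out[[nm]] <- series_list[[nm]]$values
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: pocket metrics, site expansion, prong distances,
#' beta-sheet scaffold, RMSF, virtual dihedrals and the hydrophobic panel.
#' Each stage is wrapped so a failure is captured in the status table rather
#' than aborting the run.
#'
#' @param config a \code{\link{run_config}} or a path to a YAML config file.
#' @return a \code{run_bundle}: list with \code{summary}, \code{tables}
#'   (per-stage data.frames of per-frame metrics), \code{events},
#'   \code{status} (stage status table), \code{config} and \code{log}.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", "stage", sprintf(...))
    if (identical(config$log_level, "info")) message(sprintf(...))
    log_lines <<- c(log_lines, sprintf(...))
  }

  topo <- NULL
  if (!is.null(config$structure)) topo <- read_structure(config$structure)
  traj <- if (identical(config$trajectory_format, "xyz"))
    read_trajectory(config$trajectory, format = "xyz", topology = topo)
  else read_trajectory(config$trajectory, format = "pdb")
  validate_chain_map(config$chains, traj$topology)
  tnc <- config$chains$tnc
  th <- config$thresholds
  f <- n_frames(traj)
  note("loaded trajectory: %d frames x %d atoms", f, nrow(traj$topology$atoms))

  tables <- list(); summary <- list(); events <- list()
  status <- data.frame(stage = character(0), status = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    dt <- proc.time()[["elapsed"]] - t0
    if (res$ok) {
      note("stage %-18s ok    (%d frames, %.2fs)", name, f, dt)
      status <<- rbind(status, data.frame(stage = name, status = "ok",
                                          detail = "", stringsAsFactors = FALSE))
    } else {
      note("stage %-18s ERROR (%s)", name, res$msg)
      status <<- rbind(status, data.frame(stage = name, status = "error",
                                          detail = res$msg,
                                          stringsAsFactors = FALSE))
    }
    if (res$ok) res$value else NULL
  }

  run_stage("pocket", function() {
    s <- pocket_openness_series(traj, config$pocket_residues[1L],
                                config$pocket_residues[2L], chain = tnc)
    ws <- window_stats(s, config$window)
    thr <- pocket_state_thresholds(th$closed_max, th$semi_closed_max)
    tables$pocket <<- series_frame(s)
    summary$pocket <<- list(
      mean = unname(ws["mean"]), sd = unname(ws["sd"]), n = unname(ws["n"]),
      state = classify_pocket_state(unname(ws["mean"]), thr),
      anchors = s$anchors)
    invisible(NULL)
  })

  run_stage("site_expansion", function() {
    out <- lapply(config$sites, function(site) site_expansion_series(traj, site))
    names(out) <- vapply(config$sites, function(s)
      paste0("site_", s$site_id), character(1))
    tables$site_expansion <<- series_frame(out)
    summary$site_expansion <<- lapply(out, function(s) {
      ws <- window_stats(s, config$window)
      list(mean = unname(ws["mean"]), sd = unname(ws["sd"]))
    })
    invisible(NULL)
  })

  run_stage("prong", function() {
    all <- list()
    ev <- list()
    for (site in config$sites) {
      ser <- prong_distance_series(traj, site)
      names(ser) <- paste0("site_", site$site_id, "_", names(ser))
      all <- c(all, ser)
    }
    tables$prong <<- series_frame(all)
    summary$prong <<- lapply(all, function(s) {
      ws <- window_stats(s, config$window)
      list(mean = unname(ws["mean"]), sd = unname(ws["sd"]),
           formed_fraction = mean(s$values <= th$prong_contact_max))
    })
    for (nm in grep("_OE$", names(all), value = TRUE)) {
      tr <- detect_transitions(all[[nm]], th$prong_contact_max,
                               th$event_min_dwell)
      if (nrow(tr)) ev[[nm]] <- tr
    }
    events$prong <<- ev
    invisible(NULL)
  })

  run_stage("beta_scaffold", function() {
    rep <- beta_scaffold_report(traj, chain = tnc,
                                formed_max = th$hbond_formed_max)
    tables$beta_scaffold <<- series_frame(rep$series)
    summary$beta_scaffold <<- list(formed_fraction = as.list(rep$formed_fraction))
    ev <- list()
    for (nm in names(rep$series)) {
      tr <- detect_transitions(rep$series[[nm]], th$hbond_formed_max,
                               th$event_min_dwell)
      if (nrow(tr)) ev[[nm]] <- tr
    }
    events$beta_scaffold <<- ev
    invisible(NULL)
  })

  run_stage("rmsf", function() {
    sel <- selection(chain = tnc, residue_range = config$rmsf_range,
                     atom_names = "CA")
    prof <- rmsf_profile(traj, analyze = sel, fit = sel, reference = "mean")
    tables$rmsf <<- data.frame(residue = prof$residue, rmsf = prof$rmsf)
    summary$rmsf <<- list(mean = mean(prof$rmsf), max = max(prof$rmsf),
                          max_residue = prof$residue[which.max(prof$rmsf)])
    invisible(NULL)
  })

  run_stage("virtual_dihedrals", function() {
    out <- lapply(config$virtual_dihedrals, function(vd)
      virtual_dihedral_series(traj, vd))
    names(out) <- vapply(config$virtual_dihedrals, `[[`, character(1), "label")
    tables$virtual_dihedrals <<- series_frame(out)
    summary$virtual_dihedrals <<- lapply(out, function(s)
      list(first = s$values[1L], last = s$values[length(s$values)],
           delta = wrap_angle(s$values[length(s$values)] - s$values[1L])))
    invisible(NULL)
  })

  run_stage("hydrophobic", function() {
    panel <- default_contact_panel(tnc, cutoff = th$contact_cutoff)
    pers <- contact_persistence(traj, panel)
    tables$hydrophobic <<- pers
    summary$hydrophobic <<- stats::setNames(as.list(pers$persistence),
                                            pers$pair)
    invisible(NULL)
  })

  summary$frames <- f
  summary$stage_status <- status
  bundle <- list(summary = summary, tables = tables, events = events,
                 status = status, config = config, log = log_lines)
  class(bundle) <- "run_bundle"
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("analysis bundle:", nrow(x$status), "stages;",
      sum(x$status$status == "ok"), "ok\n")
  if (!is.null(x$summary$pocket))
    cat(sprintf("  pocket: mean %.2f A (%s)\n", x$summary$pocket$mean,
                x$summary$pocket$state))
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Layout: \code{metrics/*.csv}, \code{summary.json}, \code{events.json},
#' \code{run.log} and \code{config.echo.yaml}. Every JSON summary cites the
#' MD5 hash of the echoed config for provenance.
#'
#' @param bundle a \code{run_bundle} from \code{\link{run_analysis}}.
#' @param out_dir output directory; defaults to the config's \code{out_dir}.
#' @return the output directory, invisibly.
#' @export
write_report <- function(bundle, out_dir = NULL) {
  stopifnot(inherits(bundle, "run_bundle"))
  out_dir <- out_dir %||% bundle$config$out_dir
  if (is.null(out_dir)) stop("write_report: no output directory", call. = FALSE)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("write_report: cannot create output directory ", out_dir,
         call. = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE)))
    stop("write_report: output directory is not writable", call. = FALSE)
  unlink(probe)

  echo_path <- file.path(out_dir, "config.echo.yaml")
  yaml::write_yaml(config_as_plain_list(bundle$config), echo_path)
  config_hash <- unname(tools::md5sum(echo_path))

  dir.create(file.path(out_dir, "metrics"), showWarnings = FALSE)
  for (nm in names(bundle$tables))
    utils::write.csv(bundle$tables[[nm]],
                     file.path(out_dir, "metrics", paste0(nm, ".csv")),
                     row.names = FALSE)

  summary <- bundle$summary
  summary$config_hash <- config_hash
  summary$stage_status <- NULL
  summary$stages <- lapply(seq_len(nrow(bundle$status)), function(i)
    as.list(bundle$status[i, ]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  flat_events <- list()
  for (stage in names(bundle$events)) {
    for (nm in names(bundle$events[[stage]])) {
      tr <- bundle$events[[stage]][[nm]]
      for (i in seq_len(nrow(tr)))
        flat_events[[length(flat_events) + 1L]] <- list(
          stage = stage, pair = nm, kind = tr$kind[i], frame = tr$frame[i])
    }
  }
  jsonlite::write_json(list(config_hash = config_hash, events = flat_events),
                       file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
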