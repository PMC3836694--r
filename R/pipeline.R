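# End-to-end orchestration from a single declarative YAML/JSON config:
# simulate -> geometry -> essential dynamics -> torsion clustering -> state
# comparison -> correlation/tally -> conservation -> hinge report. Every
# stage writes CSV/JSON with its parameters echoed, and reruns with the
# same config are byte-identical.

pipeline_defaults <- function() {
  list(k = 60, min_runs = 4, min_occupancy = 0.05, match_radius = 40,
       delta_occ = 0.3, openness_threshold = 29.5, near_cutoff = 8,
       bend_threshold = 30, identity_min = 90,
       groups_required = c("bacteria", "animals"),
       n_runs = 5, n_frames = 300, seed = 1,
       states = c("apo", "ATP", "ADP_Pi"))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) config, rejects unknown keys, fills defaults
#' (k = 60 top correlations, tally threshold 4 runs, cluster occupancy
#' floor 0.05, state-shift match radius 40 deg / occupancy delta 0.3,
#' openness threshold 29.5 A, near-ligand cutoff 8 A) and range-checks
#' every parameter.
#'
#' @param config path to a config file, or an equivalent named list.
#' @return A `run_config` list with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a file path or a list")
  defs <- pipeline_defaults()
  known <- c(names(defs), "simulate", "trajectories", "conservation",
             "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, config)
  chk <- function(cond, msg) if (!cond) stopf("config: %s", msg)
  chk(cfg$k >= 1, "k must be >= 1")
  chk(cfg$min_runs >= 1, "min_runs must be >= 1")
  chk(cfg$min_occupancy > 0 && cfg$min_occupancy < 1,
      "min_occupancy must be in (0, 1)")
  chk(cfg$match_radius > 0, "match_radius must be positive")
  chk(cfg$delta_occ > 0 && cfg$delta_occ <= 1, "delta_occ must be in (0, 1]")
  chk(cfg$openness_threshold > 0, "openness_threshold must be positive")
  chk(cfg$near_cutoff > 0, "near_cutoff must be positive")
  chk(cfg$n_runs >= 1 && cfg$n_frames >= 10, "n_runs/n_frames too small")
  if (is.null(config$simulate) && is.null(config$trajectories))
    stopf("config needs either 'simulate' or 'trajectories'")
  if (!is.null(config$trajectories)) {
    for (st in names(config$trajectories)) {
      for (p in config$trajectories[[st]])
        if (!file.exists(p)) stopf("config: missing trajectory file %s", p)
    }
  }
  if (!is.null(config$conservation)) {
    for (key in c("msa", "groups"))
      if (!is.null(config$conservation[[key]]) &&
          !file.exists(config$conservation[[key]]))
        stopf("config: missing conservation file %s", config$conservation[[key]])
  }
  cfg$out_dir <- cfg$out_dir %||% "hingescan_out"
  class(cfg) <- "run_config"
  cfg
}

write_stage_csv <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full hinge-detection pipeline
#'
#' Executes all stages in order on simulated (or supplied) per-state
#' ensembles and writes `openness.csv`, `eigen.csv`, `clusters.csv`,
#' `state_shifts.csv`, `tally.csv`, optional `conservation.csv`,
#' `report.csv`, `report.json` and `log.txt` (parameter echo) into the
#' output directory. Nucleotide correlation is tallied over the runs of
#' the nucleotide-bound states (ATP and ADP/Pi), matching the
#' 4-of-10-trajectories significance rule.
#'
#' @param config a [validate_config()] result (or something it accepts).
#' @param out_dir overrides the configured output directory.
#' @return The hinge report (invisibly); side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  ## ---- simulate / load -------------------------------------------------
  ensembles <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      lapply(stats::setNames(cfg$states, cfg$states), function(st) {
        sp <- plant_spec(
          n_residues = sim$n_residues %||% 120, state = st,
          openness_sd = sim$openness_sd %||% 1.0,
          hinges = sim$hinges %||% "default",
          coupled = if (st == "apo") NULL else sim$coupled %||% "default",
          noise_sd = sim$noise_sd %||% 0.1,
          seed = (sim$seed %||% cfg$seed) + match(st, cfg$states) * 1000)
        generate_ensemble(sp, cfg$n_runs, cfg$n_frames)
      })
    } else {
      lapply(stats::setNames(names(cfg$trajectories), names(cfg$trajectories)),
             function(st) {
        runs <- lapply(seq_along(cfg$trajectories[[st]]), function(k) {
          tr <- read_trajectory(cfg$trajectories[[st]][k],
                                label = sprintf("%s_run%d", st, k))
          list(trajectory = tr, ligand = NULL, truth = NULL)
        })
        list(runs = runs, truth = NULL)
      })
    }
  })
  states <- names(ensembles)
  n_res <- max(ensembles[[1]]$runs[[1]]$trajectory$topology$atoms$resno)
  map <- scaled_subdomain_map(n_res)
  ## ---- geometry: openness ---------------------------------------------
  openness <- stage("geometry", {
    do.call(rbind, lapply(states, function(st) {
      do.call(rbind, lapply(ensembles[[st]]$runs, function(r) {
        o <- openness_series(r$trajectory, map,
                             threshold = cfg$openness_threshold)
        data.frame(state = st, run = r$trajectory$label,
                   mean_A = o$mean, sd_A = o$sd,
                   classification = o$classification)
      }))
    }))
  })
  write_stage_csv(openness, out_dir, "openness.csv")
  ## ---- essential dynamics ---------------------------------------------
  eig <- stage("essential_dynamics", {
    do.call(rbind, lapply(states, function(st) {
      comb <- combine_runs(lapply(ensembles[[st]]$runs, `[[`, "trajectory"))
      ed <- compute_ed(comb)
      k <- seq_len(min(25, length(ed$values)))
      data.frame(state = st, mode = k, eigenvalue_A2 = ed$values[k],
                 cumulative_fraction = ed$cumfrac[k])
    }))
  })
  write_stage_csv(eig, out_dir, "eigen.csv")
  ## ---- torsion clustering + state comparison --------------------------
  clusterings <- stage("torsions", {
    lapply(ensembles, function(e) {
      xyz <- do.call(rbind, lapply(e$runs, function(r) r$trajectory$xyz))
      pooled <- trajectory(e$runs[[1]]$trajectory$topology, xyz)
      cluster_residues(compute_dihedrals(pooled),
                       min_occupancy = cfg$min_occupancy)
    })
  })
  cl_tab <- do.call(rbind, lapply(states, function(st) {
    do.call(rbind, lapply(names(clusterings[[st]]), function(r) {
      cl <- clusterings[[st]][[r]]$clusters
      if (nrow(cl) == 0) return(NULL)
      data.frame(state = st, residue = as.integer(r), cluster = cl$id,
                 phi_center = round(cl$phi, 1), psi_center = round(cl$psi, 1),
                 occupancy = round(cl$occupancy, 3))
    }))
  }))
  write_stage_csv(cl_tab, out_dir, "clusters.csv")
  multimodal <- lapply(clusterings, multimodal_residues)
  shifts <- stage("state_comparison", {
    pairs <- utils::combn(states, 2, simplify = FALSE)
    out <- lapply(pairs, function(p)
      compare_states(clusterings[[p[1]]], clusterings[[p[2]]],
                     match_radius = cfg$match_radius,
                     delta_occ = cfg$delta_occ))
    names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    out
  })
  shift_tab <- do.call(rbind, lapply(names(shifts), function(nm)
    cbind(pair = nm, shifts[[nm]])))
  write_stage_csv(shift_tab, out_dir, "state_shifts.csv")
  ## ---- correlation + tally (nucleotide-bound runs only) ---------------
  tally <- stage("correlation", {
    bound <- intersect(states, c("ATP", "ADP_Pi"))
    runs <- unlist(lapply(bound, function(st) ensembles[[st]]$runs),
                   recursive = FALSE)
    runs <- Filter(function(r) !is.null(r$ligand), runs)
    if (length(runs) == 0) NULL else {
      tops <- lapply(runs, function(r)
        rank_by_ligand(dcc_matrix(r$trajectory, ligand = r$ligand), k = cfg$k))
      names(tops) <- vapply(runs, function(r) r$trajectory$label, character(1))
      tally_runs(tops, min_runs = cfg$min_runs, universe = seq_len(n_res))
    }
  })
  if (!is.null(tally)) write_stage_csv(tally, out_dir, "tally.csv")
  ## ---- conservation (optional) ----------------------------------------
  cons <- stage("conservation", {
    if (is.null(cfg$conservation)) NULL else {
      grp <- if (!is.null(cfg$conservation$groups))
        utils::read.delim(cfg$conservation$groups, stringsAsFactors = FALSE)
      else NULL
      prof <- conservation_profile(read_alignment(cfg$conservation$msa, grp))
      write_stage_csv(prof, out_dir, "conservation.csv")
      prof
    }
  })
  ## ---- report ----------------------------------------------------------
  report <- stage("report", {
    build_report(multimodal, shifts = shifts, tally = tally,
                 conservation = cons, universe = seq_len(n_res),
                 identity_min = cfg$identity_min,
                 groups_required = if (is.null(cons)) character(0) else
                   intersect(cfg$groups_required, unique(cons$group)))
  })
  write_stage_csv(report$table, out_dir, "report.csv")
  params <- cfg[c("k", "min_runs", "min_occupancy", "match_radius",
                  "delta_occ", "openness_threshold", "near_cutoff",
                  "identity_min", "n_runs", "n_frames", "seed")]
  jsonlite::write_json(
    list(parameters = params,
         conservation = report$params$conservation,
         openness = openness,
         multimodal = lapply(multimodal, as.integer),
         tiers = split(report$table$residue, report$table$tier),
         table = report$table),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 8,
    pretty = TRUE)
  if (!is.null(cfg$simulate)) {
    jsonlite::write_json(lapply(ensembles, `[[`, "truth"),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
  }
  writeLines(c("hingescan pipeline parameters:",
               paste0("  ", names(params), " = ",
                      vapply(params, function(p) paste(p, collapse = ","),
                             character(1))),
               paste0("  states = ", paste(states, collapse = ",")),
               paste0("  conservation = ", report$params$conservation)),
             file.path(out_dir, "log.txt"))
  invisible(report)
}
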