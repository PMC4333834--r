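#' Read a run configuration
#'
#' A run is described by one YAML file with blocks `model`, `sampling`,
#' `kinetics`, `dynamics` and `multi_pf` plus a global `seed` and an output
#' directory; every field has a default, and the fully resolved
#' configuration is snapshotted into the run directory so reruns are
#' bit-reproducible.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides Named list merged on top (CLI flags).
#' @return A nested list of class `run_config` with all defaults
#'   materialized.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- modifyList(default_run_config(), cfg)
  cfg <- modifyList(cfg, overrides)
  # YAML sequences come back as lists; restore atomic types
  cfg$stages <- as.character(unlist(cfg$stages))
  cfg$dynamics$forces_pN <- as.numeric(unlist(cfg$dynamics$forces_pN))
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "mtpeel-run",
    stages = c("sample", "landscape", "kinetics", "dynamics"),
    model = list(b_nm = 8, n_subunits = 32, l0_nm = 6.5, lmax_over_l0 = 1.2,
                 E_ms_kBT = 8, E_mb_kBT = 6.8, theta_D_rad = 0.4,
                 theta_T_rad = 0, cap_T_subunits = 0,
                 temperature_factor = 1),
    sampling = list(n_steps_per_window = 1e6, record_every = 100,
                    max_rotation = 1.5, window_spacing_nm = 10,
                    k_bias = 0.1, bin_width_nm = 2),
    kinetics = list(a_nm = 40, eta_Pa_s = 0.001, temperature_K = 298,
                    A_nm = 0, B_nm = 125, C_nm = 250, prominence_kBT = 1),
    dynamics = list(dt_s = 1e-7, t_total_s = 0.2, n_traj = 4,
                    record_every = 1000, k_off_per_s = 75, rx_gate_nm = 8,
                    l_d = 1, L0_nm = 2000, forces_pN = numeric(0)))
}

params_from_config <- function(cfg) {
  m <- cfg$model
  base <- model_params(b = m$b_nm, N = m$n_subunits, l0 = m$l0_nm,
                       lmax = m$lmax_over_l0 * m$l0_nm,
                       theta_D = m$theta_D_rad, theta_T = m$theta_T_rad,
                       temperature_factor = m$temperature_factor)
  params_from_energies(m$E_ms_kBT, m$E_mb_kBT, base)
}

composition_from_config <- function(cfg) {
  m <- cfg$model
  cap_composition(m$cap_T_subunits, m$n_subunits - m$cap_T_subunits)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order (sample -> landscape -> kinetics
#' -> dynamics), writing each stage's outputs into a stage-named
#' subdirectory of the run directory, plus the resolved config snapshot, a
#' log of parameters/seeds/acceptance rates and a manifest with file
#' checksums. A stage failure halts the run with the stage named; earlier
#' outputs are preserved.
#'
#' @param config A [read_run_config()] object (or path to a YAML file).
#' @return The run directory, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  log_lines <- c(sprintf("mtpeel pipeline, seed %d", config$seed))
  outputs <- character(0)
  land <- NULL

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                   stage, conditionMessage(e), config$out_dir), call. = FALSE))
  }

  params <- params_from_config(config)
  comp <- composition_from_config(config)

  if ("sample" %in% config$stages || "landscape" %in% config$stages) {
    run_stage("sample", function() {
      sdir <- file.path(config$out_dir, "landscape")
      dir.create(sdir, showWarnings = FALSE)
      s <- config$sampling
      mc <- mc_config(n_steps = s$n_steps_per_window, seed = config$seed,
                      record_every = s$record_every,
                      max_rotation = s$max_rotation,
                      bin_width = s$bin_width_nm)
      land <<- sample_landscape(comp, params, mc,
                                spacing = s$window_spacing_nm,
                                k_bias = s$k_bias)
      f <- file.path(sdir, "landscape.tsv")
      write_landscape_tsv(land, f)
      wins <- attr(land, "windows")
      jsonlite::write_json(list(seed = config$seed,
                                n_steps_per_window = s$n_steps_per_window,
                                acceptance = wins$acceptance,
                                wham_iterations = attr(attr(land, "dist"), "wham_iterations")),
                           file.path(sdir, "sampling.json"), auto_unbox = TRUE)
      outputs <<- c(outputs, f, file.path(sdir, "sampling.json"))
      log_lines <<- c(log_lines, sprintf(
        "landscape: %d windows, acceptance %.3f-%.3f", nrow(wins),
        min(wins$acceptance), max(wins$acceptance)))
    })
  }
  if ("kinetics" %in% config$stages) {
    run_stage("kinetics", function() {
      k <- config$kinetics
      kdir <- file.path(config$out_dir, "kinetics")
      dir.create(kdir, showWarnings = FALSE)
      Cmax <- min(k$C_nm, max(land$grid))
      rep <- kinetics_report(land, a = k$a_nm, eta = k$eta_Pa_s,
                             temperature_K = k$temperature_K,
                             A = k$A_nm, B = min(k$B_nm, Cmax), C = Cmax,
                             prominence = k$prominence_kBT)
      f <- file.path(kdir, "kinetics.json")
      jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      outputs <<- c(outputs, f)
      log_lines <<- c(log_lines,
                      sprintf("kinetics: v_AC = %.4g nm/s", rep$v_AC_nm_s))
    })
  }
  if ("dynamics" %in% config$stages) {
    run_stage("dynamics", function() {
      d <- config$dynamics
      ddir <- file.path(config$out_dir, "dynamics")
      dir.create(ddir, showWarnings = FALSE)
      D <- diffusion_coefficient(config$kinetics$a_nm, config$kinetics$eta_Pa_s,
                                 config$kinetics$temperature_K)
      dcfg <- dissociation_config(d$k_off_per_s, d$rx_gate_nm)
      trajs <- lapply(seq_len(d$n_traj), function(i) {
        lcfg <- langevin_config(dt = d$dt_s, t_total = d$t_total_s,
                                seed = config$seed * 1000L + i, D = D,
                                record_every = d$record_every)
        tr <- simulate_shrinkage(land, lcfg, dcfg, l_d = d$l_d, L0 = d$L0_nm,
                                 b = params$b)
        utils::write.table(tr, file.path(ddir, sprintf("traj_%03d.tsv", i)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        tr
      })
      v <- shrinkage_velocity(trajs)
      horns <- horn_statistics(trajs[[1]])
      f <- file.path(ddir, "shrinkage.json")
      jsonlite::write_json(c(v, horns,
                             list(k_off_per_s = d$k_off_per_s, l_d = d$l_d,
                                  rx_gate_nm = d$rx_gate_nm,
                                  seeds = config$seed * 1000L + seq_len(d$n_traj))),
                           f, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs,
                    file.path(ddir, sprintf("traj_%03d.tsv", seq_len(d$n_traj))), f)
      log_lines <<- c(log_lines,
                      sprintf("dynamics: v- = %.4g nm/s over %d trajectories",
                              v$v_minus_nm_s, d$n_traj))
    })
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  outputs <- c(outputs, file.path(config$out_dir, "config.yaml"),
               file.path(config$out_dir, "run.log"))
  manifest <- data.frame(file = sub(paste0("^", config$out_dir, "/?"), "", outputs),
                         md5 = vapply(outputs, function(f)
                           as.character(tools::md5sum(f)), character(1)),
                         row.names = NULL)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"))
  attr(config$out_dir, "manifest") <- manifest
  invisible(config$out_dir)
}
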