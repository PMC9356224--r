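#' Scenario configuration
#'
#' One validated object drives an end-to-end run: synthetic sampling ->
#' umbrella histograms -> WHAM (+ bootstrap) -> contacts -> geometry ->
#' electrostatics.  The `"full"` profile mirrors the production protocol
#' (0.25 A spacing, 5 x 2.4 ns runs); the `"ci"` profile is a reduced grid
#' for fast tests (0.5 A spacing over -6..6 A, 3 x 0.2 ns runs).
#'
#' @param preset groove preset (`"open_pg"`, `"open_pc"`, `"l302a"`).
#' @param profile `"ci"` or `"full"`.
#' @param seed master seed; every stage derives its stream from it.
#' @param outdir output directory.
#' @param overrides named list overriding any nested default, e.g.
#'   `list(windows = list(spacing = 0.25), bootstrap = list(n_trials = 50))`.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(preset = "open_pg", profile = c("ci", "full"),
                            seed = 1L, outdir = tempfile("scenario_"),
                            overrides = list()) {
  profile <- match.arg(profile)
  cfg <- list(
    preset = preset,
    profile = profile,
    seed = as.integer(seed),
    outdir = outdir,
    windows = if (profile == "full") {
      list(z_min = -10.25, z_max = 10.5, spacing = 0.25, force_constant = 10,
           n_runs = 5, run_length = 2400, equil_discard = 600)
    } else {
      list(z_min = -6, z_max = 6, spacing = 0.5, force_constant = 10,
           n_runs = 3, run_length = 400, equil_discard = 80)
    },
    # dt 0.005 keeps the Euler-Maruyama O(dt) sampling bias well below the
    # statistical error of a reduced run; stride 400 = one frame per 2 ps.
    sampling = list(dt = 0.005, diffusion = 0.2, frame_stride = 400),
    wham = list(bin_width = 0.1, tol = 1e-6, max_iter = 1e5, temperature = 310),
    # In the ci profile the Brownian sampler's frames (2 ps apart) are
    # effectively uncorrelated (harmonic-well relaxation ~0.3 ps), so the
    # bootstrap correlation time equals the frame interval there; the full
    # profile keeps the production 20 ps setting.
    bootstrap = list(n_trials = if (profile == "full") 200 else 25,
                     correlation_time = if (profile == "full") 20 else 2,
                     frame_interval = 2),
    contacts = list(cutoff = 3.0, threshold = 50),
    geometry = list(bin_width = 0.25,
                    min_samples = if (profile == "full") 50 else 20,
                    z_step = 0.5),
    electrostatics = list(spacing = if (profile == "full") 1.0 else 1.5,
                          padding = if (profile == "full") 20 else 10))
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

#' Validate a scenario configuration
#'
#' Checks types, signs and ranges before any computation; failures signal
#' a condition of class `config_error`.
#'
#' @param cfg a configuration list.
#' @return invisibly TRUE.
#' @export
validate_scenario_config <- function(cfg) {
  fail <- function(msg) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  if (!cfg$preset %in% c("open_pg", "open_pc", "l302a")) {
    fail(paste0("unknown preset '", cfg$preset, "'"))
  }
  w <- cfg$windows
  if (w$spacing <= 0) fail("windows$spacing must be > 0")
  if (w$z_max <= w$z_min) fail("windows$z_max must exceed z_min")
  if (w$force_constant < 0) fail("windows$force_constant must be >= 0")
  if (w$equil_discard >= w$run_length) fail("equil_discard must be < run_length")
  if (cfg$sampling$dt <= 0 || cfg$sampling$diffusion <= 0) {
    fail("sampling dt and diffusion must be > 0")
  }
  if (cfg$bootstrap$n_trials < 2) fail("bootstrap$n_trials must be >= 2")
  if (cfg$contacts$cutoff <= 0) fail("contacts$cutoff must be > 0")
  if (cfg$electrostatics$spacing <= 0) fail("electrostatics$spacing must be > 0")
  invisible(TRUE)
}

#' Read a scenario configuration from a JSON file
#'
#' @param path JSON file with the same nested structure as
#'   [scenario_config()] output.
#' @return a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base_args <- raw[intersect(names(raw), c("preset", "profile", "seed", "outdir"))]
  overrides <- raw[setdiff(names(raw), c("preset", "profile", "seed", "outdir"))]
  do.call(scenario_config, c(base_args, list(overrides = overrides)))
}

## Small deterministic FNV-1a hash of the serialized config (hex string).
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # the hash identifies the science, not the location
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Default interaction-partner rules per preset (charge in e).
.preset_rules <- function(preset) {
  gate <- partner_rule("E313", c(5.5, 9.5), 0.8, charge = -1)
  switch(preset,
    open_pg = list(partner_rule("POPG", c(-3.25, 1.25), 0.829, charge = -1),
                   gate),
    open_pc = list(partner_rule("POPC", c(-3, 4.75), 0.8, charge = 0), gate),
    l302a = list(gate))
}

#' Run a full scenario end to end
#'
#' Executes synthetic sampling, umbrella QC, WHAM with bootstrap errors,
#' contact/critical-range annotation, path and pore geometry, and the
#' linearized Poisson-Boltzmann potential along the average path, writing
#' every stage product under `cfg$outdir` and a consolidated
#' `summary.json`.  Rerunning with the same configuration reproduces all
#' outputs exactly.
#'
#' @param cfg a [scenario_config()].
#' @return invisibly, the summary list.
#' @export
run_scenario <- function(cfg) {
  validate_scenario_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", "INFO", sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat(sprintf("# groovePMF run, config %s\n", hash), file = log_path)
  stage <- "setup"
  result <- tryCatch({
    logf("preset %s, profile %s, seed %d, config hash %s",
         cfg$preset, cfg$profile, cfg$seed, hash)
    potential <- groove_potential(cfg$preset)

    stage <- "synthetic_data"
    w <- cfg$windows
    windows <- generate_windows(w$z_min, w$z_max, w$spacing, w$force_constant,
                                n_runs = w$n_runs, run_length = w$run_length,
                                equil_discard = w$equil_discard)
    params <- langevin_params(dt = cfg$sampling$dt,
                              diffusion = cfg$sampling$diffusion,
                              frame_stride = cfg$sampling$frame_stride,
                              seed = cfg$seed,
                              temperature = cfg$wham$temperature)
    samples <- sample_windows_langevin(potential, windows, params)
    write_window_samples(samples, file.path(cfg$outdir, "windows"),
                         meta = list(preset = cfg$preset, seed = cfg$seed,
                                     config_hash = hash))
    logf("sampled %d windows (%d frames total)", length(windows),
         sum(vapply(samples, function(s) length(s$rc_values), integer(1))))

    stage <- "umbrella"
    hists <- build_histograms(samples, cfg$wham$bin_width)
    qc <- overlap_report(hists)
    utils::write.csv(qc, file.path(cfg$outdir, "overlap_qc.csv"),
                     row.names = FALSE)
    logf("overlap QC: min neighbor overlap %.3f (all pass: %s)",
         if (nrow(qc)) min(qc$overlap) else NA, attr(qc, "all_pass"))

    stage <- "wham"
    res <- solve_wham(hists, windows, cfg$wham$temperature, cfg$wham$tol,
                      cfg$wham$max_iter)
    errs <- bootstrap_errors(samples, windows, cfg$wham$temperature,
                             cfg$bootstrap$correlation_time,
                             cfg$bootstrap$frame_interval,
                             cfg$bootstrap$n_trials, seed = cfg$seed + 10000L,
                             bin_width = cfg$wham$bin_width,
                             tol = cfg$wham$tol, max_iter = cfg$wham$max_iter)
    write_pmf_csv(res, file.path(cfg$outdir, "pmf.csv"), errs,
                  meta = list(config_hash = hash))
    barrier <- barrier_height(res, c(w$z_min, w$z_max))
    logf("WHAM converged in %d iterations; barrier %.3f kcal/mol",
         res$iterations, barrier)

    stage <- "contacts"
    rules <- .preset_rules(cfg$preset)
    tables <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      fr <- data.frame(time = s$times, x = s$xyz[, 1], y = s$xyz[, 2],
                       z = s$xyz[, 3], ref_z = 0, rc = s$rc_values)
      ctraj <- emit_partner_frames(fr, rules, seed = cfg$seed + 20000L + i)
      tables[[i]] <- count_contacts(ctraj, cfg$contacts$cutoff,
                                    window_center = s$spec$center)
    }
    ranges <- critical_ranges(tables, cfg$contacts$threshold)
    utils::write.csv(ranges[, c("partner", "z_min_A", "z_max_A", "n_windows")],
                     file.path(cfg$outdir, "critical_ranges.csv"),
                     row.names = FALSE)
    logf("critical ranges: %d", nrow(ranges))

    stage <- "geometry"
    pos <- do.call(rbind, lapply(samples, `[[`, "xyz"))
    path <- average_path(pos, cfg$geometry$bin_width, cfg$geometry$min_samples)
    scaffold <- build_groove_geometry(
      if (cfg$preset == "l302a") "constricted" else "open")
    pore <- pore_profile(scaffold, c(w$z_min, w$z_max), cfg$geometry$z_step)
    dev <- path_axis_deviation(path, pore)
    utils::write.csv(path, file.path(cfg$outdir, "average_path.csv"),
                     row.names = FALSE)
    utils::write.csv(pore, file.path(cfg$outdir, "pore_profile.csv"),
                     row.names = FALSE)
    logf("path/axis RMS deviation %.3f A", dev$rms)

    stage <- "electrostatics"
    beads <- scaffold
    for (r in rules) {
      # static partner beads at their window midpoints, against the groove
      # wall (off the pore axis, as a headgroup or gate side chain sits)
      beads <- rbind(beads, bead(r$partner_id, "partner", 3, 0,
                                 mean(r$z_window), r$radius, r$charge))
    }
    maps <- build_maps(beads, dielectric_model(),
                       spacing = cfg$electrostatics$spacing,
                       padding = cfg$electrostatics$padding)
    field <- solve_lpb(maps)
    ep <- sample_along_path(field, path)
    utils::write.csv(ep, file.path(cfg$outdir, "path_ep.csv"),
                     row.names = FALSE)
    logf("EP along path: [%.3f, %.3f] kcal/(mol e)", min(ep$phi), max(ep$phi))

    stage <- "summary"
    summary <- list(
      config_hash = hash, preset = cfg$preset, profile = cfg$profile,
      seed = cfg$seed,
      n_windows = length(windows),
      barrier_kcal_mol = barrier,
      designed_barrier_kcal_mol = designed_barrier(potential,
                                                   c(w$z_min, w$z_max)),
      wham_iterations = res$iterations,
      median_pmf_sd_kcal_mol = stats::median(errs$per_bin_sd, na.rm = TRUE),
      critical_ranges = lapply(seq_len(nrow(ranges)), function(i) {
        list(partner = ranges$partner[i], z_min_A = ranges$z_min_A[i],
             z_max_A = ranges$z_max_A[i])
      }),
      path_axis_rms_A = dev$rms,
      ep_range_kcal_mol_e = c(min(ep$phi), max(ep$phi)))
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    summary
  }, error = function(e) {
    if (inherits(e, "config_error")) stop(e)
    stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                 stage, conditionMessage(e), cfg$outdir), call. = FALSE)
  })
  invisible(result)
}
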