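# File-based orchestration of the analysis stages, with run manifests.

#' Read and write profile CSV files
#'
#' Profiles are exchanged as long-format CSV with columns `embryo_id`,
#' `section_id`, `channel`, `dv_length_um`, `position_um`, `intensity_au`,
#' `background_au`.
#'
#' @param path CSV file path.
#' @return `read_profiles_csv` returns a list of `gradient_profile`s.
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("embryo_id", "section_id", "channel", "dv_length_um",
            "position_um", "intensity_au", "background_au")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("profile CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  keys <- interaction(d$embryo_id, d$section_id, drop = TRUE)
  lapply(split(d, keys), function(s) {
    s <- s[order(s$position_um), ]
    gradient_profile(s$position_um, s$intensity_au, s$dv_length_um[1],
                     background = s$background_au[1],
                     channel = as.character(s$channel[1]),
                     embryo_id = s$embryo_id[1], section_id = s$section_id[1])
  })
}

#' @rdname read_profiles_csv
#' @param profiles list of `gradient_profile`s.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(embryo_id = p$embryo_id, section_id = p$section_id,
               channel = p$channel, dv_length_um = p$dv_length,
               position_um = p$positions, intensity_au = p$intensity,
               background_au = p$background)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(out_dir, command, config, seed = NULL) {
  manifest <- list(command = command,
                   config = config,
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("shhadapt")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Gradient-quantification pipeline
#'
#' Reads profile CSVs, subtracts backgrounds, fits the exponential gradient
#' of each profile, regresses amplitude and decay length on DV length, bins
#' the ventral 0-10% and 10-20% bands across stages, stereotypes their time
#' courses and builds the two normalized ramp inputs. Writes `fits.csv`,
#' `trends.csv`, `ramps.json` and `manifest.json` into `out_dir`.
#'
#' @param profiles_csv path to a profile CSV (see [read_profiles_csv()]).
#' @param out_dir output directory (created if needed).
#' @param calibration a [stage_calibration()] mapping DV length to somite
#'   stage; when `NULL`, embryo time is taken proportional to DV length
#'   (arbitrary clock; the ramps are normalized anyway).
#' @param dorsal_cutoff_frac dorsal end of the exponential-fit window.
#' @return Invisibly, a list with `fits`, `trends`, `ramps`.
#' @export
gradient_pipeline <- function(profiles_csv, out_dir, calibration = NULL,
                              dorsal_cutoff_frac = 0.5) {
  profiles <- read_profiles_csv(profiles_csv)
  if (!length(profiles)) stop("no profiles found in ", profiles_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- lapply(profiles, subtract_background)

  fits <- lapply(profiles, fit_exponential,
                 dorsal_cutoff_frac = dorsal_cutoff_frac)
  dv <- vapply(profiles, `[[`, numeric(1), "dv_length")
  fits_df <- data.frame(
    embryo_id = vapply(profiles, function(p) as.character(p$embryo_id),
                       character(1)),
    dv_length_um = dv,
    C0 = vapply(fits, `[[`, numeric(1), "C0"),
    lambda_um = vapply(fits, `[[`, numeric(1), "lambda"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    boundary_um = vapply(fits, `[[`, numeric(1), "boundary_position"))
  utils::write.csv(fits_df, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)

  trends <- trend_vs_size(fits, dv)
  utils::write.csv(trends$table, file.path(out_dir, "trends.csv"),
                   row.names = FALSE)

  binned <- bin_profiles(profiles)
  ventral <- binned[binned$position_bin %in% c(0, 1), ]
  time_h <- if (is.null(calibration)) ventral$stage_mid / 4
    else stage_by_dv_length(ventral$stage_mid, calibration)
  tc <- data.frame(time_h = as.numeric(time_h),
                   band = ifelse(ventral$position_bin == 0,
                                 "0-10%", "10-20%"),
                   intensity = ventral$mean)
  stereo <- stereotype_timecourse(tc)
  ramps <- build_ramp_inputs(stereo[[1]], stereo[[2]])
  jsonlite::write_json(
    lapply(ramps, unclass), file.path(out_dir, "ramps.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  .write_manifest(out_dir, "gradient",
                  list(profiles_csv = profiles_csv,
                       dorsal_cutoff_frac = dorsal_cutoff_frac))
  invisible(list(fits = fits_df, trends = trends, ramps = ramps,
                 stereotyped = stereo))
}

#' Simulation pipeline
#'
#' Runs the pre-equilibration + stimulation protocol for a parameter file
#' and a protocol file, writing the tidy trajectory CSV, the adaptation
#' metrics of the reporter, and a manifest.
#'
#' The protocol JSON holds `variant`, `input` (`kind`, `onset`, `level` or
#' `slope`, `duration`), and optional `t_pre`, `t_stim`, `dt_out`, `rtol`,
#' `atol`.
#'
#' @param params_json path to a flat parameter JSON ([read_parameters()]).
#' @param protocol_json path to the protocol JSON.
#' @param out_dir output directory.
#' @return Invisibly, the `pathway_sim` result.
#' @export
simulate_pipeline <- function(params_json, protocol_json, out_dir) {
  params <- read_parameters(params_json)
  proto <- jsonlite::read_json(protocol_json, simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- proto$input
  input <- shh_signal(kind = inp$kind,
                      onset = if (is.null(inp$onset)) 0 else inp$onset,
                      slope = inp$slope, level = inp$level,
                      duration = if (is.null(inp$duration)) Inf
                                 else inp$duration)
  arg <- function(nm, default) if (is.null(proto[[nm]])) default
                               else proto[[nm]]
  sim <- run_protocol(params,
                      variant = arg("variant", "full"), input = input,
                      t_pre = arg("t_pre", 300), t_stim = arg("t_stim", 70),
                      dt_out = arg("dt_out", 0.5),
                      rtol = arg("rtol", 1e-6), atol = arg("atol", 1e-9))
  utils::write.csv(as.data.frame(sim),
                   file.path(out_dir, "trajectories.csv"),
                   row.names = FALSE)
  m <- compute_metrics(sim$times, sim$traj[, "gfp_mRNA"],
                       sim$traj[, "gfp_mRNA"],
                       basal = sim$pre_state[["gfp_mRNA"]])
  jsonlite::write_json(unclass(m), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, "simulate",
                  list(params_json = params_json,
                       protocol_json = protocol_json))
  invisible(sim)
}

#' ABC inference pipeline
#'
#' Runs [shh_abc()] and writes each generation's particles as JSON-lines
#' (one particle per line: log10 parameters, distance, weight, metrics),
#' the marginal posterior quantile table as CSV, and a manifest.
#'
#' @param variant one of [model_variants()].
#' @param out_dir output directory.
#' @param n_particles,seed,... passed to [shh_abc()].
#' @return Invisibly, the `shh_abc` fit.
#' @export
abc_pipeline <- function(variant, out_dir, n_particles = 128, seed = 1,
                         ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- shh_abc(variant, n_particles = n_particles, seed = seed, ...)
  con <- file(file.path(out_dir, "populations.jsonl"), open = "wt")
  on.exit(close(con))
  for (pop in fit$populations) {
    for (i in seq_len(nrow(pop$theta))) {
      rec <- list(generation = pop$generation, epsilon = pop$epsilon,
                  log10_params = as.list(pop$theta[i, ]),
                  distance = pop$distances[i], weight = pop$weights[i],
                  metrics = if (!is.null(pop$metrics[[i]]))
                    lapply(Filter(Negate(is.null), pop$metrics[[i]]),
                           unclass))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
    }
  }
  utils::write.csv(posterior_summaries(fit),
                   file.path(out_dir, "posterior_summary.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "abc",
                  list(variant = variant, n_particles = n_particles),
                  seed = seed)
  invisible(fit)
}
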