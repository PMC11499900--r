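#' Default run configuration
#'
#' Builds the structured configuration driving the pipeline. Keys carry
#' explicit units in their names. The defaults describe the idealized
#' phantom imaged near the inlet (straight-tube region of ROI1) at the
#' published camera scale, with the high-amplitude flow case and the C4
#' illumination setting.
#'
#' @param flow_case "FL", "FM" or "FH".
#' @param illumination "C1".."C4".
#' @param seed master seed for all stochastic stages.
#' @return nested list of class \code{run_config}.
#' @export
default_run_config <- function(flow_case = "FH", illumination = "C4",
                               seed = 1) {
  cfg <- list(
    geometry = list(d_mm = 20, aspect_ratio = 2.9, dilation_ratio = 1.9,
                    total_length_mm = 250, wall_thickness_mm = 1.8),
    fluid = list(kinematic_viscosity_mm2s = 3.82, density_kgm3 = 1060),
    flow = list(case = flow_case, period_s = 0.8, n_harmonics = 12),
    loop = list(n_cycles = 6, fs_hz = 5000, delay_s = 0.023,
                noise_q_m3s = 0, noise_p_pa = 0),
    camera = list(width_px = 1920, height_px = 1200, bit_depth = 12,
                  scale_px_mm = 24.6, exposure_us = 13000,
                  min_interframe_us = 80),
    illumination = list(label = illumination),
    roi = list(x0_mm = -118, x1_mm = -96, width_px = 540, height_px = 560),
    seeding = list(density_mm2 = 7, sheet_thickness_mm = 1.5),
    acquisition = list(phases = 25, n_cycles = 1, jitter = 0),
    piv = list(passes = c(128, 64, 32), overlap = 0.5, snr_min = 1.25,
               global_k = 5, median_k = 3),
    seed = seed
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a run configuration (YAML)
#' @param path YAML file path.
#' @param cfg a \code{run_config}.
#' @return the configuration (reader) or \code{path} invisibly (writer).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks every numeric field against the preconditions of the stage that
#' consumes it; stops with an informative message on the first violation.
#'
#' @param cfg a \code{run_config}.
#' @return \code{cfg}, invisibly.
#' @export
validate_run_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("config: ", msg)
  chk(cfg$geometry$d_mm > 0, "geometry d_mm must be > 0")
  chk(cfg$geometry$dilation_ratio >= 1, "dilation_ratio must be >= 1")
  chk(cfg$fluid$kinematic_viscosity_mm2s > 0, "viscosity must be > 0")
  chk(cfg$flow$case %in% c("FL", "FM", "FH"), "unknown flow case")
  chk(cfg$flow$period_s > 0, "period must be > 0")
  chk(cfg$loop$fs_hz > 0, "logging rate must be > 0")
  chk(cfg$camera$scale_px_mm > 0, "camera scale must be > 0")
  chk(cfg$illumination$label %in% c("C1", "C2", "C3", "C4"),
      "unknown illumination label")
  chk(cfg$seeding$density_mm2 > 0, "seeding density must be > 0")
  chk(cfg$piv$overlap >= 0 && cfg$piv$overlap < 1, "overlap must be in [0,1)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed is mandatory")
  invisible(cfg)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages \code{simulate} (loop simulation and sensor log),
#' \code{generate} (synthetic image pairs with ground truth), \code{piv}
#' (preprocess + multi-pass correlation + validation) and \code{metrics}
#' (phase statistics and flow-rate reconstruction). Later stages consume the
#' in-memory outputs of earlier ones; requesting a stage whose inputs are
#' absent raises an error naming the stage to run first. Deterministic for a
#' fixed configuration and seed.
#'
#' @param cfg a \code{run_config}.
#' @param stages subset of \code{c("simulate", "generate", "piv",
#'   "metrics")}.
#' @param out_dir optional output directory; when given, the sensor log,
#'   vector fields, metrics tables and the run report are written there.
#' @param state result of a previous call, to resume from its artifacts.
#' @return list of class \code{pipeline_state} with elements \code{config},
#'   \code{log}, \code{dataset}, \code{fields}, \code{metrics},
#'   \code{report}.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "generate", "piv",
                                         "metrics"),
                         out_dir = NULL, state = NULL) {
  validate_run_config(cfg)
  stages <- match.arg(stages, several.ok = TRUE)
  st <- if (is.null(state)) list() else state
  st$config <- cfg
  t_all <- Sys.time()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  fluid <- fluid_properties(cfg$fluid$kinematic_viscosity_mm2s,
                            cfg$fluid$density_kgm3)
  d_m <- cfg$geometry$d_mm / 1000
  wf <- flow_case_waveform(cfg$flow$case, d = d_m,
                           period = cfg$flow$period_s,
                           n_harmonics = cfg$flow$n_harmonics)
  report <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                 stages = list())

  if ("simulate" %in% stages) {
    p <- flow_case_params(cfg$flow$case)
    wk <- wk3_params(p$Rp, p$Rd, p$C)
    st$log <- run_loop(wf, wk, hybrid_unit_config(dt = 1 / cfg$loop$fs_hz),
                       compliant_segment(),
                       n_cycles = cfg$loop$n_cycles, fs = cfg$loop$fs_hz,
                       delay = cfg$loop$delay_s,
                       noise_sd = list(q = cfg$loop$noise_q_m3s,
                                       p = cfg$loop$noise_p_pa),
                       seed = cfg$seed)
    if (!is.null(out_dir)) {
      write_sensor_log_csv(st$log, file.path(out_dir, "sensor_log.csv"))
    }
    report$stages$simulate <- list(n_samples = nrow(st$log$data))
  }

  if ("generate" %in% stages) {
    geom <- aaa_geometry(cfg$geometry$d_mm, cfg$geometry$aspect_ratio,
                         cfg$geometry$dilation_ratio,
                         cfg$geometry$total_length_mm,
                         cfg$geometry$wall_thickness_mm)
    mask <- lumen_mask(geom, c(cfg$roi$x0_mm, cfg$roi$x1_mm),
                       cfg$camera$scale_px_mm,
                       c(cfg$roi$width_px, cfg$roi$height_px))
    cam <- camera_model(c(cfg$camera$width_px, cfg$camera$height_px),
                        cfg$camera$bit_depth, cfg$camera$scale_px_mm,
                        cfg$camera$exposure_us, cfg$camera$min_interframe_us)
    illum <- illumination_config(cfg$illumination$label)
    st$dataset <- generate_dataset(
      wf, mask, cam, illum, d = d_m, fluid = fluid,
      n_cycles = cfg$acquisition$n_cycles, phases = cfg$acquisition$phases,
      jitter = cfg$acquisition$jitter, density = cfg$seeding$density_mm2,
      final_window = utils::tail(cfg$piv$passes, 1),
      overlap = cfg$piv$overlap, seed = cfg$seed)
    report$stages$generate <- list(
      n_pairs = length(st$dataset$pairs),
      saturation_max = max(vapply(st$dataset$pairs,
                                  function(p) p$saturation, 0)))
  }

  if ("piv" %in% stages) {
    if (is.null(st$dataset)) {
      stop("piv stage needs generated images; run the 'generate' stage first")
    }
    st$fields <- piv_process_dataset(st$dataset, cfg)
    if (!is.null(out_dir)) {
      vd <- file.path(out_dir, "vectors")
      dir.create(vd, showWarnings = FALSE)
      for (i in seq_along(st$fields)) {
        write_vector_field_csv(
          st$fields[[i]],
          file.path(vd, sprintf("c%03d_p%02d.csv", st$dataset$cycle[i],
                                st$dataset$phase[i])))
      }
    }
    rates <- vapply(st$fields, function(f) attr(f, "invalid_rate"), 0)
    report$stages$piv <- list(n_fields = length(st$fields),
                              invalid_rate_mean = mean(rates),
                              invalid_rate_max = max(rates))
  }

  if ("metrics" %in% stages) {
    if (is.null(st$fields)) {
      stop("metrics stage needs PIV vector fields; run the 'piv' stage first")
    }
    ds <- st$dataset
    R_m <- cfg$geometry$d_mm / 2000
    band <- c(8, 12)
    # field-local mm coordinates: x from the ROI left edge, axis moved to y=0
    q_piv <- vapply(seq_along(st$fields), function(i) {
      flow_rate_from_profile(
        shift_field_origin(st$fields[[i]], 0,
                           -cfg$roi$height_px / 2 / cfg$camera$scale_px_mm),
        band, R_m)
    }, 0)
    q_ref <- waveform_eval(ds$waveform, ds$phase_t[ds$phase])
    st$metrics <- data.frame(
      cycle = ds$cycle, phase = ds$phase, t_s = ds$phase_t[ds$phase],
      q_piv_m3s = q_piv, q_ref_m3s = q_ref,
      q_piv_lmin = m3s_to_lmin(q_piv), q_ref_lmin = m3s_to_lmin(q_ref))
    if (!is.null(out_dir)) {
      utils::write.csv(st$metrics, file.path(out_dir, "flow_rate.csv"),
                       row.names = FALSE)
    }
    report$stages$metrics <- list(
      q_max_abs_err_lmin = max(abs(st$metrics$q_piv_lmin -
                                   st$metrics$q_ref_lmin)))
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  st$report <- report
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(st) <- "pipeline_state"
  st
}

#' Run the PIV chain over a generated dataset
#'
#' Preprocesses all frames of an \code{image_pair_sequence} together (shared
#' mean background), then runs multi-pass correlation and three-criterion
#' validation on every pair.
#'
#' @param dataset an \code{image_pair_sequence}.
#' @param cfg a \code{run_config} (PIV section and camera scale are used).
#' @return list of validated \code{vector_field}s aligned with
#'   \code{dataset$pairs}.
#' @export
piv_process_dataset <- function(dataset, cfg = default_run_config()) {
  stopifnot(inherits(dataset, "image_pair_sequence"))
  stack <- unlist(lapply(dataset$pairs, function(p) list(p$a, p$b)),
                  recursive = FALSE)
  pp <- preprocess(stack, preprocess_config())
  m <- dataset$mask$mask
  pp$frames <- lapply(pp$frames, function(fr) fr * m)
  dt_s <- dataset$illum$dt_us * 1e-6
  lapply(seq_along(dataset$pairs), function(i) {
    f <- piv_multipass(pp$frames[[2 * i - 1]], pp$frames[[2 * i]],
                       mask = dataset$mask$mask,
                       passes = cfg$piv$passes, overlap = cfg$piv$overlap,
                       scale = dataset$camera$scale, dt_s = dt_s)
    validate_vectors(f, global_k = cfg$piv$global_k,
                     median_k = cfg$piv$median_k,
                     snr_min = cfg$piv$snr_min)
  })
}

#' Shift the mm origin of a vector field
#'
#' Re-expresses a field's mm coordinates in another frame (e.g. from
#' image-local to bulge-centered axial coordinates, or moving the transverse
#' origin onto the tube axis).
#'
#' @param field a \code{vector_field}.
#' @param dx_mm,dy_mm offsets added to the mm coordinates.
#' @return the field with shifted \code{x_mm}/\code{y_mm}.
#' @export
shift_field_origin <- function(field, dx_mm = 0, dy_mm = 0) {
  stopifnot(inherits(field, "vector_field"), !is.null(field$x_mm))
  field$x_mm <- field$x_mm + dx_mm
  field$y_mm <- field$y_mm + dy_mm
  field
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialization, for the run report.
#'
#' @param cfg a \code{run_config}.
#' @return character MD5 string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Compare illumination configurations on one ground-truth field
#'
#' Renders the same peak-systole particle field (identical particle seed)
#' under several pulse-width/pulse-separation configurations, processes each
#' pair with the full PIV chain, and reports the per-configuration maximum
#' absolute velocity-magnitude difference against the reference
#' configuration. The static background used for preprocessing is estimated,
#' as on the rig, from an ensemble of additional renders of the same phase
#' with independent particle seeds.
#'
#' @param waveform a \code{\link{flow_waveform}}.
#' @param mask imaging \code{\link{lumen_mask}}.
#' @param camera a \code{\link{camera_model}}.
#' @param configs labels of the configurations to compare.
#' @param ref reference configuration label.
#' @param t0 phase of the rendered field, s; default the waveform peak.
#' @param d tube diameter, m.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param seed particle/noise seed shared by all configurations.
#' @param n_bg number of extra pair renders used for the background average.
#' @param piv_cfg \code{run_config} whose PIV section to use.
#' @param ... further arguments to \code{\link{render_pair}}.
#' @return list with \code{fields} (validated \code{vector_field} per
#'   label), \code{max_diff} (named numeric, m/s, vs the reference) and
#'   \code{t0}.
#' @export
compare_illumination_configs <- function(waveform, mask, camera,
                                         configs = c("C1", "C2", "C3"),
                                         ref = "C4", t0 = NULL, d = 0.02,
                                         fluid = fluid_properties(),
                                         seed = 1, n_bg = 8,
                                         piv_cfg = default_run_config(),
                                         ...) {
  sampler <- womersley_sampler(waveform, d, fluid)
  if (is.null(t0)) t0 <- waveform$time[which.max(waveform$flow)]
  ref_il <- illumination_config(ref)
  set.seed(seed)
  bg_seeds <- sample.int(.Machine$integer.max - 1, n_bg)
  bg_frames <- list()
  for (s in bg_seeds) {
    p <- seed_particles(mask, density = piv_cfg$seeding$density_mm2, seed = s)
    pr <- render_pair(p, mask, camera, ref_il, sampler, t0 = t0, seed = s, ...)
    bg_frames <- c(bg_frames, list(pr$a, pr$b))
  }
  bg <- Reduce(`+`, bg_frames) / length(bg_frames)
  run_one <- function(lab) {
    il <- illumination_config(lab)
    p <- seed_particles(mask, density = piv_cfg$seeding$density_mm2,
                        seed = seed)
    pr <- render_pair(p, mask, camera, il, sampler, t0 = t0, seed = seed, ...)
    pp <- preprocess(list(pr$a, pr$b), background = bg)
    pp$frames <- lapply(pp$frames, function(fr) fr * mask$mask)
    f <- piv_multipass(pp$frames[[1]], pp$frames[[2]], mask = mask$mask,
                       passes = piv_cfg$piv$passes,
                       overlap = piv_cfg$piv$overlap,
                       scale = camera$scale, dt_s = il$dt_us * 1e-6)
    validate_vectors(f, global_k = piv_cfg$piv$global_k,
                     median_k = piv_cfg$piv$median_k,
                     snr_min = piv_cfg$piv$snr_min)
  }
  labs <- unique(c(configs, ref))
  fields <- stats::setNames(lapply(labs, run_one), labs)
  md <- vapply(configs, function(lab) {
    attr(config_difference(fields[[lab]], fields[[ref]]), "max_abs")
  }, 0)
  list(fields = fields, max_diff = md, t0 = t0)
}
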