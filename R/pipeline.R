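default_config <- function() {
  list(
    seed = 42L,
    outdir = NULL,
    phantom = list(grid_shape = c(64L, 64L, 64L), voxel_size = 1,
                   bundle_spread = 2.5, distractor_margin = 1),
    tractogram = list(n_streamlines = 2000L, bundle_fraction = 0.04),
    cohort = list(n_patients = 10L, jitter_sd = 1.75, effect = 5,
                  noise_sd = 5),
    vta = list(sigma_gm = 0.33, sigma_wm = 0.14, sigma_csf = 2.0,
               threshold = 0.2, impedance_ohm = 1000),
    structconn = list(dilate_mm = 0),
    fiberdisc = list(fraction = 0.10, min_per_group = 2L),
    funcconn = list(band = c(0.01, 0.08), fwhm = 6, n_subjects = 20L,
                    n_timepoints = 124L, TR = 3, coupling = 0.6,
                    grid_shape = c(22L, 22L, 22L), voxel_size = 3))
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop(sprintf("unknown config key: %s", full))
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], full)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate and normalize a run configuration
#'
#' Fills defaults (the paper-derived constants: conductivities 0.33/0.14
#' S/m, threshold 0.2 V/mm, retention fraction 0.10, band 0.01-0.08 Hz,
#' 6 mm FWHM, 60 Hz / 90 us stimulation), rejects unknown keys and
#' out-of-range values with field-level messages.
#'
#' @param config nested list of overrides, or a YAML file path, or NULL for
#'   the full default configuration.
#' @return normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- merge_config(default_config(), config)
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("config field `%s`: %s", field, msg))
  }
  chk(cfg$vta$threshold >= 0, "vta.threshold", "must be >= 0")
  chk(all(c(cfg$vta$sigma_gm, cfg$vta$sigma_wm, cfg$vta$sigma_csf) > 0),
      "vta.sigma_*", "conductivities must be > 0")
  chk(cfg$vta$impedance_ohm > 0, "vta.impedance_ohm", "must be > 0")
  chk(cfg$fiberdisc$fraction > 0 && cfg$fiberdisc$fraction <= 1,
      "fiberdisc.fraction", "must be in (0, 1]")
  chk(length(cfg$funcconn$band) == 2 &&
        cfg$funcconn$band[1] < cfg$funcconn$band[2],
      "funcconn.band", "must be an increasing Hz pair")
  chk(cfg$funcconn$band[1] > 0 &&
        cfg$funcconn$band[2] < 1 / (2 * cfg$funcconn$TR),
      "funcconn.band", "must lie strictly inside (0, Nyquist)")
  chk(cfg$cohort$n_patients >= 3, "cohort.n_patients", "must be >= 3")
  chk(cfg$cohort$noise_sd >= 0, "cohort.noise_sd", "must be >= 0")
  chk(cfg$tractogram$n_streamlines >= 1, "tractogram.n_streamlines",
      "must be >= 1")
  chk(cfg$tractogram$bundle_fraction >= 0 &&
        cfg$tractogram$bundle_fraction <= 1,
      "tractogram.bundle_fraction", "must be in [0, 1]")
  chk(abs(cfg$funcconn$coupling) < 1, "funcconn.coupling",
      "must be inside (-1, 1)")
  chk(cfg$funcconn$fwhm >= 0, "funcconn.fwhm", "must be >= 0")
  cfg
}

stage <- function(name, expr, log_level = "info") {
  if (log_level != "quiet")
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full phantom experiment end-to-end
#'
#' Generates the phantom, cohort and tractogram, computes per-patient VTAs
#' and VTA-nucleus metrics, regional fiber-count profiles and their outcome
#' associations, the discriminative fibertract selection with
#' ground-truth recovery, the normative functional-connectivity group
#' t-map, and the outcome statistics (rm-ANOVA + Tukey-Kramer + linear
#' regressions). Identical config + seed gives an identical report.
#'
#' @param config see \code{\link{validate_config}}.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return run report (list); written with all artifacts to
#'   \code{config$outdir} if set.
#' @export
run_all <- function(config = NULL, log_level = "info") {
  cfg <- validate_config(config)
  outdir <- cfg$outdir
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  put <- function(x, f, writer) {
    if (!is.null(outdir)) writer(x, file.path(outdir, f))
    invisible(NULL)
  }

  spec <- stage("phantom", phantom_spec(
    grid_shape = cfg$phantom$grid_shape,
    voxel_size = cfg$phantom$voxel_size, seed = cfg$seed,
    bundle_spread = cfg$phantom$bundle_spread,
    distractor_margin = cfg$phantom$distractor_margin), log_level)
  vols <- make_head_phantom(spec)
  put(vols$tissue, "tissue.nii.gz", write_volume)
  put(vols$nuclei, "nuclei.nii.gz", write_volume)
  put(vols$parcellation, "parcellation.nii.gz", write_volume)

  tg <- stage("tractogram", make_tractogram(
    spec, n_streamlines = cfg$tractogram$n_streamlines,
    bundle_fraction = cfg$tractogram$bundle_fraction), log_level)
  if (!is.null(outdir))
    write_trk(tg$tractogram, file.path(outdir, "tractogram.trk"),
              grid = vols$tissue)

  co <- stage("cohort", make_cohort(
    spec, n_patients = cfg$cohort$n_patients,
    jitter_sd = cfg$cohort$jitter_sd, effect = cfg$cohort$effect,
    noise_sd = cfg$cohort$noise_sd, tract = tg$tractogram,
    truth = tg$truth, impedance_ohm = cfg$vta$impedance_ohm,
    threshold = cfg$vta$threshold), log_level)
  cohort <- co$cohort
  if (!is.null(outdir)) {
    write.csv(cohort$table, file.path(outdir, "cohort.csv"),
              row.names = FALSE)
    jsonlite::write_json(co$truth[c("effect", "noise_sd", "connectivity")],
                         file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  vm <- stage("vta_metrics", {
    cm_union <- label_volume(array(vols$nuclei$data %in% c(1L, 2L),
                                   dim(vols$nuclei$data)), spec$voxel_size)
    res <- lapply(seq_along(cohort$vtas), function(p) {
      m <- vta_metrics(cohort$vtas[[p]], cm_union)
      data.frame(patient_id = sprintf("P%02d", p),
                 overlap_mm3 = m$overlap_mm3,
                 overlap_fraction_of_nucleus = m$overlap_fraction_of_nucleus,
                 centroid_distance_mm = m$centroid_distance_mm,
                 min_distance_mm = m$min_distance_mm)
    })
    do.call(rbind, res)
  }, log_level)
  if (!is.null(outdir))
    write.csv(vm, file.path(outdir, "vta_metrics.csv"), row.names = FALSE)

  profs <- stage("structconn", {
    rs <- resample_points(tg$tractogram, spec$voxel_size / 2)
    lapply(cohort$vtas, function(v)
      regional_profile(tg$tractogram, v, vols$parcellation, resampled = rs))
  }, log_level)
  assoc <- profile_outcome_association(profs, cohort$outcome)
  if (!is.null(outdir)) {
    ptab <- do.call(rbind, lapply(seq_along(profs), function(p)
      cbind(patient_id = sprintf("P%02d", p), as.data.frame(profs[[p]]))))
    write.csv(ptab, file.path(outdir, "regional_profiles.csv"),
              row.names = FALSE)
  }

  fib <- stage("fiberdisc", discriminative_fibertracts(
    tg$tractogram, cohort$vtas, cohort$outcome,
    fraction = cfg$fiberdisc$fraction,
    min_per_group = cfg$fiberdisc$min_per_group), log_level)
  rec <- recovery_metrics(fib$selected, tg$truth)
  if (!is.null(outdir)) {
    sc <- fib$scores
    write.csv(cbind(streamline_id = seq_len(nrow(sc)), sc),
              file.path(outdir, "fiber_scores.csv"), row.names = FALSE)
    if (length(fib$selected)) {
      sel_tract <- tractogram(lapply(fib$selected,
                                     function(i) streamline(tg$tractogram, i)),
                              labels = tg$truth$labels[fib$selected])
      write_trk(sel_tract, file.path(outdir, "discriminative_fibers.trk"),
                properties = list(tscore = sc$t[fib$selected]),
                grid = vols$tissue)
    }
  }

  fc <- stage("funcconn", {
    fspec <- phantom_spec(grid_shape = cfg$funcconn$grid_shape,
                          voxel_size = cfg$funcconn$voxel_size,
                          seed = cfg$seed,
                          bundle_spread = cfg$phantom$bundle_spread,
                          distractor_margin = cfg$phantom$distractor_margin)
    series <- make_normative_fmri(fspec,
                                  n_subjects = cfg$funcconn$n_subjects,
                                  n_timepoints = cfg$funcconn$n_timepoints,
                                  TR = cfg$funcconn$TR,
                                  coupling = cfg$funcconn$coupling)
    seedm <- attr(series, "seed")
    tissue <- attr(series, "tissue")
    net <- attr(series, "network")
    fvols <- make_head_phantom(fspec)
    zmaps <- lapply(series, function(s) {
      conf <- tissue_confounds(s, tissue)
      pre <- preprocess_series(s, conf, band = cfg$funcconn$band,
                               fwhm = cfg$funcconn$fwhm)
      fisher_z(seed_map(pre, seedm))
    })
    tmap <- group_tmap(zmaps)
    if (!is.null(outdir))
      write_volume(tmap, file.path(outdir, "group_tmap.nii.gz"))
    summ <- summarize_map_by_region(tmap, fvols$parcellation)
    inside <- mean(tmap$data[net$data & !seedm$data])
    outside <- mean(tmap$data[!net$data & fvols$tissue$data > 0])
    list(region_mean_t = summ, mean_t_network = inside,
         mean_t_background = outside)
  }, log_level)

  stats_out <- stage("stats", {
    an <- rm_anova(cohort$improvement)
    tk <- tukey_kramer(cohort$improvement)
    reg_conn <- pearson_regression(cohort$connectivity, cohort$outcome)
    reg_dist <- if (var(vm$centroid_distance_mm) > 0)
      pearson_regression(vm$centroid_distance_mm, cohort$outcome) else NULL
    list(rm_anova = an, tukey = tk, regression_connectivity = reg_conn,
         regression_vta_cm_distance = reg_dist)
  }, log_level)

  cfg_echo <- cfg
  cfg_echo$outdir <- NULL    # path-independent report for reproducibility
  report <- list(
    config = cfg_echo,
    vta_metrics = vm,
    regional_profiles = list(association = assoc,
                             mean_raw_counts = stats::setNames(
                               rowMeans(sapply(profs, function(p)
                                 p$raw_count)), profs[[1]]$region)),
    fiber_selection = list(n_streamlines = nrow(fib$scores),
                           n_defined = sum(!is.na(fib$scores$t)),
                           n_retained = length(fib$selected),
                           fraction = cfg$fiberdisc$fraction),
    recovery = rec,
    funcconn_summary = fc,
    outcome_stats = stats_out)
  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  report
}
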