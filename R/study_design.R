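# Study-level simulation: a cohort of phantoms, each segmented by 5 manual
# observers and 3 semiauto observers twice (11 segmentations per tumor).

#' Configuration of a synthetic reproducibility study
#'
#' Defaults reproduce the canonical design: 20 tumors, 5 manual observers,
#' 3 semi-automatic observers with 2 GrowCut runs each (5 + 3 x 2 = 11
#' segmentations per tumor). Per-tumor phantom parameters are drawn from
#' `phantom_ranges`; everything is a pure function of `master_seed`.
#'
#' Manual observers get independent smooth boundary jitter
#' (`manual_jitter_sd`, default 1.5 mm) plus a per-observer systematic bias
#' drawn once with sd `manual_bias_sd`; semi-automatic variability comes only
#' from stroke randomization (plus a small per-observer stroke-margin
#' idiosyncrasy), so manual inter-observer variance exceeds semi-auto
#' variance by construction.
#'
#' @param n_tumors number of tumors (default 20).
#' @param n_manual_observers manual observers per tumor (default 5).
#' @param n_semiauto_observers semiauto observers (default 3).
#' @param n_semiauto_runs GrowCut runs per semiauto observer (default 2).
#' @param base_spec a [phantom_spec()] providing grid, spacing, intensities
#'   and noise; per-tumor geometry fields are overridden from the ranges.
#' @param phantom_ranges list of per-tumor parameter ranges:
#'   `lesion_radius`, `spiculation_count`, `spiculation_amplitude`,
#'   `texture_correlation_length` (each `c(min, max)`).
#' @param manual_jitter_sd boundary jitter sd (mm) of manual observers.
#' @param manual_smoothing_fwhm manual displacement/smoothing FWHM (mm).
#' @param manual_bias_sd sd (mm) of per-observer systematic bias.
#' @param semiauto_strokes foreground strokes per semiauto run.
#' @param semiauto_margin_jitter half-width of the per-observer stroke margin
#'   factor (factor ~ 1 +/- this).
#' @param master_seed integer master seed.
#' @return a `study_config` list.
#' @export
study_config <- function(n_tumors = 20L,
                         n_manual_observers = 5L,
                         n_semiauto_observers = 3L,
                         n_semiauto_runs = 2L,
                         base_spec = phantom_spec(),
                         phantom_ranges = list(
                           lesion_radius = c(7, 12),
                           spiculation_count = c(0L, 8L),
                           spiculation_amplitude = c(0.5, 2),
                           texture_correlation_length = c(2, 5)),
                         manual_jitter_sd = 1.5,
                         manual_smoothing_fwhm = 4,
                         manual_bias_sd = 0.5,
                         semiauto_strokes = 3L,
                         semiauto_margin_jitter = 0.15,
                         master_seed = 1L) {
  cfg <- list(n_tumors = as.integer(n_tumors),
              n_manual_observers = as.integer(n_manual_observers),
              n_semiauto_observers = as.integer(n_semiauto_observers),
              n_semiauto_runs = as.integer(n_semiauto_runs),
              base_spec = base_spec, phantom_ranges = phantom_ranges,
              manual_jitter_sd = manual_jitter_sd,
              manual_smoothing_fwhm = manual_smoothing_fwhm,
              manual_bias_sd = manual_bias_sd,
              semiauto_strokes = as.integer(semiauto_strokes),
              semiauto_margin_jitter = semiauto_margin_jitter,
              master_seed = as.integer(master_seed))
  if (cfg$n_tumors < 1) stopf("n_tumors must be >= 1")
  if (cfg$n_manual_observers < 2 || cfg$n_semiauto_observers < 2)
    stopf("at least 2 observers per group are required")
  if (cfg$n_semiauto_runs < 1) stopf("n_semiauto_runs must be >= 1")
  # check that the largest drawn lesion fits the grid
  probe <- cfg$base_spec
  probe$lesion_radius <- max(phantom_ranges$lesion_radius)
  probe$spiculation_amplitude <- max(phantom_ranges$spiculation_amplitude)
  validate_phantom_spec(probe)
  structure(cfg, class = "study_config")
}

draw_phantom_spec <- function(config, tumor) {
  rg <- config$phantom_ranges
  spec <- config$base_spec
  with_seed(derive_seed(config$master_seed, tumor, 101L), {
    spec$lesion_radius <- runif(1, rg$lesion_radius[1], rg$lesion_radius[2])
    spec$spiculation_count <- sample(rg$spiculation_count[1]:rg$spiculation_count[2], 1L)
    spec$spiculation_amplitude <- runif(1, rg$spiculation_amplitude[1],
                                        rg$spiculation_amplitude[2])
    spec$texture_correlation_length <- runif(1, rg$texture_correlation_length[1],
                                             rg$texture_correlation_length[2])
  })
  spec$seed <- derive_seed(config$master_seed, tumor, 102L)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

# Per-observer idiosyncrasies (constant across tumors -> true observer
# effects): manual systematic bias, semiauto stroke-margin factor.
observer_profiles <- function(config) {
  man_bias <- with_seed(derive_seed(config$master_seed, 900L), {
    rnorm(config$n_manual_observers, 0, config$manual_bias_sd)
  })
  sa_margin <- with_seed(derive_seed(config$master_seed, 901L), {
    1 + runif(config$n_semiauto_observers,
              -config$semiauto_margin_jitter, config$semiauto_margin_jitter)
  })
  list(manual_bias = man_bias, semiauto_margin = sa_margin)
}

#' Generate a full synthetic observer study
#'
#' For every tumor: one phantom volume + truth mask, `n_manual_observers`
#' simulated manual delineations, and `n_semiauto_observers x
#' n_semiauto_runs` GrowCut segmentations. Fully reproducible from
#' `config$master_seed`. When `out_dir` is given, all volumes and masks are
#' written (NRRD by default, or NIfTI) together with a JSON manifest.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory for persisted volumes/masks.
#' @param format `"nrrd"` or `"nifti"` for persisted files.
#' @param verbose print per-tumor progress.
#' @return a `study_dataset`: list with `config`, `tumors` (each with `id`,
#'   `volume`, `truth`, `masks`, `meta`) and, if persisted, `manifest`.
#' @export
generate_study <- function(config = study_config(), out_dir = NULL,
                           format = c("nrrd", "nifti"), verbose = FALSE) {
  format <- match.arg(format)
  ext <- if (format == "nrrd") ".nrrd" else ".nii.gz"
  prof <- observer_profiles(config)
  tumors <- vector("list", config$n_tumors)
  records <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (t in seq_len(config$n_tumors)) {
    if (verbose) message(sprintf("tumor %d/%d", t, config$n_tumors))
    spec <- draw_phantom_spec(config, t)
    ph <- generate_phantom(spec)
    masks <- list()
    meta <- list()
    for (o in seq_len(config$n_manual_observers)) {
      sd_obs <- derive_seed(config$master_seed, t, 200L, o)
      model <- observer_model("manual",
                              boundary_jitter_sd = config$manual_jitter_sd,
                              smoothing_fwhm = config$manual_smoothing_fwhm,
                              systematic_bias = prof$manual_bias[o],
                              seed = sd_obs)
      key <- sprintf("manual_o%d", o)
      masks[[key]] <- simulate_manual_mask(ph$mask, model)
      meta[[key]] <- list(group = "manual", observer = o, run = 1L, seed = sd_obs)
    }
    for (o in seq_len(config$n_semiauto_observers)) {
      for (rr in seq_len(config$n_semiauto_runs)) {
        sd_run <- derive_seed(config$master_seed, t, 300L, o, rr)
        model <- observer_model("semiauto",
                                n_seed_strokes = config$semiauto_strokes,
                                margin_factor = prof$semiauto_margin[o],
                                seed = sd_run)
        key <- sprintf("semiauto_o%d_r%d", o, rr)
        masks[[key]] <- simulate_semiauto_mask(ph$volume, ph$mask, model)
        meta[[key]] <- list(group = "semiauto", observer = o, run = rr,
                            seed = sd_run)
      }
    }
    tumors[[t]] <- list(id = t, spec = spec, volume = ph$volume,
                        truth = ph$mask, masks = masks, meta = meta)
    if (!is.null(out_dir)) {
      volf <- sprintf("tumor%02d_volume%s", t, ext)
      trf <- sprintf("tumor%02d_truth%s", t, ext)
      write_volume(ph$volume, file.path(out_dir, volf))
      write_mask(ph$mask, file.path(out_dir, trf))
      for (key in names(masks)) {
        mf <- sprintf("tumor%02d_%s%s", t, key, ext)
        write_mask(masks[[key]], file.path(out_dir, mf))
        mm <- meta[[key]]
        records[[length(records) + 1L]] <-
          data.frame(tumor = t, group = mm$group, observer = mm$observer,
                     run = mm$run, volume = volf, mask = mf, seed = mm$seed,
                     stringsAsFactors = FALSE)
      }
    }
  }
  ds <- list(config = config, tumors = tumors)
  if (!is.null(out_dir)) {
    manifest <- do.call(rbind, records)
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    ds$manifest <- manifest
    ds$out_dir <- out_dir
  }
  structure(ds, class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  n_masks <- if (length(x$tumors)) length(x$tumors[[1]]$masks) else 0L
  cat(sprintf("<study_dataset> %d tumor(s), %d segmentation(s) per tumor (master seed %d)\n",
              length(x$tumors), n_masks, x$config$master_seed))
  invisible(x)
}
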