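#' Write a B-scan (and its label mask) to TIFF
#'
#' The intensity image is written as 32-bit float TIFF; the mask as an
#' 8-bit indexed TIFF using the [label_codes()] table (0 = background).
#'
#' @param bscan an `oct_bscan`.
#' @param path image file path (`.tif`); the mask goes to
#'   `<path>_mask.tif`.
#' @return invisibly, the two paths.
#' @export
write_bscan_tiff <- function(bscan, path) {
  stopifnot(inherits(bscan, "oct_bscan"))
  img <- bscan$image
  tiff::writeTIFF(img / max(img, 1e-300), path, bits.per.sample = 32L)
  codes <- label_codes()
  m <- matrix(0L, nrow(bscan$mask), ncol(bscan$mask))
  for (l in names(codes)) m[bscan$mask == l & !is.na(bscan$mask)] <- codes[[l]]
  mask_path <- sub("\\.tiff?$", "", path)
  mask_path <- paste0(mask_path, "_mask.tif")
  tiff::writeTIFF(m / 255, mask_path, bits.per.sample = 8L)
  invisible(c(image = path, mask = mask_path))
}

#' Write / read tab-delimited result tables
#'
#' All pipeline tables are TSV with a header line; `write_table_tsv` also
#' embeds provenance (profile, seed, config hash) as `#`-prefixed comment
#' lines that `read_table_tsv` skips.
#'
#' @param x data.frame.
#' @param path file path.
#' @param provenance optional named character vector written as comments.
#' @return `path` (write) / data.frame (read), invisibly for write.
#' @export
write_table_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' A fully serializable (YAML) configuration driving [run_pipeline()]. One
#' root seed deterministically spawns per-stage seeds, so partial re-runs
#' reproduce.
#'
#' @param profile profile name (`"ss"`/`"sd"`) or a profile field list.
#' @param seed root seed.
#' @param n_patients,samples_per_patient,class_mix cohort shape.
#' @param task,classifier,epochs classification settings.
#' @param noise noise spec for the simulator.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = "ss", seed = 1, n_patients = 4,
                            samples_per_patient = 2,
                            class_mix = c("WM0%" = 0.5, "WM>60%" = 0.5),
                            task = "I", classifier = "fcnn", epochs = 15,
                            noise = list(type = "speckle", background = 1e-5)) {
  if (!task %in% c("I", "II", "III", "IV")) {
    stop("unknown classification task id '", task, "'", call. = FALSE)
  }
  if (!classifier %in% c("fcnn", "cnn")) {
    stop("unknown classifier '", classifier, "'", call. = FALSE)
  }
  structure(list(schema_version = 1L, profile = profile, seed = as.integer(seed),
                 n_patients = n_patients,
                 samples_per_patient = samples_per_patient,
                 class_mix = as.list(class_mix), task = task,
                 classifier = classifier, epochs = epochs, noise = noise),
            class = "pipeline_config")
}

# per-stage seeds spawned from the root seed (counter-based, < 2^31)
.stage_seed <- function(root, stage) {
  (as.integer(root) + 101L * match(stage, c("cohort", "calibration", "fit",
                                            "classify"))) %% .Machine$integer.max
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> calibrate -> extract -> fit -> summarize -> classify
#' on a synthetic cohort and writes every intermediate artifact into
#' `out_dir`: B-scan/mask TIFFs, sweep and fits tables (TSV), per-label
#' summaries, classification metrics, a YAML manifest of seeds and settings,
#' and a plain-text log. Re-running with the same config reproduces the
#' deterministic stages bit-identically.
#'
#' @param config a [pipeline_config()] (or a path to its YAML form).
#' @param out_dir output directory (created).
#' @param write_images write per-sample TIFF stacks (slowest part; disable
#'   for speed).
#' @return invisibly, a list with the in-memory results: `cohort`,
#'   `calibration`, `fits`, `summary_mu`, `lopo`, and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("octrun"),
                         write_images = FALSE) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    cfg$class_mix <- unlist(cfg$class_mix)
    config <- do.call(pipeline_config, cfg[setdiff(names(cfg), "schema_version")])
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  stage <- "setup"
  result <- list(out_dir = out_dir)
  tryCatch({
    profile <- load_profile(config$profile)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")))
    prov <- c(profile = profile$name, seed = as.character(config$seed),
              config_hash = sprintf("%x", cfg_hash))
    log_line("pipeline start: profile=%s seed=%d", profile$name, config$seed)

    stage <- "simulate"
    true_rolloff <- if (profile$apply_rolloff) rolloff_model(1.5) else NULL
    true_confocal <- confocal_model(0.9, 0.3)
    cohort <- generate_cohort(config$n_patients, config$samples_per_patient,
                              unlist(config$class_mix), profile,
                              seed = .stage_seed(config$seed, "cohort"),
                              confocal = true_confocal, rolloff = true_rolloff,
                              noise = config$noise)
    result$cohort <- cohort
    if (write_images) {
      img_dir <- file.path(out_dir, "bscans")
      dir.create(img_dir, showWarnings = FALSE)
      for (i in seq_along(cohort$bscans)) {
        b <- cohort$bscans[[i]]
        write_bscan_tiff(b, file.path(img_dir, sprintf("%s_%s_%s.tif",
                                                       b$patient_id,
                                                       b$sample_id, b$bscan_id)))
      }
    }
    log_line("simulated %d B-scans / %d patients", length(cohort$bscans),
             config$n_patients)

    stage <- "calibrate"
    cal_seed <- .stage_seed(config$seed, "calibration")
    ro_sweep <- if (profile$apply_rolloff) {
      simulate_mirror_sweep(profile, "reference_arm_only", true_rolloff,
                            true_confocal, n_positions = 50, noise_sd = 0.01,
                            seed = cal_seed)
    }
    co_sweep <- simulate_mirror_sweep(profile, "fixed_reference", true_rolloff,
                                      true_confocal, n_positions = 50,
                                      noise_sd = 0.01, seed = cal_seed + 1L)
    calibration <- calibrate_system(profile, ro_sweep, co_sweep)
    result$calibration <- calibration
    write_table_tsv(data.frame(depth_mm = co_sweep$depth_mm,
                               intensity = co_sweep$intensity),
                    file.path(out_dir, "confocal_sweep.tsv"), prov)
    log_line("calibration: z_f=%.3f mm z_r=%.3f mm%s",
             calibration$confocal$focus_mm, calibration$confocal$rayleigh_mm,
             if (is.null(calibration$rolloff)) " (roll-off neglected)"
             else sprintf(" omega=%.3f", calibration$rolloff$omega))

    stage <- "extract"
    patches <- cohort_patches(cohort, profile)
    if (!length(patches)) stop("no patches extracted", call. = FALSE)
    write_table_tsv(patch_manifest(patches),
                    file.path(out_dir, "patch_manifest.tsv"), prov)
    log_line("extracted %d patches", length(patches))

    stage <- "fit"
    fits <- batch_fit(patches, profile, calibration)
    result$fits <- fits
    write_table_tsv(fits, file.path(out_dir, "fits.tsv"), prov)
    log_line("fitted %d/%d patches", sum(fits$ok), nrow(fits))

    stage <- "summarize"
    result$summary_mu <- summarize_by_label(fits, "mu")
    write_table_tsv(result$summary_mu, file.path(out_dir, "summary_mu.tsv"),
                    prov)
    write_table_tsv(summarize_by_label(fits, "i0_normalized"),
                    file.path(out_dir, "summary_i0.tsv"), prov)

    stage <- "classify"
    ds <- assemble_task(fits[fits$ok, ], config$task)
    cfg_train <- train_config(epochs = config$epochs,
                              seed = .stage_seed(config$seed, "classify"))
    lopo <- run_lopo_cv(ds, config$classifier, cfg_train,
                        patches = if (config$classifier == "cnn") patches)
    result$lopo <- lopo
    agg <- data.frame(task = config$task, classifier = config$classifier,
                      metric = c("sensitivity", "specificity"),
                      mean = c(lopo$mean_sensitivity, lopo$mean_specificity),
                      sd = c(lopo$sd_sensitivity, lopo$sd_specificity))
    write_table_tsv(lopo$folds, file.path(out_dir, "folds.tsv"), prov)
    write_table_tsv(agg, file.path(out_dir, "metrics.tsv"), prov)
    log_line("classification task %s (%s): sens %.2f+/-%.2f spec %.2f+/-%.2f",
             config$task, config$classifier, lopo$mean_sensitivity,
             lopo$sd_sensitivity, lopo$mean_specificity, lopo$sd_specificity)

    yaml::write_yaml(list(schema_version = 1L, profile = profile$name,
                          root_seed = config$seed,
                          stage_seeds = list(
                            cohort = .stage_seed(config$seed, "cohort"),
                            calibration = cal_seed,
                            classify = .stage_seed(config$seed, "classify")),
                          n_patches = length(patches),
                          package_version = as.character(
                            utils::packageVersion("octatten"))),
                    file.path(out_dir, "manifest.yaml"))
    log_line("pipeline done")
  }, error = function(e) {
    log_line("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "' (artifacts up to the last ",
         "good stage are in ", out_dir, "): ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
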