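#' Default study configuration
#'
#' Nested configuration for the full simulation-reconstruction-IDIF
#' pipeline. Every block mirrors the arguments of the corresponding stage
#' function; [run_study()] rejects unknown keys so that typos cannot
#' silently fall back to defaults. The defaults reproduce the scaled-down
#' study conditions: 96 x 96 single-slice phantom with a ~3-voxel aorta,
#' 96 projection angles, the 45-frame dynamic scheme, 10 Poisson
#' realisations, and 21 subsets x 10 iterations for every algorithm.
#'
#' @return nested list of class `study_config`.
#' @export
default_study_config <- function() {
  structure(list(
    phantom = list(grid_dim = c(96L, 96L), spacing = c(1.56, 1.56),
                   n_slices = 1L, z_spacing = 2.031,
                   aorta_diameter_mm = 5, body_diameter_mm = 120,
                   organ_large_diameter_mm = 40, organ_mid_diameter_mm = 16,
                   mu_soft = 0.0096, guidance_noise_sd = 0.05,
                   guidance_seed = 42L),
    geometry = list(n_angles = 96L, n_radial = NULL, radial_spacing = NULL),
    frames = list(spec = default_frame_spec()),
    acquisition = list(counts_scale = default_counts_scale(),
                       n_realisations = 10L, base_seed = 1L,
                       randoms_fraction = 0.2, scatter_fraction = 0.15,
                       scatter_width_bins = 5, randoms_basis = "trues"),
    recon = list(n_subsets = 21L, n_iterations = 10L, fwhm_mm = 3,
                 kernel = list(sigma_m = 1, sigma_dm = 3, sigma_p = 1,
                               sigma_dp = 3, neighbourhood = NULL,
                               normalise_rows = TRUE)),
    idif = list(threshold_fraction = 0.75, roi_source = "self"),
    algorithms = c("osem", "osem_g", "kem", "hkem")
  ), class = "study_config")
}

# recursive unknown-key validation against the default schema
.validate_config <- function(cfg, template = default_study_config(),
                             path = "config") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop("unknown ", path, " key(s): ", paste(extra, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]])))
      .validate_config(cfg[[nm]], template[[nm]], paste(path, nm, sep = "$"))
  }
  invisible(TRUE)
}

# deep merge of user config over defaults (lists merged by name)
.merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]])))
      defaults[[nm]] <- .merge_config(defaults[[nm]], cfg[[nm]])
    else defaults[[nm]] <- cfg[[nm]]
  }
  defaults
}

#' Read a study configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration, validates it against the
#' default schema (unknown keys are an error) and merges it over the
#' defaults.
#'
#' @param path YAML file path.
#' @return full `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$frames$spec))
    cfg$frames$spec <- lapply(cfg$frames$spec, as.numeric)
  .validate_config(cfg)
  structure(.merge_config(unclass(default_study_config()), cfg),
            class = "study_config")
}

# short provenance hash of the serialised configuration (polynomial hash
# over the canonical JSON encoding)
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  b <- utf8ToInt(as.character(s))
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full simulation / reconstruction / IDIF study
#'
#' Executes all stages for the requested algorithms: phantom and frame
#' scheme construction, dynamic acquisition simulation with Poisson noise
#' realisations, per-frame reconstruction, ROI extraction at the
#' peak-activity frame, and the bias / CoV summaries in both the
#' all-frames (pooled) and peak-frame (repeatability) layouts. Re-running
#' with the same configuration reproduces every number bitwise.
#'
#' ROI policy (`idif$roi_source`): `"self"` derives the ROI from the
#' peak-activity frame of the algorithm under test, one ROI per
#' (algorithm, realisation); `"hkem"` uses the hybrid-kernel
#' reconstruction's ROI for every algorithm; `"truth"` thresholds the
#' noiseless ground-truth image.
#'
#' @param config a `study_config` (see [default_study_config()],
#'   [read_study_config()]), or a partial named list merged over the
#'   defaults.
#' @param output_dir optional directory: writes metrics and IDIF tables
#'   (CSV), ROI masks (NIfTI), the resolved configuration (YAML) and a log.
#' @param verbose print per-stage progress.
#' @return list of class `study_report`: `metrics` (pooled mean/max/min
#'   |bias| and CoV per algorithm), `metrics_peak` (peak-frame
#'   repeatability), `idif` (per-algorithm bias/cov/means matrices and
#'   per-realisation curves), `truth`, `roi_voxels`, `config`,
#'   `config_hash`.
#' @export
run_study <- function(config = default_study_config(), output_dir = NULL,
                      verbose = TRUE) {
  if (!inherits(config, "study_config")) {
    .validate_config(config)
    config <- structure(.merge_config(unclass(default_study_config()),
                                      config), class = "study_config")
  }
  cfg <- config
  say <- function(...) if (verbose) message(...)
  hash <- .config_hash(unclass(cfg))
  say("study config hash ", hash)

  ph <- do.call(make_phantom, c(cfg$phantom[setdiff(names(cfg$phantom),
                                                    "guidance_seed")],
                                list(seed = cfg$phantom$guidance_seed)))
  scheme <- make_frame_scheme(cfg$frames$spec)
  tacs <- default_tac_table()
  geom <- pet_geometry(dim(ph$labels), ph$spacing[seq_along(dim(ph$labels))],
                       n_angles = cfg$geometry$n_angles,
                       n_radial = cfg$geometry$n_radial,
                       radial_spacing = cfg$geometry$radial_spacing)
  say("simulating ", nrow(scheme), " frames x ",
      cfg$acquisition$n_realisations, " realisations")
  study <- simulate_study(ph, tacs, scheme, geom,
                          counts_scale = cfg$acquisition$counts_scale,
                          n_realisations = cfg$acquisition$n_realisations,
                          base_seed = cfg$acquisition$base_seed,
                          randoms_fraction = cfg$acquisition$randoms_fraction,
                          scatter_fraction = cfg$acquisition$scatter_fraction,
                          scatter_width_bins = cfg$acquisition$scatter_width_bins,
                          randoms_basis = cfg$acquisition$randoms_basis)
  tot_trues <- sum(vapply(study$noiseless, function(s) sum(s$trues),
                          numeric(1)))
  say(sprintf("total true counts %.4g; realised randoms fraction %.4f",
              tot_trues,
              sum(vapply(study$noiseless, function(s) sum(s$randoms),
                         numeric(1))) / tot_trues))
  att <- attenuation_factors(ph$mu, geom)
  system <- make_em_system(geom, att, cfg$recon$n_subsets)

  kp_h <- do.call(kernel_params,
                  c(cfg$recon$kernel, list(use_pet_component = TRUE)))
  kp_k <- do.call(kernel_params,
                  c(cfg$recon$kernel, list(use_pet_component = FALSE)))
  st <- list(
    osem = recon_settings("osem", cfg$recon$n_subsets, cfg$recon$n_iterations),
    osem_g = recon_settings("osem_g", cfg$recon$n_subsets,
                            cfg$recon$n_iterations, fwhm_mm = cfg$recon$fwhm_mm),
    kem = recon_settings("kem", cfg$recon$n_subsets, cfg$recon$n_iterations,
                         kernel = kp_k),
    hkem = recon_settings("hkem", cfg$recon$n_subsets, cfg$recon$n_iterations,
                          kernel = kp_h)
  )
  algos <- cfg$algorithms
  stopifnot(all(algos %in% names(st)))
  roi_source <- cfg$idif$roi_source
  if (roi_source == "hkem" && !"hkem" %in% algos)
    stop("roi_source 'hkem' needs hkem among the algorithms")
  bases <- unique(ifelse(algos == "osem_g", "osem", algos))

  segment <- ph$labels == ph$label_names[["aorta"]]
  truth <- study$truth
  peak_true <- which.max(truth)
  K <- nrow(scheme); R <- cfg$acquisition$n_realisations
  res <- lapply(algos, function(a)
    list(bias = matrix(NA_real_, K, R), cov = matrix(NA_real_, K, R),
         means = matrix(NA_real_, K, R), roi_voxels = integer(R)))
  names(res) <- algos
  curves <- lapply(algos, function(a) vector("list", R))
  names(curves) <- algos
  rois_out <- lapply(algos, function(a) vector("list", R))
  names(rois_out) <- algos

  truth_peak_img <- sample_activity_image(ph, tacs, scheme[peak_true, ])
  for (r in seq_len(R)) {
    say("realisation ", r, "/", R)
    frames_base <- list()
    for (b in bases) {
      frames_base[[b]] <- lapply(seq_len(K), function(k)
        reconstruct(get_frame_data(study, r, k), system, st[[b]],
                    guidance = ph$guidance, body_mask = ph$body_mask))
    }
    for (a in algos) {
      frames <- if (a == "osem_g") {
        lapply(frames_base[["osem"]], gaussian_postfilter,
               fwhm_mm = cfg$recon$fwhm_mm, spacing = ph$spacing)
      } else frames_base[[a]]
      roi_frames <- switch(roi_source,
                           self = frames,
                           hkem = frames_base[["hkem"]],
                           truth = NULL,
                           stop("unknown roi_source: ", roi_source))
      if (is.null(roi_frames)) {
        roi <- extract_roi(segment, truth_peak_img,
                           cfg$idif$threshold_fraction)
      } else {
        seg_means <- vapply(roi_frames, function(f) roi_mean(segment, f),
                            numeric(1))
        roi <- extract_roi(segment, roi_frames[[which.max(seg_means)]],
                           cfg$idif$threshold_fraction)
      }
      idif <- compute_idif(frames, roi, truth, scheme)
      res[[a]]$bias[, r] <- idif$bias
      res[[a]]$cov[, r] <- idif$cov
      res[[a]]$means[, r] <- idif$mean
      res[[a]]$roi_voxels[r] <- attr(roi, "n_voxels")
      curves[[a]][[r]] <- idif
      rois_out[[a]][[r]] <- roi
    }
  }

  metrics <- do.call(rbind, lapply(algos, function(a)
    cbind(data.frame(algorithm = a),
          summarise_study(res[[a]]$bias, res[[a]]$cov, "pooled"))))
  metrics_peak <- do.call(rbind, lapply(algos, function(a)
    cbind(data.frame(algorithm = a),
          summarise_study(res[[a]]$bias, res[[a]]$cov, "peak_frame",
                          peak_frame = peak_true, truth = truth,
                          means = res[[a]]$means))))
  say("ROI sizes (voxels): ",
      paste(vapply(algos, function(a)
        paste0(a, "=", paste(range(res[[a]]$roi_voxels), collapse = "-")),
        character(1)), collapse = ", "))

  report <- structure(list(metrics = metrics, metrics_peak = metrics_peak,
                           idif = res, curves = curves, truth = truth,
                           peak_frame = peak_true,
                           roi_voxels = lapply(res, `[[`, "roi_voxels"),
                           config = cfg, config_hash = hash,
                           seeds = study$seeds),
                      class = "study_report")
  if (!is.null(output_dir)) .write_report(report, rois_out, ph, output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report (config ", x$config_hash, ")\n", sep = "")
  cat("pooled |bias| and CoV over frames x realisations (%):\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  cat("peak-frame repeatability (frame ", x$peak_frame, "):\n", sep = "")
  print(x$metrics_peak, row.names = FALSE, digits = 3)
  invisible(x)
}

.write_report <- function(report, rois_out, phantom, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- report$config_hash; df }
  utils::write.csv(stamp(report$metrics),
                   file.path(output_dir, "metrics_pooled.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(report$metrics_peak),
                   file.path(output_dir, "metrics_peak_frame.csv"),
                   row.names = FALSE)
  curves <- do.call(rbind, lapply(names(report$curves), function(a)
    do.call(rbind, lapply(seq_along(report$curves[[a]]), function(r)
      cbind(algorithm = a, realisation = r, report$curves[[a]][[r]])))))
  utils::write.csv(stamp(curves), file.path(output_dir, "idif_curves.csv"),
                   row.names = FALSE)
  for (a in names(rois_out))
    write_image(rois_out[[a]][[1]] * 1,
                file.path(output_dir, paste0("roi_", a, ".nii")),
                spacing = phantom$spacing[seq_along(dim(phantom$labels))])
  cfg <- unclass(report$config)
  cfg$config_hash <- report$config_hash
  yaml::write_yaml(cfg, file.path(output_dir, "study_config.yaml"))
  invisible(output_dir)
}

#' NIfTI image I/O
#'
#' Thin wrappers for voxel images: data and voxel spacing round-trip
#' losslessly.
#'
#' @param image numeric array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm, one value per image dimension.
#' @return `read_image()` returns the array with attribute `spacing`.
#' @export
write_image <- function(image, path, spacing) {
  img <- RNifti::asNifti(array(as.numeric(image), dim = dim(image)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)
  out
}

#' Study container I/O
#'
#' Saves / loads a simulated study (all realisations, frames and noiseless
#' components plus settings) as a single-file container.
#'
#' @param study a [simulate_study()] object.
#' @param path file path (`.rds`).
#' @return `read_study()` returns the `pet_study`.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "pet_study"))
  saveRDS(study, path)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read study container '",
                                           path, "': ", conditionMessage(e)))
  if (!inherits(obj, "pet_study"))
    stop("file '", path, "' is not a study container")
  obj
}
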