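# File exchange: multi-page TIFF frame stacks with a CSV ground-truth /
# provenance sidecar, and a YAML run configuration. Counts are stored as
# photons (no camera gain). All angles in data files are radians; coordinates
# are continuous nm from the ROI center, x rightward, y upward.

sidecar_columns <- c("frame", "x_nm", "y_nm", "d_nm", "theta_rad", "phi_rad",
                     "Nx", "Ny", "Neff", "seed")

#' Write a frame stack with its ground-truth sidecar
#'
#' Frames go to a multi-page TIFF: 16-bit unsigned for integer counts below
#' 2^16, with an automatic fall-back to 32-bit (scaled) storage when counts
#' overflow 16 bits or are non-integer (noise-free expected images). The
#' scale used is recorded in the sidecar header so [read_frames()] restores
#' values bit-exactly. The sidecar CSV carries one row per frame in a fixed
#' column order plus provenance header lines (seed, scale, coordinate
#' convention).
#'
#' @param sim Tibble from [simulate_frames()] (`frame_px` list-column plus
#'   ground-truth columns).
#' @param outdir Output directory (created if needed).
#' @param basename File basename (default `"frames"`).
#' @param config Optional run configuration list echoed to
#'   `<basename>_config.yaml`.
#' @return Invisibly, the paths written (`tiff`, `csv`, maybe `config`).
#' @export
write_frames <- function(sim, outdir, basename = "frames", config = NULL) {
  stopifnot(is.data.frame(sim), "frame_px" %in% names(sim))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  frames <- sim$frame_px
  mx <- max(vapply(frames, max, numeric(1)))
  integer_data <- all(vapply(frames, function(f) all(f == round(f)), logical(1)))
  if (integer_data && mx < 2^16) {
    bits <- 16L; scale <- 2^16 - 1
  } else {
    bits <- 32L
    scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
    if (integer_data) {
      message("counts overflow 16-bit storage; falling back to scaled 32-bit TIFF")
    }
  }
  tiff_path <- file.path(outdir, paste0(basename, ".tif"))
  tiff::writeTIFF(lapply(frames, function(f) f / scale), tiff_path,
                  bits.per.sample = bits, compression = "none")
  csv_path <- file.path(outdir, paste0(basename, "_ground_truth.csv"))
  gt <- data.frame(frame = sim$frame, x_nm = sim$x_nm, y_nm = sim$y_nm,
                   d_nm = sim$d_nm, theta_rad = sim$theta_rad,
                   phi_rad = sim$phi_rad, Nx = sim$n_x, Ny = sim$n_y,
                   Neff = sim$n_eff,
                   seed = if ("seed" %in% names(sim)) sim$seed else NA)
  header <- c("# dipoleloc frame stack sidecar",
              sprintf("# scale=%.17g bits=%d integer=%s", scale, bits,
                      integer_data),
              "# coordinates: nm from ROI center, x right / y up; angles in radians")
  writeLines(header, csv_path)
  suppressWarnings(utils::write.table(gt, csv_path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  paths <- list(tiff = tiff_path, csv = csv_path)
  if (!is.null(config)) {
    cfg_path <- file.path(outdir, paste0(basename, "_config.yaml"))
    yaml::write_yaml(config, cfg_path)
    paths$config <- cfg_path
  }
  invisible(paths)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param tiff_path Path to the multi-page TIFF.
#' @param csv_path Path to the sidecar (default: derived from `tiff_path`).
#' @return Tibble with the ground-truth columns and the `frame_px`
#'   list-column; integer stacks are restored exactly.
#' @export
read_frames <- function(tiff_path, csv_path = NULL) {
  if (is.null(csv_path)) {
    csv_path <- sub("\\.tif{1,2}$", "_ground_truth.csv", tiff_path)
  }
  header <- readLines(csv_path, n = 3)
  m <- regmatches(header[2], regexec("scale=([0-9.eE+-]+) bits=([0-9]+) integer=(\\w+)", header[2]))[[1]]
  scale <- as.numeric(m[2]); integer_data <- identical(m[4], "TRUE")
  gt <- utils::read.csv(csv_path, comment.char = "#")
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  frames <- lapply(pages, function(p) {
    f <- p * scale
    if (integer_data) f <- round(f)
    f
  })
  out <- tibble::tibble(frame = gt$frame, x_nm = gt$x_nm, y_nm = gt$y_nm,
                        d_nm = gt$d_nm, theta_rad = gt$theta_rad,
                        phi_rad = gt$phi_rad, n_x = gt$Nx, n_y = gt$Ny,
                        n_eff = gt$Neff, seed = gt$seed)
  out$frame_px <- frames
  out
}

config_defaults <- function() {
  list(
    optical = list(numerical_aperture = 0.7, n_sample = 1.33, n_immersion = 1.0,
                   magnification = 60, tube_focal_length_mm = 180,
                   wavelength_nm = 680, camera_pixel_um = 6.5,
                   defocus_model = "exact_air", pupil_samples = 128),
    aberrations = list(astigmatism_rms_nm = 0.11 * 680),
    acquisition = list(n_max = 5e5, background_sd = 0, roi_px = 17,
                       oversampling = 9, excitation_coupling = FALSE),
    fit = list(fitted_parameters = "xyd", orientation_input = "exact",
               sigma_theta_deg = 2, sigma_phi_deg = 2, oversampling = 3,
               start_d_min = -500, start_d_max = 500),
    seed = 1,
    output_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a sectioned YAML file with sections `optical`, `aberrations`,
#' `acquisition`, `fit`, `seed`, `output_dir`. Absent keys take the standard
#' defaults (NA 0.7 air objective, 60x, 680 nm, 6.5 um pixels, 17 px ROI,
#' N_max 5e5, w6 = 0.11 lambda). Unknown keys are rejected with a per-field
#' diagnostic. In `aberrations`, keys are Noll indices (`"6": 74.8`) or the
#' convenience name `astigmatism_rms_nm`.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return Object of class `run_config`: validated list with constructed
#'   `optical_config`, `zernike_coefficients`, `acquisition_params`,
#'   `fit_config` objects plus the raw values.
#' @export
load_config <- function(path = NULL) {
  raw <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must contain a YAML mapping")
    bad_top <- setdiff(names(user), names(raw))
    if (length(bad_top)) stop("unknown config section(s): ", paste(bad_top, collapse = ", "))
    for (sec in names(user)) {
      if (sec %in% c("seed", "output_dir")) { raw[[sec]] <- user[[sec]]; next }
      if (sec == "aberrations") { raw$aberrations <- user$aberrations; next }
      bad <- setdiff(names(user[[sec]]), names(raw[[sec]]))
      if (length(bad)) {
        stop("unknown key(s) in section '", sec, "': ", paste(bad, collapse = ", "))
      }
      raw[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  optical <- do.call(optical_config, raw$optical)
  coeffs <- do.call(zernike_coefficients, raw$aberrations)
  acquisition <- do.call(acquisition_params, raw$acquisition)
  fit_raw <- raw$fit
  fit <- fit_config(fitted_parameters = fit_raw$fitted_parameters,
                    orientation_input = fit_raw$orientation_input,
                    sigma_theta_deg = fit_raw$sigma_theta_deg,
                    sigma_phi_deg = fit_raw$sigma_phi_deg,
                    oversampling = fit_raw$oversampling,
                    start_d_range = c(fit_raw$start_d_min, fit_raw$start_d_max))
  structure(list(optical = optical, aberrations = coeffs,
                 acquisition = acquisition, fit = fit,
                 seed = raw$seed, output_dir = raw$output_dir, raw = raw),
            class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' Writing then re-loading a configuration reproduces it exactly
#' (round-trip identity).
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$optical); print(x$aberrations); print(x$acquisition); print(x$fit)
  cat(sprintf("  seed %s, output '%s'\n", format(x$seed), x$output_dir))
  invisible(x)
}
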