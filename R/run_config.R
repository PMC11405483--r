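#' Run configuration for the analysis pipeline
#'
#' Collects the tunable parameters of every stage in one validated list so a
#' whole run is reproducible from a single object. All lengths are in µm,
#' volumes in µm³; `NULL` means "derive from the data" where a data-driven
#' default exists (e.g. Otsu threshold).
#'
#' @param channel_map Named integer vector mapping channel position to name,
#'   e.g. `c(dna = 1, h3k4me1 = 2, h3k9me2 = 3, edu = 4, wall = 5)`; `NULL`
#'   keeps stored names (HDF5) or a single unnamed channel (TIFF).
#' @param voxel_size Optional `(dx, dy, dz)` µm override for files without
#'   voxel metadata.
#' @param bit_depth Optional intensity ceiling override.
#' @param threshold Absolute DNA-channel threshold; `NULL` uses Otsu.
#' @param connectivity Voxel connectivity for labelling, 6 or 26.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed seeded at local maxima.
#' @param min_seed_sep_um Minimum separation between watershed seeds (µm).
#' @param vmin_um3,vmax_um3 Volume window used by [curate()] (µm³).
#' @param noise_k EdU noise floor multiplier: background mean + `noise_k` SD.
#' @param coverage_threshold EdU coverage fraction above which a labelled
#'   nucleus is called S1 (homogeneous incorporation).
#' @param min_spots Minimum EdU foci for an S2 (spotted) call.
#' @param min_spot_sep_um Minimum separation between EdU foci (µm).
#' @param enrichment_threshold Fraction of integrated mark signal one
#'   hemisphere must hold for a non-uniform configuration code.
#' @param layer_radii Named increasing outer radial bounds of the tissue
#'   layers (µm), innermost first.
#' @param lrc_zmax Longitudinal extent of the lateral root cap (µm).
#' @param columella_radius Radial bound separating columella from LRC for
#'   nuclei below the QC (µm).
#' @param calibration_window Half-width of the `|z|` window around the QC
#'   used for the 2C ploidy reference (µm).
#' @param k_td Spacing-increase factor defining the PD/TD boundary.
#' @param k_ez Spacing-increase factor defining the TD/EZ boundary.
#' @param seed Random seed recorded with the run.
#'
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(channel_map = NULL,
                       voxel_size = NULL,
                       bit_depth = NULL,
                       threshold = NULL,
                       connectivity = 26,
                       split_touching = TRUE,
                       min_seed_sep_um = 2,
                       vmin_um3 = 5,
                       vmax_um3 = 500,
                       noise_k = 3,
                       coverage_threshold = 0.6,
                       min_spots = 3,
                       min_spot_sep_um = 1,
                       enrichment_threshold = 0.55,
                       layer_radii = c(vascular = 8, pericycle = 13,
                                       endodermis = 18, cortex = 24,
                                       epidermis = 30),
                       lrc_zmax = 80,
                       columella_radius = 15,
                       calibration_window = 15,
                       k_td = 1.5,
                       k_ez = 3,
                       seed = 1L) {
  if (!is.null(channel_map)) {
    if (is.null(names(channel_map)) || any(!nzchar(names(channel_map)))) {
      stop("`channel_map` must be a named integer vector", call. = FALSE)
    }
  }
  stopifnot(connectivity %in% c(6, 26),
            vmin_um3 < vmax_um3,
            noise_k >= 0,
            coverage_threshold > 0, coverage_threshold <= 1,
            min_spots >= 1,
            enrichment_threshold > 0.5, enrichment_threshold <= 1,
            calibration_window > 0,
            k_td > 1, k_ez > k_td)
  if (is.null(names(layer_radii)) || is.unsorted(layer_radii, strictly = TRUE)) {
    stop("`layer_radii` must be named and strictly increasing", call. = FALSE)
  }
  structure(
    list(channel_map = channel_map, voxel_size = voxel_size,
         bit_depth = bit_depth, threshold = threshold,
         connectivity = connectivity, split_touching = split_touching,
         min_seed_sep_um = min_seed_sep_um,
         vmin_um3 = vmin_um3, vmax_um3 = vmax_um3,
         noise_k = noise_k, coverage_threshold = coverage_threshold,
         min_spots = min_spots, min_spot_sep_um = min_spot_sep_um,
         enrichment_threshold = enrichment_threshold,
         layer_radii = layer_radii, lrc_zmax = lrc_zmax,
         columella_radius = columella_radius,
         calibration_window = calibration_window,
         k_td = k_td, k_ez = k_ez, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.null(val)) val <- "NULL"
    cat("  ", nm, ": ",
        paste(if (!is.null(names(val))) paste0(names(val), "=", val) else val,
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
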