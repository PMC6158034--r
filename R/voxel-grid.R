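#' Single-channel 3D intensity volume with physical voxel sizes
#'
#' The unit every imaging operation consumes: a non-negative intensity array in
#' `(z, y, x)` axis order together with the lateral and axial voxel dimensions
#' in nanometres and a channel label. Physical coordinates are nanometres with
#' the origin at the centre of voxel `(0, 0, 0)`; voxel indices are 0-based.
#'
#' @param data numeric 3D array, axis order `(z, y, x)`, all values finite.
#' @param voxel_xy_nm lateral voxel size in nm (> 0).
#' @param voxel_z_nm axial voxel size (z-spacing) in nm (> 0).
#' @param channel channel label; the triplex pipeline uses
#'   `"INSL5"`, `"PYY"`, `"GLP1"`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 16, 16)), voxel_xy_nm = 40, voxel_z_nm = 110)
#' dim(g$data)
#' @export
voxel_grid <- function(data, voxel_xy_nm, voxel_z_nm, channel = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array in (z, y, x) order")
  if (!all(is.finite(data)))
    stopf("`data` must be finite everywhere")
  if (!is.numeric(voxel_xy_nm) || voxel_xy_nm <= 0 ||
      !is.numeric(voxel_z_nm) || voxel_z_nm <= 0)
    stopf("voxel sizes must be positive lengths in nm")
  structure(list(data = data,
                 voxel_xy_nm = as.numeric(voxel_xy_nm),
                 voxel_z_nm = as.numeric(voxel_z_nm),
                 channel = as.character(channel)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> channel %s, %d x %d x %d (z,y,x), voxel %g x %g nm\n",
              x$channel, d[1], d[2], d[3], x$voxel_xy_nm, x$voxel_z_nm))
  invisible(x)
}

# Analysis calls need enough voxels for histograms, windows and masks.
check_analysis_grid <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  if (d[1] < 3L || d[2] < 16L || d[3] < 16L)
    stopf("grid too small for analysis: need shape >= (3, 16, 16), got (%d, %d, %d)",
          d[1], d[2], d[3])
  invisible(grid)
}

#' Analysis configuration for the co-localization pipeline
#'
#' Collects every tunable of the detection / localization / classification /
#' sizing pipeline with its default. Defaults encode the published rules:
#' duplicate removal within 2 pixels, dim-spot component size gate
#' 12 < np < 250, inter-channel prefilter at 200 nm, a 150 nm spherical
#' intensity mask, positive/negative intensity thresholds at 5% / 2% of the
#' per-channel maximum, and an R-squared > 0.75 gate on 1D size fits.
#'
#' @param dedupe_radius_px duplicate-removal radius in xy-pixel units.
#' @param np_min,np_max strict bounds on dim-component voxel counts
#'   (a component is kept iff `np_min < np < np_max`).
#' @param prefilter_nm inter-channel separation prefilter, nm (strict `<`).
#' @param mask_radius_nm spherical intensity-mask radius, nm.
#' @param pos_threshold normalized intensity above which a channel is called
#'   positive (strict `>`).
#' @param neg_threshold normalized intensity below which a channel is called
#'   negative (strict `<`); must be below `pos_threshold`.
#' @param r2_min minimum R-squared for an accepted 1D size fit (strict `>`).
#' @param fit_window_px odd window extents `(x, y, z)` in voxels for the local
#'   3D Gaussian fits.
#' @param min_fit_significance a 3D fit counts as converged only when its
#'   amplitude exceeds this multiple of the window's residual standard
#'   deviation; noise-only windows then fall back to the window centroid.
#' @param profile_half_length_px half-length of the x-axis intensity line
#'   profile used for sizing, in voxels.
#' @param bright_mode strategy tag for the bright-vesicle histogram split;
#'   `"otsu3"` (three-class Otsu, top class bright) is the only built-in.
#' @return An object of class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$prefilter_nm
#' @export
analysis_config <- function(dedupe_radius_px = 2.0,
                            np_min = 12L,
                            np_max = 250L,
                            prefilter_nm = 200,
                            mask_radius_nm = 150,
                            pos_threshold = 0.05,
                            neg_threshold = 0.02,
                            r2_min = 0.75,
                            fit_window_px = c(x = 9L, y = 9L, z = 5L),
                            min_fit_significance = 5,
                            profile_half_length_px = 7L,
                            bright_mode = "otsu3") {
  if (!(neg_threshold < pos_threshold))
    stopf("neg_threshold (%g) must be < pos_threshold (%g)",
          neg_threshold, pos_threshold)
  if (!(np_min < np_max)) stopf("np_min must be < np_max")
  if (dedupe_radius_px <= 0 || prefilter_nm <= 0 || mask_radius_nm <= 0)
    stopf("all radii must be > 0")
  fit_window_px <- as.integer(fit_window_px)
  if (length(fit_window_px) != 3L || any(fit_window_px < 3L) ||
      any(fit_window_px %% 2L == 0L))
    stopf("fit_window_px must be three odd integers >= 3 in (x, y, z) order")
  names(fit_window_px) <- c("x", "y", "z")
  structure(list(dedupe_radius_px = dedupe_radius_px,
                 np_min = as.integer(np_min), np_max = as.integer(np_max),
                 prefilter_nm = prefilter_nm,
                 mask_radius_nm = mask_radius_nm,
                 pos_threshold = pos_threshold,
                 neg_threshold = neg_threshold,
                 r2_min = r2_min,
                 fit_window_px = fit_window_px,
                 min_fit_significance = min_fit_significance,
                 profile_half_length_px = as.integer(profile_half_length_px),
                 bright_mode = bright_mode),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
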