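# Apparent vesicle size from 1D x-axis intensity line profiles: Gaussian
# fits with an R-squared gate, and a bootstrap CI on the median size.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Extract an x-axis intensity line profile through a vesicle centre
#'
#' Samples raw intensities at voxel x-positions along the voxel row nearest
#' (in y and z) to the sub-pixel vesicle centre, clipped at the volume
#' borders. No sub-pixel interpolation is performed: the profile is the
#' microscope's x-axis sample grid.
#'
#' @param grid a [voxel_grid()].
#' @param centre_nm numeric `(z, y, x)` position, nm.
#' @param half_length_px profile half-length in voxels (default 7, giving up
#'   to 15 samples).
#' @return Data frame with `x_nm` (relative to the centre) and `intensity`.
#' @export
line_profile <- function(grid, centre_nm, half_length_px = 7L) {
  check_analysis_grid(grid)
  dims <- dim(grid$data)
  zc <- centre_nm[1] / grid$voxel_z_nm
  yc <- centre_nm[2] / grid$voxel_xy_nm
  xc <- centre_nm[3] / grid$voxel_xy_nm
  zi <- min(max(round(zc), 0), dims[1] - 1)
  yi <- min(max(round(yc), 0), dims[2] - 1)
  if (xc < 0 || xc > dims[3] - 1) stopf("centre lies outside the volume")
  xs <- max(0, round(xc) - half_length_px):min(dims[3] - 1, round(xc) + half_length_px)
  data.frame(x_nm = xs * grid$voxel_xy_nm - centre_nm[3],
             intensity = grid$data[zi + 1, yi + 1, xs + 1])
}

#' Fit a 1D Gaussian to an intensity line profile
#'
#' Least-squares fit of `amplitude * exp(-(x - mu)^2 / (2 sigma^2)) + offset`;
#' the apparent vesicle size is the fitted standard deviation `sigma`.
#' Goodness of fit is `R^2 = 1 - SS_res / SS_tot` computed on the profile. A
#' degenerate profile (zero variance) returns `r_squared = 0`.
#'
#' @param profile data frame with `x_nm` and `intensity` (>= 5 samples).
#' @return List with `sigma_nm`, `fwhm_nm` (`2 sqrt(2 ln 2) sigma`), `mu_nm`,
#'   `amplitude`, `offset`, `r_squared`.
#' @export
fit_profile <- function(profile) {
  x <- profile$x_nm; y <- profile$intensity
  if (length(x) < 5L) stopf("profile needs >= 5 samples, got %d", length(x))
  if (stats::sd(y) == 0)
    return(list(sigma_nm = NA_real_, fwhm_nm = NA_real_, mu_nm = NA_real_,
                amplitude = NA_real_, offset = mean(y), r_squared = 0))
  off0 <- min(y)
  w <- pmax(y - off0, 0)
  mu0 <- if (sum(w) > 0) sum(w * x) / sum(w) else mean(x)
  s0 <- if (sum(w) > 0) sqrt(sum(w * (x - mu0)^2) / sum(w)) else diff(range(x)) / 4
  s0 <- min(max(s0, 10), diff(range(x)))
  span <- diff(range(x))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(amp = max(y) - off0, mu = mu0, sigma = s0,
                               off = off0),
                       fn = function(th)
                         th[1] * exp(-(x - th[2])^2 / (2 * th[3]^2)) + th[4] - y,
                       lower = c(0, min(x) - span, 1e-3, -Inf),
                       upper = c(Inf, max(x) + span, 4 * span, Inf),
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(sigma_nm = NA_real_, fwhm_nm = NA_real_, mu_nm = NA_real_,
                amplitude = NA_real_, offset = NA_real_, r_squared = 0))
  th <- fit$par
  pred <- th[1] * exp(-(x - th[2])^2 / (2 * th[3]^2)) + th[4]
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(sigma_nm = unname(th[3]), fwhm_nm = unname(FWHM_FACTOR * th[3]),
       mu_nm = unname(th[2]), amplitude = unname(th[1]),
       offset = unname(th[4]), r_squared = max(0, r2))
}

#' Measure apparent vesicle sizes per channel
#'
#' For each vesicle and channel, extracts an x-axis line profile centred at
#' the channel's own fitted position and fits a 1D Gaussian. Fits are
#' accepted only when `r_squared > r2_min` (default 0.75); only accepted fits
#' contribute to size distributions.
#'
#' @param channels list of [voxel_grid()]s.
#' @param spots_raw localized spots (pre-registration) from [localize_cell()].
#' @param config an [analysis_config()].
#' @return Data frame with `vesicle_id`, `channel`, `sigma_nm`, `fwhm_nm`,
#'   `r_squared`, `accepted`.
#' @export
measure_sizes <- function(channels, spots_raw, config = analysis_config()) {
  rows <- lapply(channels, function(g) {
    s <- spots_raw[spots_raw$channel == g$channel, ]
    if (!nrow(s)) return(NULL)
    fits <- lapply(seq_len(nrow(s)), function(i) {
      pr <- line_profile(g, c(s$z_nm[i], s$y_nm[i], s$x_nm[i]),
                         config$profile_half_length_px)
      if (nrow(pr) < 5L)
        return(list(sigma_nm = NA_real_, fwhm_nm = NA_real_, r_squared = 0))
      fit_profile(pr)
    })
    data.frame(vesicle_id = s$vesicle_id, channel = g$channel,
               sigma_nm = vapply(fits, `[[`, 0, "sigma_nm"),
               fwhm_nm = vapply(fits, `[[`, 0, "fwhm_nm"),
               r_squared = vapply(fits, `[[`, 0, "r_squared"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$accepted <- !is.na(out$sigma_nm) & out$r_squared > config$r2_min
  out
}

#' Summarize a vesicle size distribution
#'
#' Median of the accepted sigmas (and of the corresponding FWHMs), with a 95%
#' confidence interval on each median from a seeded bootstrap.
#'
#' @param measurements data frame from [measure_sizes()] (needs `sigma_nm`,
#'   `fwhm_nm`, `accepted`).
#' @param n_boot bootstrap resamples.
#' @param rng_seed integer seed for the bootstrap.
#' @return List with `n_accepted`, `n_rejected`, `median_sigma_nm`,
#'   `ci95_sigma_nm`, `median_fwhm_nm`, `ci95_fwhm_nm`. All statistics are
#'   `NA` when nothing was accepted.
#' @export
size_distribution <- function(measurements, n_boot = 10000L, rng_seed = 1L) {
  acc <- measurements[measurements$accepted, , drop = FALSE]
  n <- nrow(acc)
  if (n == 0L)
    return(list(n_accepted = 0L, n_rejected = nrow(measurements),
                median_sigma_nm = NA_real_, ci95_sigma_nm = c(NA_real_, NA_real_),
                median_fwhm_nm = NA_real_, ci95_fwhm_nm = c(NA_real_, NA_real_)))
  boot_ci <- function(v) {
    if (n == 1L) return(c(v, v))
    meds <- with_seed_if(rng_seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      apply(matrix(v[idx], nrow = n), 2, stats::median)
    })
    unname(stats::quantile(meds, c(0.025, 0.975)))
  }
  list(n_accepted = n, n_rejected = nrow(measurements) - n,
       median_sigma_nm = stats::median(acc$sigma_nm),
       ci95_sigma_nm = boot_ci(acc$sigma_nm),
       median_fwhm_nm = stats::median(acc$fwhm_nm),
       ci95_fwhm_nm = boot_ci(acc$fwhm_nm))
}
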