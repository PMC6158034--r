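# Sub-pixel localization by local 3D Gaussian (mixture) fitting, and
# chromatic registration by making per-channel mean positions coincident.

# Voxels of the local fit window around a 0-based seed index, clipped at the
# borders. Returns 0-based coordinate ranges.
window_ranges <- function(seed, half, dims) {
  list(z = max(0L, seed[1] - half[1]):min(dims[1] - 1L, seed[1] + half[1]),
       y = max(0L, seed[2] - half[2]):min(dims[2] - 1L, seed[2] + half[2]),
       x = max(0L, seed[3] - half[3]):min(dims[3] - 1L, seed[3] + half[3]))
}

# Sum-of-Gaussians + shared constant offset model on scattered voxels.
# theta = c(offset, then per spot: amp, z0, y0, x0, sigma_xy, sigma_z), all
# position/sigma entries in pixel units (z in z-pixels).
mixture_model <- function(theta, zz, yy, xx, k) {
  mod <- rep(theta[1], length(zz))
  for (j in seq_len(k)) {
    p <- theta[2 + (j - 1) * 6 + 0:5]
    mod <- mod + p[1] * exp(-((zz - p[2])^2) / (2 * p[6]^2) -
                              ((yy - p[3])^2 + (xx - p[4])^2) / (2 * p[5]^2))
  }
  mod
}

#' Fit sub-pixel vesicle centres by local 3D Gaussian mixture fitting
#'
#' For each seed, a local window (default 9 x 9 x 5 voxels in x, y, z) is
#' extracted and an anisotropic axis-aligned 3D Gaussian plus a shared
#' constant offset is fitted by bounded Levenberg-Marquardt least squares.
#' Seeds whose windows overlap are fitted jointly as a sum of Gaussians over
#' the union of their windows (the "mixture"). On non-convergence or an
#' all-zero window the intensity-weighted centroid of the window is returned
#' with `converged = FALSE`.
#'
#' @param grid a [voxel_grid()].
#' @param seeds data frame with 0-based voxel columns `z, y, x` (e.g. from
#'   [detect_candidates()]).
#' @param fit_window_px odd window extents `(x, y, z)` in voxels.
#' @param sigma_start_px optional start values `(sigma_xy, sigma_z)` in pixel
#'   units; defaults to `c(1.5, 1.2)`.
#' @param min_significance a fitted component counts as converged only when
#'   its amplitude exceeds `min_significance` times the residual standard
#'   deviation of its window fit; windows holding no real spot (noise only)
#'   then fall back to the intensity-weighted window centroid, which stays
#'   near the seed.
#' @return Data frame, one row per seed: `z_nm, y_nm, x_nm` (sub-pixel
#'   position), `amplitude`, `sigma_xy_nm`, `sigma_z_nm`, `converged`.
#' @export
fit_centres <- function(grid, seeds, fit_window_px = c(x = 9L, y = 9L, z = 5L),
                        sigma_start_px = c(1.5, 1.2), min_significance = 5) {
  check_analysis_grid(grid)
  dims <- dim(grid$data)
  n <- nrow(seeds)
  out <- data.frame(z_nm = rep(NA_real_, n), y_nm = NA_real_, x_nm = NA_real_,
                    amplitude = NA_real_, sigma_xy_nm = NA_real_,
                    sigma_z_nm = NA_real_, converged = FALSE)
  if (!n) return(out)
  half <- c(z = (fit_window_px[["z"]] - 1L) %/% 2L,
            y = (fit_window_px[["y"]] - 1L) %/% 2L,
            x = (fit_window_px[["x"]] - 1L) %/% 2L)
  smat <- cbind(seeds$z, seeds$y, seeds$x)
  if (any(smat < 0) || any(t(smat) >= dims))
    stopf("seed indices must lie inside the volume")

  # group seeds whose windows overlap (boxes of half-width h intersect iff
  # the index difference is <= 2h on every axis)
  if (n > 1L) {
    from <- integer(0); to <- integer(0)
    for (i in 1:(n - 1L)) {
      j <- (i + 1L):n
      hit <- j[abs(smat[j, 1] - smat[i, 1]) <= 2L * half["z"] &
                 abs(smat[j, 2] - smat[i, 2]) <= 2L * half["y"] &
                 abs(smat[j, 3] - smat[i, 3]) <= 2L * half["x"]]
      if (length(hit)) { from <- c(from, rep(i, length(hit))); to <- c(to, hit) }
    }
    g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
    memb <- igraph::components(g)$membership
  } else memb <- 1L

  centroid_fallback <- function(i) {
    w <- window_ranges(smat[i, ], half, dims)
    v <- grid$data[w$z + 1L, w$y + 1L, w$x + 1L, drop = FALSE]
    tot <- sum(v)
    if (tot <= 0) {
      ctr <- smat[i, ]
    } else {
      ctr <- c(sum(apply(v, 1, sum) * w$z), sum(apply(v, 2, sum) * w$y),
               sum(apply(v, 3, sum) * w$x)) / tot
    }
    list(pos = ctr, amp = max(v) - min(v))
  }

  for (grp in split(seq_len(n), memb)) {
    k <- length(grp)
    # union of the member windows as scattered voxels
    vox <- unique(do.call(rbind, lapply(grp, function(i) {
      w <- window_ranges(smat[i, ], half, dims)
      as.matrix(expand.grid(z = w$z, y = w$y, x = w$x))
    })))
    vals <- grid$data[zyx_to_linear(vox[, 1], vox[, 2], vox[, 3], dims)]
    fitted_ok <- FALSE
    if (sum(vals) > 0 && stats::sd(vals) > 0) {
      off0 <- min(vals)
      theta0 <- c(off0)
      lower <- c(0); upper <- c(max(vals))
      for (i in grp) {
        peak <- grid$data[smat[i, 1] + 1L, smat[i, 2] + 1L, smat[i, 3] + 1L]
        theta0 <- c(theta0, max(peak - off0, 1e-6), smat[i, ],
                    sigma_start_px[1], sigma_start_px[2])
        lower <- c(lower, 0, smat[i, ] - (half + 1L), 0.5, 0.5)
        upper <- c(upper, 2 * max(vals), smat[i, ] + (half + 1L), 10, 10)
      }
      zz <- vox[, 1]; yy <- vox[, 2]; xx <- vox[, 3]
      fit <- tryCatch(
        minpack.lm::nls.lm(par = theta0,
                           fn = function(th) mixture_model(th, zz, yy, xx, k) - vals,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-8, ptol = 1e-8, maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$info %in% 1:4) {
        th <- fit$par
        resid_sd <- stats::sd(mixture_model(th, zz, yy, xx, k) - vals)
        for (jj in seq_len(k)) {
          i <- grp[jj]
          p <- th[2 + (jj - 1) * 6 + 0:5]
          if (p[1] > min_significance * resid_sd) {
            out$z_nm[i] <- p[2] * grid$voxel_z_nm
            out$y_nm[i] <- p[3] * grid$voxel_xy_nm
            out$x_nm[i] <- p[4] * grid$voxel_xy_nm
            out$amplitude[i] <- p[1]
            out$sigma_xy_nm[i] <- p[5] * grid$voxel_xy_nm
            out$sigma_z_nm[i] <- p[6] * grid$voxel_z_nm
            out$converged[i] <- TRUE
          }
        }
        fitted_ok <- TRUE
      }
    }
    for (i in grp) {
      if (!out$converged[i]) {
        cb <- centroid_fallback(i)
        out$z_nm[i] <- cb$pos[1] * grid$voxel_z_nm
        out$y_nm[i] <- cb$pos[2] * grid$voxel_xy_nm
        out$x_nm[i] <- cb$pos[3] * grid$voxel_xy_nm
        out$amplitude[i] <- cb$amp
        out$converged[i] <- FALSE
      }
    }
  }
  out
}

#' Localize merged candidates in every channel
#'
#' Runs [fit_centres()] independently in each channel at the shared merged
#' candidate seeds and assembles one long table of localized spots.
#'
#' @param channels list of three [voxel_grid()]s.
#' @param candidates merged candidate data frame with `vesicle_id` (from
#'   [detect_candidates()]).
#' @param config an [analysis_config()].
#' @return Data frame with columns `vesicle_id`, `channel`, `z_nm`, `y_nm`,
#'   `x_nm`, `amplitude`, `sigma_xy_nm`, `sigma_z_nm`, `converged`.
#' @export
localize_cell <- function(channels, candidates, config = analysis_config()) {
  out <- lapply(channels, function(g) {
    f <- fit_centres(g, candidates, config$fit_window_px,
                     min_significance = config$min_fit_significance)
    cbind(data.frame(vesicle_id = candidates$vesicle_id, channel = g$channel,
                     stringsAsFactors = FALSE), f)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove sub-pixel duplicates after localization
#'
#' Candidate-level duplicate removal operates on voxel-rounded detector
#' coordinates, so two candidates of one vesicle can survive it and then
#' converge onto the same sub-pixel centre. This step re-applies the 2-pixel
#' duplicate rule to the refined positions: vesicles are visited in
#' descending summed fit amplitude and absorbed when their mean fitted
#' position (over channels) lies within `dedupe_radius_px` (voxel-index
#' units) of an already-kept vesicle.
#'
#' @param spots localized-spot data frame from [localize_cell()].
#' @param voxel_xy_nm,voxel_z_nm voxel sizes used to convert nm to pixels.
#' @param dedupe_radius_px duplicate radius in voxel-index units.
#' @return `spots` restricted to the surviving vesicle ids.
#' @export
dedupe_localized <- function(spots, voxel_xy_nm, voxel_z_nm,
                             dedupe_radius_px = 2.0) {
  ids <- unique(spots$vesicle_id)
  if (length(ids) < 2L) return(spots)
  pos <- t(vapply(ids, function(id) {
    s <- spots[spots$vesicle_id == id, ]
    c(mean(s$z_nm) / voxel_z_nm, mean(s$y_nm) / voxel_xy_nm,
      mean(s$x_nm) / voxel_xy_nm, sum(s$amplitude, na.rm = TRUE))
  }, numeric(4)))
  ord <- order(-pos[, 4])
  keep <- logical(length(ids))
  kz <- numeric(0); ky <- numeric(0); kx <- numeric(0)
  for (i in ord) {
    if (length(kz)) {
      d2 <- (pos[i, 1] - kz)^2 + (pos[i, 2] - ky)^2 + (pos[i, 3] - kx)^2
      if (any(d2 <= dedupe_radius_px^2)) next
    }
    keep[i] <- TRUE
    kz <- c(kz, pos[i, 1]); ky <- c(ky, pos[i, 2]); kx <- c(kx, pos[i, 3])
  }
  spots[spots$vesicle_id %in% ids[keep], , drop = FALSE]
}

#' Register channels by making mean vesicle positions coincident
#'
#' Chromatic aberration is removed by translating every channel so that its
#' mean 3D vesicle position coincides with the mean of the reference channel.
#' The mean is taken over the vesicles whose fits converged in every channel,
#' so that the (large) spread of vesicle positions across the cell cancels
#' exactly and the correction estimates the pure inter-channel offset. After
#' the call the per-channel means over that set are identical to machine
#' precision; the transform is a pure translation, so within-channel
#' inter-vesicle distances are unchanged.
#'
#' @param spots localized-spot data frame from [localize_cell()].
#' @param reference reference channel label; defaults to the first channel
#'   appearing in `spots`.
#' @return `spots` with translated positions; the per-channel correction
#'   vectors (nm, added to each position) are attached as
#'   `attr(, "correction_nm")` (channels x (z, y, x)).
#' @export
register_channels <- function(spots, reference = NULL) {
  chans <- unique(spots$channel)
  reference <- reference %||% chans[1]
  if (!reference %in% chans) stopf("reference channel '%s' not present", reference)
  conv_ids <- Reduce(intersect, lapply(chans, function(ch)
    spots$vesicle_id[spots$channel == ch & spots$converged]))
  for (ch in chans) {
    if (!any(spots$channel == ch & spots$converged))
      stopf(paste("channel '%s' has no converged localizations;",
                  "relax detection or check the stack"), ch)
  }
  if (!length(conv_ids))
    stopf("no vesicle has converged localizations in every channel; relax detection")
  means <- sapply(chans, function(ch) {
    sel <- spots$channel == ch & spots$vesicle_id %in% conv_ids
    c(mean(spots$z_nm[sel]), mean(spots$y_nm[sel]), mean(spots$x_nm[sel]))
  })
  corr <- means[, reference] - means
  for (ch in chans) {
    sel <- spots$channel == ch
    spots$z_nm[sel] <- spots$z_nm[sel] + corr[1, ch]
    spots$y_nm[sel] <- spots$y_nm[sel] + corr[2, ch]
    spots$x_nm[sel] <- spots$x_nm[sel] + corr[3, ch]
  }
  corr <- t(corr)
  colnames(corr) <- c("z", "y", "x")
  attr(spots, "correction_nm") <- corr
  spots
}
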