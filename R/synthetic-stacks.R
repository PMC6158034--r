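#' Imaging configuration for the synthetic-stack generator
#'
#' Describes the virtual microscope used to render simulated immunolabelled
#' vesicles: volume shape, voxel sizes, an anisotropic Gaussian PSF, a global
#' per-channel chromatic translation, and a Poisson-then-Gaussian noise model.
#' The z-spacing default of 110 nm matches the acquisition the pipeline was
#' built for; the 40 nm lateral default is typical of reconstructed
#' structured-illumination data. Noise defaults model a shot-noise-dominated
#' camera (100 photons per intensity unit, so peak SNR of about 10 for a
#' unit-amplitude vesicle) with a small additive Gaussian read-noise floor.
#'
#' @param shape_voxels integer `(nz, ny, nx)` volume shape.
#' @param voxel_xy_nm,voxel_z_nm voxel sizes, nm.
#' @param psf_sigma_xy_nm,psf_sigma_z_nm PSF Gaussian sigmas, nm.
#' @param chromatic_shift_nm 3x3 numeric matrix: per-channel (rows INSL5, PYY,
#'   GLP1) translation `(z, y, x)` in nm applied when rendering that channel.
#' @param noise_gaussian_sd additive Gaussian noise sd, as a fraction of the
#'   maximum vesicle amplitude.
#' @param noise_poisson_scale photons per intensity unit for the optional shot
#'   noise stage; 0 disables it.
#' @param seed integer; fully determines rendered noise.
#' @return An object of class `imaging_config`.
#' @examples
#' cfg <- imaging_config(shape_voxels = c(8, 32, 32))
#' cfg$voxel_z_nm
#' @export
imaging_config <- function(shape_voxels = c(16L, 128L, 128L),
                           voxel_xy_nm = 40,
                           voxel_z_nm = 110,
                           psf_sigma_xy_nm = 60,
                           psf_sigma_z_nm = 150,
                           chromatic_shift_nm = matrix(0, 3, 3,
                             dimnames = list(CHANNELS, c("z", "y", "x"))),
                           noise_gaussian_sd = 0.01,
                           noise_poisson_scale = 100,
                           seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 1L))
    stopf("shape_voxels must be three positive integers (nz, ny, nx)")
  for (v in c(voxel_xy_nm, voxel_z_nm, psf_sigma_xy_nm, psf_sigma_z_nm))
    if (!is.numeric(v) || v <= 0) stopf("all lengths must be > 0")
  chromatic_shift_nm <- as.matrix(chromatic_shift_nm)
  if (!all(dim(chromatic_shift_nm) == c(3L, 3L)))
    stopf("chromatic_shift_nm must be a 3x3 matrix (channels x (z,y,x))")
  dimnames(chromatic_shift_nm) <- list(CHANNELS, c("z", "y", "x"))
  if (noise_gaussian_sd < 0 || noise_poisson_scale < 0)
    stopf("noise parameters must be >= 0")
  cfg <- structure(list(shape_voxels = shape_voxels,
                        voxel_xy_nm = voxel_xy_nm, voxel_z_nm = voxel_z_nm,
                        psf_sigma_xy_nm = psf_sigma_xy_nm,
                        psf_sigma_z_nm = psf_sigma_z_nm,
                        chromatic_shift_nm = chromatic_shift_nm,
                        noise_gaussian_sd = noise_gaussian_sd,
                        noise_poisson_scale = noise_poisson_scale,
                        seed = as.integer(seed)),
                   class = "imaging_config")
  # a vesicle +-3 sigma (plus the largest chromatic shift) must fit inside
  m <- field_margin_nm(cfg)
  ext <- volume_extent_nm(cfg)
  if (any(ext <= 2 * m))
    stopf("shape too small: a vesicle +-3 sigma does not fit inside the border margin")
  cfg
}

volume_extent_nm <- function(config) {
  s <- config$shape_voxels
  c(z = (s[1] - 1) * config$voxel_z_nm,
    y = (s[2] - 1) * config$voxel_xy_nm,
    x = (s[3] - 1) * config$voxel_xy_nm)
}

field_margin_nm <- function(config) {
  3 * c(z = config$psf_sigma_z_nm, y = config$psf_sigma_xy_nm,
        x = config$psf_sigma_xy_nm) + max(abs(config$chromatic_shift_nm))
}

#' Category mixing proportions for simulated vesicles
#'
#' Convenience constructor spreading a total triple / double / single mass
#' uniformly over the seven label-set categories.
#'
#' @param triple proportion of triple-labelled vesicles.
#' @param double total proportion of double-labelled vesicles (split evenly
#'   over the three pairs).
#' @param single total proportion of single-labelled vesicles (split evenly
#'   over the three peptides).
#' @return Named numeric vector over the seven categories, summing to 1.
#' @examples
#' category_fractions(triple = 0.9)
#' @export
category_fractions <- function(triple = 1, double = 0, single = 0) {
  tot <- triple + double + single
  if (abs(tot - 1) > 1e-9) stopf("fractions must sum to 1 (got %g)", tot)
  c(single_INSL5 = single / 3, single_PYY = single / 3, single_GLP1 = single / 3,
    double_INSL5_PYY = double / 3, double_INSL5_GLP1 = double / 3,
    double_PYY_GLP1 = double / 3, triple = triple)
}

category_labels <- function(category) {
  switch(category,
         single_INSL5 = "INSL5", single_PYY = "PYY", single_GLP1 = "GLP1",
         double_INSL5_PYY = c("INSL5", "PYY"),
         double_INSL5_GLP1 = c("INSL5", "GLP1"),
         double_PYY_GLP1 = c("PYY", "GLP1"),
         triple = CHANNELS,
         stopf("unknown category '%s'", category))
}

#' Sample a ground-truth vesicle field
#'
#' Draws vesicle positions uniformly inside the volume (keeping every vesicle
#' at least 3 PSF sigmas plus the largest chromatic shift away from the
#' border), with a minimum pairwise separation enforced by bounded rejection
#' sampling. Category counts are a single multinomial draw from
#' `category_fractions`; per-channel amplitudes are positive exactly for the
#' labelled channels.
#'
#' @param n_vesicles number of vesicles.
#' @param category_fractions named proportions over the seven label-set
#'   categories (see [category_fractions()]); must sum to 1.
#' @param config an [imaging_config()].
#' @param min_separation_nm minimum pairwise centre distance, nm.
#' @param amplitude mean per-channel amplitude of a labelled channel.
#' @param amplitude_cv lognormal coefficient of variation of amplitudes
#'   (0 gives every labelled channel exactly `amplitude`).
#' @param rng_seed integer seed; fully determines the field.
#' @param max_tries rejection-sampling attempts per vesicle before failing.
#' @return A data frame of class `ground_truth` with one row per vesicle:
#'   `vesicle_id`, `z_nm`, `y_nm`, `x_nm`, `amp_insl5`, `amp_pyy`, `amp_glp1`,
#'   `category`, `label_set`.
#' @examples
#' cfg <- imaging_config(shape_voxels = c(10, 48, 48))
#' gt <- sample_vesicle_field(5, category_fractions(triple = 1), cfg,
#'                            rng_seed = 1)
#' nrow(gt)
#' @export
sample_vesicle_field <- function(n_vesicles,
                                 category_fractions,
                                 config,
                                 min_separation_nm = 400,
                                 amplitude = 1,
                                 amplitude_cv = 0,
                                 rng_seed = 1L,
                                 max_tries = 200L) {
  stopifnot(inherits(config, "imaging_config"), is_count(n_vesicles))
  fr <- category_fractions
  if (is.null(names(fr)) || !all(names(fr) %in% CATEGORY_LEVELS[1:7]))
    stopf("category_fractions must be named over the seven label-set categories")
  if (abs(sum(fr) - 1) > 1e-9) stopf("category fractions must sum to 1")
  if (any(fr < 0)) stopf("category fractions must be >= 0")

  empty <- data.frame(vesicle_id = integer(0), z_nm = numeric(0),
                      y_nm = numeric(0), x_nm = numeric(0),
                      amp_insl5 = numeric(0), amp_pyy = numeric(0),
                      amp_glp1 = numeric(0), category = character(0),
                      label_set = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("ground_truth", "data.frame")
  if (n_vesicles == 0) return(empty)

  m <- field_margin_nm(config)
  ext <- volume_extent_nm(config)
  lo <- m
  hi <- ext - m

  with_seed_if(rng_seed, {
    counts <- as.vector(stats::rmultinom(1, n_vesicles, prob = fr))
    cats <- rep(names(fr), counts)

    pos <- matrix(NA_real_, n_vesicles, 3)
    for (i in seq_len(n_vesicles)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        p <- lo + stats::runif(3) * (hi - lo)
        if (i == 1L) { ok <- TRUE } else {
          d2 <- colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) - p)^2)
          ok <- all(d2 >= min_separation_nm^2)
        }
        if (ok) { pos[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed)
        stopf(paste("could not place vesicle %d of %d with min separation %g nm",
                    "after %d attempts; enlarge the volume or reduce",
                    "n_vesicles/min_separation_nm"),
              i, n_vesicles, min_separation_nm, max_tries)
    }

    amps <- matrix(0, n_vesicles, 3, dimnames = list(NULL, CHANNELS))
    sdlog <- sqrt(log(1 + amplitude_cv^2))
    for (i in seq_len(n_vesicles)) {
      labs <- category_labels(cats[i])
      a <- if (amplitude_cv > 0)
        amplitude * exp(stats::rnorm(length(labs), -sdlog^2 / 2, sdlog))
      else rep(amplitude, length(labs))
      amps[i, labs] <- a
    }

    out <- data.frame(vesicle_id = seq_len(n_vesicles),
                      z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3],
                      amp_insl5 = amps[, "INSL5"], amp_pyy = amps[, "PYY"],
                      amp_glp1 = amps[, "GLP1"],
                      category = cats,
                      label_set = vapply(cats, function(cc)
                        paste(category_labels(cc), collapse = "+"), ""),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("ground_truth", "data.frame")
    out
  })
}

truth_amplitude_matrix <- function(truth) {
  m <- as.matrix(truth[, c("amp_insl5", "amp_pyy", "amp_glp1")])
  colnames(m) <- CHANNELS
  m
}

#' Render a three-channel stack from ground truth
#'
#' Forward model: every vesicle contributes, in each channel it is labelled
#' for, an anisotropic 3D Gaussian (PSF sigmas from the config) centred at its
#' true position plus that channel's chromatic translation. After summation an
#' optional Poisson shot-noise stage and additive Gaussian noise are applied;
#' negative intensities are clipped at zero. The config seed fully determines
#' the noise.
#'
#' @param truth a `ground_truth` data frame from [sample_vesicle_field()].
#' @param config an [imaging_config()].
#' @return An object of class `synthetic_cell`: list with `channels` (three
#'   [voxel_grid()]s in order INSL5, PYY, GLP1), `truth`, and `config`.
#' @examples
#' cfg <- imaging_config(shape_voxels = c(10, 48, 48), noise_gaussian_sd = 0)
#' gt <- sample_vesicle_field(3, category_fractions(triple = 1), cfg,
#'                            rng_seed = 1)
#' cell <- render_stack(gt, cfg)
#' names(cell$channels)
#' @export
render_stack <- function(truth, config) {
  stopifnot(inherits(config, "imaging_config"))
  s <- config$shape_voxels
  amps <- if (nrow(truth)) truth_amplitude_matrix(truth) else
    matrix(0, 0, 3, dimnames = list(NULL, CHANNELS))
  max_amp <- if (nrow(truth)) max(amps) else 1

  zc <- index_to_nm(0:(s[1] - 1), config$voxel_z_nm)
  yc <- index_to_nm(0:(s[2] - 1), config$voxel_xy_nm)
  xc <- index_to_nm(0:(s[3] - 1), config$voxel_xy_nm)
  sz <- config$psf_sigma_z_nm
  sxy <- config$psf_sigma_xy_nm

  channels <- vector("list", 3)
  names(channels) <- CHANNELS

  render_channel <- function(ch) {
    vol <- array(0, dim = s)
    shift <- config$chromatic_shift_nm[ch, ]
    for (i in seq_len(nrow(truth))) {
      a <- amps[i, ch]
      if (a <= 0) next
      ctr <- c(truth$z_nm[i], truth$y_nm[i], truth$x_nm[i]) + shift
      zi <- which(abs(zc - ctr[1]) <= 4 * sz)
      yi <- which(abs(yc - ctr[2]) <= 4 * sxy)
      xi <- which(abs(xc - ctr[3]) <= 4 * sxy)
      if (!length(zi) || !length(yi) || !length(xi)) next
      gz <- exp(-(zc[zi] - ctr[1])^2 / (2 * sz^2))
      gy <- exp(-(yc[yi] - ctr[2])^2 / (2 * sxy^2))
      gx <- exp(-(xc[xi] - ctr[3])^2 / (2 * sxy^2))
      vol[zi, yi, xi] <- vol[zi, yi, xi] +
        a * outer(outer(gz, gy), gx)
    }
    vol
  }

  clean <- lapply(CHANNELS, render_channel)

  noisy <- with_seed_if(config$seed, {
    lapply(clean, function(vol) {
      if (config$noise_poisson_scale > 0) {
        vol <- stats::rpois(length(vol), as.vector(vol) * config$noise_poisson_scale) /
          config$noise_poisson_scale
        vol <- array(vol, dim = s)
      }
      if (config$noise_gaussian_sd > 0) {
        vol <- vol + array(stats::rnorm(length(vol), 0,
                                        config$noise_gaussian_sd * max_amp),
                           dim = s)
      }
      vol[vol < 0] <- 0
      vol
    })
  })

  for (k in 1:3) {
    channels[[k]] <- voxel_grid(noisy[[k]], config$voxel_xy_nm,
                                config$voxel_z_nm, channel = CHANNELS[k])
  }
  structure(list(channels = channels, truth = truth, config = config),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf("<synthetic_cell> %d vesicles, shape (%s), channels %s\n",
              nrow(x$truth), paste(x$config$shape_voxels, collapse = ", "),
              paste(names(x$channels), collapse = "/")))
  invisible(x)
}

#' Simulate one synthetic cell (field + rendering)
#'
#' @inheritParams sample_vesicle_field
#' @param ... passed on to [sample_vesicle_field()].
#' @return A `synthetic_cell` (see [render_stack()]).
#' @export
simulate_cell <- function(n_vesicles, category_fractions, config,
                          rng_seed = 1L, ...) {
  truth <- sample_vesicle_field(n_vesicles, category_fractions, config,
                                rng_seed = rng_seed, ...)
  render_stack(truth, config)
}

#' Simulate a secretion assay table
#'
#' Emulates a multi-condition hormone-secretion experiment on primary
#' cultures: each culture is treated in duplicate wells per condition, and a
#' shared latent stimulus strength drives all three hormones, inducing
#' positive inter-hormone correlation across conditions. Each measured peak
#' area is `protein_mg x well_effect x hormone_scale x lognormal noise`,
#' where `well_effect` is the condition's effect size perturbed by a
#' lognormal well-to-well response factor shared by the three hormones of
#' that well (cells in one well respond coherently). Half of `noise_cv`'s
#' log-variance goes into that shared factor and half into per-hormone
#' measurement noise, so the total per-measurement CV equals `noise_cv`.
#'
#' @param conditions named numeric vector of latent effect sizes (fold over
#'   control); must contain `control_label` with effect 1 recommended.
#' @param n_cultures number of independent cultures.
#' @param noise_cv lognormal coefficient of variation of measurement noise.
#' @param n_replicates wells per culture per condition (duplicates by default).
#' @param hormone_scales per-hormone response scale in peak-area units.
#' @param protein_mg_mean,protein_mg_cv per-well protein content distribution.
#' @param control_label name of the control condition.
#' @param rng_seed integer seed.
#' @return Data frame with columns `culture_id`, `condition`, `replicate`,
#'   `hormone`, `peak_area`, `protein_mg`.
#' @examples
#' tab <- make_secretion_table(c(control = 1, stim = 3), n_cultures = 2,
#'                             noise_cv = 0, rng_seed = 1)
#' head(tab)
#' @export
make_secretion_table <- function(conditions,
                                 n_cultures = 3L,
                                 noise_cv = 0.2,
                                 n_replicates = 2L,
                                 hormone_scales = c(INSL5 = 1, GLP1 = 5, PYY = 3),
                                 protein_mg_mean = 0.5,
                                 protein_mg_cv = 0.1,
                                 control_label = "control",
                                 rng_seed = 1L) {
  if (is.null(names(conditions)) || !(control_label %in% names(conditions)))
    stopf("`conditions` must be named and include the control condition '%s'",
          control_label)
  if (any(conditions < 0)) stopf("effect sizes must be >= 0")
  stopifnot(all(CHANNELS %in% names(hormone_scales)))

  grid <- expand.grid(hormone = CHANNELS,
                      replicate = seq_len(n_replicates),
                      condition = names(conditions),
                      culture_id = paste0("culture", seq_len(n_cultures)),
                      stringsAsFactors = FALSE)
  with_seed_if(rng_seed, {
    wells <- unique(grid[, c("culture_id", "condition", "replicate")])
    sdp <- sqrt(log(1 + protein_mg_cv^2))
    wells$protein_mg <- if (protein_mg_cv > 0)
      protein_mg_mean * exp(stats::rnorm(nrow(wells), -sdp^2 / 2, sdp))
    else rep(protein_mg_mean, nrow(wells))
    sdl <- sqrt(log(1 + noise_cv^2) / 2)  # split: shared well factor + noise
    wells$well_factor <- if (noise_cv > 0)
      exp(stats::rnorm(nrow(wells), -sdl^2 / 2, sdl)) else rep(1, nrow(wells))
    out <- merge(grid, wells, by = c("culture_id", "condition", "replicate"),
                 sort = FALSE)
    noise <- if (noise_cv > 0)
      exp(stats::rnorm(nrow(out), -sdl^2 / 2, sdl)) else rep(1, nrow(out))
    out$peak_area <- out$protein_mg * conditions[out$condition] *
      out$well_factor * hormone_scales[out$hormone] * noise
    out$well_factor <- NULL
    out <- out[order(out$culture_id, out$condition, out$replicate, out$hormone),
               c("culture_id", "condition", "replicate", "hormone",
                 "peak_area", "protein_mg")]
    rownames(out) <- NULL
    out
  })
}
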