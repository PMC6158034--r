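# Independent oracles used across tests. These deliberately re-derive results
# by brute force (loops, closed forms) rather than sharing code with the
# implementation under test.

# 26-connected component labelling by stack-based flood fill over a logical
# 3D mask. Returns an integer array (0 = background).
flood_fill_label <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i0 <- v - 1L
      z <- i0 %% dims[1]; y <- (i0 %/% dims[1]) %% dims[2]
      x <- i0 %/% (dims[1] * dims[2])
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        z2 <- z + dz; y2 <- y + dy; x2 <- x + dx
        if (z2 < 0 || z2 >= dims[1] || y2 < 0 || y2 >= dims[2] ||
            x2 < 0 || x2 >= dims[3]) next
        w <- z2 + dims[1] * (y2 + dims[2] * x2) + 1L
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; stack <- c(stack, w) }
      }
    }
  }
  lab
}

# Mean normalized in-sphere intensity minus background, by an explicit loop
# over every voxel of the volume.
brute_sphere_intensity <- function(grid, centre_nm, radius_nm) {
  d <- dim(grid$data)
  mx <- max(grid$data)
  bg <- mean(grid$data) / mx
  tot <- 0; k <- 0L
  for (z in 0:(d[1] - 1)) for (y in 0:(d[2] - 1)) for (x in 0:(d[3] - 1)) {
    dz <- z * grid$voxel_z_nm - centre_nm[1]
    dy <- y * grid$voxel_xy_nm - centre_nm[2]
    dx <- x * grid$voxel_xy_nm - centre_nm[3]
    if (dz * dz + dy * dy + dx * dx <= radius_nm^2) {
      tot <- tot + grid$data[z + 1, y + 1, x + 1]
      k <- k + 1L
    }
  }
  tot / k / mx - bg
}

# Textbook product-moment correlation.
pearson_formula <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# Closed-form anisotropic 3D Gaussian at a voxel centre.
gauss3d <- function(z_nm, y_nm, x_nm, ctr_nm, amp, sigma_xy, sigma_z) {
  amp * exp(-(z_nm - ctr_nm[1])^2 / (2 * sigma_z^2) -
              ((y_nm - ctr_nm[2])^2 + (x_nm - ctr_nm[3])^2) / (2 * sigma_xy^2))
}

# Ground-truth row constructor for hand-placed vesicles.
manual_truth <- function(z_nm, y_nm, x_nm, amps = c(1, 1, 1)) {
  out <- data.frame(vesicle_id = seq_along(z_nm), z_nm = z_nm, y_nm = y_nm,
                    x_nm = x_nm, amp_insl5 = amps[1], amp_pyy = amps[2],
                    amp_glp1 = amps[3],
                    category = "triple", label_set = "INSL5+PYY+GLP1",
                    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

# Small noiseless imaging config for unit tests.
quiet_config <- function(shape = c(12, 32, 32), ...) {
  imaging_config(shape_voxels = shape, noise_poisson_scale = 0,
                 noise_gaussian_sd = 0, ...)
}

# Default-noise (shot-noise dominated, peak SNR ~10) config.
noisy_config <- function(shape = c(16, 96, 96), seed = 1L, ...) {
  imaging_config(shape_voxels = shape, seed = seed, ...)
}
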