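test_that("constant volumes yield no candidates in either mode", {
  g <- voxel_grid(array(0, c(8, 24, 24)), 40, 110, "INSL5")
  expect_equal(nrow(detect_bright(g)), 0)
  expect_equal(nrow(detect_dim(g)), 0)
  g2 <- voxel_grid(array(0.7, c(8, 24, 24)), 40, 110, "INSL5")
  expect_equal(nrow(detect_bright(g2)), 0)
  expect_equal(nrow(detect_dim(g2)), 0)
})

test_that("bright detection finds isolated spots at their argmax voxel", {
  cfg <- quiet_config(shape = c(12, 48, 48))
  gt <- manual_truth(z_nm = c(6, 5) * 110, y_nm = c(12, 36) * 40,
                     x_nm = c(12, 36) * 40)
  cell <- render_stack(gt, cfg)
  g <- cell$channels$INSL5
  cand <- detect_bright(g)
  expect_equal(nrow(cand), 2)
  # oracle: per-spot argmax in disjoint neighbourhoods
  for (i in 1:2) {
    sub <- g$data
    zs <- round(gt$z_nm[i] / 110); ys <- round(gt$y_nm[i] / 40)
    xs <- round(gt$x_nm[i] / 40)
    hit <- cand[abs(cand$y - ys) < 6 & abs(cand$x - xs) < 6, ]
    expect_equal(nrow(hit), 1)
    expect_equal(c(hit$z, hit$y, hit$x), c(zs, ys, xs))
  }
})

test_that("dim-component size gate is strict at 12 and 250 voxels", {
  # blobs of exactly controlled voxel counts on a zero background: Otsu
  # splits the two-level histogram, so each blob is one positive component
  mk <- function(np_list) {
    arr <- array(0, c(12, 40, 40))
    # fill a 6 x 7 x 7 box row-major: every prefix is 26-connected
    local_box <- as.matrix(expand.grid(dz = 0:5, dy = 0:6, dx = 0:6))
    x0 <- 4
    for (np in np_list) {
      stopifnot(np <= nrow(local_box))
      for (i in seq_len(np)) {
        arr[3 + local_box[i, 1], 10 + local_box[i, 2], x0 + local_box[i, 3]] <- 1
      }
      x0 <- x0 + 12
    }
    voxel_grid(arr, 40, 110, "INSL5")
  }
  expect_equal(nrow(detect_dim(mk(12))), 0)   # np = 12 rejected (strict)
  expect_equal(nrow(detect_dim(mk(13))), 1)   # np = 13 kept
  expect_equal(nrow(detect_dim(mk(250))), 0)  # np = 250 rejected (strict)
  expect_equal(nrow(detect_dim(mk(c(16, 249)))), 2)
})

test_that("dim detection equals a brute-force threshold + flood fill", {
  for (seed in 1:6) {
    arr <- withr::with_seed(seed, {
      a <- array(stats::rexp(32^3, rate = 8), c(32, 32, 32))
      # a few planted blobs of mid size
      for (i in 1:3) {
        z <- sample(4:28, 1); y <- sample(4:28, 1); x <- sample(4:28, 1)
        a[z + (-1:1), y + (-1:1), x + (-1:1)] <- 2 + stats::runif(27)
      }
      a
    })
    g <- voxel_grid(arr, 40, 110, "INSL5")
    cand <- detect_dim(g, np_min = 12, np_max = 250)

    thr <- vesicoloc:::otsu_thresholds(arr, 2)
    lab <- flood_fill_label(arr > thr)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes > 12 & sizes < 250)
    expect_equal(nrow(cand), length(keep))
    # centroids match the flood-fill components
    oracle <- t(vapply(keep, function(k) {
      w <- which(lab == k)
      co <- vesicoloc:::linear_to_zyx(w, dim(arr))
      wt <- arr[w] / sum(arr[w])
      round(c(sum(wt * co[, 1]), sum(wt * co[, 2]), sum(wt * co[, 3])))
    }, numeric(3)))
    got <- cand[order(cand$z, cand$y, cand$x), c("z", "y", "x")]
    ord <- order(oracle[, 1], oracle[, 2], oracle[, 3])
    expect_equal(unname(as.matrix(got)),
                 unname(oracle[ord, , drop = FALSE]))
  }
})

test_that("the histogram threshold maximizes between-class variance", {
  # oracle: exhaustive evaluation of the Otsu objective on a dense
  # threshold grid, straight from the defining formula
  for (seed in 1:3) {
    x <- withr::with_seed(seed,
      pmin(pmax(c(stats::rnorm(5000, 0.2, 0.03),
                  stats::rnorm(500, 0.7, 0.05)), 0), 1))
    cand <- seq(min(x), max(x), length.out = 512)
    bcv <- vapply(cand, function(t) {
      a <- x[x <= t]; b <- x[x > t]
      if (!length(a) || !length(b)) return(-Inf)
      w0 <- length(a) / length(x)
      w0 * (1 - w0) * (mean(a) - mean(b))^2
    }, 0)
    oracle <- cand[which.max(bcv)]
    mine <- vesicoloc:::otsu_thresholds(x, 2)
    expect_lt(abs(mine - oracle), diff(range(x)) / 128)  # within 2 bins
  }
})

test_that("duplicate removal keeps the brighter of a close pair", {
  base <- data.frame(z = c(3L, 3L), y = c(10L, 10L), channel = "INSL5",
                     mode = "bright", np = 20L, stringsAsFactors = FALSE)
  near <- cbind(base, x = c(10L, 12L), peak = c(1.0, 0.6))  # 2 px apart
  m <- merge_candidates(near, dedupe_radius_px = 2, z_ratio = 110 / 40)
  expect_equal(nrow(m), 1)
  expect_equal(m$peak, 1.0)

  apart <- cbind(base, x = c(10L, 13L), peak = c(1.0, 0.6)) # 3 px apart
  m2 <- merge_candidates(apart, dedupe_radius_px = 2, z_ratio = 110 / 40)
  expect_equal(nrow(m2), 2)

  # fractional distances: 1.9 px merged, 2.5 px kept (z scaled by anisotropy)
  zpair <- data.frame(z = c(4L, 5L), y = c(10L, 10L), x = c(10L, 10L),
                      channel = "INSL5", mode = "bright", np = 20L,
                      peak = c(1, 0.9), stringsAsFactors = FALSE)
  # z distance = 110/40 = 2.75 px > 2 -> kept
  expect_equal(nrow(merge_candidates(zpair, 2, z_ratio = 110 / 40)), 2)
  # with isotropic voxels it collapses
  expect_equal(nrow(merge_candidates(zpair, 2, z_ratio = 1)), 1)
})

test_that("merging is idempotent and output is duplicate-free (property)", {
  for (seed in 1:20) {
    cand <- withr::with_seed(seed, data.frame(
      z = sample(0:9, 40, TRUE), y = sample(0:30, 40, TRUE),
      x = sample(0:30, 40, TRUE), channel = "INSL5", mode = "bright",
      peak = stats::runif(40), np = 20L, stringsAsFactors = FALSE))
    m1 <- merge_candidates(cand, 2, z_ratio = 110 / 40)
    m2 <- merge_candidates(m1[, names(cand)], 2, z_ratio = 110 / 40)
    expect_equal(m1[, names(cand)], m2[, names(cand)])
    # all-pairs brute force: no surviving pair within the radius
    if (nrow(m1) > 1) {
      p <- cbind(m1$z * 110 / 40, m1$y, m1$x)
      d <- as.matrix(dist(p)); diag(d) <- Inf
      expect_true(all(d > 2))
    }
  }
})

test_that("every well-separated true vesicle yields a nearby merged candidate", {
  # union property at peak SNR 5 (shot-noise dominated)
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    cfg <- imaging_config(shape_voxels = c(16, 96, 96),
                          noise_poisson_scale = 25, noise_gaussian_sd = 0.01,
                          seed = seed)
    gt <- sample_vesicle_field(30, category_fractions(triple = 1), cfg,
                               rng_seed = seed + 100)
    cell <- render_stack(gt, cfg)
    cand <- detect_candidates(cell$channels)
    for (i in seq_len(nrow(gt))) {
      total <- total + 1L
      d <- sqrt(((cand$z - gt$z_nm[i] / 110) * 110 / 40)^2 +
                  (cand$y - gt$y_nm[i] / 40)^2 + (cand$x - gt$x_nm[i] / 40)^2)
      if (any(d <= 2)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
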