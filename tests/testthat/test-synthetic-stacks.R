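test_that("degenerate mixtures and empty fields behave as stated", {
  cfg <- quiet_config(shape = c(16, 96, 96))
  gt <- sample_vesicle_field(100, category_fractions(triple = 1), cfg,
                             min_separation_nm = 150, rng_seed = 1)
  expect_equal(nrow(gt), 100)
  expect_true(all(gt$label_set == "INSL5+PYY+GLP1"))
  expect_true(all(gt$amp_insl5 > 0 & gt$amp_pyy > 0 & gt$amp_glp1 > 0))

  expect_equal(nrow(sample_vesicle_field(0, category_fractions(triple = 1),
                                         cfg, rng_seed = 1)), 0)
})

test_that("realized category counts are the seeded multinomial draw", {
  cfg <- quiet_config(shape = c(16, 96, 96))
  fr <- c(single_INSL5 = 0.04 / 3, single_PYY = 0.04 / 3, single_GLP1 = 0.04 / 3,
          double_INSL5_PYY = 0.02, double_INSL5_GLP1 = 0.02,
          double_PYY_GLP1 = 0.02, triple = 0.9)
  gt <- sample_vesicle_field(200, fr, cfg, min_separation_nm = 200,
                             rng_seed = 7)
  # independent oracle: the first RNG action under the same seed
  expected <- withr::with_seed(7L, as.vector(stats::rmultinom(1, 200, fr)))
  realized <- as.integer(table(factor(gt$category, levels = names(fr))))
  expect_identical(realized, expected)
})

test_that("fields are deterministic, separated and inside the margin", {
  cfg <- quiet_config(shape = c(12, 48, 48))
  a <- sample_vesicle_field(25, category_fractions(triple = 1), cfg,
                            min_separation_nm = 300, rng_seed = 5)
  b <- sample_vesicle_field(25, category_fractions(triple = 1), cfg,
                            min_separation_nm = 300, rng_seed = 5)
  expect_identical(a, b)
  d <- as.matrix(dist(cbind(a$z_nm, a$y_nm, a$x_nm)))
  diag(d) <- Inf
  expect_true(all(d >= 300))
  ext <- vesicoloc:::volume_extent_nm(cfg)
  m <- vesicoloc:::field_margin_nm(cfg)
  expect_true(all(a$z_nm >= m[1] & a$z_nm <= ext[1] - m[1]))
  expect_true(all(a$x_nm >= m[3] & a$x_nm <= ext[3] - m[3]))
})

test_that("impossible packing fails with a clear message", {
  cfg <- quiet_config(shape = c(10, 28, 28))
  expect_error(
    sample_vesicle_field(500, category_fractions(triple = 1), cfg,
                         min_separation_nm = 400, rng_seed = 1,
                         max_tries = 20),
    "could not place")
})

test_that("rendered spots match the closed-form Gaussian", {
  cfg <- quiet_config()
  gt <- manual_truth(z_nm = 5.4 * 110, y_nm = 15.2 * 40, x_nm = 16.7 * 40)
  cell <- render_stack(gt, cfg)
  ctr <- c(gt$z_nm, gt$y_nm, gt$x_nm)
  for (g in cell$channels) {
    # probe a handful of voxels
    for (probe in list(c(5, 15, 17), c(6, 14, 16), c(5, 16, 18))) {
      expected <- gauss3d(probe[1] * 110, probe[2] * 40, probe[3] * 40, ctr, 1,
                          cfg$psf_sigma_xy_nm, cfg$psf_sigma_z_nm)
      expect_equal(g$data[probe[1] + 1, probe[2] + 1, probe[3] + 1], expected,
                   tolerance = 1e-6)
    }
  }
  # symmetry: same max voxel in all three channels, zero shift
  idx <- lapply(cell$channels, function(g) which.max(g$data))
  expect_true(all(idx[[1]] == unlist(idx)))
})

test_that("rendering an empty field with no noise gives all-zero volumes", {
  cfg <- quiet_config(shape = c(10, 28, 28))
  gt <- sample_vesicle_field(0, category_fractions(triple = 1), cfg, rng_seed = 1)
  cell <- render_stack(gt, cfg)
  for (g in cell$channels) expect_true(all(g$data == 0))
})

test_that("unlabelled channels receive zero signal (noiseless)", {
  cfg <- quiet_config()
  gt <- manual_truth(550, 600, 700, amps = c(1, 0, 0))
  gt$category <- "single_INSL5"; gt$label_set <- "INSL5"
  cell <- render_stack(gt, cfg)
  expect_true(all(cell$channels$PYY$data == 0))
  expect_true(all(cell$channels$GLP1$data == 0))
  expect_gt(max(cell$channels$INSL5$data), 0.9)
})

test_that("noiseless flux is conserved: integral equals the Gaussian norm", {
  cfg <- quiet_config(shape = c(16, 40, 40))
  gt <- manual_truth(z_nm = 8 * 110, y_nm = 20 * 40, x_nm = 19.5 * 40)
  cell <- render_stack(gt, cfg)
  expected <- (2 * pi)^1.5 * cfg$psf_sigma_xy_nm^2 * cfg$psf_sigma_z_nm /
    (cfg$voxel_xy_nm^2 * cfg$voxel_z_nm)
  expect_equal(sum(cell$channels$INSL5$data), expected, tolerance = 0.01)
})

test_that("rendering with a fixed seed is reproducible", {
  cfg <- noisy_config(shape = c(10, 32, 32), seed = 42)
  gt <- manual_truth(550, 640, 640)
  a <- render_stack(gt, cfg)
  b <- render_stack(gt, cfg)
  expect_identical(a$channels$INSL5$data, b$channels$INSL5$data)
  expect_true(all(a$channels$PYY$data >= 0))
})

test_that("noiseless secretion tables give exact fold changes", {
  tab <- make_secretion_table(c(control = 1, stim = 3), n_cultures = 3,
                              noise_cv = 0, rng_seed = 1)
  f <- fold_change(tab)
  expect_equal(f$fold[f$condition == "stim"], rep(3, 18))
  expect_equal(f$fold[f$condition == "control"], rep(1, 18))

  only_ctrl <- make_secretion_table(c(control = 1), n_cultures = 2,
                                    noise_cv = 0, rng_seed = 1)
  f2 <- fold_change(only_ctrl)
  expect_equal(f2$fold, rep(1, nrow(f2)))
})

test_that("a shared latent stimulus gradient induces strong inter-hormone correlation", {
  effects <- c(control = 1, stats::setNames(
    exp(seq(log(1.5), log(30), length.out = 13)), paste0("cond", 1:13)))
  tab <- make_secretion_table(effects, n_cultures = 6, noise_cv = 0.2,
                              rng_seed = 3)
  f <- fold_change(tab)
  for (pair in list(c("INSL5", "GLP1"), c("INSL5", "PYY"), c("PYY", "GLP1"))) {
    r <- hormone_correlation(f, pair)
    # oracle: direct textbook formula on the same matched values
    key <- c("culture_id", "condition", "replicate")
    a <- f[f$hormone == pair[1], c(key, "fold")]
    b <- f[f$hormone == pair[2], c(key, "fold")]
    m <- merge(a, b, by = key)
    expect_equal(r, pearson_formula(m$fold.x, m$fold.y), tolerance = 1e-12)
    expect_gte(r, 0.9)
  }
})
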