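make_spots <- function(pos) {
  # pos: list per channel of c(z, y, x) nm
  do.call(rbind, lapply(names(pos), function(ch) {
    data.frame(vesicle_id = 1L, channel = ch, z_nm = pos[[ch]][1],
               y_nm = pos[[ch]][2], x_nm = pos[[ch]][3], amplitude = 1,
               sigma_xy_nm = 60, sigma_z_nm = 150, converged = TRUE,
               stringsAsFactors = FALSE)
  }))
}

test_that("separation prefilter is strict at 200 nm on all three pairs", {
  near <- make_spots(list(INSL5 = c(0, 0, 0), PYY = c(0, 0, 50),
                          GLP1 = c(0, 60, 0)))  # pairwise 50, 60, ~78 nm
  expect_true(unname(prefilter_by_separation(near, 200)))

  far <- make_spots(list(INSL5 = c(0, 0, 0), PYY = c(0, 0, 210),
                         GLP1 = c(0, 60, 0)))
  expect_false(unname(prefilter_by_separation(far, 200)))

  same <- make_spots(list(INSL5 = c(100, 100, 100), PYY = c(100, 100, 100),
                          GLP1 = c(100, 100, 100)))
  expect_true(unname(prefilter_by_separation(same, 200)))

  # exactly at the bound: strict "<" fails
  at <- make_spots(list(INSL5 = c(0, 0, 0), PYY = c(0, 0, 200),
                        GLP1 = c(0, 0, 100)))
  expect_false(unname(prefilter_by_separation(at, 200)))
})

test_that("a uniform image measures zero intensity everywhere", {
  g <- voxel_grid(array(0.4, c(8, 20, 20)), 40, 110, "INSL5")
  expect_equal(measure_intensity(g, c(4 * 110, 10 * 40, 10 * 40), 150), 0)
  expect_equal(measure_intensity(g, c(3 * 110 + 7, 8 * 40 + 3, 11 * 40), 150), 0)
})

test_that("a single hot voxel measures (1/k) - background", {
  arr <- array(0, c(9, 20, 20))
  arr[5, 10, 10] <- 1
  g <- voxel_grid(arr, 40, 110, "INSL5")
  ctr <- c(4 * 110, 9 * 40, 9 * 40)
  # brute-force count of in-sphere voxel centres
  k <- 0L
  for (z in 0:8) for (y in 0:19) for (x in 0:19) {
    if ((z * 110 - ctr[1])^2 + (y * 40 - ctr[2])^2 + (x * 40 - ctr[3])^2 <= 150^2)
      k <- k + 1L
  }
  bg <- mean(arr)  # max is 1 so normalized == raw
  expect_equal(measure_intensity(g, ctr, 150), 1 / k - bg)
})

test_that("sphere measurement equals the brute-force loop exactly", {
  cfg <- quiet_config(shape = c(10, 24, 24))
  gt <- manual_truth(5.3 * 110, 11.6 * 40, 12.2 * 40)
  cell <- render_stack(gt, cfg)
  g <- cell$channels$GLP1
  for (ctr in list(c(5.3 * 110, 11.6 * 40, 12.2 * 40),
                   c(4 * 110, 10 * 40, 10 * 40),
                   c(5 * 110 + 55, 12 * 40 + 20, 13 * 40))) {
    expect_equal(measure_intensity(g, ctr, 150),
                 brute_sphere_intensity(g, ctr, 150), tolerance = 1e-14)
  }
})

test_that("an empty sphere raises an actionable error", {
  g <- voxel_grid(array(0.5, c(8, 20, 20)), 40, 110, "INSL5")
  expect_error(measure_intensity(g, c(4 * 110 + 55, 10 * 40 + 20, 10 * 40 + 20), 10),
               "larger radius")
})

test_that("vesicle calls follow the 5% / 2% thresholds with a dead band", {
  expect_equal(classify_vesicle(c(INSL5 = 0.06, PYY = 0.06, GLP1 = 0.06))$category,
               "triple")
  expect_equal(classify_vesicle(c(INSL5 = 0.06, PYY = 0.01, GLP1 = 0.01))$category,
               "single_INSL5")
  expect_equal(classify_vesicle(c(INSL5 = 0.03, PYY = 0.06, GLP1 = 0.06))$category,
               "indeterminate")
  expect_equal(classify_vesicle(c(INSL5 = 0.06, PYY = 0.07, GLP1 = 0.004))$category,
               "double_INSL5_PYY")
  expect_equal(classify_vesicle(c(INSL5 = 0.01, PYY = 0.06, GLP1 = 0.06))$category,
               "double_PYY_GLP1")
  # exact threshold equality is indeterminate (strict comparisons)
  expect_equal(unname(classify_vesicle(c(INSL5 = 0.05, PYY = 0.06, GLP1 = 0.06))$calls["INSL5"]),
               "indeterminate")
  expect_equal(unname(classify_vesicle(c(INSL5 = 0.02, PYY = 0.06, GLP1 = 0.06))$calls["INSL5"]),
               "indeterminate")
  # all-negative vesicles are indeterminate, not a category of their own
  expect_equal(classify_vesicle(c(INSL5 = 0.0, PYY = 0.0, GLP1 = 0.0))$category,
               "indeterminate")
})

test_that("raising one channel's intensity never demotes its call", {
  rank_call <- c(negative = 1, indeterminate = 2, positive = 3)
  base <- c(INSL5 = 0.01, PYY = 0.04, GLP1 = 0.2)
  grid <- seq(0, 0.2, by = 0.005)
  prev <- -Inf
  for (v in grid) {
    cur <- rank_call[[classify_vesicle(replace(base, 1, v))$calls["INSL5"]]]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("cell summaries count and percentage correctly", {
  recs <- data.frame(vesicle_id = 1:10,
                     category = c(rep("triple", 9), "single_PYY"),
                     stringsAsFactors = FALSE)
  s <- summarize_cell(recs, "1.02")
  expect_equal(s$pct_triple, 90)
  expect_equal(s$pct_single, 10)
  expect_equal(s$n_prefilter_pass, 10)

  all_exc <- data.frame(vesicle_id = 1:4, category = "excluded",
                        stringsAsFactors = FALSE)
  s2 <- summarize_cell(all_exc)
  expect_equal(s2$n_prefilter_pass, 0)
  expect_true(is.na(s2$pct_triple))

  # recount oracle on random seeded category sets
  cats <- c(vesicoloc:::CATEGORY_LEVELS)
  for (seed in 1:10) {
    cc <- withr::with_seed(seed, sample(cats, 60, replace = TRUE))
    recs <- data.frame(vesicle_id = seq_along(cc), category = cc,
                       stringsAsFactors = FALSE)
    s <- summarize_cell(recs)
    tab <- table(factor(cc, levels = cats))
    expect_equal(s$n_triple, unname(tab["triple"]), ignore_attr = TRUE)
    expect_equal(s$n_single, sum(tab[startsWith(names(tab), "single_")]))
    expect_equal(s$n_double, sum(tab[startsWith(names(tab), "double_")]))
    expect_equal(s$n_detected - s$n_prefilter_pass, unname(tab["excluded"]),
                 ignore_attr = TRUE)
    # partition invariant
    expect_equal(s$n_single + s$n_double + s$n_triple + s$n_indeterminate +
                   (s$n_detected - s$n_prefilter_pass), s$n_detected)
    det <- s$n_single + s$n_double + s$n_triple
    if (det > 0)
      expect_equal(s$pct_single + s$pct_double + s$pct_triple, 100,
                   tolerance = 1e-9)
  }
})

test_that("the pipeline partitions every detection into a category", {
  cfg <- noisy_config(shape = c(16, 96, 96), seed = 12)
  fr <- category_fractions(triple = 0.6, double = 0.2, single = 0.2)
  gt <- sample_vesicle_field(25, fr, cfg, rng_seed = 13)
  cell <- render_stack(gt, cfg)
  res <- analyze_cell(cell)
  s <- res$summary
  expect_equal(s$n_single + s$n_double + s$n_triple + s$n_indeterminate,
               s$n_prefilter_pass)
  expect_equal(s$n_detected, nrow(res$records))
  expect_true(all(res$records$category %in% vesicoloc:::CATEGORY_LEVELS))
  # category 'excluded' iff prefilter failed
  expect_identical(res$records$category == "excluded",
                   !res$records$prefilter_pass)
})

test_that("pooled summaries recompute percentages from pooled counts", {
  a <- summarize_cell(data.frame(vesicle_id = 1:4,
                                 category = c("triple", "triple", "triple",
                                              "single_GLP1")), "1.01")
  b <- summarize_cell(data.frame(vesicle_id = 1:2,
                                 category = c("double_PYY_GLP1", "excluded")),
                      "1.02")
  tab <- summarize_cells(list(a, b))
  expect_equal(nrow(tab), 3)
  all_row <- tab[tab$cell_id == "All", ]
  expect_equal(all_row$n_detected, 6)
  expect_equal(all_row$pct_triple, 100 * 3 / 5)
})
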