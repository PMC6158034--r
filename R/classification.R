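# Inter-channel separation prefilter, normalized background-subtracted
# intensity measurement, per-channel peptide calls, and per-cell summaries.

#' Prefilter vesicles by inter-channel separation
#'
#' A vesicle passes iff the registered positions of its three channel signals
#' are all pairwise closer than `prefilter_nm` (strict `<`; anisotropy is
#' already absorbed by the nm coordinates). Larger separations indicate that a
#' neighbouring vesicle was detected in one of the channels.
#'
#' @param spots registered localized-spot data frame (long format from
#'   [register_channels()]) with all three channels per `vesicle_id`.
#' @param prefilter_nm separation bound, nm.
#' @return Logical vector indexed by unique `vesicle_id` (names = ids).
#' @export
prefilter_by_separation <- function(spots, prefilter_nm = 200) {
  ids <- sort(unique(spots$vesicle_id))
  res <- vapply(ids, function(id) {
    s <- spots[spots$vesicle_id == id, ]
    if (nrow(s) < 2L) return(TRUE)
    p <- cbind(s$z_nm, s$y_nm, s$x_nm)
    d <- stats::dist(p)
    all(d < prefilter_nm)
  }, logical(1))
  names(res) <- ids
  res
}

#' Per-channel normalization constants
#'
#' Normalizes a channel to its maximum intensity voxel (forcing intensities
#' into `[0, 1]`) and measures background as the mean normalized intensity of
#' the full 3D image. Computed once per channel per image and reused for every
#' vesicle measurement.
#'
#' @param grid a [voxel_grid()].
#' @return List with `max` (raw maximum) and `background` (mean of the
#'   normalized volume).
#' @export
channel_normalization <- function(grid) {
  mx <- max(grid$data)
  if (mx <= 0) stopf("channel '%s' has no positive intensity to normalize to",
                     grid$channel)
  list(max = mx, background = mean(grid$data) / mx)
}

#' Measure normalized background-subtracted vesicle intensity
#'
#' Mean normalized intensity over the voxels whose centres lie within
#' `mask_radius_nm` of the vesicle centre (a true physical sphere; anisotropic
#' voxels handled via nm distances), minus the channel background. May be
#' negative.
#'
#' @param grid a [voxel_grid()].
#' @param centre_nm numeric `(z, y, x)` position, nm.
#' @param mask_radius_nm spherical mask radius, nm.
#' @param norm optional precomputed [channel_normalization()] (computed from
#'   `grid` if missing).
#' @return Normalized background-subtracted mean intensity (unitless).
#' @export
measure_intensity <- function(grid, centre_nm, mask_radius_nm = 150,
                              norm = NULL) {
  check_analysis_grid(grid)
  norm <- norm %||% channel_normalization(grid)
  dims <- dim(grid$data)
  vz <- grid$voxel_z_nm; vxy <- grid$voxel_xy_nm
  axis_range <- function(ctr, v, nmax) {
    lo <- max(0, ceiling((ctr - mask_radius_nm) / v))
    hi <- min(nmax - 1, floor((ctr + mask_radius_nm) / v))
    if (lo > hi) integer(0) else lo:hi
  }
  zr <- axis_range(centre_nm[1], vz, dims[1])
  yr <- axis_range(centre_nm[2], vxy, dims[2])
  xr <- axis_range(centre_nm[3], vxy, dims[3])
  if (!length(zr) || !length(yr) || !length(xr))
    stopf("spherical mask of radius %g nm contains no voxel centres; use a larger radius or finer sampling",
          mask_radius_nm)
  gridpts <- expand.grid(z = zr, y = yr, x = xr)
  d2 <- (gridpts$z * vz - centre_nm[1])^2 + (gridpts$y * vxy - centre_nm[2])^2 +
    (gridpts$x * vxy - centre_nm[3])^2
  inside <- d2 <= mask_radius_nm^2
  if (!any(inside))
    stopf("spherical mask of radius %g nm contains no voxel centres; use a larger radius or finer sampling",
          mask_radius_nm)
  idx <- zyx_to_linear(gridpts$z[inside], gridpts$y[inside], gridpts$x[inside],
                       dims)
  mean(grid$data[idx]) / norm$max - norm$background
}

#' Call a vesicle's peptide content from per-channel intensities
#'
#' A channel is called positive if its normalized intensity is strictly above
#' `pos_threshold` (it contains the peptide), negative if strictly below
#' `neg_threshold` (empty), and indeterminate in between or at either
#' threshold exactly. The vesicle category is `triple` iff all three calls are
#' positive; a single or double category requires the remaining channels to be
#' negative; any indeterminate call (outside the all-positive case) makes the
#' vesicle indeterminate.
#'
#' @param intensities named numeric vector over `INSL5, PYY, GLP1`.
#' @param pos_threshold,neg_threshold classification thresholds on the
#'   normalized intensity scale.
#' @return List with `calls` (named character vector, values `positive`,
#'   `negative`, `indeterminate`) and `category`.
#' @examples
#' classify_vesicle(c(INSL5 = 0.06, PYY = 0.06, GLP1 = 0.06))$category
#' classify_vesicle(c(INSL5 = 0.06, PYY = 0.01, GLP1 = 0.01))$category
#' @export
classify_vesicle <- function(intensities, pos_threshold = 0.05,
                             neg_threshold = 0.02) {
  if (!(neg_threshold < pos_threshold))
    stopf("neg_threshold must be < pos_threshold")
  stopifnot(all(CHANNELS %in% names(intensities)))
  v <- intensities[CHANNELS]
  calls <- ifelse(v > pos_threshold, "positive",
                  ifelse(v < neg_threshold, "negative", "indeterminate"))
  names(calls) <- CHANNELS
  pos <- names(calls)[calls == "positive"]
  neg <- names(calls)[calls == "negative"]
  category <- if (length(pos) == 3L) {
    "triple"
  } else if (any(calls == "indeterminate")) {
    "indeterminate"
  } else if (length(pos) == 2L) {
    paste0("double_", paste(CHANNELS[CHANNELS %in% pos], collapse = "_"))
  } else if (length(pos) == 1L) {
    paste0("single_", pos)
  } else {
    "indeterminate"
  }
  list(calls = calls, category = category)
}

#' Build per-vesicle records from registered spots
#'
#' Applies the separation prefilter on registered positions, measures each
#' channel's normalized background-subtracted intensity with a spherical mask
#' centred at that channel's own fitted (pre-registration) position, and calls
#' each vesicle's peptide content. Vesicles failing the prefilter are
#' categorized `excluded` and receive no calls.
#'
#' @param channels list of three [voxel_grid()]s (INSL5, PYY, GLP1).
#' @param spots_registered registered spots (long format) from
#'   [register_channels()].
#' @param spots_raw the same spots before registration (from
#'   [localize_cell()]); defaults to `spots_registered` if the raw positions
#'   are not available.
#' @param config an [analysis_config()].
#' @return Data frame of class `vesicle_records`, one row per vesicle:
#'   per-channel registered positions (`z_nm_insl5`, ...), per-channel
#'   normalized intensities (`int_insl5`, ...), per-channel calls,
#'   `prefilter_pass`, `category`.
#' @export
classify_cell <- function(channels, spots_registered, spots_raw = NULL,
                          config = analysis_config()) {
  spots_raw <- spots_raw %||% spots_registered
  norms <- lapply(channels, channel_normalization)
  pass <- prefilter_by_separation(spots_registered, config$prefilter_nm)
  ids <- as.integer(names(pass))

  chan_key <- c(INSL5 = "insl5", PYY = "pyy", GLP1 = "glp1")
  rows <- lapply(seq_along(ids), function(ii) {
    id <- ids[ii]
    rec <- list(vesicle_id = id)
    sreg <- spots_registered[spots_registered$vesicle_id == id, ]
    sraw <- spots_raw[spots_raw$vesicle_id == id, ]
    ints <- c(INSL5 = NA_real_, PYY = NA_real_, GLP1 = NA_real_)
    for (k in seq_along(channels)) {
      ch <- channels[[k]]$channel
      key <- chan_key[[ch]]
      rr <- sreg[sreg$channel == ch, ]
      rec[[paste0("z_nm_", key)]] <- rr$z_nm
      rec[[paste0("y_nm_", key)]] <- rr$y_nm
      rec[[paste0("x_nm_", key)]] <- rr$x_nm
      raw <- sraw[sraw$channel == ch, ]
      ints[ch] <- measure_intensity(channels[[k]],
                                    c(raw$z_nm, raw$y_nm, raw$x_nm),
                                    config$mask_radius_nm, norm = norms[[k]])
      rec[[paste0("int_", key)]] <- ints[[ch]]
    }
    if (pass[ii]) {
      cl <- classify_vesicle(ints, config$pos_threshold, config$neg_threshold)
      for (ch in CHANNELS) rec[[paste0("call_", chan_key[[ch]])]] <- cl$calls[[ch]]
      rec$prefilter_pass <- TRUE
      rec$category <- cl$category
    } else {
      for (ch in CHANNELS) rec[[paste0("call_", chan_key[[ch]])]] <- NA_character_
      rec$prefilter_pass <- FALSE
      rec$category <- "excluded"
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(vesicle_id = integer(0))
  }
  rownames(out) <- NULL
  class(out) <- c("vesicle_records", "data.frame")
  out
}

#' Summarize vesicle categories for one cell
#'
#' Counts detected, prefilter-passing, single, double, triple and
#' indeterminate vesicles, and reports category percentages over the
#' determinate prefilter-passing vesicles (the denominator excludes
#' indeterminate vesicles). With zero determinate vesicles the percentages
#' are `NA` while the counts are still emitted.
#'
#' @param records a `vesicle_records` data frame from [classify_cell()].
#' @param cell_id label for the cell (the conventional format is
#'   `experiment.cell`, e.g. `"1.01"`).
#' @return An object of class `cell_summary` (a one-row data frame) with
#'   counts `n_detected`, `n_prefilter_pass`, `n_single`, `n_double`,
#'   `n_triple`, `n_indeterminate` and percentages `pct_single`, `pct_double`,
#'   `pct_triple`.
#' @export
summarize_cell <- function(records, cell_id = "1.01") {
  cat_of <- records$category
  n_detected <- nrow(records)
  n_excluded <- sum(cat_of == "excluded")
  n_single <- sum(startsWith(cat_of, "single_"))
  n_double <- sum(startsWith(cat_of, "double_"))
  n_triple <- sum(cat_of == "triple")
  n_indet <- sum(cat_of == "indeterminate")
  n_pass <- n_detected - n_excluded
  n_det <- n_single + n_double + n_triple
  pct <- function(k) if (n_det > 0) 100 * k / n_det else NA_real_
  out <- data.frame(cell_id = cell_id, n_detected = n_detected,
                    n_prefilter_pass = n_pass, n_single = n_single,
                    n_double = n_double, n_triple = n_triple,
                    n_indeterminate = n_indet,
                    pct_single = pct(n_single), pct_double = pct(n_double),
                    pct_triple = pct(n_triple), stringsAsFactors = FALSE)
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Aggregate many cell summaries into one table
#'
#' One row per cell plus a pooled `"All"` row whose counts are the column
#' sums and whose percentages are recomputed from the pooled counts.
#'
#' @param summaries list of `cell_summary` objects.
#' @return Data frame in the same layout.
#' @export
summarize_cells <- function(summaries) {
  tab <- do.call(rbind, lapply(summaries, as.data.frame))
  pooled <- data.frame(cell_id = "All",
                       n_detected = sum(tab$n_detected),
                       n_prefilter_pass = sum(tab$n_prefilter_pass),
                       n_single = sum(tab$n_single),
                       n_double = sum(tab$n_double),
                       n_triple = sum(tab$n_triple),
                       n_indeterminate = sum(tab$n_indeterminate),
                       stringsAsFactors = FALSE)
  n_det <- pooled$n_single + pooled$n_double + pooled$n_triple
  pooled$pct_single <- if (n_det > 0) 100 * pooled$n_single / n_det else NA_real_
  pooled$pct_double <- if (n_det > 0) 100 * pooled$n_double / n_det else NA_real_
  pooled$pct_triple <- if (n_det > 0) 100 * pooled$n_triple / n_det else NA_real_
  out <- rbind(tab, pooled)
  rownames(out) <- NULL
  out
}

#' Run the full per-cell co-localization pipeline
#'
#' Detection (both modes, all channels) -> cross-channel duplicate removal ->
#' per-channel sub-pixel localization -> chromatic registration -> separation
#' prefilter -> intensity classification -> per-cell summary.
#'
#' @param channels list of three [voxel_grid()]s in order INSL5, PYY, GLP1,
#'   or a `synthetic_cell`.
#' @param config an [analysis_config()].
#' @param cell_id label used in the summary.
#' @return List with `records` (per-vesicle), `summary` (per-cell),
#'   `candidates`, `spots_raw`, `spots` (registered) and the chromatic
#'   `correction_nm` matrix.
#' @export
analyze_cell <- function(channels, config = analysis_config(),
                         cell_id = "1.01") {
  if (inherits(channels, "synthetic_cell")) channels <- channels$channels
  if (length(channels) != 3L)
    stopf("expected 3 channels for the co-localization pipeline, got %d",
          length(channels))
  cand <- detect_candidates(channels, config)
  spots_raw <- localize_cell(channels, cand, config)
  spots_raw <- dedupe_localized(spots_raw, channels[[1]]$voxel_xy_nm,
                                channels[[1]]$voxel_z_nm,
                                config$dedupe_radius_px)
  spots <- register_channels(spots_raw)
  records <- classify_cell(channels, spots, spots_raw, config)
  summary <- summarize_cell(records, cell_id)
  list(records = records, summary = summary, candidates = cand,
       spots_raw = spots_raw, spots = spots,
       correction_nm = attr(spots, "correction_nm"))
}
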