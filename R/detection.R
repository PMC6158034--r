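# Candidate detection: histogram-split bright spots, Otsu-thresholded dim
# spots with a component-size gate, and cross-channel duplicate removal.

# Otsu thresholding on a 256-bin histogram. n_classes = 2 returns one
# threshold, n_classes = 3 returns the two class boundaries (between-class
# variance maximized over all boundary pairs). Returns NULL for a constant
# image. Thresholds are bin upper edges in intensity units.
otsu_thresholds <- function(x, n_classes = 2L, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(NULL)
  b <- pmin(floor((x - rng[1]) / diff(rng) * levels) + 1L, levels)
  counts <- tabulate(b, nbins = levels)
  p <- counts / sum(counts)
  mids <- seq_len(levels)
  cp <- cumsum(p)
  cm <- cumsum(p * mids)
  muT <- cm[levels]
  edge <- function(t) rng[1] + t / levels * diff(rng)

  if (n_classes == 2L) {
    w0 <- cp[-levels]
    w1 <- 1 - w0
    mu0 <- cm[-levels] / w0
    mu1 <- (muT - cm[-levels]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    bcv[!is.finite(bcv)] <- -Inf
    return(edge(which.max(bcv)))
  }
  if (n_classes != 3L) stopf("n_classes must be 2 or 3")

  best <- -Inf; best_t <- c(NA_integer_, NA_integer_)
  for (t1 in 1:(levels - 2L)) {
    w0 <- cp[t1]
    if (w0 <= 0) next
    m0 <- cm[t1] / w0
    for (t2 in (t1 + 1L):(levels - 1L)) {
      w1 <- cp[t2] - cp[t1]
      w2 <- 1 - cp[t2]
      if (w1 <= 0 || w2 <= 0) next
      m1 <- (cm[t2] - cm[t1]) / w1
      m2 <- (muT - cm[t2]) / w2
      v <- w0 * (m0 - muT)^2 + w1 * (m1 - muT)^2 + w2 * (m2 - muT)^2
      if (v > best) { best <- v; best_t <- c(t1, t2) }
    }
  }
  if (!is.finite(best)) return(NULL)
  edge(best_t)
}

# 26-connected component labelling of the voxels at 1-based linear indices
# `idx` (sorted) in a volume of dim `dims`. Returns an integer membership
# vector parallel to `idx`.
label_components_26 <- function(idx, dims) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  co <- linear_to_zyx(idx, dims)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  # keep strictly "positive" half to emit each undirected edge once
  keep <- offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    z2 <- co[, "z"] + offs[k, 1]
    y2 <- co[, "y"] + offs[k, 2]
    x2 <- co[, "x"] + offs[k, 3]
    ok <- z2 >= 0L & z2 < dims[1L] & y2 >= 0L & y2 < dims[2L] &
      x2 >= 0L & x2 < dims[3L]
    if (!any(ok)) next
    nb <- zyx_to_linear(z2[ok], y2[ok], x2[ok], dims)
    m <- match(nb, idx)
    hit <- !is.na(m)
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, m[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

component_candidates <- function(grid, mask_idx, mode) {
  dims <- dim(grid$data)
  memb <- label_components_26(mask_idx, dims)
  empty <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      channel = character(0), mode = character(0),
                      peak = numeric(0), np = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(memb)) return(empty)
  co <- linear_to_zyx(mask_idx, dims)
  vals <- grid$data[mask_idx]
  sp <- split(seq_along(memb), memb)
  out <- lapply(sp, function(ii) {
    w <- vals[ii] / sum(vals[ii])  # intensity-weighted component centroid
    data.frame(z = as.integer(round(sum(w * co[ii, "z"]))),
               y = as.integer(round(sum(w * co[ii, "y"]))),
               x = as.integer(round(sum(w * co[ii, "x"]))),
               channel = grid$channel, mode = mode,
               peak = max(vals[ii]), np = length(ii),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect bright vesicle candidates by histogram splitting
#'
#' Splits the channel's intensity histogram into three classes (three-class
#' Otsu); voxels in the top class are "bright". Candidates are the
#' intensity-weighted centroids (rounded to the nearest voxel) of the
#' 26-connected components of the bright voxel set.
#'
#' @param grid a [voxel_grid()].
#' @return Data frame of candidate spots: 0-based voxel indices `z, y, x`,
#'   `channel`, `mode = "bright"`, component `peak` intensity and voxel count
#'   `np`. Empty for a constant image (no split possible).
#' @export
detect_bright <- function(grid) {
  check_analysis_grid(grid)
  thr <- otsu_thresholds(grid$data, n_classes = 3L)
  if (is.null(thr)) return(component_candidates(grid, integer(0), "bright"))
  idx <- which(grid$data > thr[2])
  component_candidates(grid, idx, "bright")
}

#' Detect dim vesicle candidates by Otsu thresholding with a size gate
#'
#' Binarizes the volume with a (two-class) Otsu threshold on the full 3D
#' intensity histogram, labels 26-connected positive components, and keeps
#' only components whose voxel count np satisfies `np_min < np < np_max`
#' (strict at both ends; defaults 12 and 250). Candidates are
#' intensity-weighted component centroids rounded to the nearest voxel.
#'
#' @param grid a [voxel_grid()].
#' @param np_min,np_max strict component-size bounds in voxels.
#' @return Data frame of candidate spots as in [detect_bright()], with
#'   `mode = "dim"`.
#' @export
detect_dim <- function(grid, np_min = 12L, np_max = 250L) {
  check_analysis_grid(grid)
  if (!(np_min < np_max)) stopf("np_min must be < np_max")
  thr <- otsu_thresholds(grid$data, n_classes = 2L)
  if (is.null(thr)) return(component_candidates(grid, integer(0), "dim"))
  idx <- which(grid$data > thr)
  cand <- component_candidates(grid, idx, "dim")
  cand[cand$np > np_min & cand$np < np_max, , drop = FALSE]
}

#' Merge candidate spots across channels, removing duplicates
#'
#' Greedy brighter-wins merge: candidates are visited in descending peak
#' intensity and absorbed by an already-kept candidate whenever their distance
#' is at most `dedupe_radius_px`. Distance is Euclidean in voxel-index units
#' (one z-plane counts as one pixel, matching the "within 2 pixels" duplicate
#' rule on the detector grid); `z_ratio` can rescale z index differences if an
#' anisotropy-corrected rule is wanted. The output is duplicate-free under
#' the same rule.
#'
#' @param candidates data frame of candidate spots (rows from
#'   [detect_bright()] / [detect_dim()], possibly from several channels, all
#'   sharing one voxel geometry).
#' @param dedupe_radius_px duplicate radius, pixel units ("within" = `<=`).
#' @param z_ratio scale applied to z index differences (default 1: plain
#'   voxel-index distance).
#' @return The surviving candidate rows with a `vesicle_id` column, ordered by
#'   descending peak intensity.
#' @export
merge_candidates <- function(candidates, dedupe_radius_px = 2.0, z_ratio = 1) {
  if (!nrow(candidates)) {
    candidates$vesicle_id <- integer(0)
    return(candidates)
  }
  ord <- order(-candidates$peak, candidates$z, candidates$y, candidates$x)
  cand <- candidates[ord, , drop = FALSE]
  kz <- numeric(0); ky <- numeric(0); kx <- numeric(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (length(kz)) {
      d2 <- ((cand$z[i] - kz) * z_ratio)^2 + (cand$y[i] - ky)^2 +
        (cand$x[i] - kx)^2
      if (any(d2 <= dedupe_radius_px^2)) next
    }
    keep[i] <- TRUE
    kz <- c(kz, cand$z[i]); ky <- c(ky, cand$y[i]); kx <- c(kx, cand$x[i])
  }
  out <- cand[keep, , drop = FALSE]
  out$vesicle_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect and merge vesicle candidates across all three channels
#'
#' Runs both detection modes on every channel and merges the pooled candidate
#' list with [merge_candidates()].
#'
#' @param channels list of three [voxel_grid()]s (INSL5, PYY, GLP1).
#' @param config an [analysis_config()].
#' @return Merged candidate data frame with `vesicle_id`.
#' @export
detect_candidates <- function(channels, config = analysis_config()) {
  stopifnot(length(channels) >= 1L)
  cands <- do.call(rbind, lapply(channels, function(g) {
    rbind(detect_bright(g), detect_dim(g, config$np_min, config$np_max))
  }))
  merge_candidates(cands, config$dedupe_radius_px)
}
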