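# Assay statistics: protein-normalized secretion fold changes, Dunn post-hoc
# tests vs control, inter-hormone Pearson correlations, qPCR relative
# expression (2^dCT) with ratio paired t-tests, and calcium fold responses
# with a Wilcoxon signed-rank cohort test.

#' Secretion fold changes relative to same-culture controls
#'
#' Peak areas are first normalized by the well's protein content, then each
#' replicate is divided by the mean of that culture's protein-normalized
#' control replicates (matched by hormone). Control replicates' own folds
#' therefore average 1 within each culture, and the result is invariant to
#' rescaling any culture's peak areas.
#'
#' @param records data frame with columns `culture_id`, `condition`,
#'   `replicate`, `hormone`, `peak_area`, `protein_mg` (see
#'   [make_secretion_table()]).
#' @param control_label label of the control condition.
#' @return `records` with additional column `fold`.
#' @export
fold_change <- function(records, control_label = "control") {
  need <- c("culture_id", "condition", "hormone", "peak_area", "protein_mg")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  if (any(records$protein_mg <= 0)) stopf("protein_mg must be > 0")
  rel <- records$peak_area / records$protein_mg
  key <- interaction(records$culture_id, records$hormone, drop = TRUE)
  ctrl <- records$condition == control_label
  fold <- rep(NA_real_, nrow(records))
  for (k in levels(key)) {
    sel <- key == k
    cm <- mean(rel[sel & ctrl])
    if (!length(rel[sel & ctrl]) || !is.finite(cm) || cm == 0)
      stopf("culture/hormone group '%s' has no usable control replicates", k)
    fold[sel] <- rel[sel] / cm
  }
  records$fold <- fold
  records
}

#' Dunn post-hoc comparisons of each condition against control
#'
#' Pools all values into one Kruskal-Wallis ranking and computes, for every
#' non-control condition, Dunn's z statistic against the control group using
#' the tie-corrected rank variance
#' `(N(N+1)/12 - sum(t^3 - t) / (12(N-1))) (1/n_i + 1/n_c)`. Two-sided normal
#' p-values are adjusted across comparisons (Holm by default).
#'
#' @param values numeric response values (e.g. secretion folds).
#' @param conditions condition label per value; must include `control_label`.
#' @param control_label the reference condition.
#' @param p_adjust multiplicity adjustment: `"holm"`, `"bonferroni"` or
#'   `"none"`.
#' @return Data frame with one row per non-control condition: `condition`,
#'   `n`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_vs_control <- function(values, conditions, control_label = "control",
                            p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  conditions <- as.character(conditions)
  if (!control_label %in% conditions)
    stopf("control condition '%s' absent from data", control_label)
  groups <- unique(conditions)
  if (length(groups) < 2L) stopf("need >= 2 conditions including control")
  ns <- table(conditions)
  if (any(ns < 3L))
    stopf("every condition needs >= 3 values (smallest has %d)", min(ns))
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  ties <- as.numeric(tie_tab[tie_tab > 1])
  tie_corr <- if (length(ties)) sum(ties^3 - ties) / (12 * (N - 1)) else 0
  var_unit <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(r, conditions, mean)
  others <- setdiff(groups, control_label)
  nc <- ns[[control_label]]
  z <- vapply(others, function(g) {
    v <- var_unit * (1 / ns[[g]] + 1 / nc)
    if (v <= 0) return(0)
    (mean_rank[[g]] - mean_rank[[control_label]]) / sqrt(v)
  }, 0)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(condition = others, n = as.integer(ns[others]), z = z,
                    p_value = p,
                    p_adjusted = stats::p.adjust(p, method = p_adjust),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two hormones' secretion responses
#'
#' Standard product-moment correlation between matched fold changes of two
#' hormones (pairing by culture x condition x replicate). Computed on
#' untransformed folds by default; `log = TRUE` correlates log folds.
#'
#' @param folds data frame with `fold` values and a `hormone` column (output
#'   of [fold_change()]), or `NULL` when `x` and `y` are given directly.
#' @param hormones length-2 character vector naming the pair.
#' @param x,y alternatively, two matched numeric vectors.
#' @param log correlate natural-log folds instead.
#' @return Pearson R (scalar); `NA` if either side has zero variance.
#' @export
hormone_correlation <- function(folds = NULL, hormones = c("INSL5", "GLP1"),
                                x = NULL, y = NULL, log = FALSE) {
  if (is.null(x) || is.null(y)) {
    stopifnot(is.data.frame(folds), length(hormones) == 2L)
    key <- c("culture_id", "condition", "replicate")
    a <- folds[folds$hormone == hormones[1], c(key, "fold")]
    b <- folds[folds$hormone == hormones[2], c(key, "fold")]
    m <- merge(a, b, by = key)
    x <- m$fold.x; y <- m$fold.y
  }
  if (length(x) < 3L) stopf("need >= 3 paired values")
  if (log) { x <- base::log(x); y <- base::log(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Relative gene expression (2^dCT) with a ratio paired t-test
#'
#' dCT is the housekeeper CT minus the gene-of-interest CT; relative
#' expression is `2^dCT`. Undetermined CT values (`NA`) are substituted with
#' 40 (the maximum cycle number) before the difference. The ratio paired
#' t-test between the two groups is realized as a paired t-test on the
#' natural-log expressions of samples paired by `sample_id`.
#'
#' @param records data frame with columns `sample_id`, `group` (two levels),
#'   `gene`, `ct`, `housekeeper_ct`. `ct` may contain `NA` for undetermined.
#' @param groups length-2 character vector ordering the groups (fold =
#'   first / second); defaults to the two levels in data order.
#' @return List with `expression` (per-sample table with `dct` and
#'   `rel_expr`) and `tests` (per-gene data frame: group means, mean ratio,
#'   `p_value`).
#' @export
relative_expression <- function(records, groups = NULL) {
  need <- c("sample_id", "group", "gene", "ct", "housekeeper_ct")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  groups <- groups %||% unique(as.character(records$group))
  if (length(groups) != 2L) stopf("exactly two groups are required")
  ct <- ifelse(is.na(records$ct), 40, records$ct)
  if (any(ct <= 0 | ct > 40)) stopf("CT values must lie in (0, 40]")
  records$dct <- records$housekeeper_ct - ct
  records$rel_expr <- 2^records$dct

  tests <- lapply(unique(records$gene), function(g) {
    a <- records[records$gene == g & records$group == groups[1], ]
    b <- records[records$gene == g & records$group == groups[2], ]
    m <- merge(a[, c("sample_id", "rel_expr")], b[, c("sample_id", "rel_expr")],
               by = "sample_id")
    if (nrow(m) < nrow(a) || nrow(m) < nrow(b))
      stopf("gene '%s': samples are not fully paired across groups", g)
    d <- base::log(m$rel_expr.x) - base::log(m$rel_expr.y)
    p <- if (nrow(m) < 2L) NA_real_
    else if (stats::sd(d) < 1e-12) 1 else stats::t.test(d)$p.value
    data.frame(gene = g, n_pairs = nrow(m),
               mean_expr_1 = mean(m$rel_expr.x), mean_expr_2 = mean(m$rel_expr.y),
               mean_log_ratio = mean(d), p_value = p, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(expression = records, tests = tests)
}

#' Calcium fold response of one cell to a drug application
#'
#' Fold change = maximum fluorescence during the application window divided
#' by the mean of the maxima over the 30 s immediately before application and
#' the 30 s immediately after washout.
#'
#' @param times sample times, seconds.
#' @param fluorescence background-subtracted fluorescence trace.
#' @param application_window numeric `(start, end)` of drug application, s.
#' @param washout_time time at which washout is complete, s.
#' @param baseline_s length of the pre/post windows, s.
#' @return Fold change (scalar); `NA` with a warning on a zero denominator.
#' @export
ca_response <- function(times, fluorescence, application_window,
                        washout_time, baseline_s = 30) {
  stopifnot(length(times) == length(fluorescence),
            length(application_window) == 2L)
  in_app <- times >= application_window[1] & times <= application_window[2]
  in_pre <- times >= application_window[1] - baseline_s &
    times < application_window[1]
  in_post <- times >= washout_time & times <= washout_time + baseline_s
  if (!any(in_app) || !any(in_pre) || !any(in_post))
    stopf("application, pre and post windows must each contain >= 1 sample")
  denom <- mean(c(max(fluorescence[in_pre]), max(fluorescence[in_post])))
  if (denom == 0) {
    warning("zero baseline fluorescence; fold response undefined")
    return(NA_real_)
  }
  max(fluorescence[in_app]) / denom
}

#' Cohort-level test of calcium fold responses against 1
#'
#' Two-sided Wilcoxon signed-rank test of the observed fold changes against 1
#' (no change). With no nonzero differences (all folds exactly 1) the result
#' is reported as non-significant with `p = 1`.
#'
#' @param folds numeric vector of per-cell fold responses.
#' @return List with `n`, `median_fold`, `p_value`, `significant` (at 0.05).
#' @export
ca_cohort_test <- function(folds) {
  folds <- folds[is.finite(folds)]
  if (!length(folds)) stopf("no finite fold responses")
  if (all(folds == 1)) {
    return(list(n = length(folds), median_fold = 1, p_value = 1,
                significant = FALSE))
  }
  p <- suppressWarnings(stats::wilcox.test(folds, mu = 1)$p.value)
  list(n = length(folds), median_fold = stats::median(folds), p_value = p,
       significant = is.finite(p) && p < 0.05)
}

#' Exclude non-responding cells by positive-control response
#'
#' A cell is kept iff its fold response to at least one positive control
#' exceeds `cutoff`.
#'
#' @param control_folds numeric matrix or data frame, one row per cell, one
#'   column per positive control.
#' @param cutoff responder threshold on the fold response.
#' @return Logical vector, `TRUE` for responders.
#' @export
responder_filter <- function(control_folds, cutoff = 1.1) {
  m <- as.matrix(control_folds)
  apply(m, 1, function(r) any(r > cutoff, na.rm = TRUE))
}
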