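#' Binarize SAV classes into presence/absence
#'
#' Classes 2-3 become presence (1), class 1 absence (0); missing cells
#' stay missing.
#'
#' @param classgrid A class grid from [classify_light()] /
#'   [classify_biovolume()], or an integer vector of classes.
#' @return A grid with a `presence` layer, or an integer vector of 0/1.
#' @export
binarize <- function(classgrid) {
  to_presence <- function(cls) {
    if (any(!is.na(cls) & !(cls %in% 1:3))) {
      stop_domain("Classes must be 1, 2 or 3.")
    }
    ifelse(is.na(cls), NA_integer_, as.integer(cls >= 2))
  }
  if (is_lake_grid(classgrid)) {
    check_columns(classgrid, "class", "classgrid")
    return(grid_with_layer(classgrid, "presence", to_presence(classgrid$class)))
  }
  to_presence(classgrid)
}

#' Random spatial subsample of assessable cells
#'
#' Uniform sample without replacement from the cells that are non-missing
#' in both layers (the assessable universe), of size
#' `round(fraction * n)`. Reproducible under a fixed seed.
#'
#' @param observed,predicted Aligned grids (or equal-length vectors) whose
#'   non-missing cells define the sampling universe.
#' @param fraction Sampling fraction in (0, 1\] (default 0.20).
#' @param seed Integer seed.
#' @return Integer vector of sampled cell indices.
#' @export
subsample_cells <- function(observed, predicted, fraction = 0.20, seed = 1L) {
  if (fraction <= 0 || fraction > 1) {
    stop_domain("`fraction` must lie in (0, 1].")
  }
  obs <- if (is_lake_grid(observed)) observed$presence %||% observed$class else observed
  prd <- if (is_lake_grid(predicted)) predicted$presence %||% predicted$class else predicted
  if (is_lake_grid(observed) && is_lake_grid(predicted)) {
    check_aligned(observed, predicted)
  } else if (length(obs) != length(prd)) {
    stop_align("Observed and predicted layers differ in length.")
  }
  universe <- which(!is.na(obs) & !is.na(prd))
  if (length(universe) == 0) {
    stop_domain("Observed and predicted layers share no assessable cells.")
  }
  size <- round(fraction * length(universe))
  withr::with_seed(seed, sample(universe, size))
}

#' Confusion counts between observed and predicted presence
#'
#' Tallies true/false positives and negatives over the given cell indices
#' (all assessable cells by default). Cells missing in either layer are
#' excluded and their number reported in `n_excluded`. "Positive" is
#' observed/predicted presence (1).
#'
#' @param observed,predicted Aligned presence grids from [binarize()] (or
#'   0/1 vectors).
#' @param indices Optional cell indices (e.g. from [subsample_cells()]).
#' @return A `sav_confusion` list: `tp`, `fn`, `fp`, `tn`, the marginals
#'   `op`, `on`, `pp`, `pn`, total `t`, and `n_excluded`.
#' @export
confusion_counts <- function(observed, predicted, indices = NULL) {
  obs <- if (is_lake_grid(observed)) observed$presence else observed
  prd <- if (is_lake_grid(predicted)) predicted$presence else predicted
  if (is_lake_grid(observed) && is_lake_grid(predicted)) {
    check_aligned(observed, predicted)
  } else if (length(obs) != length(prd)) {
    stop_align("Observed and predicted layers differ in length.")
  }
  if (!is.null(indices)) {
    obs <- obs[indices]; prd <- prd[indices]
  }
  keep <- !is.na(obs) & !is.na(prd)
  n_excluded <- sum(!keep)
  obs <- obs[keep]; prd <- prd[keep]
  if (length(obs) == 0) {
    stop_domain("No jointly non-missing cells to assess.")
  }
  new_confusion(tp = sum(obs == 1 & prd == 1), fn = sum(obs == 1 & prd == 0),
                fp = sum(obs == 0 & prd == 1), tn = sum(obs == 0 & prd == 0),
                n_excluded = n_excluded)
}

#' Construct confusion counts directly
#'
#' For driving the metric suite from published counts without rasters.
#'
#' @param tp,fn,fp,tn Cell counts (non-negative).
#' @param n_excluded Cells dropped for missingness (bookkeeping only).
#' @return A `sav_confusion` object.
#' @export
new_confusion <- function(tp, fn, fp, tn, n_excluded = 0L) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop_domain("Confusion counts must be non-negative.")
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    op = tp + fn, on = fp + tn, pp = tp + fp, pn = fn + tn,
    t = tp + fn + fp + tn, n_excluded = n_excluded
  ), class = "sav_confusion")
}

#' @export
print.sav_confusion <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d):\n", x$t))
  cat(sprintf("  tp = %d  fn = %d  (observed presence %d)\n", x$tp, x$fn, x$op))
  cat(sprintf("  fp = %d  tn = %d  (observed absence  %d)\n", x$fp, x$tn, x$on))
  invisible(x)
}

#' @export
tidy.sav_confusion <- function(x, ...) {
  tibble::tibble(
    observed = c("presence", "presence", "absence", "absence"),
    predicted = c("presence", "absence", "presence", "absence"),
    count = c(x$tp, x$fn, x$fp, x$tn)
  )
}

# Matthews correlation with the product under the root taken as a sum of
# logarithms, so large cell counts cannot overflow the double product.
mcc_from_counts <- function(tp, fn, fp, tn) {
  tp <- as.numeric(tp); fn <- as.numeric(fn)
  fp <- as.numeric(fp); tn <- as.numeric(tn)
  op <- tp + fn; on <- fp + tn; pp <- tp + fp; pn <- fn + tn
  if (min(op, on, pp, pn) == 0) return(list(mcc = 0, degenerate = TRUE))
  denom <- exp(0.5 * (log(pp) + log(pn) + log(op) + log(on)))
  list(mcc = (tp * tn - fp * fn) / denom, degenerate = FALSE)
}

#' Confusion-matrix performance metrics
#'
#' The seven standard metrics: error rate `(fp + fn) / t`, accuracy
#' `(tp + tn) / t`, sensitivity `tp / op`, specificity `tn / on`,
#' precision `tp / pp`, false-positive rate `fp / on`, and the Matthews
#' correlation coefficient
#' `(tp * tn - fp * fn) / sqrt(pp * pn * op * on)`. A metric whose
#' denominator is zero is returned as `NA` and named in the `undefined`
#' attribute rather than silently zeroed; the MCC alone falls back to 0
#' (flagged in `mcc_degenerate`) when any marginal is empty, the usual
#' convention. Note: accuracy + error = 1 by construction (the error rate
#' is the complement of accuracy, i.e. the misclassified fraction).
#'
#' @param counts A `sav_confusion` from [confusion_counts()] or
#'   [new_confusion()].
#' @return A one-row `sav_confusion_metrics` tibble: `err`, `acc`, `sn`,
#'   `sp`, `prec`, `fpr`, `mcc`.
#' @export
#' @examples
#' confusion_metrics(new_confusion(tp = 184, fn = 450, fp = 1133, tn = 33941))
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "sav_confusion"))
  if (counts$t <= 0) stop_domain("Total count must be positive.")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  m <- mcc_from_counts(counts$tp, counts$fn, counts$fp, counts$tn)
  out <- tibble::tibble(
    err = (counts$fp + counts$fn) / counts$t,
    acc = (counts$tp + counts$tn) / counts$t,
    sn = safe_div(counts$tp, counts$op),
    sp = safe_div(counts$tn, counts$on),
    prec = safe_div(counts$tp, counts$pp),
    fpr = safe_div(counts$fp, counts$on),
    mcc = m$mcc
  )
  undefined <- names(out)[vapply(out, is.na, logical(1))]
  if (length(undefined) > 0) {
    warn(sprintf("Metric(s) undefined (zero marginal): %s.",
                 paste(undefined, collapse = ", ")))
  }
  attr(out, "undefined") <- undefined
  attr(out, "mcc_degenerate") <- m$degenerate
  class(out) <- c("sav_confusion_metrics", class(out))
  out
}

#' Round metrics to reporting precision
#'
#' Percents to the nearest integer and MCC to two decimals, the precision
#' typically used in published validation tables; the full-precision
#' values remain in the input.
#'
#' @param metrics A `sav_confusion_metrics` row.
#' @return A tibble with `metric`, `value` (full precision) and
#'   `reported` (formatted) columns.
#' @export
format_metrics <- function(metrics) {
  stopifnot(inherits(metrics, "sav_confusion_metrics"))
  vals <- unlist(metrics[1, c("err", "acc", "sn", "sp", "prec", "fpr", "mcc")])
  reported <- c(sprintf("%d%%", round(100 * vals[1:6])),
                sprintf("%.2f", vals[7]))
  tibble::tibble(metric = names(vals), value = unname(vals),
                 reported = unname(reported))
}

#' @export
tidy.sav_confusion_metrics <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
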