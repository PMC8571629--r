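#' Screen station chemistry for extreme outliers
#'
#' Per variable, values farther than `k` pooled standard deviations from
#' the pooled mean (across all stations and months, single pass) are set
#' to missing. The input table is otherwise untouched; the number of
#' values removed per variable is attached as the `outliers_removed`
#' attribute and reported via a message.
#'
#' @param samples Station-sample tibble with (any of) columns `tn`, `tp`,
#'   `tchl`, `secchi`.
#' @param k Standard-deviation multiple (default 3); `Inf` disables
#'   screening.
#' @param vars Variables to screen.
#' @return `samples` with flagged values set to `NA`.
#' @export
remove_outliers <- function(samples, k = 3,
                            vars = c("tn", "tp", "tchl", "secchi")) {
  check_columns(samples, character(0), "samples")
  if (k <= 0) stop_domain("`k` must be positive.")
  vars <- intersect(vars, names(samples))
  removed <- setNames(integer(length(vars)), vars)
  out <- samples
  for (v in vars) {
    vals <- out[[v]]
    ok <- !is.na(vals)
    if (sum(ok) == 0) {
      warn(sprintf("Variable `%s` is all-missing; passed through.", v))
      next
    }
    if (sum(ok) < 3) {
      warn(sprintf(
        "Variable `%s` has fewer than 3 values; dispersion not estimable, passed through.", v))
      next
    }
    mu <- mean(vals[ok]); sigma <- sd(vals[ok])
    if (is.finite(k) && sigma > 0) {
      flag <- ok & abs(vals - mu) > k * sigma
      removed[v] <- sum(flag)
      out[[v]][flag] <- NA
    }
  }
  if (sum(removed) > 0) {
    inform(sprintf("Removed %d extreme value(s): %s.", sum(removed),
                   paste(sprintf("%s=%d", names(removed), removed)[removed > 0],
                         collapse = ", ")))
  }
  attr(out, "outliers_removed") <- removed
  out
}

zone_summary_one <- function(df, zone_label) {
  vars <- intersect(c("tn", "tp", "tchl", "secchi"), names(df))
  out <- tibble::tibble(zone = zone_label, n = nrow(df))
  for (v in vars) {
    vals <- df[[v]][!is.na(df[[v]])]
    out[[paste0(v, "_mean")]] <- if (length(vals)) mean(vals) else NA_real_
    out[[paste0(v, "_min")]]  <- if (length(vals)) min(vals) else NA_real_
    out[[paste0(v, "_max")]]  <- if (length(vals)) max(vals) else NA_real_
  }
  if (all(c("tn", "tp") %in% vars)) {
    ratio <- df$tn / df$tp
    out$tn_tp_ratio <- mean(ratio, na.rm = TRUE)
  }
  out
}

#' Summarise station chemistry by lake zone
#'
#' Mean, minimum and maximum of TN, TP, TChl and Secchi depth per zone
#' plus a `combined` row over all samples. The TN/TP ratio is the mean of
#' per-sample ratios (ratio first, then average), not the ratio of means:
#' for samples (TN, TP) = (100, 10) and (100, 50) the summary reports
#' mean(10, 2) = 6, not 200/60.
#'
#' @param samples Station-sample tibble; needs a `zone` column with values
#'   in south/middle/north (rows with missing zone only contribute to the
#'   combined summary).
#' @param average `"station_months"` (default) averages all station-month
#'   records directly; `"station_means"` first averages each station over
#'   months, then summarises stations.
#' @return A tibble with one row per zone plus `combined`.
#' @export
summarize_zones <- function(samples,
                            average = c("station_months", "station_means")) {
  average <- match.arg(average)
  check_columns(samples, "zone", "samples")
  if (average == "station_means") {
    vars <- intersect(c("tn", "tp", "tchl", "secchi"), names(samples))
    samples <- samples |>
      dplyr::group_by(.data$station_id, .data$zone) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  zones <- c("south", "middle", "north")
  present <- zones[zones %in% samples$zone]
  skipped <- setdiff(zones, present)
  if (length(skipped) > 0) {
    warn(sprintf("Zone(s) with no samples omitted: %s.",
                 paste(skipped, collapse = ", ")))
  }
  rows <- purrr::map(present,
                     ~ zone_summary_one(samples[samples$zone %in% .x, ], .x))
  dplyr::bind_rows(c(rows, list(zone_summary_one(samples, "combined"))))
}

carlson_category <- function(tsi) {
  dplyr::case_when(
    is.na(tsi) ~ NA_character_,
    tsi < 40 ~ "oligotrophic",
    tsi < 50 ~ "mesotrophic",
    tsi <= 70 ~ "eutrophic",
    TRUE ~ "hypereutrophic"
  )
}

#' Carlson trophic state assessment and nutrient limitation
#'
#' Computes the Carlson (1977) trophic state indices for whichever of
#' chlorophyll, total phosphorus and Secchi depth are available:
#' \deqn{TSI(Chl) = 9.81 \ln(Chl) + 30.6}
#' \deqn{TSI(TP) = 14.42 \ln(TP) + 4.15}
#' \deqn{TSI(SD) = 60 - 14.41 \ln(SD)}
#' Each index is categorised (< 40 oligotrophic, 40-50 mesotrophic, 50-70
#' eutrophic, > 70 hypereutrophic); the overall category follows TSI(Chl)
#' when chlorophyll is available. The limiting nutrient is called from the
#' mean TN/TP mass ratio: phosphorus above 17, co-limited between 10 and
#' 17, nitrogen below 10.
#'
#' @param summary A one-or-more-row zone summary from [summarize_zones()]
#'   (columns `tchl_mean`, `tp_mean`, `secchi_mean`, `tn_tp_ratio`), or
#'   `NULL` to pass scalar values directly.
#' @param tchl,tp,secchi,tn_tp_ratio Scalar values (ug/L, ug/L, m,
#'   dimensionless) used when `summary` is `NULL`.
#' @return A tibble with one row per input row: the three indices, their
#'   categories, the overall category and the limiting-nutrient call.
#' @export
#' @examples
#' assess_trophic_state(tchl = 19.8, tp = 28.2, secchi = 1.2,
#'                      tn_tp_ratio = 19.3)
assess_trophic_state <- function(summary = NULL, tchl = NULL, tp = NULL,
                                 secchi = NULL, tn_tp_ratio = NULL) {
  if (!is.null(summary)) {
    check_columns(summary, character(0), "summary")
    grab <- function(col) if (col %in% names(summary)) summary[[col]] else NA_real_
    zone <- if ("zone" %in% names(summary)) summary$zone else NA_character_
    tchl <- grab("tchl_mean"); tp <- grab("tp_mean")
    secchi <- grab("secchi_mean"); tn_tp_ratio <- grab("tn_tp_ratio")
  } else {
    zone <- NA_character_
    tchl <- tchl %||% NA_real_; tp <- tp %||% NA_real_
    secchi <- secchi %||% NA_real_; tn_tp_ratio <- tn_tp_ratio %||% NA_real_
  }
  if (all(is.na(tchl) & is.na(tp) & is.na(secchi))) {
    stop_domain("At least one of chlorophyll, TP or Secchi depth is required.")
  }
  if (any(!is.na(tchl) & tchl <= 0) || any(!is.na(tp) & tp <= 0) ||
      any(!is.na(secchi) & secchi <= 0)) {
    stop_domain("Chlorophyll, TP and Secchi depth must be positive.")
  }
  tsi_chl <- ifelse(is.na(tchl), NA_real_, 9.81 * log(tchl) + 30.6)
  tsi_tp  <- ifelse(is.na(tp), NA_real_, 14.42 * log(tp) + 4.15)
  tsi_sd  <- ifelse(is.na(secchi), NA_real_, 60 - 14.41 * log(secchi))
  overall <- dplyr::coalesce(carlson_category(tsi_chl),
                             carlson_category(tsi_tp),
                             carlson_category(tsi_sd))
  limiting <- dplyr::case_when(
    is.na(tn_tp_ratio) ~ NA_character_,
    tn_tp_ratio > 17 ~ "phosphorus",
    tn_tp_ratio >= 10 ~ "co-limited",
    TRUE ~ "nitrogen"
  )
  tibble::tibble(
    zone = zone,
    tsi_chl = tsi_chl, category_chl = carlson_category(tsi_chl),
    tsi_tp = tsi_tp, category_tp = carlson_category(tsi_tp),
    tsi_sd = tsi_sd, category_sd = carlson_category(tsi_sd),
    category_overall = overall,
    tn_tp_ratio = tn_tp_ratio,
    limiting_nutrient = limiting
  )
}

fit_one_lm <- function(formula, data, label) {
  data <- data[complete.cases(data[all.vars(formula)]), ]
  p <- length(all.vars(formula))  # response + predictors
  if (nrow(data) < p + 1) {
    stop_domain(sprintf("Model `%s` needs at least %d complete cases; got %d.",
                        label, p + 1, nrow(data)))
  }
  fit <- lm(formula, data = data)
  if (fit$rank < length(coef(fit))) {
    stop_domain(sprintf("Model `%s` has a rank-deficient design.", label))
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat) || !all(is.finite(fstat))) {
    NA_real_
  } else {
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  r2 <- sm$r.squared
  if (!is.na(r2) && r2 > 1 - 1e-12 && (is.na(pval) || !is.finite(pval))) pval <- 0
  cf <- coef(fit)
  tibble::tibble(
    model = label,
    response = all.vars(formula)[1],
    predictors = paste(all.vars(formula)[-1], collapse = " + "),
    intercept = unname(cf["(Intercept)"]),
    slopes = list(cf[setdiff(names(cf), "(Intercept)")]),
    r_squared = r2,
    p_value = unname(pval),
    n = nrow(data),
    fit = list(fit)
  )
}

#' Regression suite linking nutrients, chlorophyll, clarity and distance
#'
#' Ordinary least squares fits of the empirical trophic chain: monthly
#' TChl on TP, TChl on TN, Secchi depth on TChl; station-mean Secchi depth
#' on distance to the outlet; and the multivariate Secchi ~ TChl +
#' distance fit on monthly values, with the added variance explained by
#' TChl beyond distance reported in `delta_r2_tchl`.
#'
#' @param samples Station-sample tibble with `tn`, `tp`, `tchl`, `secchi`
#'   and a per-record `distance_km` column (or supply `distances`).
#' @param distances Optional tibble `station_id`, `distance_km` joined on
#'   when `samples` lacks distances.
#' @return A `sav_regressions` tibble, one row per model, with the fitted
#'   `lm` objects in the `fit` list-column. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
fit_regressions <- function(samples, distances = NULL) {
  check_columns(samples, c("tn", "tp", "tchl", "secchi"), "samples")
  if (!"distance_km" %in% names(samples)) {
    if (is.null(distances)) {
      stop_domain("Provide `distance_km` in `samples` or via `distances`.")
    }
    check_columns(distances, c("station_id", "distance_km"), "distances")
    samples <- dplyr::left_join(samples, distances, by = "station_id")
  }
  station_means <- samples |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(secchi = mean(.data$secchi, na.rm = TRUE),
                     distance_km = mean(.data$distance_km), .groups = "drop")

  res <- dplyr::bind_rows(
    fit_one_lm(tchl ~ tp, samples, "tchl_vs_tp"),
    fit_one_lm(tchl ~ tn, samples, "tchl_vs_tn"),
    fit_one_lm(secchi ~ tchl, samples, "secchi_vs_tchl"),
    fit_one_lm(secchi ~ distance_km, station_means, "secchi_vs_distance"),
    fit_one_lm(secchi ~ tchl + distance_km, samples, "secchi_vs_tchl_distance")
  )
  r2_dist_monthly <- fit_one_lm(secchi ~ distance_km, samples, "aux")$r_squared
  res$delta_r2_tchl <- ifelse(
    res$model == "secchi_vs_tchl_distance",
    res$r_squared - r2_dist_monthly, NA_real_)
  class(res) <- c("sav_regressions", class(res))
  res
}

#' @export
tidy.sav_regressions <- function(x, ...) {
  purrr::map2(x$fit, x$model, function(f, m) {
    sm <- summary(f)$coefficients
    tibble::tibble(model = m, term = rownames(sm),
                   estimate = sm[, 1], std.error = sm[, 2],
                   statistic = sm[, 3], p.value = sm[, 4])
  }) |> dplyr::bind_rows()
}

#' @export
glance.sav_regressions <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r_squared,
                 adj.r.squared = purrr::map_dbl(x$fit,
                   ~ summary(.x)$adj.r.squared),
                 p.value = x$p_value, nobs = x$n)
}

#' @export
autoplot.sav_regressions <- function(object, ...) {
  pts <- purrr::map2(object$fit, object$model, function(f, m) {
    d <- f$model
    if (ncol(d) != 2) return(NULL)  # only simple regressions are panelled
    tibble::tibble(model = m, x = d[[2]], y = d[[1]])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~model, scales = "free") +
    ggplot2::theme_minimal()
}
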