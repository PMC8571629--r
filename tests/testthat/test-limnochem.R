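test_that("outlier screening matches the brute-force pooled flagging oracle", {
  # the classic spike case: 1000 is NOT beyond 3 pooled SDs of {10,11,12,9,1000}
  x <- c(10, 11, 12, 9, 1000)
  flags <- brute_outlier_flags(x, 3)
  expect_false(any(flags))
  out <- remove_outliers(tibble::tibble(tn = x), k = 3)
  expect_identical(is.na(out$tn), flags)

  # a spike that is flagged, and random cases, agree with the oracle
  withr::with_seed(42, {
    for (i in 1:20) {
      v <- c(rnorm(30), sample(c(0, 50, 200), 1))
      flags <- brute_outlier_flags(v, 3)
      out <- suppressMessages(remove_outliers(tibble::tibble(tchl = v), k = 3))
      expect_identical(is.na(out$tchl), flags)
    }
  })
})

test_that("outlier screening leaves identical values and k = Inf untouched", {
  same <- tibble::tibble(tp = rep(5, 10))
  expect_identical(remove_outliers(same, k = 3), same,
                   ignore_attr = "outliers_removed")
  withr::with_seed(1, {
    v <- tibble::tibble(tn = rnorm(20, 100, 300))
    expect_identical(remove_outliers(v, k = Inf)$tn, v$tn)
  })
})

test_that("outlier screening reports removals and tolerates bad variables", {
  df <- tibble::tibble(tn = c(rep(10, 10), 1e6), tp = rep(NA_real_, 11))
  expect_warning(out <- suppressMessages(remove_outliers(df)),
                 "all-missing")
  expect_equal(unname(attr(out, "outliers_removed")["tn"]), 1)
  expect_true(is.na(out$tn[11]))
})

test_that("zone summaries use the mean-of-ratios TN/TP convention", {
  df <- tibble::tibble(station_id = c("a", "b"), zone = "south",
                       tn = c(100, 100), tp = c(10, 50),
                       tchl = c(5, 5), secchi = c(1, 1))
  s <- suppressWarnings(summarize_zones(df))
  south <- s[s$zone == "south", ]
  expect_equal(south$tn_tp_ratio, 6)          # mean(10, 2), not 200/60
  # with constant TP the ratio reduces exactly to mean(TN)/TP
  df2 <- tibble::tibble(station_id = c("a", "b"), zone = "south",
                        tn = c(100, 300), tp = c(10, 10),
                        tchl = c(5, 5), secchi = c(1, 1))
  s2 <- suppressWarnings(summarize_zones(df2))
  expect_equal(s2$tn_tp_ratio[s2$zone == "south"], mean(df2$tn) / 10)
})

test_that("single-sample zones have mean = min = max and empty zones warn", {
  df <- tibble::tibble(station_id = "a", zone = "north",
                       tn = 50, tp = 5, tchl = 9, secchi = 1.4)
  expect_warning(s <- summarize_zones(df), "omitted")
  north <- s[s$zone == "north", ]
  expect_equal(north$tchl_mean, north$tchl_min)
  expect_equal(north$tchl_mean, north$tchl_max)
  expect_true("combined" %in% s$zone)
})

test_that("station-means averaging is available as an alternative", {
  df <- tibble::tibble(station_id = c("a", "a", "b"), zone = "middle",
                       tn = c(100, 300, 100), tp = c(10, 10, 10),
                       tchl = c(10, 30, 10), secchi = c(1, 1, 1))
  sm <- suppressWarnings(summarize_zones(df, average = "station_means"))
  mid <- sm[sm$zone == "middle", ]
  expect_equal(mid$tchl_mean, mean(c(mean(c(10, 30)), 10)))
  expect_equal(mid$n, 2)  # two stations, not three records
})

test_that("Carlson indices reproduce closed-form worked values", {
  a <- assess_trophic_state(tchl = 19.8)
  expect_equal(a$tsi_chl, 9.81 * log(19.8) + 30.6, tolerance = 1e-12)
  expect_equal(round(a$tsi_chl, 1), 59.9)
  expect_equal(a$category_overall, "eutrophic")

  b <- assess_trophic_state(tp = 12.9)
  expect_equal(round(b$tsi_tp, 1), 41.0)
  expect_equal(b$category_tp, "mesotrophic")

  c3 <- assess_trophic_state(secchi = 1.2)
  expect_equal(c3$tsi_sd, 60 - 14.41 * log(1.2), tolerance = 1e-12)
})

test_that("nutrient limitation follows the TN/TP = 17 rule", {
  expect_equal(assess_trophic_state(tchl = 19.8, tn_tp_ratio = 19.3)$limiting_nutrient,
               "phosphorus")
  expect_equal(assess_trophic_state(tchl = 19.8, tn_tp_ratio = 12)$limiting_nutrient,
               "co-limited")
  expect_equal(assess_trophic_state(tchl = 19.8, tn_tp_ratio = 7)$limiting_nutrient,
               "nitrogen")
  expect_error(assess_trophic_state(tchl = -1), class = "lakesav_error_domain")
  expect_error(assess_trophic_state(), class = "lakesav_error_domain")
})

test_that("trophic categories are monotone in their drivers", {
  rank_of <- function(cat) match(cat, c("oligotrophic", "mesotrophic",
                                        "eutrophic", "hypereutrophic"))
  chl <- sort(exp(seq(log(0.5), log(500), length.out = 60)))
  cats <- assess_trophic_state(tibble::tibble(tchl_mean = chl))$category_chl
  expect_true(all(diff(rank_of(cats)) >= 0))
  sds <- sort(exp(seq(log(0.05), log(15), length.out = 60)))
  cats_sd <- assess_trophic_state(tibble::tibble(secchi_mean = sds))$category_sd
  expect_true(all(diff(rank_of(cats_sd)) <= 0))  # clearer water, lower trophic state
})

test_that("regression suite recovers an exact line", {
  df <- tibble::tibble(station_id = sprintf("s%d", 1:10),
                       tn = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3),
                       tp = 1:10,
                       tchl = 2 * (1:10) + 1,
                       secchi = c(0.7, 1.1, 0.5, 1.3, 0.9, 1.2, 0.6, 1.4, 1.0, 0.8),
                       distance_km = c(0.5, 2, 1, 4, 3, 7, 6, 9, 8, 5))
  # the exact tchl ~ tp line triggers lm's perfect-fit warning; harmless here
  fits <- suppressWarnings(fit_regressions(df))
  row <- fits[fits$model == "tchl_vs_tp", ]
  expect_equal(unname(row$slopes[[1]]), 2, tolerance = 1e-12)
  expect_equal(row$intercept, 1, tolerance = 1e-12)
  expect_equal(row$r_squared, 1, tolerance = 1e-12)
  expect_equal(nrow(fits), 5)
  expect_false(is.na(fits$delta_r2_tchl[fits$model == "secchi_vs_tchl_distance"]))
})

test_that("OLS estimates agree with a normal-equations solver", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(5:40, 1)
      df <- tibble::tibble(station_id = sprintf("s%d", seq_len(n)),
                           tn = runif(n, 50, 900), tp = runif(n, 5, 200),
                           tchl = runif(n, 5, 60) + 0.1 * runif(n, 5, 200),
                           secchi = runif(n, 0.3, 3),
                           distance_km = runif(n, 0, 12))
      fits <- fit_regressions(df)
      for (m in c("tchl_vs_tp", "tchl_vs_tn", "secchi_vs_tchl")) {
        row <- fits[fits$model == m, ]
        d <- row$fit[[1]]$model
        ref <- brute_ols(as.matrix(d[, -1]), d[[1]])
        got <- c(row$intercept, row$slopes[[1]])
        expect_equal(unname(got), unname(ref), tolerance = 1e-8)
      }
      mrow <- fits[fits$model == "secchi_vs_tchl_distance", ]
      d <- mrow$fit[[1]]$model
      ref <- brute_ols(as.matrix(d[, -1]), d[[1]])
      expect_equal(unname(c(mrow$intercept, mrow$slopes[[1]])), unname(ref),
                   tolerance = 1e-8)
    }
  })
})

test_that("regression errors name the failing model", {
  df <- tibble::tibble(station_id = c("a", "b", "c", "d"),
                       tn = 1:4, tp = rep(2, 4), tchl = 1:4,
                       secchi = rep(1, 4), distance_km = 1:4)
  expect_error(fit_regressions(df), "tchl_vs_tp")
  expect_error(fit_regressions(df[1:2, ]), class = "lakesav_error_domain")
})

test_that("tidy and glance return per-term and per-model tables", {
  withr::with_seed(2, {
    df <- tibble::tibble(station_id = sprintf("s%d", 1:12),
                         tn = runif(12, 100, 600), tp = runif(12, 5, 60),
                         tchl = runif(12, 8, 50), secchi = runif(12, 0.4, 2),
                         distance_km = runif(12, 0, 10))
  })
  fits <- fit_regressions(df)
  td <- tidy(fits)
  expect_true(all(c("model", "term", "estimate", "p.value") %in% names(td)))
  expect_equal(sum(td$model == "secchi_vs_tchl_distance"), 3)
  gl <- glance(fits)
  expect_equal(nrow(gl), 5)
  expect_true(all(gl$r.squared >= 0 & gl$r.squared <= 1))
  expect_true(all(gl$nobs > 2))
})
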