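day <- function(d) ts0(d * 24)
no_tx <- list(patient_id = "P1", transplant_history = FALSE)

test_that("chronicity windows require a span strictly over 91 days", {
  w <- chronic_windows(c(50, 40), day(c(0, 120)))
  expect_equal(nrow(w), 1)
  expect_equal(w$span_hours, 2880)
  expect_equal(w$n_values, 2L)

  expect_equal(nrow(chronic_windows(c(50, 40), day(c(0, 60)))), 0)
  expect_equal(nrow(chronic_windows(c(50, 40), day(c(0, 91)))), 0)   # exactly 91 days
  expect_equal(nrow(chronic_windows(c(50, 40), day(c(0, 91)) + c(0, 3600))), 1)

  # brute-force cross-check incl. carried statistics
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    d <- sort(runif(n, 0, 400))
    v <- runif(n, 10, 100)
    w <- chronic_windows(v, day(d))
    expected <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if ((d[j] - d[i]) * 24 > 2184) expected <- expected + 1
    }
    expect_equal(nrow(w), expected)
    if (nrow(w)) {
      expect_true(all(w$span_hours > 2184))
      expect_equal(w$max_egfr, vapply(w$values, max, numeric(1)))
      expect_equal(w$min_egfr, vapply(w$values, min, numeric(1)))
      expect_equal(w$mean_egfr, vapply(w$values, mean, numeric(1)))
    }
  }
})

test_that("a window is staged by the smallest threshold bounding all its values", {
  expect_equal(stage_window(c(25, 28, 22)), 4L)
  expect_equal(stage_window(c(25, 65, 22)), 2L)  # 65 blocks stage 3
  expect_null(stage_window(c(95, 80)))           # a value >= 90 disqualifies
  expect_equal(stage_window(c(10, 14)), 5L)
  expect_equal(stage_window(c(10, 89.99)), 2L)
  expect_null(stage_window(c(10, 90)))
})

test_that("classify_ckd stages persistent low eGFR and enforces the recency constraint", {
  ser <- tibble::tibble(value = c(25, 28, 22), ts = day(c(0, 50, 120)))
  f <- classify_ckd(no_tx, ser, index_date = day(121))
  expect_equal(f$stage, 4L)
  expect_equal(f$window_start_ts, day(0))
  expect_equal(f$window_end_ts, day(120))
  expect_identical(f$evidence, "egfr_window")
  expect_equal(f$max_egfr_in_window, 28)

  # no confirming value in the 90 days before the index date -> no finding
  ser2 <- tibble::tibble(value = c(25, 22), ts = day(c(0, 100)))
  expect_null(classify_ckd(no_tx, ser2, index_date = day(300)))
  # unless the recency requirement is switched off
  f2 <- classify_ckd(no_tx, ser2, index_date = day(300),
                     config = kd_config(ckd.require_recency = FALSE))
  expect_equal(f2$stage, 4L)
})

test_that("transplant history and albuminuria establish unspecified-stage CKD", {
  tx <- list(patient_id = "P1", transplant_history = TRUE)
  f <- classify_ckd(tx, tibble::tibble(value = numeric(0), ts = day(numeric(0))))
  expect_identical(f$stage, "unspecified")
  expect_identical(f$evidence, "transplant")

  acr <- compute_acr(list(value = 80, ts = day(100)),
                     list(value = 1, unit = "g/L", ts = day(100)))
  f <- classify_ckd(no_tx, NULL, acr_results = list(acr), index_date = day(120))
  expect_identical(f$stage, "unspecified")
  expect_identical(f$evidence, "acr_only")
  expect_equal(f$acr$acr_mg_per_g, 80)

  # A1 albuminuria is not a CKD marker
  a1 <- compute_acr(list(value = 2, ts = day(100)),
                    list(value = 1, unit = "g/L", ts = day(100)))
  expect_null(classify_ckd(no_tx, NULL, acr_results = list(a1), index_date = day(120)))
  # transplant evidence outranks albuminuria
  f <- classify_ckd(tx, NULL, acr_results = list(acr), index_date = day(120))
  expect_identical(f$evidence, "transplant")
})

test_that("classify_ckd equals the brute-force all-windows oracle on random series", {
  set.seed(20240916)
  for (rep in 1:300) {
    n <- sample(0:8, 1)
    ser <- random_egfr_series(n)
    index <- day(410)
    got <- classify_ckd(no_tx, ser, index_date = index)
    want <- oracle_classify_ckd(ser$value, ser$ts, index)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$stage, want$stage)
      expect_equal(got$span_hours, want$span)
      expect_equal(got$window_start_ts, want$start)
      expect_equal(got$window_end_ts, want$end)
    }
  }
})

test_that("a normal value inside the window invalidates or downgrades the finding", {
  ser <- tibble::tibble(value = c(25, 28, 22), ts = day(c(0, 50, 120)))
  f <- classify_ckd(no_tx, ser, index_date = day(121))
  expect_equal(f$stage, 4L)
  # adding a 92 inside the window leaves no stageable window
  ser92 <- dplyr::bind_rows(ser, tibble::tibble(value = 92, ts = day(60)))
  expect_null(classify_ckd(no_tx, ser92, index_date = day(121)))
  # adding a 65 downgrades to stage 2
  ser65 <- dplyr::bind_rows(ser, tibble::tibble(value = 65, ts = day(60)))
  expect_equal(classify_ckd(no_tx, ser65, index_date = day(121))$stage, 2L)
})

test_that("increasing a single value never raises the stage", {
  # pure staging monotonicity; the recency gate is orthogonal and can
  # let a lower-stage window confirm where a higher one could not
  cfg <- kd_config(ckd.require_recency = FALSE)
  set.seed(909)
  for (rep in 1:40) {
    ser <- random_egfr_series(sample(2:8, 1))
    f1 <- classify_ckd(no_tx, ser, index_date = day(410), config = cfg)
    k <- sample(nrow(ser), 1)
    ser2 <- ser
    ser2$value[k] <- ser2$value[k] + runif(1, 5, 60)
    f2 <- classify_ckd(no_tx, ser2, index_date = day(410), config = cfg)
    s1 <- if (is.null(f1)) 0L else f1$stage
    s2 <- if (is.null(f2)) 0L else f2$stage
    expect_lte(s2, s1 + 0L)
    if (!is.null(f2)) expect_gt(f2$span_hours, 2184)
  }
})
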