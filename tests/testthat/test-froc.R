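test_that("the FROC sweep reproduces the hand-enumerated example", {
  ms <- list(e1 = mock_match(0.9, 0.6, 1), e2 = mock_match(0.4, numeric(0), 1))
  curve <- froc_curve(ms)
  expect_equal(curve$tau, c(0.9, 0.6, 0.4))
  expect_equal(curve$avg_fp, c(0, 0.5, 0.5))
  expect_equal(curve$sensitivity, c(0.5, 0.5, 1))
})

test_that("degenerate detectors give the expected single-point curves", {
  perfect <- list(mock_match(1.0, numeric(0), 1), mock_match(1.0, numeric(0), 1))
  curve <- froc_curve(perfect)
  expect_equal(nrow(curve), 1L)
  expect_equal(unlist(curve[1, ]), c(tau = 1, avg_fp = 0, sensitivity = 1))

  all_fp <- list(mock_match(numeric(0), c(0.3, 0.6), 2))
  expect_true(all(froc_curve(all_fp)$sensitivity == 0))

  no_lesions <- list(mock_match(numeric(0), 0.5, 0))
  expect_error(froc_curve(no_lesions), class = "reprocad_error_no_lesions")
})

test_that("avg_fp and sensitivity are monotone along every random curve", {
  withr::local_seed(707)
  for (rep in 1:200) {
    ms <- random_matches(sample(2:5, 1))
    if (sum(vapply(ms, function(m) m$n_lesions, integer(1))) == 0L) next
    curve <- froc_curve(ms)
    expect_true(all(diff(curve$tau) < 0))
    expect_true(all(diff(curve$avg_fp) >= 0))
    expect_true(all(diff(curve$sensitivity) >= 0))
    expect_true(all(curve$sensitivity >= 0 & curve$sensitivity <= 1))
    expect_true(all(curve$avg_fp >= 0))
  }
})

test_that("the operating threshold honours the false-positive budget", {
  ms <- list(e1 = mock_match(0.9, 0.6, 1), e2 = mock_match(0.4, numeric(0), 1))
  curve <- froc_curve(ms)
  expect_equal(threshold_at_fp(curve, 0.5), 0.4)
  expect_equal(threshold_at_fp(curve, 0.0), 0.9)
  expect_equal(threshold_at_fp(curve, 10), 0.4)   # budget never binds
  expect_error(threshold_at_fp(curve, -0.1), class = "reprocad_error_bad_fp_target")
  # unreachable budget silences the detector entirely
  noisy <- list(mock_match(0.9, c(0.95, 0.92), 1))
  expect_equal(threshold_at_fp(froc_curve(noisy), 0.5), Inf)
})

test_that("the figure of merit matches exhaustive psi enumeration", {
  ms <- list(i1 = mock_match(0.9, 0.6, 1), i2 = mock_match(0.4, numeric(0), 1))
  expect_equal(jafroc_fom(ms), 0.75)

  perfect <- list(mock_match(c(0.9, 0.8), numeric(0), 2), mock_match(0.7, numeric(0), 1))
  expect_equal(jafroc_fom(perfect), 1)

  silent <- list(mock_match(numeric(0), numeric(0), 1),
                 mock_match(numeric(0), numeric(0), 2))
  expect_equal(jafroc_fom(silent), 0.5)

  expect_error(jafroc_fom(list(mock_match(numeric(0), 0.5, 0))),
               class = "reprocad_error_no_lesions")

  withr::local_seed(515)
  for (rep in 1:100) {
    ms <- random_matches(sample(1:4, 1))
    if (sum(vapply(ms, function(m) m$n_lesions, integer(1))) == 0L) next
    expect_equal(jafroc_fom(ms), fom_brute(ms))
  }
})

test_that("the figure of merit only depends on the ordering of confidences", {
  withr::local_seed(99)
  transform <- function(ms, f) {
    lapply(ms, function(m) {
      m$hits$confidence <- f(m$hits$confidence)
      m$false_positives$confidence <- f(m$false_positives$confidence)
      m
    })
  }
  for (rep in 1:25) {
    ms <- random_matches(4)
    if (sum(vapply(ms, function(m) m$n_lesions, integer(1))) == 0L) next
    base <- jafroc_fom(ms)
    expect_equal(jafroc_fom(transform(ms, function(x) x^3)), base)
    expect_equal(jafroc_fom(transform(ms, function(x) exp(5 * x))), base)
  }
})

test_that("resampled confidence intervals are reproducible and bracket the estimate", {
  ds <- simulate_paired_detections(sim_config(n_pairs = 40, seed = 12))$dataset
  r1 <- fom_ci(ds, n_boot = 200, seed = 4)
  r2 <- fom_ci(ds, n_boot = 200, seed = 4)
  expect_identical(r1, r2)
  expect_true(r1$ci_low <= r1$fom && r1$fom <= r1$ci_high)
  expect_true(r1$fom >= 0 && r1$fom <= 1)

  jk <- fom_ci(ds, seed = 4, method = "jackknife")
  expect_true(jk$ci_low <= jk$fom && jk$fom <= jk$ci_high)

  expect_error(fom_ci(ds, n_boot = 10), class = "reprocad_error_bad_n_boot")
})

test_that("a perfect detector has a degenerate unit interval", {
  ds <- simulate_paired_detections(
    sim_config(n_pairs = 10, sensitivity = 1, rho = 1, fp_rate = 0,
               tp_score = function(n) rep(0.9, n), seed = 2)
  )$dataset
  r <- fom_ci(ds, n_boot = 200, seed = 1)
  expect_equal(r$fom, 1)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)
})

test_that("the bootstrap interval contains the full-data figure of merit", {
  ds <- simulate_paired_detections(sim_config(n_pairs = 200, seed = 31))$dataset
  r <- fom_ci(ds, n_boot = 1000, seed = 9)
  expect_true(r$ci_low <= r$fom && r$fom <= r$ci_high)
  expect_gt(r$ci_high - r$ci_low, 0)
})
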