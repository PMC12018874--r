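# Percentile conventions, per-point statistics and the Van Herk
# decomposition, against hand-computed closed forms.

make_field <- function(signed, base = NULL) {
  n <- nrow(signed)
  if (is.null(base)) base <- matrix(0, n, 3)
  structure(list(baseline_scan_id = "b", test_scan_id = "t",
                 baseline_points = base, mapped_idx = seq_len(n),
                 mapped_point = base, bld_mm = sqrt(rowSums(signed^2)),
                 vector_mm = signed, signed_mm = signed),
            class = "displacement_field")
}

test_that("percentile follows the linear-interpolation order-statistic rule", {
  expect_equal(percentile(c(0, 10), 50), 5)
  expect_equal(percentile(1:100, 95), 95.05)   # h = 1 + 99 * 0.95
  expect_equal(percentile(rep(3.7, 9), 42), 3.7)
  expect_equal(percentile(c(4, 1, 3, 2), 25), 1.75)
  expect_error(percentile(numeric(0), 50), "at least one")
})

test_that("per-point statistics: closed forms and shift invariance", {
  vals <- c(1, 2, 3, 4, 5)
  fields <- lapply(vals, function(v) make_field(matrix(v, 7, 3)))
  st <- per_point_stats(fields)
  expect_equal(st$mean_mm[, "ap_mm"], rep(3, 7))
  expect_equal(st$sd_mm[, "rl_mm"], rep(sqrt(2.5), 7))  # sd(1..5) = 1.5811
  expect_equal(st$n_test, 5)

  # identical fields: sd == 0
  same <- per_point_stats(lapply(1:5, function(i) make_field(matrix(2, 4, 3))))
  expect_equal(same$sd_mm, matrix(0, 4, 3, dimnames = dimnames(same$sd_mm)))
  expect_equal(same$mean_mm[, 1], rep(2, 4), ignore_attr = TRUE)

  # adding a constant shifts means, leaves SDs unchanged
  set.seed(8)
  rand <- lapply(1:4, function(i) make_field(matrix(rnorm(30), 10, 3)))
  shifted <- lapply(rand, function(f) {
    f$signed_mm <- f$signed_mm + 1.25
    f
  })
  s0 <- per_point_stats(rand); s1 <- per_point_stats(shifted)
  expect_equal(s1$mean_mm, s0$mean_mm + 1.25)
  expect_equal(s1$sd_mm, s0$sd_mm, tolerance = 1e-12)

  expect_error(per_point_stats(rand[1]), ">= 2")
  bad <- c(rand[1:2], list(make_field(matrix(0, 9, 3))))
  expect_error(per_point_stats(bad), "mismatched point counts")
})

test_that("surface patient summary aggregates by the 95th percentile", {
  # per-point means uniform over 1..100 -> p95 of means = 95.05
  fields <- lapply(1:3, function(i) make_field(matrix(1:100, 100, 3)))
  st <- per_point_stats(fields)
  s <- patient_summary_surface(st, fields, "p1")
  expect_equal(unname(s$mean_mm), rep(95.05, 3))
  expect_equal(unname(s$sd_mm), rep(0, 3))
  expect_equal(unname(s$median_mm), rep(50.5, 3))
  expect_equal(unname(s$p95_mm), rep(95.05, 3))
  expect_gte(s$p95_mm[1], s$median_mm[1])
  expect_true(all(s$iqr_mm >= 0))

  # the sensitivity mode percentiles each scan first
  s2 <- patient_summary_surface(st, fields, "p1", mode = "stats_of_p95")
  expect_equal(unname(s2$mean_mm), rep(95.05, 3))
  expect_equal(unname(s2$sd_mm), rep(0, 3))
})

test_that("COM patient summary: closed forms and negation symmetry", {
  mk <- function(v) structure(c(rl_mm = v[1], ap_mm = v[2], cc_mm = v[3]),
                              class = "com_displacement")
  s <- patient_summary_com(lapply(1:5, function(i) mk(c(0, 0, 1))), "p")
  expect_equal(unname(s$mean_mm[3]), 1)
  expect_equal(unname(s$sd_mm[3]), 0)

  shifts <- lapply(c(-2, 0, 2), function(v) mk(c(v, v, v)))
  s2 <- patient_summary_com(shifts, "p")
  expect_equal(unname(s2$mean_mm), c(0, 0, 0))
  expect_equal(unname(s2$sd_mm), c(2, 2, 2))
  neg <- patient_summary_com(lapply(shifts, function(x) {
    structure(-unclass(x), class = "com_displacement")
  }), "p")
  expect_equal(neg$mean_mm, -s2$mean_mm)
  expect_equal(neg$sd_mm, s2$sd_mm)
})

test_that("population errors implement the Van Herk closed forms", {
  mk <- function(m, s) rectvar:::new_patient_summary("x", "com",
                                                     rep(m, 3), rep(s, 3),
                                                     n_test = 5)
  p <- population_errors(list(mk(1, 2), mk(3, 2)))
  expect_equal(unname(p$gm_mm), rep(2, 3))
  expect_equal(unname(p$Sigma_mm), rep(sqrt(2), 3))
  expect_equal(unname(p$sigma_mm), rep(2, 3))

  same <- population_errors(lapply(1:6, function(i) mk(1.5, 0.7)))
  expect_equal(unname(same$gm_mm), rep(1.5, 3))
  expect_equal(unname(same$Sigma_mm), rep(0, 3))
  expect_equal(unname(same$sigma_mm), rep(0.7, 3))

  expect_error(population_errors(list(mk(1, 2))), ">= 2")
  mixed <- list(mk(1, 2), rectvar:::new_patient_summary("y", "surface_p95",
                                                        rep(1, 3), rep(1, 3),
                                                        n_test = 5))
  expect_error(population_errors(mixed), "share one method")
})

test_that("Sigma/sigma invariances and the pooled-variance identity", {
  set.seed(21)
  mk <- function(means, sds) rectvar:::new_patient_summary("x", "com",
                                                           means, sds,
                                                           n_test = 5)
  sums <- lapply(1:8, function(i) mk(rnorm(3), abs(rnorm(3))))
  p0 <- population_errors(sums)
  shifted <- lapply(sums, function(s) { s$mean_mm <- s$mean_mm + c(1, -2, 3); s })
  p1 <- population_errors(shifted)
  expect_equal(p1$Sigma_mm, p0$Sigma_mm, tolerance = 1e-12)
  expect_equal(p1$sigma_mm, p0$sigma_mm)
  expect_equal(p1$gm_mm, p0$gm_mm + c(1, -2, 3))

  # sigma^2 equals the pooled within-patient variance at equal n_test
  sds <- t(vapply(sums, `[[`, numeric(3), "sd_mm"))
  k <- 5
  pooled <- sqrt(colSums(sds^2 * (k - 1)) / (nrow(sds) * (k - 1)))
  expect_equal(unname(p0$sigma_mm), unname(pooled))
})
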