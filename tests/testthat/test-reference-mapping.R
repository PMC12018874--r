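# Reference rectum geometry, patient-to-reference assignment, inter-patient
# aggregation with the occupancy mask, and segment summaries.

fake_cloud <- function(pts) {
  structure(list(points = pts, source_scan_id = "b", nominal_spacing_mm = 1,
                 slab_mm = 1.5, point_z = pts[, 3],
                 is_cap = rep(FALSE, nrow(pts)), z_range = range(pts[, 3])),
            class = "surface_point_cloud")
}

fake_stats <- function(n, mean = 1, sd = 0.5) {
  structure(list(mean_mm = matrix(mean, n, 3,
                                  dimnames = list(NULL, c("rl_mm", "ap_mm", "cc_mm"))),
                 sd_mm = matrix(sd, n, 3,
                                dimnames = list(NULL, c("rl_mm", "ap_mm", "cc_mm"))),
                 n_test = 5),
            class = "per_point_stats")
}

fake_contrib <- function(ids, mean = 1, sd = 0.5) {
  out <- data.frame(ref_point_id = ids, n_points = 1L,
                    mean_rl = mean, sd_rl = sd, mean_ap = mean, sd_ap = sd,
                    mean_cc = mean, sd_cc = sd)
  class(out) <- c("reference_contribution", "data.frame")
  out
}

dummy_patient <- function() {
  st <- make_square_structure(side = 10, zs = seq(30, 40.5, by = 1.5))
  make_manual_patient(list(st, st, st))
}

test_that("reference rectum geometry and angle convention", {
  ref <- build_reference_rectum(130, 1.5)
  expect_equal(length(ref$slice_cax), 87)        # floor(130 / 1.5) + 1
  expect_equal(nrow(ref$points), 87 * 120)
  # k = 0 anterior (y < 0), k = 30 patient-left (x > 0)
  expect_lt(ref$points[1, 2], 0)
  expect_equal(unname(ref$points[1, 1]), 0, tolerance = 1e-12)
  expect_gt(ref$points[31, 1], 0)
  expect_equal(unname(ref$points[31, 2]), 0, tolerance = 1e-12)
  expect_error(build_reference_rectum(-5), "positive")
  expect_error(build_reference_rectum(100), "130")
})

test_that("directional halves cover 60 points each, every point in 2 halves", {
  ref <- build_reference_rectum()
  th <- ref$theta_deg[1:120]
  counts <- vapply(c("anterior", "posterior", "left", "right"),
                   function(h) sum(rectvar:::theta_in_half(th, h)), numeric(1))
  expect_equal(unname(counts), rep(60, 4))
  membership <- vapply(c("anterior", "posterior", "left", "right"),
                       function(h) rectvar:::theta_in_half(th, h), logical(120))
  expect_equal(unname(rowSums(membership)), rep(2, 120))
  expect_error(section_scheme(low = c(28, 60), mid = c(52, 100)), "disjoint")
})

test_that("points on the reference surface map to their own reference points", {
  ref <- build_reference_rectum()
  sel <- which(ref$cax_mm >= 30 & ref$cax_mm <= 40)
  cloud <- fake_cloud(ref$points[sel, ])
  contrib <- map_patient_to_reference(cloud, fake_stats(length(sel), 2, 0.3),
                                      dummy_patient(), ref)
  expect_setequal(contrib$ref_point_id, sel)
  expect_true(all(contrib$n_points == 1L))
  expect_equal(contrib$mean_rl, rep(2, length(sel)))
  # contribution mass conserved
  expect_equal(sum(contrib$n_points), length(sel))
})

test_that("an anterior-wall tumor contributes nothing to the posterior half", {
  ref <- build_reference_rectum()
  th <- seq(-50, 50, by = 5) * pi / 180
  pts <- do.call(rbind, lapply(seq(30, 39, by = 1.5), function(z)
    cbind(15 * sin(th), -15 * cos(th), z)))
  contrib <- map_patient_to_reference(fake_cloud(pts),
                                      fake_stats(nrow(pts)),
                                      dummy_patient(), ref)
  expect_equal(sum(contrib$n_points), nrow(pts))
  expect_false(any(rectvar:::theta_in_half(
    ref$theta_deg[contrib$ref_point_id], "posterior")))
})

test_that("a mid-height tumor lands entirely in the 52-100 mm band", {
  ref <- build_reference_rectum()
  cfg <- small_config(seed = 401, tumor_center_cax_mm = c(60, 60),
                      tumor_height_mm = c(14, 16))
  gen <- generate_patient(cfg, 1)
  cloud <- sample_surface(gen$record$scans[[1]]$gtvp, 2)
  contrib <- map_patient_to_reference(cloud, fake_stats(nrow(cloud$points)),
                                      gen$record, ref)
  cax <- ref$cax_mm[contrib$ref_point_id]
  expect_true(all(cax >= 52 & cax <= 100))
  expect_equal(sum(contrib$n_points), nrow(cloud$points))
  # a tumor outside the reference CAX span is refused with its extent
  long_ref <- build_reference_rectum(130)
  cfg2 <- small_config(seed = 402, rectum_length_mm = 220,
                       tumor_center_cax_mm = c(180, 180),
                       tumor_height_mm = c(14, 16))
  gen2 <- generate_patient(cfg2, 1)
  cl2 <- sample_surface(gen2$record$scans[[1]]$gtvp, 2)
  expect_error(map_patient_to_reference(cl2, fake_stats(nrow(cl2$points)),
                                        gen2$record, long_ref),
               "outside the reference range")
})

test_that("aggregation applies the minimum-patient occupancy mask", {
  ref <- build_reference_rectum()
  ids <- 1:50
  four <- lapply(1:4, function(i) fake_contrib(ids, mean = i))
  map4 <- aggregate_reference(four, ref, min_patients = 5)
  expect_false(any(map4$valid))
  map5 <- aggregate_reference(c(four, list(fake_contrib(ids, mean = 5))),
                              ref, min_patients = 5)
  expect_true(all(map5$valid))
  expect_equal(map5$gm_rl, rep(3, 50))
  expect_equal(map5$Sigma_rl, rep(sd(1:5), 50))

  # identical contributions: gm = m, Sigma = 0, sigma = s
  same <- lapply(1:6, function(i) fake_contrib(ids, mean = 1.2, sd = 0.8))
  ms <- aggregate_reference(same, ref, min_patients = 5)
  expect_equal(ms$gm_ap, rep(1.2, 50))
  expect_equal(ms$Sigma_ap, rep(0, 50))
  expect_equal(ms$sigma_ap, rep(0.8, 50))

  # single patient at min_patients 1: gm equals the contributed mean exactly
  one <- aggregate_reference(list(fake_contrib(ids, mean = 2.5)), ref, 1)
  expect_true(all(one$valid))
  expect_equal(one$gm_rl, rep(2.5, 50))

  # occupancy is monotone: adding a patient never invalidates a point
  grown <- aggregate_reference(c(four, list(fake_contrib(1:10, mean = 9))),
                               ref, min_patients = 4)
  base_valid <- aggregate_reference(four, ref, min_patients = 4)
  expect_true(all(grown$valid[match(base_valid$ref_point_id[base_valid$valid],
                                    grown$ref_point_id)]))
})

test_that("segment summaries respect masking and reproduce gradients", {
  ref <- build_reference_rectum()
  mk_map <- function(Sigma_fun, valid = TRUE) {
    out <- data.frame(ref_point_id = seq_len(nrow(ref$points)),
                      cax_mm = ref$cax_mm, theta_deg = ref$theta_deg,
                      n_patients = 6L, valid = valid)
    for (d in c("rl", "ap", "cc")) {
      out[[paste0("gm_", d)]] <- 0.5
      out[[paste0("Sigma_", d)]] <- Sigma_fun(ref$cax_mm)
      out[[paste0("sigma_", d)]] <- 1
    }
    class(out) <- c("reference_point_map", "data.frame")
    out
  }
  # constant map: median = p95, IQR = 0 in every segment
  segs <- segment_summary(mk_map(function(cax) 1.0))
  expect_equal(nrow(segs), 12)
  expect_equal(segs$median_Sigma_mm, rep(1, 12))
  expect_equal(segs$p95_Sigma_mm, rep(1, 12))
  expect_equal(segs$iqr_Sigma_mm, rep(0, 12))

  # Sigma increasing with CAX: high-band medians exceed low-band medians
  segs2 <- segment_summary(mk_map(function(cax) cax / 50))
  for (d in c("anterior", "posterior", "right", "left")) {
    lo <- segs2$median_Sigma_mm[segs2$direction == d & segs2$band == "low"]
    hi <- segs2$median_Sigma_mm[segs2$direction == d & segs2$band == "high"]
    expect_gt(hi, lo)
  }

  # masked points contribute nothing: deleting them changes no statistic
  m <- mk_map(function(cax) cax / 50)
  m$valid[seq(1, nrow(m), by = 3)] <- FALSE
  s_masked <- suppressWarnings(segment_summary(m))
  s_deleted <- suppressWarnings(segment_summary(m[m$valid, , drop = FALSE]))
  expect_equal(s_masked, s_deleted)

  # zero valid points: NA rows plus one warning per empty segment
  w <- capture_warnings(s_none <- segment_summary(mk_map(function(cax) 1,
                                                         valid = FALSE)))
  expect_length(w, 12)
  expect_true(all(grepl("no valid reference points", w)))
  expect_true(all(is.na(s_none$median_Sigma_mm)))
})

test_that("cranial/caudal end-slice analysis follows the CC sign rule", {
  cfg <- small_config(seed = 403, n_patients = 3,
                      Sigma_true_mm = rep(0, 3), sigma_true_mm = rep(0, 3),
                      gm_true_mm = c(0, 0, 3))
  co <- generate_cohort(cfg)
  analyses <- lapply(co$records, function(r) {
    a <- analyze_patient(r, spacing_mm = 2)
    list(cloud = a$cloud, stats = a$stats, patient = r)
  })
  ref <- build_reference_rectum()
  cc <- cc_extremes(analyses, ref, min_patients = 1)
  # rigid cranial shift: cranial outward (+), caudal inward (-)
  expect_true(all(cc$patient_cranial$mean_cc_mm > 1))
  expect_true(all(cc$patient_cranial$mean_cc_mm < 3.5))
  expect_true(all(cc$patient_caudal$mean_cc_mm < -1))
  expect_equal(cc$segments$direction, c("cranial", "caudal"))
  expect_gt(cc$segments$median_gm_mm[1], 0)
  expect_lt(cc$segments$median_gm_mm[2], 0)
  # the cranial statistics use exactly the top-slice points
  a1 <- analyses[[1]]
  expect_equal(cc$patient_cranial$n_points[1],
               sum(a1$cloud$point_z == a1$cloud$z_range[2]))

  # no motion at all: every cranial/caudal error vanishes
  cfg0 <- small_config(seed = 404, n_patients = 2,
                       Sigma_true_mm = rep(0, 3), sigma_true_mm = rep(0, 3),
                       gm_true_mm = rep(0, 3))
  co0 <- generate_cohort(cfg0)
  an0 <- lapply(co0$records, function(r) {
    a <- analyze_patient(r, spacing_mm = 2)
    list(cloud = a$cloud, stats = a$stats, patient = r)
  })
  cc0 <- cc_extremes(an0, ref, min_patients = 1)
  expect_equal(cc0$patient_cranial$mean_cc_mm, rep(0, 2))
  expect_equal(cc0$segments$median_gm_mm, rep(0, 2))
  expect_equal(cc0$segments$median_sigma_mm, rep(0, 2))
  S <- c(cc0$map_cranial$Sigma_cc, cc0$map_caudal$Sigma_cc)
  expect_true(all(S[is.finite(S)] == 0))
})
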