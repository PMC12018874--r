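# Synthetic cohort generator.
#
# Emulates the study design the analysis assumes: per patient one baseline
# plus n_test repeat delineations of a wall-hugging rectal tumor on a
# straight tubular rectum (anal verge at z = 0, centerline along +z).
# Interfraction motion is additive Gaussian per direction: a per-patient
# systematic offset s_p ~ N(0, Sigma_true), per-scan random offsets
# r_pk ~ N(0, sigma_true) and a constant group-mean drift gm_true.  Optional
# local deformation is modelled as Gaussian radial surface bumps with
# patient-specific centers, held fixed across that patient's test scans.
# Everything is deterministic under the seed, with independent per-patient
# RNG streams so cohort size changes do not reshuffle earlier patients.

#' Configuration for a synthetic cohort
#'
#' Defaults state a study-like world: 16 patients, 5 test scans, 1.5 mm
#' slice spacing, a 150 mm rectum, and motion magnitudes of the order
#' reported for rectal GTVp interfraction variation. All lengths mm, all
#' per-direction vectors ordered (RL, AP, CC).
#'
#' @param n_patients number of patients.
#' @param n_test_scans repeat scans per patient (baseline excluded).
#' @param Sigma_true_mm,sigma_true_mm,gm_true_mm per-direction true
#'   systematic SD, random SD and group-mean drift (numeric(3), RL/AP/CC).
#' @param bump_amplitude_mm peak amplitude of local surface bumps (0
#'   disables deformation).
#' @param bump_count bumps per patient.
#' @param bump_sigma_mm Gaussian width of a bump along the tumor surface.
#' @param bump_sign `"mixed"` (random outward/inward per bump), `"outward"`
#'   or `"inward"`.
#' @param rectum_length_mm rectum/centerline length from the anal verge.
#' @param rectum_radius_mm numeric(2) range of per-patient rectal radii.
#' @param tumor_center_cax_mm numeric(2) range of tumor center heights (CAX).
#' @param tumor_height_mm numeric(2) range of cranio-caudal tumor extents.
#' @param tumor_extent_deg numeric(2) range of angular extents of the
#'   crescent cross-section (rectal tumors are typically
#'   semi-circumferential rather than annular).
#' @param tumor_thickness_mm numeric(2) range of peak wall-thickness of the
#'   tumor crescent.
#' @param location_mix optional named integer vector like `c(low = 13,
#'   mid = 3)`: patients are assigned height bands in this order and tumor
#'   centers drawn inside the band (overrides `tumor_center_cax_mm`).
#' @param size_range_n optional numeric(2): when given, tumor shape draws
#'   are conditioned (by per-patient rejection) on the baseline surface
#'   cloud at `spacing_mm` having a point count inside this range.
#' @param slab_mm inter-slice spacing of the generated contours.
#' @param spacing_mm default surface sampling distance carried in the config.
#' @param misregister when `TRUE`, each test scan is stored in a misaligned
#'   frame (random in-plane rotation + translation) together with the exact
#'   rigid transform back to baseline, to exercise transform plumbing.
#' @param seed mandatory integer seed; no implicit entropy.
#' @return class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_patients = 16L,
                          n_test_scans = 5L,
                          Sigma_true_mm = c(1.3, 1.7, 2.0),
                          sigma_true_mm = c(1.2, 2.1, 2.2),
                          gm_true_mm = c(0.5, -0.3, -0.3),
                          bump_amplitude_mm = 0,
                          bump_count = 0L,
                          bump_sigma_mm = 10,
                          bump_sign = c("mixed", "outward", "inward"),
                          rectum_length_mm = 150,
                          rectum_radius_mm = c(16, 25),
                          tumor_center_cax_mm = c(34, 80),
                          tumor_height_mm = c(30, 55),
                          tumor_extent_deg = c(160, 280),
                          tumor_thickness_mm = c(9, 17),
                          location_mix = NULL,
                          size_range_n = NULL,
                          slab_mm = 1.5,
                          spacing_mm = 1,
                          misregister = FALSE,
                          seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    pv_stop("cohort_config requires an explicit integer seed")
  bump_sign <- match.arg(bump_sign)
  viol <- character()
  for (nm in c("Sigma_true_mm", "sigma_true_mm", "gm_true_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)))
      viol <- c(viol, sprintf("%s must be numeric(3)", nm))
  }
  if (any(Sigma_true_mm < 0) || any(sigma_true_mm < 0))
    viol <- c(viol, "true SDs must be >= 0")
  if (bump_amplitude_mm < 0 || bump_count < 0 || bump_sigma_mm <= 0)
    viol <- c(viol, "bump parameters must be non-negative (sigma positive)")
  if (n_patients < 1L || n_test_scans < 2L)
    viol <- c(viol, "need >= 1 patient and >= 2 test scans")
  if (!is.null(location_mix) && sum(location_mix) != n_patients)
    viol <- c(viol, "location_mix must sum to n_patients")
  if (length(viol)) pv_validation_error(viol)
  structure(list(n_patients = as.integer(n_patients),
                 n_test_scans = as.integer(n_test_scans),
                 Sigma_true_mm = Sigma_true_mm, sigma_true_mm = sigma_true_mm,
                 gm_true_mm = gm_true_mm,
                 bump_amplitude_mm = bump_amplitude_mm,
                 bump_count = as.integer(bump_count),
                 bump_sigma_mm = bump_sigma_mm, bump_sign = bump_sign,
                 rectum_length_mm = rectum_length_mm,
                 rectum_radius_mm = rectum_radius_mm,
                 tumor_center_cax_mm = tumor_center_cax_mm,
                 tumor_height_mm = tumor_height_mm,
                 tumor_extent_deg = tumor_extent_deg,
                 tumor_thickness_mm = tumor_thickness_mm,
                 location_mix = location_mix, size_range_n = size_range_n,
                 slab_mm = slab_mm, spacing_mm = spacing_mm,
                 misregister = isTRUE(misregister),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# per-patient RNG stream: independent of cohort size and of other patients
patient_seed <- function(seed, patient_index) {
  as.integer((as.double(seed) + 7919 * patient_index) %% 2147483647)
}

# crescent cross-section polygon of the tumor at one slice.
# u in [0, 1] is the normalized height within the tumor; win() tapers the
# thickness towards the angular tips, wz() towards the cranio-caudal ends.
# An optional bump field displaces both arcs radially by the same amount per
# azimuth (so the local wall thickness is preserved), clamped so the inner
# arc cannot fold through the axis.
tumor_slice_polygon <- function(radius, theta_c_deg, extent_deg, thickness,
                                u, z = NULL, bumps = NULL, n_theta = 48L) {
  wz <- 0.25 + 0.75 * sin(pi * u)^0.7
  th <- seq(-extent_deg / 2, extent_deg / 2, length.out = n_theta)
  win <- 0.2 + 0.8 * cos(pi / 2 * th / (extent_deg / 2))
  w <- thickness * win * wz
  ang <- (theta_c_deg + th) * pi / 180
  ex <- sin(ang); ey <- -cos(ang)  # azimuth 0 = anterior (-y), +90 = left
  r_out <- radius + 0.25 * w
  r_in <- pmax(radius - w, 2)
  if (!is.null(bumps) && nrow(bumps) > 0L) {
    delta <- bump_displacement((theta_c_deg + th) %% 360, z, bumps, radius)
    delta <- pmax(delta, -(r_in - 1))
    r_out <- r_out + delta
    r_in <- r_in + delta
  }
  cbind(c(r_out * ex, rev(r_in * ex)),
        c(r_out * ey, rev(r_in * ey)))
}

# radial Gaussian bump field evaluated at azimuth theta (deg) and height z
bump_displacement <- function(theta_deg, z, bumps, radius) {
  if (is.null(bumps) || nrow(bumps) == 0L) return(rep(0, length(theta_deg)))
  delta <- rep(0, length(theta_deg))
  for (b in seq_len(nrow(bumps))) {
    dth <- (theta_deg - bumps$theta_deg[b] + 180) %% 360 - 180
    d2 <- (radius * dth * pi / 180)^2 + (z - bumps$z_mm[b])^2
    delta <- delta + bumps$sign[b] * bumps$amplitude_mm[b] *
      exp(-d2 / (2 * bumps$sigma_mm[b]^2))
  }
  delta
}

#' Generate one synthetic patient with known ground truth
#'
#' @param config a [cohort_config()].
#' @param patient_index 1-based patient number (fixes the RNG stream).
#' @return list with `record` (a validated [patient_record()]) and `truth`
#'   (systematic offset, per-scan random offsets, bump parameters).
#' @export
generate_patient <- function(config, patient_index) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(patient_seed(config$seed, patient_index))

  runifr <- function(r) stats::runif(1, r[1L], r[2L])
  band <- NULL
  if (!is.null(config$location_mix))
    band <- rep(names(config$location_mix), config$location_mix)[patient_index]

  draw_shape <- function() {
    radius <- runifr(config$rectum_radius_mm)
    center_cax <- switch(if (is.null(band)) "free" else band,
                         low = stats::runif(1, 28.5, 51),
                         mid = stats::runif(1, 52, 95),
                         high = stats::runif(1, 102, 125),
                         free = runifr(config$tumor_center_cax_mm))
    height <- runifr(config$tumor_height_mm)
    # keep the tumor inside the rectum's CAX span
    height <- min(height,
                  2 * (center_cax - config$slab_mm - 0.5),
                  2 * (config$rectum_length_mm - config$slab_mm - center_cax))
    list(radius = radius, center_cax = center_cax, height = height,
         extent = runifr(config$tumor_extent_deg),
         thickness = runifr(config$tumor_thickness_mm),
         theta_c = stats::runif(1, 0, 360))
  }
  shape_slices <- function(sh) {
    z0 <- sh$center_cax - sh$height / 2
    z1 <- sh$center_cax + sh$height / 2
    zs <- seq(z0, z1, by = config$slab_mm)
    us <- if (length(zs) > 1L) (zs - z0) / (z1 - z0) else 0.5
    list(zs = zs, us = us, z0 = z0, z1 = z1)
  }
  baseline_structure <- function(sh, sl) {
    structure_set("GTVp", lapply(seq_along(sl$zs), function(i) {
      v <- tumor_slice_polygon(sh$radius, sh$theta_c, sh$extent,
                               sh$thickness, sl$us[i])
      contour_slice(sl$zs[i], v)
    }))
  }

  sh <- draw_shape()
  sl <- shape_slices(sh)
  if (!is.null(config$size_range_n)) {
    # condition the shape draw on the sampled cloud size (preset contract)
    for (try in 1:40) {
      n <- nrow(sample_surface(baseline_structure(sh, sl),
                               config$spacing_mm)$points)
      if (n >= config$size_range_n[1L] && n <= config$size_range_n[2L]) break
      sh <- draw_shape()
      sl <- shape_slices(sh)
    }
  }
  radius <- sh$radius; center_cax <- sh$center_cax; height <- sh$height
  extent <- sh$extent; thickness <- sh$thickness; theta_c <- sh$theta_c
  z0 <- sl$z0; z1 <- sl$z1; zs <- sl$zs; us <- sl$us
  if (z0 < config$slab_mm || z1 > config$rectum_length_mm - config$slab_mm)
    pv_stop(sprintf("tumor z range [%.1f, %.1f] leaves the rectum CAX range [0, %g]",
                    z0, z1, config$rectum_length_mm))

  s_p <- stats::rnorm(3, 0, config$Sigma_true_mm)
  r_pk <- matrix(stats::rnorm(3 * config$n_test_scans, 0,
                              rep(config$sigma_true_mm, each = config$n_test_scans)),
                 config$n_test_scans, 3L)
  bumps <- NULL
  if (config$bump_count > 0L && config$bump_amplitude_mm > 0) {
    sgn <- switch(config$bump_sign,
                  outward = rep(1, config$bump_count),
                  inward = rep(-1, config$bump_count),
                  mixed = sample(c(-1, 1), config$bump_count, replace = TRUE))
    bumps <- data.frame(
      theta_deg = (theta_c + stats::runif(config$bump_count,
                                          -extent / 2, extent / 2)) %% 360,
      z_mm = stats::runif(config$bump_count, z0 + 2, z1 - 2),
      sign = sgn,
      amplitude_mm = rep(config$bump_amplitude_mm, config$bump_count),
      sigma_mm = rep(config$bump_sigma_mm, config$bump_count))
  }

  make_structure <- function(shift = c(0, 0, 0), bumped = FALSE) {
    slices <- lapply(seq_along(zs), function(i) {
      v <- tumor_slice_polygon(radius, theta_c, extent, thickness, us[i],
                               z = zs[i], bumps = if (bumped) bumps)
      contour_slice(zs[i] + shift[3L],
                    cbind(v[, 1L] + shift[1L], v[, 2L] + shift[2L]))
    })
    structure_set("GTVp", slices)
  }

  scans <- vector("list", config$n_test_scans + 1L)
  scans[[1L]] <- scan_record("scan1", 1L, "baseline",
                             rigid_transform(), make_structure())
  for (k in seq_len(config$n_test_scans)) {
    shift <- config$gm_true_mm + s_p + r_pk[k, ]
    gtvp <- make_structure(shift, bumped = TRUE)
    tr <- rigid_transform()
    if (config$misregister) {
      rz <- stats::runif(1, -3, 3)
      tt <- stats::runif(3, -5, 5)
      ctr <- c(0, 0, center_cax)
      # store the scan in its own (misaligned) frame; tr maps it back
      tr <- rigid_transform(c(0, 0, rz), tt, ctr)
      Rz <- rotation_matrix(c(0, 0, rz))
      inv <- rigid_transform(c(0, 0, -rz), -drop(t(Rz) %*% tt), ctr)
      gtvp <- structure_set("GTVp", lapply(gtvp$slices, function(sl) {
        p3 <- cbind(sl$vertices, sl$z_mm)
        q <- transform_points(p3, inv)
        contour_slice(q[1L, 3L], q[, 1:2])
      }))
    }
    scans[[k + 1L]] <- scan_record(paste0("scan", k + 1L), as.integer(k + 1L),
                                   "test", tr, gtvp)
  }

  centerline <- cbind(0, 0, seq(-5, config$rectum_length_mm, by = 5))
  # fewer than 6 scans is a deliberate design choice here, not a data defect
  rec <- suppressWarnings(
    patient_record(sprintf("P%03d", patient_index),
                   anal_verge_z_mm = 0, centerline = centerline,
                   scans = scans))
  list(record = rec,
       truth = list(patient_id = rec$patient_id,
                    systematic_mm = s_p, random_mm = r_pk,
                    bumps = bumps, radius_mm = radius,
                    center_cax_mm = center_cax, height_mm = height,
                    extent_deg = extent, thickness_mm = thickness,
                    band = band))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, one canonical JSON file
#'   per patient plus a `manifest.json` with all ground-truth draws and the
#'   analytic expected population errors are written there.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return class `synthetic_cohort`: list with `records`, `truth`, `config`
#'   and `expected` (GM = gm_true, Sigma -> Sigma_true, sigma -> sigma_true
#'   as n grows).
#' @export
generate_cohort <- function(config, dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
      pv_stop("output directory '", dir, "' is not empty; use overwrite = TRUE")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  gen <- lapply(seq_len(config$n_patients), generate_patient, config = config)
  records <- lapply(gen, `[[`, "record")
  truth <- lapply(gen, `[[`, "truth")
  expected <- list(gm_mm = config$gm_true_mm,
                   Sigma_mm = config$Sigma_true_mm,
                   sigma_mm = config$sigma_true_mm)
  cohort <- structure(list(records = records, truth = truth,
                           config = config, expected = expected),
                      class = "synthetic_cohort")
  if (!is.null(dir)) {
    for (i in seq_along(records))
      write_patient(records[[i]],
                    file.path(dir, sprintf("patient_%03d.json", i)))
    manifest <- list(
      config = unclass(config),
      expected_errors = expected,
      truth = lapply(truth, function(tr) {
        tr$random_mm <- unname(as.matrix(tr$random_mm))
        if (!is.null(tr$bumps)) tr$bumps <- as.list(tr$bumps)
        tr
      }))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 8L, null = "null")
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients x %d test scans, seed %d>\n",
              x$config$n_patients, x$config$n_test_scans, x$config$seed))
  invisible(x)
}

#' Study-like 16-patient preset
#'
#' Sixteen patients with six scans each, tumor location mix 13 low / 3 mid,
#' motion magnitudes of the order reported for rectal GTVp interfraction
#' variation, moderate local deformation, and tumor sizes calibrated so that
#' baseline clouds sampled at the default 1 mm spacing land in the
#' 7000-28000 point range of real delineations.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [cohort_config()].
#' @return a [generate_cohort()] result.
#' @export
make_study_like_cohort <- function(seed, ...) {
  args <- list(n_patients = 16L, n_test_scans = 5L,
               location_mix = c(low = 13L, mid = 3L),
               rectum_radius_mm = c(18, 28),
               tumor_height_mm = c(26, 55),
               tumor_extent_deg = c(150, 270),
               tumor_thickness_mm = c(9, 17),
               size_range_n = c(7200, 26500),
               bump_amplitude_mm = 2, bump_count = 3L, bump_sigma_mm = 8,
               seed = seed)
  args <- utils::modifyList(args, list(...))
  generate_cohort(do.call(cohort_config, args))
}
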