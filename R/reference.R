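# Reference-rectum mapping: project per-patient baseline surface statistics
# onto a common tubular reference anatomy indexed by central-axis (CAX)
# distance from the anal verge and azimuth, then form per-location
# inter-patient Sigma/sigma/GM maps and directional/height segment summaries.

#' Build the reference rectum surface
#'
#' A straight tube along +z with its caudal end at the anal verge (CAX 0).
#' Each slice carries `n_points` equidistant surface points; point k sits at
#' azimuth theta = k * 360 / n_points measured from anterior (-y),
#' counter-clockwise towards patient left (+x).
#'
#' @param length_mm tube length along the CAX; must cover at least 130 mm.
#' @param slice_spacing_mm distance between slices (default 1.5 mm, the
#'   study-like isotropic resolution).
#' @param radius_mm tube radius (default 15 mm; the true reference geometry
#'   is a configurable modelling choice).
#' @param n_points points per slice (120 unless overridden).
#' @return class `reference_rectum`: list with `points` (N x 3), `cax_mm`,
#'   `theta_deg`, `slice_cax`, and the constructor parameters.
#' @export
build_reference_rectum <- function(length_mm = 130, slice_spacing_mm = 1.5,
                                   radius_mm = 15, n_points = 120L) {
  if (length_mm <= 0 || slice_spacing_mm <= 0 || radius_mm <= 0 ||
      n_points <= 0)
    pv_stop("reference rectum dimensions must be positive")
  if (length_mm < 130)
    pv_stop("reference rectum must span at least 130 mm of CAX")
  slice_cax <- seq(0, by = slice_spacing_mm,
                   length.out = floor(length_mm / slice_spacing_mm) + 1L)
  theta <- (seq_len(n_points) - 1L) * 360 / n_points
  th <- theta * pi / 180
  ring <- cbind(radius_mm * sin(th), -radius_mm * cos(th))
  pts <- cbind(ring[rep(seq_len(n_points), times = length(slice_cax)), ],
               rep(slice_cax, each = n_points))
  dimnames(pts) <- list(NULL, c("x_mm", "y_mm", "z_mm"))
  structure(list(points = pts,
                 cax_mm = pts[, 3L],
                 theta_deg = rep(theta, times = length(slice_cax)),
                 slice_cax = slice_cax,
                 slice_spacing_mm = slice_spacing_mm,
                 radius_mm = radius_mm, n_points = as.integer(n_points)),
            class = "reference_rectum")
}

#' @export
print.reference_rectum <- function(x, ...) {
  cat(sprintf("<reference_rectum: %d slices x %d points, CAX 0..%g mm, radius %g mm>\n",
              length(x$slice_cax), x$n_points, max(x$slice_cax), x$radius_mm))
  invisible(x)
}

#' Directional and height section scheme
#'
#' Four directional halves, each a 180 degree window of 60 of the 120 slice
#' points, and three disjoint CAX height bands (mm from the anal verge).
#'
#' @param low,mid,high numeric(2) CAX intervals in mm.
#' @return class `section_scheme`.
#' @export
section_scheme <- function(low = c(28, 51), mid = c(52, 100),
                           high = c(102, 130)) {
  bands <- list(low = low, mid = mid, high = high)
  for (b in bands) stopifnot(length(b) == 2L, b[1L] < b[2L])
  if (low[2L] >= mid[1L] || mid[2L] >= high[1L])
    pv_stop("height bands must be disjoint and ordered low < mid < high")
  structure(list(bands = bands), class = "section_scheme")
}

# membership of azimuth theta (deg) in a directional half-window
theta_in_half <- function(theta_deg, half) {
  t <- theta_deg %% 360
  switch(half,
         anterior = t < 90 | t >= 270,
         posterior = t >= 90 & t < 270,
         left = t < 180,
         right = t >= 180,
         pv_stop("unknown directional half: ", half))
}

# arc-length CAX coordinate of 3-d points relative to a patient centerline;
# the origin is the centerline vertex nearest the anal verge z position
patient_cax <- function(patient, pts) {
  cl <- patient$centerline
  seg <- sqrt(rowSums((cl[-1L, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s0 <- cum[which.min(abs(cl[, 3L] - patient$anal_verge_z_mm))]
  foot <- cpp_nn_index(pts, cl)
  list(cax = cum[foot] - s0, foot = foot)
}

#' Map one patient's surface statistics onto the reference rectum
#'
#' Each baseline surface point receives a CAX coordinate (arc length along
#' the patient centerline from the anal verge to the point's nearest
#' centerline vertex), is re-expressed relative to the reference axis by
#' translating its centerline foot onto the axis at the same CAX, and is
#' then assigned to its nearest reference point (the reverse-assignment step
#' of the BLD construction, restricted to reference slices within the
#' patient's CAX range). Multiple patient points landing on one reference
#' point are averaged before any inter-patient statistic, so large tumors do
#' not dominate the variance.
#'
#' @param baseline_cloud the patient's baseline [sample_surface()] cloud.
#' @param stats the patient's [per_point_stats()].
#' @param patient the [patient_record()] (centerline and anal verge).
#' @param ref a [build_reference_rectum()] geometry.
#' @param subset optional logical/integer index of cloud points to map
#'   (used for the top/bottom-slice CC analysis).
#' @return class `reference_contribution`: data.frame with one row per
#'   occupied reference point: `ref_point_id`, `n_points`, and per direction
#'   `mean_*`/`sd_*` (mm).
#' @export
map_patient_to_reference <- function(baseline_cloud, stats, patient, ref,
                                     subset = NULL) {
  stopifnot(inherits(baseline_cloud, "surface_point_cloud"),
            inherits(stats, "per_point_stats"),
            inherits(patient, "patient_record"),
            inherits(ref, "reference_rectum"))
  pts <- baseline_cloud$points
  idx <- seq_len(nrow(pts))
  if (!is.null(subset)) idx <- idx[subset]
  pts <- pts[idx, , drop = FALSE]
  cx <- patient_cax(patient, pts)
  half <- ref$slice_spacing_mm / 2
  if (min(cx$cax) < min(ref$slice_cax) - half ||
      max(cx$cax) > max(ref$slice_cax) + half)
    pv_stop(sprintf("tumor CAX range [%.1f, %.1f] mm falls outside the reference range [%g, %g] mm",
                    min(cx$cax), max(cx$cax),
                    min(ref$slice_cax), max(ref$slice_cax)))
  # re-express relative to the reference axis
  q <- pts - patient$centerline[cx$foot, , drop = FALSE]
  q[, 3L] <- q[, 3L] + cx$cax
  keep_slice <- ref$slice_cax >= min(cx$cax) - half &
                ref$slice_cax <= max(cx$cax) + half
  ref_ok <- which(ref$cax_mm %in% ref$slice_cax[keep_slice])
  assigned <- ref_ok[cpp_nn_index(q, ref$points[ref_ok, , drop = FALSE])]
  g <- factor(assigned)
  agg <- function(v) as.vector(tapply(v, g, mean))
  out <- data.frame(ref_point_id = as.integer(levels(g)),
                    n_points = as.vector(table(g)))
  for (d in 1:3) {
    out[[paste0("mean_", DIRECTIONS[d])]] <- agg(stats$mean_mm[idx, d])
    out[[paste0("sd_", DIRECTIONS[d])]] <- agg(stats$sd_mm[idx, d])
  }
  class(out) <- c("reference_contribution", "data.frame")
  out
}

#' Aggregate per-patient contributions into an inter-patient reference map
#'
#' Per reference point and direction: GM = mean over patients of contributed
#' means, Sigma = sample SD over patients of contributed means, sigma = RMS
#' over patients of contributed SDs. Points with fewer than `min_patients`
#' contributing patients are flagged invalid and excluded from every segment
#' statistic.
#'
#' @param contributions list of `reference_contribution` data.frames, one
#'   per patient.
#' @param ref the [build_reference_rectum()] geometry.
#' @param min_patients validity threshold (default 5, matching the minimum
#'   overlapping-patient requirement for inter-patient variation).
#' @return class `reference_point_map`: data.frame with one row per occupied
#'   reference point: `ref_point_id`, `cax_mm`, `theta_deg`, `n_patients`,
#'   `valid`, and `Sigma_*`, `sigma_*`, `gm_*` per direction.
#' @export
aggregate_reference <- function(contributions, ref, min_patients = 5L) {
  if (!is.list(contributions) || length(contributions) == 0L)
    pv_stop("need >= 1 patient contribution")
  all_c <- do.call(rbind, lapply(seq_along(contributions), function(i) {
    ci <- as.data.frame(contributions[[i]])
    ci$patient <- i
    ci
  }))
  g <- factor(all_c$ref_point_id)
  ids <- as.integer(levels(g))
  n_pat <- as.vector(tapply(all_c$patient, g, function(v) length(unique(v))))
  out <- data.frame(ref_point_id = ids,
                    cax_mm = ref$cax_mm[ids],
                    theta_deg = ref$theta_deg[ids],
                    n_patients = n_pat,
                    valid = n_pat >= min_patients)
  for (d in DIRECTIONS) {
    mu <- all_c[[paste0("mean_", d)]]
    sdv <- all_c[[paste0("sd_", d)]]
    out[[paste0("gm_", d)]] <- as.vector(tapply(mu, g, mean))
    out[[paste0("Sigma_", d)]] <- as.vector(tapply(mu, g, function(v)
      if (length(v) >= 2L) stats::sd(v) else NA_real_))
    out[[paste0("sigma_", d)]] <- as.vector(tapply(sdv, g, function(v)
      sqrt(mean(v^2))))
  }
  attr(out, "min_patients") <- as.integer(min_patients)
  class(out) <- c("reference_point_map", "data.frame")
  out
}

summarise_segment_values <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(c(median = NA_real_, iqr = NA_real_, p95 = NA_real_))
  c(median = percentile(v, 50), iqr = percentile(v, 75) - percentile(v, 25),
    p95 = percentile(v, 95))
}

segment_row <- function(map_rows, direction, band, component) {
  row <- data.frame(direction = direction, band = band,
                    n_points = nrow(map_rows))
  for (q in c("Sigma", "sigma", "gm")) {
    s <- summarise_segment_values(map_rows[[paste0(q, "_", component)]])
    row[[paste0("median_", q, "_mm")]] <- s[["median"]]
    row[[paste0("iqr_", q, "_mm")]] <- s[["iqr"]]
    row[[paste0("p95_", q, "_mm")]] <- s[["p95"]]
  }
  row
}

#' Directional/height segment summaries of a reference map
#'
#' For each directional half (anterior, posterior, left, right; RL values
#' for left/right, AP values for anterior/posterior) crossed with each CAX
#' height band, computes median, IQR and 95th percentile of the per-point
#' Sigma, sigma and GM over the segment's valid reference points.
#'
#' @param map a [aggregate_reference()] result.
#' @param scheme a [section_scheme()].
#' @return class `segment_summaries`: one data.frame row per
#'   direction x band; segments without valid points carry `NA` statistics
#'   (with a warning).
#' @export
segment_summary <- function(map, scheme = section_scheme()) {
  stopifnot(inherits(map, "reference_point_map"),
            inherits(scheme, "section_scheme"))
  ok <- map[map$valid, , drop = FALSE]
  rows <- list()
  for (half in c("anterior", "posterior", "right", "left")) {
    comp <- if (half %in% c("left", "right")) "rl" else "ap"
    for (band in names(scheme$bands)) {
      b <- scheme$bands[[band]]
      sel <- ok[theta_in_half(ok$theta_deg, half) &
                ok$cax_mm >= b[1L] & ok$cax_mm <= b[2L], , drop = FALSE]
      if (nrow(sel) == 0L)
        warning(sprintf("segment %s/%s has no valid reference points", half, band))
      rows[[paste(half, band)]] <- segment_row(sel, half, band, comp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("segment_summaries", "data.frame")
  out
}

#' Cranial/caudal analysis of the tumor end slices
#'
#' Only the top and bottom slices of each baseline tumor carry meaningful CC
#' surface information, so the CC direction is analysed there: top-slice
#' (cranial) and bottom-slice (caudal) points are mapped onto the reference
#' rectum like the in-plane analysis, aggregated across patients, and
#' summarised as median/IQR/p95 of the per-point Sigma/sigma/GM over valid
#' reference points. Per-patient cranial/caudal means and SDs (averages of
#' the slice's per-point statistics) are returned alongside.
#'
#' @param analyses list with one element per patient, each a list with
#'   `cloud` (baseline cloud), `stats` ([per_point_stats()]) and `patient`
#'   (the [patient_record()]).
#' @param ref a [build_reference_rectum()] geometry.
#' @param min_patients validity threshold for reference points.
#' @return list with `segments` (two `segment_summaries` rows: cranial,
#'   caudal), `patient_cranial` / `patient_caudal` (per-patient data.frames)
#'   and the two underlying `reference_point_map`s.
#' @export
cc_extremes <- function(analyses, ref, min_patients = 5L) {
  per_end <- function(end) {
    contribs <- list()
    pat <- data.frame(patient_id = character(0), mean_cc_mm = numeric(0),
                      sd_cc_mm = numeric(0), n_points = integer(0))
    for (a in analyses) {
      zr <- a$cloud$z_range
      sel <- a$cloud$point_z == (if (end == "cranial") zr[2L] else zr[1L])
      contribs[[length(contribs) + 1L]] <-
        map_patient_to_reference(a$cloud, a$stats, a$patient, ref, subset = sel)
      pat <- rbind(pat, data.frame(
        patient_id = a$patient$patient_id,
        mean_cc_mm = mean(a$stats$mean_mm[sel, 3L]),
        sd_cc_mm = mean(a$stats$sd_mm[sel, 3L]),
        n_points = sum(sel)))
    }
    map <- aggregate_reference(contribs, ref, min_patients)
    ok <- map[map$valid, , drop = FALSE]
    if (nrow(ok) == 0L)
      warning(sprintf("%s segment has no valid reference points", end))
    list(map = map, patient = pat,
         row = segment_row(ok, end, "none", "cc"))
  }
  cranial <- per_end("cranial")
  caudal <- per_end("caudal")
  segs <- rbind(cranial$row, caudal$row)
  class(segs) <- c("segment_summaries", "data.frame")
  list(segments = segs,
       patient_cranial = cranial$patient, patient_caudal = caudal$patient,
       map_cranial = cranial$map, map_caudal = caudal$map)
}
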