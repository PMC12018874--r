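#' @useDynLib rectvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention (fixed for the whole package): patient LPS frame,
# +x = patient left, +y = posterior, +z = cranial.  All lengths in mm, all
# angles in degrees.

pv_stop <- function(..., class = "rectvar_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

pv_validation_error <- function(violations) {
  pv_stop("validation failed:\n", paste0("  - ", violations, collapse = "\n"),
          class = c("rectvar_validation_error", "rectvar_error"))
}

#' Planar contour slice
#'
#' One closed planar contour of a delineated structure at a fixed axial
#' position. Vertices are stored open (last vertex differs from the first;
#' closure is implicit) and orientation is normalized to counter-clockwise
#' in the (x, y) plane, i.e. positive shoelace area.
#'
#' @param z_mm axial position (mm, patient frame, +z cranial).
#' @param vertices numeric matrix with columns (x_mm, y_mm); at least 3 rows;
#'   the polygon must be simple (non-self-intersecting).
#' @return an object of class `contour_slice`.
#' @export
contour_slice <- function(z_mm, vertices) {
  vertices <- as.matrix(vertices)
  viol <- character()
  if (!is.numeric(z_mm) || length(z_mm) != 1L || !is.finite(z_mm))
    viol <- c(viol, "z_mm must be a single finite number")
  if (ncol(vertices) != 2L)
    viol <- c(viol, "vertices must have two columns (x_mm, y_mm)")
  if (!all(is.finite(vertices)))
    viol <- c(viol, "vertices contain non-finite coordinates")
  if (length(viol)) pv_validation_error(viol)
  # drop an explicit closing vertex if present
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1L, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L)
    viol <- c(viol, "contour needs at least 3 distinct vertices")
  if (!length(viol) && !cpp_polygon_is_simple(vertices[, 1L], vertices[, 2L]))
    viol <- c(viol, sprintf("contour at z = %g is not a simple polygon", z_mm))
  if (length(viol)) pv_validation_error(viol)
  if (polygon_area_signed(vertices) < 0)
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  dimnames(vertices) <- list(NULL, c("x_mm", "y_mm"))
  structure(list(z_mm = as.numeric(z_mm), vertices = vertices),
            class = "contour_slice")
}

# signed shoelace area; > 0 for counter-clockwise vertex order
polygon_area_signed <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

polygon_perimeter <- function(v) {
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(sqrt((v[j, 1L] - v[, 1L])^2 + (v[j, 2L] - v[, 2L])^2))
}

#' Delineated structure as a stack of contour slices
#'
#' @param name structure label, e.g. `"GTVp"`.
#' @param slices list of [contour_slice()] objects; slice z positions must be
#'   strictly increasing with constant spacing (to 1e-6 mm; the motivating
#'   study used isotropic 1.5 mm resolution). A single slice is allowed.
#' @return an object of class `structure_set` with attribute `slab_mm`
#'   (inter-slice spacing; `NA` for a single slice).
#' @export
structure_set <- function(name, slices) {
  viol <- character()
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    viol <- c(viol, "name must be a non-empty string")
  if (!is.list(slices) || length(slices) == 0L)
    viol <- c(viol, "slices must be a non-empty list of contour_slice")
  else if (!all(vapply(slices, inherits, logical(1), "contour_slice")))
    viol <- c(viol, "all slices must be contour_slice objects")
  if (length(viol)) pv_validation_error(viol)
  z <- vapply(slices, `[[`, numeric(1), "z_mm")
  if (is.unsorted(z, strictly = TRUE))
    viol <- c(viol, "slice z positions must be strictly increasing")
  slab <- NA_real_
  if (length(z) >= 2L) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-6)
      viol <- c(viol, "inter-slice spacing is not constant (tolerance 1e-6 mm)")
    slab <- dz[1L]
  }
  if (length(viol)) pv_validation_error(viol)
  structure(list(name = name, slices = slices),
            class = "structure_set", slab_mm = slab)
}

structure_z <- function(s) vapply(s$slices, `[[`, numeric(1), "z_mm")

structure_slab <- function(s, default = 1.5) {
  slab <- attr(s, "slab_mm")
  if (is.na(slab)) default else slab
}

#' @export
print.structure_set <- function(x, ...) {
  z <- structure_z(x)
  cat(sprintf("<structure_set '%s': %d slices, z %.1f..%.1f mm, slab %s mm>\n",
              x$name, length(x$slices), min(z), max(z),
              format(attr(x, "slab_mm"))))
  invisible(x)
}

#' Rigid transform (rotation about a center, then translation)
#'
#' Points map as `p -> R (p - c) + c + t` with `R = Rz Ry Rx` (intrinsic
#' rotation applied in the order rx, ry, rz), angles in degrees.
#'
#' @param rotation_deg numeric(3) Euler angles (rx, ry, rz) in degrees; each
#'   must satisfy |angle| <= 10 (the motivating setting corrects bony-anatomy
#'   rotations of up to about 3 degrees).
#' @param translation_mm numeric(3) translation (tx, ty, tz) in mm.
#' @param center_mm numeric(3) rotation center in mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  viol <- character()
  for (nm in c("rotation_deg", "translation_mm", "center_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)))
      viol <- c(viol, sprintf("%s must be numeric(3) and finite", nm))
  }
  if (!length(viol) && any(abs(rotation_deg) > 10))
    viol <- c(viol, "|rotation_deg| must be <= 10 degrees")
  if (length(viol)) pv_validation_error(viol)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

is_identity_transform <- function(tr) {
  all(tr$rotation_deg == 0) && all(tr$translation_mm == 0)
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' One imaging time point of a patient
#'
#' @param scan_id scan identifier string.
#' @param timepoint integer 1..6.
#' @param role `"baseline"` or `"test"`.
#' @param transform_to_baseline [rigid_transform()] mapping this scan's frame
#'   onto the baseline frame (identity for the baseline scan).
#' @param gtvp [structure_set()] with the delineated primary tumor.
#' @return an object of class `scan_record`.
#' @export
scan_record <- function(scan_id, timepoint, role,
                        transform_to_baseline = rigid_transform(),
                        gtvp) {
  viol <- character()
  if (!is.character(scan_id) || length(scan_id) != 1L)
    viol <- c(viol, "scan_id must be a string")
  if (!is.numeric(timepoint) || length(timepoint) != 1L ||
      timepoint != round(timepoint) || timepoint < 1 || timepoint > 6)
    viol <- c(viol, "timepoint must be an integer in 1..6")
  if (!is.character(role) || length(role) != 1L ||
      !role %in% c("baseline", "test"))
    viol <- c(viol, "role must be 'baseline' or 'test'")
  if (!inherits(transform_to_baseline, "rigid_transform"))
    viol <- c(viol, "transform_to_baseline must be a rigid_transform")
  if (!inherits(gtvp, "structure_set"))
    viol <- c(viol, "gtvp must be a structure_set")
  if (length(viol)) pv_validation_error(viol)
  structure(list(scan_id = scan_id, timepoint = as.integer(timepoint),
                 role = role, transform_to_baseline = transform_to_baseline,
                 gtvp = gtvp),
            class = "scan_record")
}

#' Patient record: six scans, anal verge and rectal centerline
#'
#' @param patient_id patient identifier string.
#' @param anal_verge_z_mm axial position (mm) of the anal verge; central-axis
#'   (CAX) distances are measured from here along the centerline.
#' @param centerline numeric matrix (>= 2 x 3) of ordered 3-d points
#'   approximating the rectal central axis, starting at (or passing through)
#'   the anal verge; its z range must cover the union of all GTVp z ranges.
#' @param scans list of [scan_record()]; exactly one baseline, unique
#'   timepoints. Fewer than 6 scans is tolerated with a warning and the
#'   record flagged `incomplete`, but at least 2 test scans are required
#'   downstream for any SD.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, anal_verge_z_mm, centerline, scans) {
  centerline <- as.matrix(centerline)
  viol <- character()
  if (!is.character(patient_id) || length(patient_id) != 1L)
    viol <- c(viol, "patient_id must be a string")
  if (!is.numeric(anal_verge_z_mm) || length(anal_verge_z_mm) != 1L ||
      !is.finite(anal_verge_z_mm))
    viol <- c(viol, "anal_verge_z_mm must be a single finite number")
  if (ncol(centerline) != 3L || nrow(centerline) < 2L ||
      !all(is.finite(centerline)))
    viol <- c(viol, "centerline must be a finite numeric matrix with 3 columns and >= 2 rows")
  if (!is.list(scans) || length(scans) < 1L ||
      !all(vapply(scans, inherits, logical(1), "scan_record")))
    viol <- c(viol, "scans must be a list of scan_record objects")
  if (length(viol)) pv_validation_error(viol)

  roles <- vapply(scans, `[[`, character(1), "role")
  if (sum(roles == "baseline") > 1L) viol <- c(viol, "multiple baselines")
  if (sum(roles == "baseline") == 0L) viol <- c(viol, "no baseline scan")
  tps <- vapply(scans, `[[`, integer(1), "timepoint")
  if (anyDuplicated(tps)) viol <- c(viol, "duplicated timepoints")
  zr <- range(unlist(lapply(scans, function(s) structure_z(s$gtvp))))
  if (!length(viol)) {
    cz <- range(centerline[, 3L])
    if (zr[1L] < cz[1L] - 1e-9 || zr[2L] > cz[2L] + 1e-9)
      viol <- c(viol, sprintf(
        "centerline z range [%.3f, %.3f] does not cover GTVp z range [%.3f, %.3f]",
        cz[1L], cz[2L], zr[1L], zr[2L]))
  }
  if (length(viol)) pv_validation_error(viol)

  incomplete <- length(scans) < 6L
  if (incomplete)
    warning(sprintf("patient '%s' has %d scans (expected 6); statistics will use n_test = %d",
                    patient_id, length(scans), length(scans) - 1L))
  scans <- scans[order(tps)]
  structure(list(patient_id = patient_id,
                 anal_verge_z_mm = as.numeric(anal_verge_z_mm),
                 centerline = centerline, scans = scans),
            class = "patient_record", incomplete = incomplete)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record '%s': %d scans, anal verge z = %.1f mm%s>\n",
              x$patient_id, length(x$scans), x$anal_verge_z_mm,
              if (isTRUE(attr(x, "incomplete"))) ", INCOMPLETE" else ""))
  invisible(x)
}

baseline_scan <- function(patient) {
  patient$scans[[which(vapply(patient$scans, `[[`, character(1), "role") == "baseline")]]
}

test_scans <- function(patient) {
  patient$scans[vapply(patient$scans, `[[`, character(1), "role") == "test"]
}
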