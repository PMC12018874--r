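# Bidirectional local distance (BLD) displacement fields.
#
# For each baseline surface point b the algorithm (1) finds the nearest test
# point to b, (2) finds every test point whose nearest baseline point is b,
# and (3) takes, among these candidates, the point at the LARGEST distance as
# the mapped point. The construction is robust to complex local deformation:
# it cannot report a small displacement for a baseline point that "owns" a
# far-away patch of the test surface. All nearest-neighbour and argmax ties
# resolve to the smallest point index, making results machine-exact and
# oracle-comparable.

cloud_points <- function(x) {
  if (inherits(x, "surface_point_cloud")) x$points else as.matrix(x)
}

cloud_id <- function(x) {
  if (inherits(x, "surface_point_cloud")) x$source_scan_id else NULL
}

new_displacement_field <- function(baseline_pts, test_pts, mapped_idx, bld_mm,
                                   baseline_scan_id, test_scan_id) {
  mapped <- test_pts[mapped_idx, , drop = FALSE]
  vec <- mapped - baseline_pts
  dimnames(vec) <- list(NULL, c("dx_mm", "dy_mm", "dz_mm"))
  structure(list(baseline_scan_id = baseline_scan_id,
                 test_scan_id = test_scan_id,
                 baseline_points = baseline_pts,
                 mapped_idx = mapped_idx,
                 mapped_point = mapped,
                 bld_mm = bld_mm,
                 vector_mm = vec,
                 signed_mm = NULL),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field: %d baseline points, bld median %.2f mm, max %.2f mm%s>\n",
              length(x$bld_mm), stats::median(x$bld_mm), max(x$bld_mm),
              if (is.null(x$signed_mm)) " (unsigned)" else ""))
  invisible(x)
}

#' BLD displacement field between two surface point clouds
#'
#' Accelerated (k-d tree) implementation; exactly equal to
#' [bld_brute_force()] under the shared smallest-index tie rule.
#'
#' @param baseline,test surface point clouds ([sample_surface()]) or plain
#'   N x 3 matrices, both in the baseline frame.
#' @return an object of class `displacement_field` with, per baseline point,
#'   the mapped test point, the non-negative BLD length `bld_mm` and the
#'   displacement `vector_mm` (mapped - baseline). Signed components are
#'   filled in by [sign_components()].
#' @export
bld_map <- function(baseline, test) {
  b <- cloud_points(baseline); t_ <- cloud_points(test)
  if (nrow(b) == 0L || nrow(t_) == 0L) pv_stop("empty point cloud")
  res <- cpp_bld_map(b, t_)
  new_displacement_field(b, t_, res$mapped_idx, res$bld_mm,
                         cloud_id(baseline), cloud_id(test))
}

#' Brute-force BLD oracle
#'
#' Exhaustive O(N*M) distance-matrix implementation of the identical
#' contract; exists as an independent correctness reference for
#' [bld_map()] and refuses problems with N*M > 1e7.
#'
#' @inheritParams bld_map
#' @return a `displacement_field`, identical to [bld_map()]'s output.
#' @export
bld_brute_force <- function(baseline, test) {
  b <- cloud_points(baseline); t_ <- cloud_points(test)
  if (nrow(b) == 0L || nrow(t_) == 0L) pv_stop("empty point cloud")
  if (as.double(nrow(b)) * nrow(t_) > 1e7)
    pv_stop("bld_brute_force refuses N*M > 1e7; use bld_map()")
  dx <- outer(b[, 1L], t_[, 1L], `-`)
  dy <- outer(b[, 2L], t_[, 2L], `-`)
  dz <- outer(b[, 3L], t_[, 3L], `-`)
  D2 <- dx * dx
  D2 <- D2 + dy * dy
  D2 <- D2 + dz * dz
  fwd <- apply(D2, 1L, which.min)          # first minimum = smallest index
  owner <- apply(D2, 2L, which.min)
  n <- nrow(b)
  mapped <- integer(n)
  bld <- numeric(n)
  rev_sets <- split(seq_len(ncol(D2)), factor(owner, levels = seq_len(n)))
  for (i in seq_len(n)) {
    cand <- sort(unique(c(fwd[i], rev_sets[[i]])))
    k <- which.max(D2[i, cand])            # first maximum = smallest index
    mapped[i] <- cand[k]
    bld[i] <- sqrt(D2[i, mapped[i]])
  }
  new_displacement_field(b, t_, mapped, bld, cloud_id(baseline), cloud_id(test))
}

#' Sign the directional components of a displacement field
#'
#' The in-plane (RL, AP) components receive a common sign: positive when the
#' mapped point lies outside the baseline structure (tissue moved out),
#' negative when it moved in. The CC sign marks displacement away from the
#' baseline COM plane as outward/positive: `dz >= 0` for baseline points at
#' or above the COM, `dz < 0` for points below.
#'
#' @param field an unsigned `displacement_field` from [bld_map()].
#' @param baseline_structure the baseline [structure_set()].
#' @param baseline_com the baseline [center_of_mass()]; computed from
#'   `baseline_structure` when omitted.
#' @return the field with `signed_mm` filled: an N x 3 matrix with columns
#'   `rl_mm`, `ap_mm`, `cc_mm`.
#' @export
sign_components <- function(field, baseline_structure,
                            baseline_com = center_of_mass(baseline_structure)) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(baseline_structure, "structure_set"))
  v <- field$vector_mm
  s_in <- ifelse(point_inside_many(baseline_structure, field$mapped_point), -1, 1)
  zb <- field$baseline_points[, 3L]
  outward_z <- (v[, 3L] >= 0 & zb >= baseline_com[3L]) |
               (v[, 3L] < 0 & zb < baseline_com[3L])
  signed <- cbind(rl_mm = s_in * abs(v[, 1L]),
                  ap_mm = s_in * abs(v[, 2L]),
                  cc_mm = ifelse(outward_z, 1, -1) * abs(v[, 3L]))
  field$signed_mm <- signed
  field
}

#' Center-of-mass displacement between baseline and a test scan
#'
#' @param baseline_com,test_com [center_of_mass()] results, both in the
#'   baseline frame.
#' @param test_scan_id optional identifier carried in the result.
#' @return class `com_displacement`: named numeric(3) `(rl, ap, cc)` in mm,
#'   positive towards patient left / posterior / cranial.
#' @export
com_displacement <- function(baseline_com, test_com, test_scan_id = NULL) {
  stopifnot(inherits(baseline_com, "com"), inherits(test_com, "com"))
  d <- unclass(test_com) - unclass(baseline_com)
  structure(c(rl_mm = unname(d[1L]), ap_mm = unname(d[2L]),
              cc_mm = unname(d[3L])),
            class = "com_displacement", test_scan_id = test_scan_id)
}

#' Per-point displacement table
#'
#' @param x a `displacement_field`.
#' @param row.names,optional,... passed over from the generic, unused.
#' @return a data.frame with one row per baseline point: coordinates, BLD
#'   length, raw vector and (when present) signed components.
#' @export
as.data.frame.displacement_field <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  out <- data.frame(baseline_point_id = seq_along(x$bld_mm),
                    x_mm = x$baseline_points[, 1L],
                    y_mm = x$baseline_points[, 2L],
                    z_mm = x$baseline_points[, 3L],
                    test_scan_id = if (is.null(x$test_scan_id)) NA_character_
                                   else x$test_scan_id,
                    bld_mm = x$bld_mm,
                    dx_mm = x$vector_mm[, 1L],
                    dy_mm = x$vector_mm[, 2L],
                    dz_mm = x$vector_mm[, 3L])
  if (!is.null(x$signed_mm)) {
    out$signed_rl_mm <- x$signed_mm[, 1L]
    out$signed_ap_mm <- x$signed_mm[, 2L]
    out$signed_cc_mm <- x$signed_mm[, 3L]
  }
  out
}
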