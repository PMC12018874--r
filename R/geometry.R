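# Surface geometry: contour stacks -> dense surface point clouds, volume
# centroids, rigid transforms and point containment.

# resample a closed polygon (open vertex list) at n uniform arc-length steps,
# starting at vertex 1
resample_closed <- function(v, n) {
  m <- nrow(v)
  vc <- rbind(v, v[1L, , drop = FALSE])
  seg <- sqrt(diff(vc[, 1L])^2 + diff(vc[, 2L])^2)
  cum <- c(0, cumsum(seg))
  P <- cum[m + 1L]
  s <- (seq_len(n) - 1L) * P / n
  x <- stats::approx(cum, vc[, 1L], xout = s)$y
  y <- stats::approx(cum, vc[, 2L], xout = s)$y
  cbind(x, y)
}

#' Sample the closed surface of a contour stack as a 3-d point cloud
#'
#' Each contour is resampled uniformly in arc length, with a per-slice point
#' budget proportional to the local lateral surface area (a frustum slant
#' correction from the slice-to-slice change of effective radius), so the
#' total point count scales as surface area / spacing^2 and the arc step
#' never exceeds `spacing_mm`. The top and bottom slices are additionally
#' filled with an interior grid at `spacing_mm` (end caps), so cranio-caudal
#' displacements at the tumor ends are represented.
#'
#' At the study-like tumor size the default 1 mm spacing yields clouds in the
#' 7000-28000 point range reported for real delineations.
#'
#' @param structure a [structure_set()].
#' @param spacing_mm target sampling distance (mm), > 0; must not exceed any
#'   contour perimeter.
#' @param scan_id optional source scan identifier stored on the cloud.
#' @return an object of class `surface_point_cloud`: a list with `points`
#'   (N x 3 matrix, mm), `source_scan_id`, `nominal_spacing_mm`, `slab_mm`,
#'   `point_z` (slice z per point), `is_cap`, and `z_range`.
#' @export
sample_surface <- function(structure, spacing_mm = 1, scan_id = NULL) {
  stopifnot(inherits(structure, "structure_set"))
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    pv_stop("spacing_mm must be a positive length")
  z <- structure_z(structure)
  ns <- length(z)
  slab <- if (ns >= 2L) z[2L] - z[1L] else spacing_mm
  verts <- lapply(structure$slices, `[[`, "vertices")
  P <- vapply(verts, polygon_perimeter, numeric(1))
  if (any(spacing_mm > P))
    pv_stop(sprintf("undersampled contour: spacing %g mm exceeds the smallest contour perimeter (%g mm)",
                    spacing_mm, min(P)))
  a <- vapply(verts, function(v) abs(polygon_area_signed(v)), numeric(1))
  reff <- sqrt(a / pi)
  slant <- rep(1, ns)
  if (ns >= 2L) {
    drdz <- numeric(ns)
    drdz[1L] <- (reff[2L] - reff[1L]) / slab
    drdz[ns] <- (reff[ns] - reff[ns - 1L]) / slab
    if (ns >= 3L) {
      mid <- 2L:(ns - 1L)
      drdz[mid] <- (reff[mid + 1L] - reff[mid - 1L]) / (2 * slab)
    }
    slant <- sqrt(1 + drdz^2)
  }
  n_i <- pmax(ceiling(P / spacing_mm),
              ceiling(P * slant * slab / spacing_mm^2), 3L)

  ring_pts <- vector("list", ns)
  for (i in seq_len(ns)) {
    xy <- resample_closed(verts[[i]], n_i[i])
    ring_pts[[i]] <- cbind(xy, z[i])
  }
  caps <- lapply(unique(c(1L, ns)), function(i) {
    v <- verts[[i]]
    gx <- seq(min(v[, 1L]) + spacing_mm / 2, max(v[, 1L]), by = spacing_mm)
    gy <- seq(min(v[, 2L]) + spacing_mm / 2, max(v[, 2L]), by = spacing_mm)
    if (!length(gx) || !length(gy)) return(NULL)
    g <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    keep <- cpp_points_in_polygon(g[, 1L], g[, 2L], v[, 1L], v[, 2L])
    if (!any(keep)) return(NULL)
    cbind(g[keep, , drop = FALSE], z[i])
  })
  caps <- caps[!vapply(caps, is.null, logical(1))]
  pts <- do.call(rbind, c(ring_pts, caps))
  point_z <- pts[, 3L]
  is_cap <- c(rep(FALSE, sum(n_i)), rep(TRUE, nrow(pts) - sum(n_i)))
  dup <- duplicated(round(pts * 1e9))
  if (any(dup)) {
    pts <- pts[!dup, , drop = FALSE]
    point_z <- point_z[!dup]
    is_cap <- is_cap[!dup]
  }
  dimnames(pts) <- list(NULL, c("x_mm", "y_mm", "z_mm"))
  structure(list(points = pts, source_scan_id = scan_id,
                 nominal_spacing_mm = spacing_mm, slab_mm = slab,
                 point_z = point_z, is_cap = is_cap,
                 z_range = range(z)),
            class = "surface_point_cloud")
}

#' @export
print.surface_point_cloud <- function(x, ...) {
  cat(sprintf("<surface_point_cloud: %d points, spacing %g mm%s>\n",
              nrow(x$points), x$nominal_spacing_mm,
              if (is.null(x$source_scan_id)) "" else
                paste0(", scan ", x$source_scan_id)))
  invisible(x)
}

#' Volume centroid (center of mass) of a contour stack
#'
#' Slice-wise polygon areas and centroids by the shoelace formulas; the
#' volume centroid weights each slice centroid by area x slab thickness,
#' with the slice z contributing at its own axial position.
#'
#' @param structure a [structure_set()].
#' @return an object of class `com`: a named numeric(3) (x, y, z) in mm.
#' @export
center_of_mass <- function(structure) {
  stopifnot(inherits(structure, "structure_set"))
  verts <- lapply(structure$slices, `[[`, "vertices")
  a <- vapply(verts, function(v) abs(polygon_area_signed(v)), numeric(1))
  if (all(a <= 1e-12))
    pv_stop("degenerate structure: all slice areas are zero")
  cxy <- t(vapply(verts, polygon_centroid, numeric(2)))
  z <- structure_z(structure)
  w <- a / sum(a)  # constant slab thickness cancels
  structure(c(x_mm = sum(w * cxy[, 1L]), y_mm = sum(w * cxy[, 2L]),
              z_mm = sum(w * z)),
            class = "com")
}

#' @export
print.com <- function(x, ...) {
  cat(sprintf("<com: (%.3f, %.3f, %.3f) mm>\n", x[1L], x[2L], x[3L]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' Maps `p -> R (p - c) + c + t`; pairwise distances are preserved.
#'
#' @param points an N x 3 numeric matrix, a numeric(3), a
#'   `surface_point_cloud`, or a `com`.
#' @param transform a [rigid_transform()].
#' @return the transformed object, same type as the input.
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(points, "surface_point_cloud")) {
    points$points[] <- transform_points(points$points, transform)
    points$point_z <- points$points[, 3L]
    points$z_range <- range(points$point_z)
    return(points)
  }
  if (inherits(points, "com")) {
    out <- transform_points(matrix(unclass(points), 1L, 3L), transform)
    return(structure(c(x_mm = out[1L], y_mm = out[2L], z_mm = out[3L]),
                     class = "com"))
  }
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1L, 3L) else as.matrix(points)
  if (is_identity_transform(transform)) return(if (vec) points else p)
  R <- rotation_matrix(transform$rotation_deg)
  cc <- transform$center_mm
  tt <- transform$translation_mm
  out <- sweep(p, 2L, cc) %*% t(R)
  out <- sweep(out, 2L, cc + tt, `+`)
  dimnames(out) <- dimnames(p)
  if (vec) drop(out) else out
}

# vectorized containment: queries is N x 3; boundary points are outside.
# z acceptance window extends slab/2 beyond the end slices.
point_inside_many <- function(structure, queries) {
  q <- as.matrix(queries)
  z <- structure_z(structure)
  slab <- structure_slab(structure)
  res <- logical(nrow(q))
  inz <- q[, 3L] >= z[1L] - slab / 2 & q[, 3L] <= z[length(z)] + slab / 2
  if (!any(inz)) return(res)
  nearest <- pmin(pmax(round((q[, 3L] - z[1L]) / if (length(z) > 1L) slab else 1) + 1L, 1L),
                  length(z))
  for (i in unique(nearest[inz])) {
    sel <- inz & nearest == i
    v <- structure$slices[[i]]$vertices
    res[sel] <- cpp_points_in_polygon(q[sel, 1L], q[sel, 2L], v[, 1L], v[, 2L])
  }
  res
}

#' Test whether a point lies inside a structure
#'
#' True iff the query z is within half a slab of the structure's z range and
#' the (x, y) projection lies strictly inside the contour polygon of the
#' nearest slice. Points exactly on the boundary classify as outside (the
#' sign of a zero-length displacement is numerically irrelevant).
#'
#' @param structure a [structure_set()].
#' @param query numeric(3) point or an N x 3 matrix of points (mm).
#' @return logical vector, one element per query point.
#' @export
point_inside <- function(structure, query) {
  stopifnot(inherits(structure, "structure_set"))
  if (is.null(dim(query))) query <- matrix(query, ncol = 3L)
  point_inside_many(structure, query)
}
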