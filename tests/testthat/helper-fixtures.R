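# Fixture builders and independent oracles, all generated in code.

# axis-aligned square contour stack
make_square_structure <- function(side = 20, center = c(0, 0),
                                  zs = seq(0, 4, by = 1), name = "sq") {
  h <- side / 2
  v <- cbind(center[1] + c(-h, h, h, -h), center[2] + c(-h, -h, h, h))
  structure_set(name, lapply(zs, contour_slice, vertices = v))
}

# sphere discretized on a z grid that avoids an equatorial slice
make_sphere_structure <- function(r = 10, center = c(0, 0, 0), slab = 1.5,
                                  n_theta = 180, name = "sphere") {
  zs <- seq(-(floor((r - 0.2) / slab) + 0.5) * slab,
            (floor((r - 0.2) / slab) + 0.5) * slab, by = slab) + slab / 2
  zs <- zs[abs(zs) < r]
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  structure_set(name, lapply(zs, function(z) {
    rr <- sqrt(r^2 - z^2)
    contour_slice(center[3] + z,
                  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th)))
  }))
}

# random star-shaped (hence simple) polygon around a center
random_simple_polygon <- function(n = 12, r_range = c(5, 12),
                                  center = c(0, 0)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1], r_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

make_blob_structure <- function(zs = seq(0, 9, by = 1.5), seed = 1) {
  set.seed(seed)
  base <- random_simple_polygon(14, c(6, 11))
  structure_set("blob", lapply(seq_along(zs), function(i) {
    s <- 0.6 + 0.4 * sin(pi * (i - 0.5) / length(zs))
    contour_slice(zs[i], base * s)
  }))
}

# --- independent voxelization oracle -------------------------------------
# Inside-ness on a regular 3-d voxel grid, decided per slice layer with
# mgcv::in.out (an implementation-independent point-location routine).

voxelize_structure <- function(structure, h = 0.25) {
  z <- vapply(structure$slices, `[[`, numeric(1), "z_mm")
  slab <- if (length(z) > 1) z[2] - z[1] else 1.5
  verts <- lapply(structure$slices, `[[`, "vertices")
  xr <- range(unlist(lapply(verts, function(v) v[, 1])))
  yr <- range(unlist(lapply(verts, function(v) v[, 2])))
  gx <- seq(xr[1] - h, xr[2] + h, by = h)
  gy <- seq(yr[1] - h, yr[2] + h, by = h)
  gz <- seq(min(z) - slab / 2 + h / 2, max(z) + slab / 2, by = h)
  grid_xy <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  layers <- lapply(gz, function(zv) {
    i <- which.min(abs(z - zv))
    bnd <- rbind(verts[[i]], verts[[i]][1, ])
    matrix(mgcv::in.out(bnd, grid_xy), length(gx), length(gy))
  })
  list(gx = gx, gy = gy, gz = gz, layers = layers, h = h)
}

voxel_inside <- function(vox, pts) {
  vapply(seq_len(nrow(pts)), function(k) {
    ix <- which.min(abs(vox$gx - pts[k, 1]))
    iy <- which.min(abs(vox$gy - pts[k, 2]))
    iz <- which.min(abs(vox$gz - pts[k, 3]))
    if (abs(vox$gz[iz] - pts[k, 3]) > vox$h) return(FALSE)
    vox$layers[[iz]][ix, iy]
  }, logical(1))
}

voxel_com <- function(vox) {
  tot <- 0; sx <- 0; sy <- 0; sz <- 0
  for (i in seq_along(vox$gz)) {
    L <- vox$layers[[i]]
    n <- sum(L)
    if (n == 0) next
    tot <- tot + n
    sx <- sx + sum(vox$gx[row(L)[L]])
    sy <- sy + sum(vox$gy[col(L)[L]])
    sz <- sz + n * vox$gz[i]
  }
  c(sx, sy, sz) / tot
}

# independent symmetric Hausdorff distance from a full distance matrix
hausdorff_oracle <- function(a, b) {
  D <- sqrt(outer(rowSums(a^2), rep(1, nrow(b))) +
            outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b))
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

random_cloud <- function(n, lim = 20) matrix(stats::runif(3 * n, 0, lim), ncol = 3)

# minimal valid patient record around a given baseline/test structure pair
make_manual_patient <- function(structures, id = "T001",
                                centerline = cbind(0, 0, seq(-5, 150, by = 5))) {
  scans <- lapply(seq_along(structures), function(i)
    scan_record(paste0("scan", i), i, if (i == 1) "baseline" else "test",
                rigid_transform(), structures[[i]]))
  suppressWarnings(patient_record(id, 0, centerline, scans))
}

# small fast cohort configuration for pipeline tests
small_config <- function(seed, ...) {
  args <- list(n_patients = 4L, n_test_scans = 3L,
               tumor_center_cax_mm = c(45, 70),
               tumor_height_mm = c(15, 24),
               tumor_extent_deg = c(140, 220),
               tumor_thickness_mm = c(7, 10),
               rectum_radius_mm = c(13, 17),
               spacing_mm = 2, seed = seed)
  do.call(cohort_config, utils::modifyList(args, list(...)))
}
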