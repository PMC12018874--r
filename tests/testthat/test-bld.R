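# The bidirectional local distance: forward/reverse candidate construction,
# tie rule, signing, and COM displacement.

test_that("hand-executable BLD case and the degenerate identities", {
  b <- rbind(c(0, 0, 0), c(4, 0, 0))
  t_ <- rbind(c(1, 0, 0))
  for (f in list(bld_map(b, t_), bld_brute_force(b, t_))) {
    # b1: forward and reverse both give t (distance 1); b2: forward nearest
    # is t (distance 3), reverse set empty
    expect_equal(f$bld_mm, c(1, 3))
    expect_equal(f$mapped_idx, c(1L, 1L))
  }
  # identical clouds: bld == 0, every point maps to itself
  set.seed(10)
  a <- random_cloud(150)
  f <- bld_map(a, a)
  expect_equal(f$bld_mm, rep(0, 150))
  expect_equal(f$mapped_idx, seq_len(150))
  # singletons at distance d
  f1 <- bld_brute_force(rbind(c(0, 0, 0)), rbind(c(0, 3, 4)))
  expect_equal(f1$bld_mm, 5)
  expect_error(bld_map(a[0, , drop = FALSE], a), "empty")
  expect_error(bld_brute_force(random_cloud(4000), random_cloud(4000)),
               "refuses")
})

test_that("accelerated map equals the brute-force oracle exactly", {
  set.seed(1234)
  for (rep in 1:40) {
    b <- random_cloud(sample(5:300, 1))
    t_ <- random_cloud(sample(5:300, 1))
    fa <- bld_map(b, t_)
    fb <- bld_brute_force(b, t_)
    expect_identical(fa$mapped_idx, fb$mapped_idx)
    expect_identical(fa$bld_mm, fb$bld_mm)
  }
  # coincident test points: tie resolved to the smallest index
  b <- rbind(c(0, 0, 0))
  t_ <- rbind(c(2, 0, 0), c(2, 0, 0))
  f <- bld_map(b, t_)
  expect_equal(f$mapped_idx, 1L)
  expect_equal(f$bld_mm, 2)
})

test_that("BLD dominates the forward distance and attains the Hausdorff distance", {
  set.seed(77)
  for (rep in 1:10) {
    b <- random_cloud(sample(20:200, 1))
    t_ <- random_cloud(sample(20:200, 1))
    f <- bld_map(b, t_)
    fwd <- sqrt(vapply(seq_len(nrow(b)), function(i)
      min(colSums((t(t_) - b[i, ])^2)), numeric(1)))
    expect_true(all(f$bld_mm >= fwd - 1e-12))
    expect_equal(max(f$bld_mm), hausdorff_oracle(b, t_), tolerance = 1e-9)
    # every test point belongs to exactly one reverse set
    field <- rectvar:::cpp_bld_map(b, t_)
    expect_length(field$reverse_owner, nrow(t_))
    expect_true(all(field$reverse_owner %in% seq_len(nrow(b))))
  }
})

test_that("BLD distances are invariant under a common rigid motion", {
  set.seed(5)
  b <- random_cloud(200)
  t_ <- random_cloud(180)
  f0 <- bld_map(b, t_)
  tr <- rigid_transform(c(2, 1, -3), c(5, -4, 2), c(10, 10, 10))
  f1 <- bld_map(transform_points(b, tr), transform_points(t_, tr))
  expect_equal(f1$bld_mm, f0$bld_mm, tolerance = 1e-9)
})

test_that("signed components follow the in/out and COM-plane rules", {
  base_st <- make_sphere_structure(r = 10)
  base_cl <- sample_surface(base_st, 1)
  com <- center_of_mass(base_st)

  # uniform expansion by +2 mm: everything moves outward
  grow <- sample_surface(make_sphere_structure(r = 12), 1)
  f <- sign_components(bld_map(base_cl, grow), base_st, com)
  expect_true(all(f$signed_mm >= 0))
  # invariants tying signed and raw components together
  expect_equal(abs(f$signed_mm[, 1]), abs(f$vector_mm[, 1]))
  expect_equal(f$bld_mm, sqrt(rowSums(f$vector_mm^2)), tolerance = 1e-9)

  # uniform shrink by -2 mm: in-plane components move inward
  shrink_st <- make_sphere_structure(r = 12)
  shrink_cl <- sample_surface(shrink_st, 1)
  com12 <- center_of_mass(shrink_st)
  f2 <- sign_components(bld_map(shrink_cl, base_cl), shrink_st, com12)
  expect_true(all(f2$signed_mm[, 1:2] <= 0))

  # cranial translation: above-COM points outward (+), below-COM inward (-)
  up <- sample_surface(make_sphere_structure(r = 10, center = c(0, 0, 3)), 1)
  f3 <- sign_components(bld_map(base_cl, up), base_st, com)
  hi <- base_cl$points[, 3] > com[3] + 1.5
  lo <- base_cl$points[, 3] < com[3] - 1.5
  expect_true(all(f3$signed_mm[hi, 3] >= 0))
  expect_true(all(f3$signed_mm[lo, 3] <= 0))
})

test_that("COM displacement uses the left/posterior/cranial sign convention", {
  a <- structure(c(x_mm = 1, y_mm = 2, z_mm = 3), class = "com")
  expect_equal(unclass(com_displacement(a, a)),
               c(rl_mm = 0, ap_mm = 0, cc_mm = 0))
  b <- structure(c(x_mm = 1, y_mm = 2, z_mm = 5), class = "com")
  expect_equal(com_displacement(a, b)[["cc_mm"]], 2)       # cranial positive
  c_ <- structure(c(x_mm = 1, y_mm = 1, z_mm = 3), class = "com")
  expect_equal(com_displacement(a, c_)[["ap_mm"]], -1)     # anterior negative
})

test_that("translation of a convex cloud: COM shift exact, signed bound holds", {
  st <- make_sphere_structure(r = 10)
  cl <- sample_surface(st, 1)
  com <- center_of_mass(st)
  t_vec <- c(2, -1.2, 0.8)
  moved_st <- structure_set("m", lapply(st$slices, function(sl)
    contour_slice(sl$z_mm + t_vec[3], sweep(sl$vertices, 2, -t_vec[1:2]))))
  expect_equal(unclass(com_displacement(com, center_of_mass(moved_st))),
               c(rl_mm = t_vec[1], ap_mm = t_vec[2], cc_mm = t_vec[3]),
               tolerance = 1e-9)
  f <- sign_components(bld_map(cl, sample_surface(moved_st, 1)), st, com)
  for (d in 1:3)
    expect_lte(max(abs(f$signed_mm[, d])), abs(t_vec[d]) + 2 * 1)
})
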