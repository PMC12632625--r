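test_that("fractional coordinates convert through the crystallographic matrix", {
  # orthogonal cell: conversion is a pure scaling
  cif <- c("data_test",
           "_cell_length_a 10", "_cell_length_b 20", "_cell_length_c 30",
           "_cell_angle_alpha 90", "_cell_angle_beta 90",
           "_cell_angle_gamma 90",
           "loop_", "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "A1 C 0.5 0.5 0.5")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(5, 10, 15))

  # monoclinic cell vs an independently coded matrix product
  cif[6] <- "_cell_angle_beta 104"
  writeLines(cif, path)
  s2 <- read_structure(path)
  beta <- 104 * pi / 180
  oracle <- c(0.5 * 10 + 0.5 * 30 * cos(beta), 0.5 * 20,
              0.5 * 30 * sin(beta))
  expect_equal(unlist(s2$atoms[1, c("x", "y", "z")], use.names = FALSE),
               oracle, tolerance = 1e-12)

  # malformed loop rows are reported with their line number
  writeLines(c(cif, "B1 C 0.1 0.2"), path)
  expect_error(read_structure(path), "line 15")
})

test_that("labeled_xyz files round-trip exactly", {
  toy <- gen_toy_complex(seed = 3, rigid_transform = FALSE)
  path <- tempfile(fileext = ".xyz")
  write_structure(toy$structure, path, "labeled_xyz")
  back <- read_structure(path)
  expect_equal(back$atoms$x, toy$structure$atoms$x, tolerance = 1e-7)
  expect_equal(back$atoms$label, toy$structure$atoms$label)
  expect_equal(back$atoms$occupancy, toy$structure$atoms$occupancy,
               tolerance = 1e-7)
  expect_equal(back$atoms$disorder_group, toy$structure$atoms$disorder_group)

  # cif round trip preserves descriptors (coordinates may be re-origined)
  cifp <- tempfile(fileext = ".cif")
  write_structure(toy$structure, cifp, "cif_min")
  back2 <- read_structure(cifp)
  expect_equal(pose_descriptors(back2, toy$selections),
               pose_descriptors(toy$structure, toy$selections),
               tolerance = 1e-5)
})

test_that("centroid is the unweighted mean position", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid(square), c(0.5, 0.5, 0))
  expect_equal(centroid(rbind(c(3, -2, 7))), c(3, -2, 7))
  th <- 2 * pi * (0:6) / 7
  circle <- cbind(2 + 1.7 * cos(th), -1 + 1.7 * sin(th), 5)
  expect_equal(centroid(circle), c(2, -1, 5), tolerance = 1e-12)
})

test_that("plane fitting minimises perpendicular residuals", {
  coplanar <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  p <- fit_plane(coplanar)
  expect_equal(p$rms, 0)
  expect_equal(abs(p$normal), c(0, 0, 1))

  # symmetric +-h perturbation: best plane is z = 0 with rms = h
  h <- 0.3
  th <- 2 * pi * (0:7) / 8
  pts <- cbind(cos(th), sin(th), rep(c(h, -h), 4))
  p2 <- fit_plane(pts)
  expect_equal(p2$rms, h, tolerance = 1e-12)
  expect_equal(abs(p2$normal[3]), 1, tolerance = 1e-12)

  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 0, 0))), "3 atoms")
})

test_that("plane fit matches a brute-force orientation-grid oracle", {
  set.seed(19)
  for (k in 1:3) {
    cloud <- matrix(rnorm(30, sd = 2), ncol = 3)
    cloud[, 3] <- 0.2 * cloud[, 3]       # flattened cloud
    p <- fit_plane(cloud)
    expect_equal(p$rms, plane_rms_grid_oracle(cloud), tolerance = 1e-6)
  }
})

test_that("plane residual does not increase when the worst atom is removed", {
  set.seed(4)
  cloud <- matrix(rnorm(36, sd = 2), ncol = 3)
  cloud[, 3] <- 0.1 * cloud[, 3]
  p <- fit_plane(cloud)
  worst <- which.max(abs(sweep(cloud, 2, p$point) %*% p$normal))
  expect_lte(fit_plane(cloud[-worst, ])$rms, p$rms)
})

test_that("distances and angles follow their definitions", {
  p <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_equal(point_plane_distance(c(0.3, 0.7, 0), p), 0)
  expect_equal(point_plane_distance(c(0, 0, 0.74), p), 0.74)
  s1 <- point_plane_distance(c(0, 0, 1), p, signed = TRUE)
  s2 <- point_plane_distance(c(0, 0, -1), p, signed = TRUE)
  expect_equal(s1, -s2)

  expect_equal(vertex_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(vertex_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(vertex_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")

  pz <- fit_plane(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2), c(1, 1, 2)))
  expect_equal(plane_plane_angle(p, pz), 0)
  px <- fit_plane(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 1)))
  expect_equal(plane_plane_angle(p, px), 90)
})

test_that("hydrogen-bond geometry matches a dot-product oracle", {
  # linear N-H...O at the distance of a typical portal hydrogen bond
  atoms <- data.frame(label = c("N29", "H29", "O1"),
                      element = c("N", "H", "O"),
                      x = c(0, 1.0, 3.10), y = 0, z = 0)
  s <- structure_model(atoms)
  hb <- hbond_geometry(s, "N29", "H29", "O1")
  expect_equal(hb$d_DA, 3.10)
  expect_equal(hb$angle_DHA, 180)

  set.seed(8)
  for (k in 1:5) {
    xyz <- matrix(rnorm(9, sd = 2), ncol = 3)
    s2 <- structure_model(data.frame(label = c("D", "H", "A"),
                                     element = c("N", "H", "O"),
                                     x = xyz[, 1], y = xyz[, 2],
                                     z = xyz[, 3]))
    hb2 <- hbond_geometry(s2, "D", "H", "A")
    u <- xyz[1, ] - xyz[2, ]; v <- xyz[3, ] - xyz[2, ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(hb2$d_DA, sqrt(sum((xyz[1, ] - xyz[3, ])^2)))
    expect_equal(hb2$angle_DHA, ang)
  }
  expect_error(hbond_geometry(s, "N29", "H29", "O99"), "O99")
})

test_that("pose descriptors are isometry-invariant and occupancy-aware", {
  toy <- gen_toy_complex(
    guests = list(list(n29_height = 0.19, axial_angle = 16.97,
                       phenyl_tilt = 83.13, occupancy = 0.6),
                  list(n29_height = 0.52, axial_angle = 3.90,
                       phenyl_tilt = 83.13, occupancy = 0.4)),
    seed = 21, rigid_transform = FALSE)
  pd <- pose_descriptors(toy$structure, toy$selections)
  expect_equal(nrow(pd), 2)
  expect_equal(pd$occupancy, c(0.6, 0.4))
  expect_equal(pd$d_N29_plane1, toy$truth$d_N29_plane1, tolerance = 1e-8)
  expect_equal(pd$angle_cen1_cen2_N29, toy$truth$angle_cen1_cen2_N29,
               tolerance = 1e-8)

  set.seed(33)
  for (k in 1:3) {
    moved <- transform_structure(toy$structure, random_rotation_matrix(),
                                 runif(3, -50, 50))
    pd2 <- pose_descriptors(moved, toy$selections)
    expect_equal(pd2, pd, tolerance = 1e-8)
  }
})

test_that("canonical poses give zero descriptors and halogen distances carry through", {
  toy <- gen_toy_complex(
    guests = list(list(n29_height = 0, axial_angle = 0, phenyl_tilt = 45,
                       occupancy = 1, halogen_dist = 2.150)),
    seed = 2, rigid_transform = FALSE)
  pd <- pose_descriptors(toy$structure, toy$selections)
  expect_equal(pd$d_N29_plane1, 0, tolerance = 1e-10)
  expect_equal(pd$angle_cen1_cen2_N29, 0, tolerance = 1e-10)
  expect_equal(pd$angle_phenyl_plane2, 45, tolerance = 1e-10)
  expect_equal(pd$d_cen1prime_halogen, 2.150, tolerance = 1e-10)
})
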