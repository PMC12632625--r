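test_that("generators are deterministic in the seed and independent of each other", {
  prot <- default_protocol()
  t1 <- gen_titration(list(n = 1, K_D = 2e-5, dH = -15), prot, seed = 42)
  t2 <- gen_titration(list(n = 1, K_D = 2e-5, dH = -15), prot, seed = 42)
  expect_identical(t1$heats, t2$heats)
  t3 <- gen_titration(list(n = 1, K_D = 2e-5, dH = -15), prot, seed = 43)
  expect_false(identical(t1$heats, t3$heats))

  e1 <- gen_energy_table(seed = 42)
  e2 <- gen_energy_table(seed = 42)
  expect_identical(e1, e2)

  b1 <- gen_bcp_table(50, seed = 42)
  expect_identical(b1, gen_bcp_table(50, seed = 42))

  g1 <- gen_toy_complex(seed = 42)
  expect_identical(g1, gen_toy_complex(seed = 42))

  # generators use split substreams of one seed, and none touches the
  # caller's RNG state
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_bcp_table(10, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("titration generator embeds recoverable truth", {
  prot <- default_protocol()
  truth <- list(n = 1, K_D = 2e-5, dH = -15)
  # zero noise: heats identical to the forward model
  sim0 <- gen_titration(truth, prot, noise_sd = 0, seed = 1)
  expect_identical(sim0$heats,
                   predict_injection_heats(list(n = 1, K_a = 5e4,
                                                dH = -15), prot))
  # zero enthalpy: no signal whatever the affinity
  sim_h0 <- gen_titration(list(n = 1, K_D = 1e-8, dH = 0), prot,
                          noise_sd = 0, seed = 1)
  expect_equal(sim_h0$heats, rep(0, 20))
  # default noise scale: 1 % of the first-injection heat
  simn <- gen_titration(truth, prot, seed = 1)
  expect_equal(simn$noise_sd, 0.01 * abs(sim0$heats[1]))
})

test_that("energy-table generator round-trips through assembly and combination", {
  for (seed in c(1, 7, 123)) {
    gen <- gen_energy_table(n_complexes = 4, n_conformers = c(1, 2, 3, 2),
                            seed = seed)
    out <- assemble_energy_table(gen$table)
    expect_equal(out$conformers$dg_calcd, gen$truth$dg_calcd,
                 tolerance = 1e-12)
    expect_equal(out$combined$dg_combined, gen$truth$combined$dg_combined,
                 tolerance = 1e-12)
  }
  # single conformer: combined equals the assembled value
  g1 <- gen_energy_table(n_complexes = 1, n_conformers = 1, seed = 3)
  expect_equal(g1$truth$combined$dg_combined, g1$truth$dg_calcd)
  # degenerate all-zero ranges give an exactly zero assembled energy
  zr <- lapply(1:6, function(i) c(0, 0))
  names(zr) <- c("e_int", "e_disp", "g_solv", "minus_tds",
                 "e_def_host", "e_def_guest")
  gz <- gen_energy_table(n_complexes = 1, n_conformers = 2,
                         term_ranges = zr, seed = 1)
  expect_equal(gz$truth$dg_calcd, c(0, 0))
  expect_error(gen_energy_table(n_conformers = 0), "n_conformers")
  expect_error(gen_energy_table(term_ranges = list(e_int = 5)), "range")
})

test_that("BCP generator satisfies the virial identity exactly and plants labels", {
  gen <- gen_bcp_table(500, seed = 17)
  tab <- gen$table
  # local virial identity to machine precision on every row (au x 10^3)
  expect_equal(0.25 * tab$lap, 2 * tab$G + tab$V, tolerance = 1e-13)
  # planted class definitions: pCS rows have lap > 0, H > 0; rCS lap > 0,
  # H < 0; SS lap < 0
  H <- tab$V + tab$G
  expect_true(all(tab$lap[gen$truth$HC == "pCS"] > 0 &
                    H[gen$truth$HC == "pCS"] > 0))
  expect_true(all(tab$lap[gen$truth$HC == "rCS"] > 0 &
                    H[gen$truth$HC == "rCS"] < 0))
  expect_true(all(tab$lap[gen$truth$HC == "SS"] < 0))

  ann <- annotate_bcp(tab)
  expect_false(any(ann$virial_flag))
  expect_equal(mean(ann$HC == gen$truth$HC), 1)
  expect_equal(mean(ann$GC == gen$truth$GC), 1)
  expect_equal(mean(ann$EC == gen$truth$EC), 1)
  expect_equal(mean(ann$itype == gen$truth$itype), 1)

  expect_error(gen_bcp_table(10, class_mix = c(pCS = 0.5, rCS = 0.2)),
               "sum to 1")
})

test_that("toy-complex generator closes the descriptor round trip to 1e-6", {
  toy <- gen_toy_complex(
    portal_radius = 2.8, equatorial_radius = 4.2,
    guests = list(list(n29_height = 0.74, axial_angle = 20.68,
                       phenyl_tilt = 78.66, occupancy = 0.6),
                  list(n29_height = 1.36, axial_angle = 1.00,
                       phenyl_tilt = 78.66, occupancy = 0.4)),
    seed = 5)
  pd <- pose_descriptors(toy$structure, toy$selections)
  for (col in c("d_N29_plane1", "angle_cen1_cen2_N29",
                "angle_phenyl_plane2"))
    expect_equal(pd[[col]], toy$truth[[col]], tolerance = 1e-6)

  expect_error(gen_toy_complex(portal_radius = -1), "radii")
  expect_error(gen_toy_complex(guests = list(list(n29_height = 0,
                                                  axial_angle = 0,
                                                  phenyl_tilt = 10,
                                                  occupancy = 1.2))),
               "occupancies")
  expect_error(gen_toy_complex(guests = list(
    list(n29_height = 0, axial_angle = 0, phenyl_tilt = 10,
         occupancy = 0.7),
    list(n29_height = 0, axial_angle = 0, phenyl_tilt = 10,
         occupancy = 0.7))), "sum")
})

test_that("toy complexes survive both structure dialects", {
  toy <- gen_toy_complex(seed = 9)
  for (dialect in c("labeled_xyz", "cif_min")) {
    path <- tempfile(fileext = if (dialect == "cif_min") ".cif" else ".xyz")
    write_structure(toy$structure, path, dialect)
    back <- read_structure(path)
    pd <- pose_descriptors(back, toy$selections)
    expect_equal(pd$angle_phenyl_plane2, toy$truth$angle_phenyl_plane2,
                 tolerance = 1e-5)
  }
})
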