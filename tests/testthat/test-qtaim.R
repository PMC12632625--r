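test_that("virial relation and local energy density reproduce tabulated points", {
  # portal hydrogen bond of the unsubstituted guest, conformer 1
  G <- virial_g(35.62e-3, -5.20e-3)
  expect_equal(G, 7.05e-3, tolerance = 0.01 / 7.05)
  expect_equal(local_h(-5.20e-3, G), 1.86e-3, tolerance = 0.05 / 1.86)
  # the partially covalent portal bond of the para-bromo guest
  G2 <- virial_g(92.25e-3, -23.90e-3)
  expect_equal(G2, 23.48e-3, tolerance = 0.01 / 23.48)
  expect_equal(local_h(-23.90e-3, G2), -0.40e-3, tolerance = 0.05 / 0.40)

  expect_equal(virial_g(0, 0), 0)
  expect_equal(local_h(-3e-3, 3e-3), 0)
  set.seed(7)
  v <- rnorm(10); g <- abs(rnorm(10))
  expect_equal(local_h(v, g), v + g)
  expect_warning(virial_g(-10e-3, 5e-3), "kinetic")
})

test_that("empirical interaction energy is the stated affine map", {
  expect_equal(afonin_energy(-23.90e-3), 18.63, tolerance = 0.005 / 18.63)
  expect_equal(afonin_energy(-4.2e-3), 4.41, tolerance = 0.01 / 4.41)
  expect_equal(afonin_energy(0), 0.33 * 4.184)
  # affine and strictly decreasing in V
  v <- seq(-30e-3, 0, length.out = 7)
  e <- afonin_energy(v)
  expect_true(all(diff(e) < 0))
  expect_equal(diff(e, lag = 2), 2 * diff(e)[-6] , tolerance = 1e-12)
  expect_warning(afonin_energy(2e-3), "positive V")
})

test_that("Hayashi and Jeffrey classifications follow their rule tables", {
  expect_equal(hayashi_class(35.62e-3, 1.86e-3), "pCS")
  expect_equal(hayashi_class(92.25e-3, -0.40e-3), "rCS")
  expect_equal(hayashi_class(-50e-3, -40e-3), "SS")

  expect_equal(as.character(jeffrey_geometric(2.42, 126.94)), "Weak")
  expect_equal(as.character(jeffrey_geometric(1.90, 171.27)), "Moderate")
  expect_equal(as.character(jeffrey_geometric(1.2, 175)), "Strong")
  # boundary values join the class whose lower edge they sit on
  expect_equal(as.character(jeffrey_geometric(c(1.5, 2.2), c(180, 180))),
               c("Moderate", "Weak"))
  expect_true(attr(jeffrey_geometric(3.5, 120), "beyond_range"))
  expect_error(jeffrey_geometric(2.0, 190), "angle")

  expect_equal(jeffrey_energetic(c(14.68, 17.01, 5.12)),
               c("Weak", "Moderate", "Weak"))
  expect_equal(jeffrey_energetic(c(16.7, 62.8)), c("Moderate", "Strong"))
})

test_that("interaction typing distinguishes the observed contact classes", {
  expect_equal(type_interaction("N", TRUE, "O", "piperazinium"),
               "ionic_hbond")
  expect_equal(type_interaction("N", TRUE, "O"), "hbond")
  expect_equal(type_interaction("C", TRUE, "F"), "fluorine_contact")
  expect_equal(type_interaction("F", FALSE, "O"), "fluorine_contact")
  expect_equal(type_interaction("H", FALSE, "H"), "dihydrogen")
  expect_equal(type_interaction("O", FALSE, "C"), "n_pi_star")
  expect_equal(type_interaction("C", FALSE, "N"), "other")
  expect_error(type_interaction("Xx", TRUE, "O"), "element")
})

test_that("annotation reproduces the full published inventory", {
  bcp <- cb7_bcp()
  ann <- annotate_bcp(bcp)

  hb <- ann$table == "hbond"
  # derived H within the rounding tolerance of the printed two-decimal
  # (hydrogen bonds) and one-decimal (fluorine contacts) inputs
  expect_lt(max(abs(ann$H[hb] - bcp$H_reported[hb])), 0.05)
  expect_lt(max(abs(ann$H[!hb] - bcp$H_reported[!hb])), 0.08)
  expect_lt(max(abs(ann$E[hb] - bcp$E_reported[hb])), 0.05)
  expect_lt(max(abs(ann$E[!hb] - bcp$E_reported[!hb])), 0.1)

  # every printed classification label is reproduced
  expect_equal(ann$HC, bcp$HC_reported)
  expect_equal(ann$EC, bcp$EC_reported)
  gc_known <- !is.na(bcp$GC_reported)
  expect_equal(ann$GC[gc_known], bcp$GC_reported[gc_known])
  # the portal contacts are ionic hydrogen bonds, the rest F contacts
  expect_true(all(ann$itype[hb] == "ionic_hbond"))
  expect_true(all(ann$itype[!hb] == "fluorine_contact"))
})

test_that("annotation is idempotent, order-independent and scale-aware", {
  ann <- annotate_bcp(cb7_bcp())
  again <- annotate_bcp(ann)
  expect_equal(again[names(ann)], ann)

  perm <- sample(nrow(ann))
  shuffled <- annotate_bcp(cb7_bcp()[perm, ])
  expect_equal(shuffled$HC, ann$HC[perm])
  expect_equal(shuffled$E, ann$E[perm])

  # classifications are invariant under the au <-> au x 10^3 rescaling
  bcp_au <- cb7_bcp()
  for (col in c("rho", "lap", "V")) bcp_au[[col]] <- bcp_au[[col]] * 1e-3
  ann_au <- annotate_bcp(bcp_au, units = "au")
  expect_equal(ann_au$HC, ann$HC)
  expect_equal(ann_au$EC, ann$EC)
  expect_equal(ann_au$E, ann$E)

  expect_error(annotate_bcp(cb7_bcp()[, -6]), "rho")
})

test_that("supplied kinetic energy densities are checked against the virial identity", {
  bcp <- cb7_bcp()[1:4, ]
  bcp$G <- virial_g(bcp$lap * 1e-3, bcp$V * 1e-3) / 1e-3
  bcp$G[2] <- bcp$G[2] + 1      # 1e-3 au violation
  ann <- annotate_bcp(bcp)
  expect_equal(ann$virial_flag, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("interaction inventory counts per complex and type", {
  ann <- annotate_bcp(cb7_bcp())
  inv <- interaction_inventory(ann)
  expect_equal(sum(inv$count), nrow(ann))
  row_1h_f <- inv[inv$complex_id == "CB7.1h" & inv$conformer == 1 &
                    inv$itype == "fluorine_contact", ]
  expect_equal(row_1h_f$count, 3L)
})
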