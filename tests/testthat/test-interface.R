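test_that("an isolated sphere matches the closed-form area", {
  m <- structure_model(data.frame(chain = "A", resno = 1, resid = "UNK",
                                  elety = "X", element = "X",
                                  x = 0, y = 0, z = 0))
  s <- shrake_rupley_sasa(m, radius_override = 1.7)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("non-overlapping spheres keep their full isolated area", {
  sys <- make_sphere_system(c(1.7, 1.7), rbind(c(0, 0, 0), c(10, 0, 0)))
  s <- shrake_rupley_sasa(sys$model, radius_override = sys$radii)
  expect_equal(s$residue$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
  # touching exactly at d = r1 + r2 + 2 probe: still no occlusion
  sys2 <- make_sphere_system(c(1.7, 1.5), rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(sys2$analytic_sasa, 4 * pi * (c(1.7, 1.5) + 1.4)^2)
  s2 <- shrake_rupley_sasa(sys2$model, radius_override = sys2$radii)
  expect_equal(s2$residue$sasa, sys2$analytic_sasa, tolerance = 1e-6)
})

test_that("sampled SASA tracks the two-sphere analytic oracle within 1%", {
  for (d in c(2.0, 3.0, 4.5, 5.5)) {
    sys <- make_sphere_system(c(1.7, 1.4), rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- shrake_rupley_sasa(sys$model, radius_override = sys$radii)
    rel <- abs(s$residue$sasa - sys$analytic_sasa) / sys$analytic_sasa
    expect_lt(max(rel), 0.01, label = sprintf("distance %g", d))
  }
})

test_that("doubling the point count changes totals by less than 0.5%", {
  # peptide-sized random atom blob (about the heavy-atom count of a 9-mer)
  set.seed(31)
  blob <- structure_model(data.frame(
    chain = "P", resno = rep(1:9, length.out = 60), resid = "GLY",
    elety = sprintf("C%02d", 1:60), element = "C",
    x = rnorm(60, sd = 4), y = rnorm(60, sd = 4), z = rnorm(60, sd = 4)))
  a <- shrake_rupley_sasa(blob, params = sasa_params(n_points = 960))$total
  b <- shrake_rupley_sasa(blob, params = sasa_params(n_points = 1920))$total
  expect_lt(abs(a - b) / a, 0.005)
})

test_that("total SASA decreases monotonically on rigid approach", {
  totals <- vapply(c(30, 10, 4, 1, 0), function(sep) {
    m <- make_toy_complex(separation = sep)$model
    shrake_rupley_sasa(m)$total
  }, numeric(1))
  expect_true(all(diff(totals) < 1e-9))
})

test_that("the toy complex interface reproduces its construction truth", {
  tc <- make_toy_complex()
  rep <- interface_report(tc$model, "A", "P")
  expect_setequal(rep$contacts$label, tc$truth$contact_residues)
  expect_false(tc$truth$no_contact_residues %in% rep$contacts$label)
  expect_identical(rep$hbonds$residues_direct, tc$truth$direct_hbond)
  expect_identical(rep$hbonds$residues_water_mediated, tc$truth$water_mediated)
  expect_identical(
    rep$contacts$hbond[match(c("ALA(A2)", "ALA(A4)"), rep$contacts$label)],
    c("direct", "water_mediated"))
  # bookkeeping identity and bounds
  expect_lte(rep$buried_B, rep$total_sasa_B_free)
  expect_equal(rep$buried_fraction, 100 * rep$buried_B / rep$total_sasa_B_free)
  expect_true(all(rep$residues_b$bsa >= -1e-9))
})

test_that("infinitely separated parts bury nothing", {
  rep <- interface_report(make_toy_complex(separation = 500)$model, "A", "P")
  expect_equal(rep$buried_B, 0, tolerance = 1e-9)
  expect_equal(nrow(rep$contacts), 0)
  expect_equal(nrow(rep$hbonds$direct), 0)
})

test_that("area buried on each side balances within method tolerance", {
  tc <- make_toy_complex()
  rep <- buried_surface(tc$model, "A", "P")
  expect_lt(abs(rep$buried_A - rep$buried_B) /
              max(rep$buried_A, rep$buried_B), 0.15)
})

test_that("a contact threshold above the maximum BSA empties the table", {
  tc <- make_toy_complex()
  rep <- buried_surface(tc$model, "A", "P")
  expect_equal(nrow(contact_table(rep, bsa_threshold = 1e6)), 0)
})

test_that("polar pairs beyond the cutoff are not hydrogen bonds", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1, resid = "SER", elety = "OG",
               element = "O", x = 0, y = 0, z = 0),
    data.frame(chain = "B", resno = 1, resid = "ASN", elety = "ND2",
               element = "N", x = 4.5, y = 0, z = 0))
  hb <- hydrogen_bonds(structure_model(atoms), "A", "B")
  expect_equal(nrow(hb$direct), 0)
  expect_equal(nrow(hb$water_mediated), 0)
})

test_that("radius resolution fails loudly for unknown atoms", {
  m <- structure_model(data.frame(chain = "A", resno = 1, resid = "LIG",
                                  elety = "XX", element = "QQ",
                                  x = 0, y = 0, z = 0))
  expect_error(shrake_rupley_sasa(m), "no radius")
  expect_error(buried_surface(make_toy_complex()$model, "A", character(0)),
               "empty selection")
})
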