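test_that("average masses follow the residue table and additivity", {
  expect_equal(average_mass("G")$theoretical_mass, 75.07, tolerance = 1e-3)
  two <- average_mass(c("ACDG", "WYK"), n_disulfides = 2)
  sep <- average_mass("ACDG")$theoretical_mass +
    average_mass("WYK")$theoretical_mass
  expect_equal(two$theoretical_mass, sep - 2 * 2.0159, tolerance = 1e-6)
  base <- average_mass("ACDGWYK")$theoretical_mass
  modded <- average_mass("ACDGWYK",
                         modifications = c(Cy7_maleimide = 830.10))
  expect_equal(modded$theoretical_mass - base, 830.10, tolerance = 1e-9)
  expect_error(average_mass("ACXZ"), "unknown residue")
})

test_that("adduct annotation explains the +178 Da species", {
  ann <- annotate_adduct(65185.01, 65007.07, tolerance = 2)
  expect_equal(ann$delta_rounded, 178)
  expect_equal(ann$match, "N_acetylcysteine_methylester")
  expect_equal(annotate_adduct(65007.07, 65007.07)$match, "none")
  far <- annotate_adduct(65007.07 + 412, 65007.07)
  expect_equal(far$match, "unexplained")
  expect_equal(far$delta_rounded, 412)
})

test_that("extinction coefficients follow the 280 nm convention", {
  expect_equal(extinction_coefficient_280("AGSPL"), 0)
  expect_equal(extinction_coefficient_280("W"), 5500)
  expect_equal(extinction_coefficient_280("WWYC", n_cystine = 1),
               2 * 5500 + 1490 + 125)
  one <- extinction_coefficient_280("AWYGC")
  expect_equal(extinction_coefficient_280(strrep("AWYGC", 3)), 3 * one)
})

test_that("decay correction is exact and composes", {
  expect_equal(decay_correct(100, 78.41), 50)
  expect_equal(decay_correct(100, 0), 100)
  expect_equal(decay_correct(decay_correct(100, 24), 54.41),
               decay_correct(100, 78.41), tolerance = 1e-12)
  expect_error(decay_correct(1, -1), "elapsed")
})

test_that("specific activity tracks dose over molar amount", {
  expect_equal(specific_activity(1, amount_umol = 1), 1)
  # 3 MBq on 9 ug of a 65 kDa tracer
  expect_equal(specific_activity(0.003, mass_ug = 9, mw_Da = 65007),
               21.7, tolerance = 0.01)
  expect_equal(specific_activity(1, amount_umol = 2),
               specific_activity(1, amount_umol = 1) / 2)
  expect_error(specific_activity(1, amount_umol = 0), "positive")
})

test_that("radiochemical purity integrates the main-peak window", {
  pos <- seq(0, 10, by = 0.01)
  peak <- function(mu, sd, h) h * exp(-(pos - mu)^2 / (2 * sd^2))
  all_in <- peak(5, 0.3, 1)
  expect_equal(radiochemical_purity(pos, all_in, c(0, 10)), 100)
  # symmetric trace, half the signal inside the window
  sym <- peak(3, 0.2, 1) + peak(7, 0.2, 1)
  expect_equal(radiochemical_purity(pos, sym, c(0, 5)), 50, tolerance = 0.1)
  # constructed 97/3 two-peak trace
  trace <- peak(4, 0.2, 9.7) + peak(8, 0.2, 0.3)
  expect_equal(radiochemical_purity(pos, trace, c(3, 5)), 97.0,
               tolerance = 0.1)
})

test_that("percent injected dose per gram reproduces constructed uptake", {
  # 1% of the injected activity in a 1 g organ -> 1 %ID/g
  rec <- data.frame(organ = "liver", activity = 1, weight = 1)
  rep <- percent_id_per_gram(rec, injected_activity = 100)
  expect_equal(rep$records$pct_id_per_g, 1)
  # tumor-bearing vs contralateral lobe ratio from planted %ID/g values
  set.seed(1)
  rec2 <- data.frame(
    organ = rep(c("thyroid_tumor", "thyroid_contralateral"), each = 5),
    activity = rep(c(4.1 * 0.05, 1.6 * 0.04), each = 5) *
      rep(c(1, 1.02, 0.98, 1.01, 0.99), 2),
    weight = rep(c(0.05, 0.04), each = 5))
  rep2 <- percent_id_per_gram(
    rec2, injected_activity = 100,
    ratios = list(tumor_to_contralateral = c("thyroid_tumor",
                                             "thyroid_contralateral")))
  expect_equal(unname(rep2$ratios["tumor_to_contralateral"]), 4.1 / 1.6,
               tolerance = 1e-9)
  expect_error(percent_id_per_gram(data.frame(organ = "x", activity = 1,
                                              weight = 0), 100),
               "weight")
})

test_that("decay-corrected uptake is invariant under activity unit rescaling", {
  rec <- data.frame(organ = c("a", "b"), activity = c(5, 2),
                    weight = c(0.5, 0.25))
  r1 <- percent_id_per_gram(rec, 100, elapsed_h = 24)
  rec$activity <- rec$activity * 3.7e4   # counts instead of Bq
  r2 <- percent_id_per_gram(rec, 100 * 3.7e4, elapsed_h = 24)
  expect_equal(r1$records$pct_id_per_g, r2$records$pct_id_per_g,
               tolerance = 1e-12)
})

test_that("group comparison uses an unpaired t-test with zero-variance guard", {
  rec <- data.frame(
    organ = rep("tumor", 10),
    group = rep(c("tracer", "blocked"), each = 5),
    activity = c(4.0, 4.2, 3.9, 4.1, 4.05, 2.0, 2.1, 1.9, 2.05, 2.0),
    weight = 1)
  rep <- percent_id_per_gram(rec, 100,
                             compare_groups = c("tracer", "blocked"))
  expect_true(rep$tests$significant[rep$tests$organ == "tumor"])
  p_ref <- stats::t.test(c(4.0, 4.2, 3.9, 4.1, 4.05),
                         c(2.0, 2.1, 1.9, 2.05, 2.0),
                         var.equal = TRUE)$p.value
  expect_equal(rep$tests$p_value, p_ref, tolerance = 1e-12)
  # identical groups with zero variance -> NA, flagged not significant
  rec2 <- rec
  rec2$activity <- 3
  rep2 <- percent_id_per_gram(rec2, 100,
                              compare_groups = c("tracer", "blocked"))
  expect_true(is.na(rep2$tests$p_value))
  expect_false(rep2$tests$significant)
})
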