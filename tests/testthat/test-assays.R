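elisa_conc <- 10^seq(-11.5, -7.5, length.out = 12)  # molar, spans 1.3 nM

test_that("noise-free ELISA curves are recovered to 4 significant digits", {
  d <- simulate_elisa(1.3e-9, a_max = 1.8, background = 0.07,
                      concentrations = elisa_conc, noise_sd = 0, seed = 1)
  f <- fit_elisa(d)
  expect_equal(f$k_d, 1.3e-9, tolerance = 1e-4)
  expect_equal(f$a_max, 1.8, tolerance = 1e-4)
  expect_equal(f$background, 0.07, tolerance = 1e-3)
  expect_false(f$no_plateau)
})

test_that("ELISA simulation is seeded and degenerate input is rejected", {
  d1 <- simulate_elisa(1.3e-9, 1, 0, elisa_conc, noise_sd = 0.05, seed = 9)
  d2 <- simulate_elisa(1.3e-9, 1, 0, elisa_conc, noise_sd = 0.05, seed = 9)
  expect_identical(d1$y, d2$y)
  expect_false(identical(
    d1$y, simulate_elisa(1.3e-9, 1, 0, elisa_conc, 0.05, seed = 10)$y))
  flat <- assay_dataset(elisa_conc, rep(1, 12))
  expect_error(fit_elisa(flat), "constant signal")
})

test_that("noisy ELISA recovery stays within the Monte-Carlo error bound", {
  errs <- vapply(1:100, function(s) {
    d <- simulate_elisa(1.3e-9, 1, 0.05, elisa_conc, noise_sd = 0.05, seed = s)
    abs(fit_elisa(d)$k_d - 1.3e-9) / 1.3e-9
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("fitters are scale-equivariant in the response", {
  d <- simulate_elisa(1.3e-9, 1, 0.05, elisa_conc, noise_sd = 0.03, seed = 2)
  f1 <- fit_elisa(d)
  d$y <- d$y * 250
  f2 <- fit_elisa(d)
  expect_equal(f2$k_d, f1$k_d, tolerance = 1e-6)
  expect_equal(f2$a_max / f1$a_max, 250, tolerance = 1e-6)
  ds <- simulate_saturation(15e-9, 100, 10^seq(-9.5, -6.5, length.out = 8),
                            noise_sd = 0.05, seed = 3)
  g1 <- fit_saturation(ds)
  ds$y <- ds$y * 40
  g2 <- fit_saturation(ds)
  expect_equal(g2$k_d, g1$k_d, tolerance = 1e-6)
  expect_equal(g2$b_max / g1$b_max, 40, tolerance = 1e-6)
})

spr_schedule <- data.frame(
  t_start = c(0, 120, 240, 360, 480, 600),
  t_end = c(120, 240, 360, 480, 600, 1200),
  conc = c(1e-9, 2e-9, 4e-9, 8e-9, 16e-9, 0))

test_that("single-cycle SPR round trip recovers kinetics to 3 digits", {
  d <- simulate_sck_spr(1e6, 3.4e-4, 120, spr_schedule, noise_sd = 0,
                        seed = 1, dt = 2)
  f <- fit_sck_spr(d)
  expect_equal(f$k_on, 1e6, tolerance = 1e-3)
  expect_equal(f$k_off, 3.4e-4, tolerance = 1e-3)
  expect_equal(f$r_max, 120, tolerance = 1e-3)
  expect_equal(f$k_d, 0.34e-9, tolerance = 1e-3)
  expect_identical(f$k_d, f$k_off / f$k_on)   # exact identity
  expect_false(f$koff_unidentifiable)
})

test_that("the integrator matches the single-association closed form", {
  t <- seq(0, 400, by = 2)
  sch <- data.frame(t_start = 0, t_end = 400, conc = 5e-9)
  num <- spr_response(t, 1e6, 3.4e-4, 100, sch)
  keq <- 1e6 * 5e-9 + 3.4e-4
  ana <- 100 * (1e6 * 5e-9 / keq) * (1 - exp(-keq * t))
  expect_lt(max(abs(num[-1] - ana[-1]) / ana[-1]), 1e-6)
})

test_that("an irreversible trace flags k_off as unidentifiable", {
  d <- simulate_sck_spr(1e6, 0, 100, spr_schedule, noise_sd = 0, seed = 1,
                        dt = 2)
  expect_true(all(diff(d$y) >= -1e-9))   # monotone saturating
  f <- fit_sck_spr(d)
  expect_true(f$koff_unidentifiable)
})

test_that("saturation binding behaves at its fixed points and under noise", {
  d <- simulate_saturation(15e-9, 200, 10^seq(-9.5, -6.5, length.out = 9),
                           noise_sd = 0, seed = 1)
  f <- fit_saturation(d)
  expect_equal(f$k_d, 15e-9, tolerance = 1e-6)
  expect_equal(f$b_max, 200, tolerance = 1e-6)
  # at c = k_d the specific binding is half-maximal
  half <- simulate_saturation(15e-9, 200, 15e-9, noise_sd = 0, seed = 1)
  expect_equal(half$y, 100)
  errs <- vapply(1:100, function(s) {
    dd <- simulate_saturation(15e-9, 200, 10^seq(-9.5, -6.5, length.out = 9),
                              noise_sd = 0.10, seed = s)
    fit_saturation(dd)$k_d / 15e-9 - 1
  }, numeric(1))
  expect_lt(abs(stats::median(errs)), 0.10)
})

test_that("the Lindmo extrapolation recovers the immunoreactive fraction", {
  cells <- c(2.5e5, 5e5, 1e6, 2e6, 4e6, 8e6)
  d <- simulate_lindmo(0.73, 2e5, cells, noise_sd = 0, seed = 1)
  f <- lindmo_fit(d)
  expect_equal(f$immunoreactive_fraction, 0.73, tolerance = 1e-9)
  # ideal tracer with effectively infinite antigen: intercept 1, fraction 1
  ideal <- simulate_lindmo(1, 0, cells, noise_sd = 0, seed = 1)
  fi <- lindmo_fit(ideal)
  expect_equal(fi$intercept, 1, tolerance = 1e-9)
  expect_equal(fi$immunoreactive_fraction, 1, tolerance = 1e-9)
  # 100-seed noisy study at 5% noise stays within +/- 0.05
  fr <- vapply(1:100, function(s) {
    lindmo_fit(simulate_lindmo(0.73, 2e5, cells, noise_sd = 0.05,
                               seed = s))$immunoreactive_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.73), 0.05)
  expect_lt(abs(stats::median(fr) - 0.73), 0.05)
})

test_that("duplicate cell concentrations average into the regression", {
  cells <- c(5e5, 5e5, 1e6, 1e6, 2e6, 2e6, 4e6, 4e6)
  d <- simulate_lindmo(0.8, 3e5, cells, noise_sd = 0.04, seed = 6)
  f_dup <- lindmo_fit(d)
  agg <- stats::aggregate(list(y = d$y), by = list(x = d$x), FUN = mean)
  f_avg <- lindmo_fit(assay_dataset(agg$x, agg$y))
  expect_equal(f_dup$immunoreactive_fraction, f_avg$immunoreactive_fraction,
               tolerance = 1e-12)
})

test_that("ill-posed Lindmo input is rejected", {
  d <- assay_dataset(c(1, 2, 4, 8), c(0.05, 0.2, 0.8, 0.99))
  expect_error(lindmo_fit(d), "nonpositive intercept")
  expect_error(lindmo_fit(assay_dataset(c(1, 2, 4), c(0.2, 0.3, 0.4))),
               ">= 4")
  expect_error(lindmo_fit(assay_dataset(c(1, 2, 4, 8), c(0.2, 0.3, 1.2, 0.4))),
               "bound fractions")
})
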