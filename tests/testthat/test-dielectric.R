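test_that("complex permittivity follows eps0*eps_rel - j*sigma/omega", {
  # lossless limits are purely real
  expect_equal(complex_permittivity(78, 0, 1e6), complex(real = 78 * EPS0))
  expect_equal(complex_permittivity(1, 0, 123), complex(real = EPS0))
  expect_equal(Re(complex_permittivity(78, 0, 1e3)), 6.906e-10,
               tolerance = 1e-3)

  # lossy DEP buffer at 1 MHz: hand arithmetic sigma/(2*pi*f)
  e <- complex_permittivity(78, 0.15, 1e6)
  expect_equal(Re(e), 78 * EPS0)
  expect_equal(Im(e), -0.15 / (2 * pi * 1e6))
  expect_equal(Im(e), -2.387e-8, tolerance = 1e-3)

  # vectorised over frequency, imaginary part scales as 1/f
  f <- c(1e3, 1e4, 1e5)
  expect_equal(Im(complex_permittivity(78, 0.15, f)) * f,
               rep(-0.15 / (2 * pi), 3))

  expect_error(complex_permittivity(78, 0.15, 0), "frequency")
  expect_error(complex_permittivity(78, 0.15, -1e3), "frequency")
  expect_error(complex_permittivity(78, -0.1, 1e3), "conductivity")
})

test_that("Clausius-Mossotti factor has the right limits and bounds", {
  em <- complex_permittivity(78, 0.15, 1e5)
  # identical particle and medium: zero contrast
  expect_equal(cm_factor(em, em), 0 + 0i)

  # perfectly polarizable limit: Re -> 1
  ep_big <- complex_permittivity(78, 0.15, 1e5) * 1e6
  expect_equal(Re(cm_factor(ep_big, em)), 1, tolerance = 1e-4)

  # insulating lossless particle in a conductive medium at low
  # frequency: the conductivity term dominates, Re -> -0.5
  ep <- complex_permittivity(2, 0, 1e3)
  em_lo <- complex_permittivity(78, 0.15, 1e3)
  expect_equal(Re(cm_factor(ep, em_lo)), -0.5, tolerance = 1e-3)

  expect_error(cm_factor(complex(real = -1), em), "positive real part")
})

test_that("single-shell permittivity degenerates to the homogeneous sphere", {
  # membrane material identical to cytoplasm: the shell disappears
  d <- 5e-9
  sigma_cyt <- 0.4
  eps_cyt_rel <- 60
  p <- shell_params(radius = 6e-6, g_eff = sigma_cyt / d,
                    c_eff = EPS0 * eps_cyt_rel / d, sigma_cyt = sigma_cyt,
                    membrane_thickness = d, eps_cyt_rel = eps_cyt_rel)
  for (f in c(1e3, 1e5, 1e7)) {
    expect_equal(single_shell_permittivity(p, f),
                 complex_permittivity(eps_cyt_rel, sigma_cyt, f),
                 tolerance = 1e-12)
  }
})

test_that("single-shell permittivity agrees with the thin-shell oracle", {
  p <- row_params(table_rows$equine_control)
  f <- c(1e3, 1e5, 1e7)
  full <- single_shell_permittivity(p, f)
  thin <- thin_shell_eps(p, f)
  expect_lt(max(Mod(full - thin) / Mod(thin)), 0.01)

  # d -> 0 with specific quantities fixed converges to the oracle
  p_small <- shell_params(p$radius, p$g_eff, p$c_eff, p$sigma_cyt,
                          membrane_thickness = 5e-12)
  expect_lt(max(Mod(single_shell_permittivity(p_small, f) - thin) / Mod(thin)),
            1e-4)

  expect_error(shell_params(6e-6, 8571, 14.5e-3, 0.26,
                            membrane_thickness = 7e-6),
               "thin-shell")
})

test_that("Re[K] spectrum has physical limits and shape contract", {
  med <- dep_medium()
  p <- row_params(table_rows$equine_control)

  # low-frequency limit: insulating membrane makes the cell less
  # conductive than the 0.15 S/m buffer -> negative DEP
  expect_lt(re_cm_spectrum(p, med, 10), 0)

  # far above all dispersions the membrane is transparent and the
  # response matches the bare permittivity contrast
  hi <- re_cm_spectrum(p, med, 1e12)
  bare <- Re(cm_factor(complex_permittivity(p$eps_cyt_rel, p$sigma_cyt, 1e12),
                       complex_permittivity(78, 0.15, 1e12)))
  expect_equal(hi, bare, tolerance = 0.05)

  f <- default_frequencies()
  expect_length(re_cm_spectrum(p, med, f), length(f))
})

test_that("DEP force prefactor scales as the formula dictates", {
  med <- dep_medium()
  expect_identical(dep_force_prefactor(5e-6, med, 0.5, 0), 0)
  expect_identical(dep_force_prefactor(5e-6, med, 0, 1e13), 0)
  f1 <- dep_force_prefactor(5e-6, med, 0.5, 1e13)
  expect_equal(dep_force_prefactor(1e-5, med, 0.5, 1e13), 8 * f1)
  expect_equal(f1, 2 * pi * 78 * EPS0 * (5e-6)^3 * 0.5 * 1e13)
  expect_lt(dep_force_prefactor(5e-6, med, -0.3, 1e13), 0)
})

test_that("crossover finder brackets and refines sign changes", {
  med <- dep_medium()
  p <- row_params(table_rows$equine_control)
  xo <- crossover_frequencies(p, med, 1e3, 4.5e7)
  expect_gt(length(xo), 0)
  # the root satisfies Re[K] ~ 0 and lies inside the band
  for (x in xo) {
    expect_lt(abs(re_cm_spectrum(p, med, x)), 1e-6)
    expect_gt(x, 1e3); expect_lt(x, 4.5e7)
  }
  expect_false(is.unsorted(xo))

  # no sign change over a band where the response stays negative
  expect_length(crossover_frequencies(p, med, 10, 1e3), 0)

  expect_error(crossover_frequencies(p, med, 1e7, 1e3), "f_min < f_max")
})

test_that("crossover matches the low-frequency closed form in its regime", {
  # valid when the membrane conductance term is negligible and the
  # cytoplasm is much more conductive than the medium
  med <- dep_medium(conductivity = 0.015)
  p <- shell_params(6.40e-6, g_eff = 0, c_eff = 14.5e-3, sigma_cyt = 0.26)
  xo <- crossover_frequencies(p, med, 1e2, 4.5e7)[1]
  closed <- sqrt(2) * 0.015 / (2 * pi * 6.40e-6 * 14.5e-3)
  expect_equal(xo, closed, tolerance = 0.05)
})
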