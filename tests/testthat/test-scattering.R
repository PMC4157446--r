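test_that("form factors match the tabulated electron counts and trends", {
  expect_equal(form_factor("C", 0), 5.9992, tolerance = 1e-4)
  # electron-count ordering at s = 0
  expect_gt(form_factor("O", 0), form_factor("N", 0))
  expect_gt(form_factor("N", 0), form_factor("C", 0))
  # strictly decreasing on [0, 0.6] for every supported element
  s <- seq(0, 0.6, by = 0.02)
  for (el in known_elements())
    expect_true(all(diff(form_factor(el, s)) < 0), label = el)
  expect_error(form_factor("Xq", 0), "XQ")
  expect_error(form_factor("C", -0.1), ">= 0")
})

test_that("a single atom at the origin scatters with zero phase", {
  cell <- c(20, 25, 30, 90, 90, 90)
  at <- toy_model(1)$atoms
  at$element <- "C"; at$x <- 0; at$y <- 0; at$z <- 0; at$b <- 0
  m <- atomic_model(at, cell)
  refl <- full_reflections(cell, 3)
  fc <- calc_structure_factors(m, refl)
  st <- 1 / (2 * refl$d)
  expect_equal(Mod(fc$f), form_factor("C", st), tolerance = 1e-10)
  expect_equal(max(abs(Im(fc$f))), 0, tolerance = 1e-8)
})

test_that("an atom at fractional (1/2,0,0) alternates sign with h", {
  cell <- c(20, 25, 30, 90, 90, 90)
  at <- toy_model(1)$atoms
  at$element <- "C"; at$x <- 10; at$y <- 0; at$z <- 0; at$b <- 5
  m <- atomic_model(at, cell)
  hkl <- cbind(1:6, 0, 0)
  refl <- reflection_set(hkl, rep(1, 6), cell)
  fc <- calc_structure_factors(m, refl)
  st <- 1 / (2 * refl$d)
  expected <- form_factor("C", st) * exp(-5 * st^2) * (-1)^(refl$hkl[, 1])
  expect_equal(Re(fc$f), expected, tolerance = 1e-10)
})

test_that("FFT-gridded structure factors match direct summation", {
  cell <- c(20, 25, 30, 90, 90, 90)
  m <- toy_model(20, seed = 11, cell = cell)
  refl <- full_reflections(cell, 3)
  fc <- calc_structure_factors(m, refl)
  fcf <- calc_structure_factors_fft(m, refl, grid_spacing = 3 / 4)
  rel <- Mod(fc$f - fcf$f) / pmax(Mod(fc$f), 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("structure factors obey Friedel symmetry and translation invariance", {
  cell <- c(20, 25, 30, 90, 90, 90)
  m <- toy_model(12, seed = 5, cell = cell)
  hkl <- matrix(c(1, 2, 3, 2, -1, 1, 0, 3, -2), ncol = 3, byrow = TRUE)
  both <- rbind(hkl, -hkl)
  # bypass reduction to evaluate both mates explicitly
  refl <- list(hkl = both, fobs = rep(1, 6), free = rep(FALSE, 6),
               d = d_spacing(both, cell), cell = cell)
  class(refl) <- "reflection_set"
  fc <- calc_structure_factors(m, refl)
  expect_equal(fc$f[1:3], Conj(fc$f[4:6]), tolerance = 1e-10)
  # shift by a whole lattice vector: amplitudes and phases unchanged
  m2 <- m; m2$atoms$x <- m2$atoms$x + cell[1]
  fc2 <- calc_structure_factors(m2, refl)
  expect_equal(fc$f, fc2$f, tolerance = 1e-8)
  # non-lattice translation preserves amplitudes only
  m3 <- m; m3$atoms$x <- m3$atoms$x + 1.7
  fc3 <- calc_structure_factors(m3, refl)
  expect_equal(Mod(fc3$f), Mod(fc$f), tolerance = 1e-8)
})

test_that("doubling occupancies doubles every amplitude", {
  m <- toy_model(8, seed = 6)
  m$atoms$occ <- 0.5
  refl <- full_reflections(m$cell, 4)
  f1 <- calc_structure_factors(m, refl)$f
  m$atoms$occ <- 1
  f2 <- calc_structure_factors(m, refl)$f
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
})

test_that("symmetry expansion reproduces an explicit two-copy P1 model", {
  cell <- c(20, 20, 30, 90, 90, 90)
  m <- toy_model(6, seed = 9, cell = cell)
  # 2-fold along z acting in fractional space
  two_fold <- list(R = diag(c(-1, -1, 1)), t = c(0, 0, 0.5))
  msym <- m; msym$symmetry <- list(xmapfit:::sym_identity(), two_fold)
  refl <- full_reflections(cell, 4)
  fc_sym <- calc_structure_factors(msym, refl)
  # build the same two copies by hand in P1
  frac <- xmapfit:::cart_to_frac(xmapfit:::model_xyz(m), cell)
  frac2 <- frac %*% t(two_fold$R) + matrix(two_fold$t, nrow(frac), 3, byrow = TRUE)
  at2 <- m$atoms
  xyz2 <- xmapfit:::frac_to_cart(frac2, cell)
  at2$x <- xyz2[, 1]; at2$y <- xyz2[, 2]; at2$z <- xyz2[, 3]
  both <- rbind(m$atoms, at2); both$serial <- seq_len(nrow(both))
  fc_p1 <- calc_structure_factors(atomic_model(both, cell), refl)
  expect_equal(fc_sym$f, fc_p1$f, tolerance = 1e-8)
})

test_that("scale fitting recovers exact linear and B-factor cases", {
  sys <- hairpin_system()
  refl <- sys$refl
  fc <- calc_structure_factors(sys$target, refl)
  # |F_obs| = 2 |F_calc| exactly
  r2 <- reflection_set(refl$hkl, 2 * Mod(fc$f), refl$cell)
  sc <- fit_scale(r2, fc)
  expect_equal(sc$k, 2, tolerance = 1e-6)
  expect_equal(sc$b_overall, 0, tolerance = 1e-4)
  # |F_obs| = |F_calc| exp(-10 s^2 / 4), s = 1/d
  st2 <- (1 / (2 * refl$d))^2
  r3 <- reflection_set(refl$hkl, Mod(fc$f) * exp(-10 * st2), refl$cell)
  sc3 <- fit_scale(r3, fc)
  expect_equal(sc3$b_overall, 10, tolerance = 1e-3)
  expect_equal(sc3$k, 1, tolerance = 1e-4)
  # random positive amplitudes still give a finite positive scale
  set.seed(1)
  r4 <- reflection_set(refl$hkl, runif(length(refl$fobs), 1, 10), refl$cell)
  sc4 <- fit_scale(r4, fc)
  expect_true(is.finite(sc4$k) && sc4$k > 0)
  expect_error(fit_scale(r2, list(f = rep(0, length(refl$fobs)), hkl = refl$hkl,
                                  cell = refl$cell)), "zero")
})

test_that("R factors: exact-scale identity and a hand-computed example", {
  sys <- hairpin_system()
  refl <- assign_free_flags(sys$refl, 0.05, 3, overwrite = TRUE)
  fc <- calc_structure_factors(sys$target, refl)
  rf <- r_factors(refl, fc)
  expect_lt(rf$r_work, 1e-6)
  expect_lt(rf$r_free, 1e-6)
  # F_obs = {10, 20}, scaled F_calc = {8, 22}: R = (2 + 2)/30
  fo <- c(10, 20); fcal <- c(8, 22)
  sc <- structure(list(k = 1, b_overall = 0), class = "scale_model")
  refl2 <- list(hkl = cbind(c(1, 2), 0, 0), fobs = fo, free = c(FALSE, FALSE),
                d = c(5, 2.5), cell = c(5, 5, 5, 90, 90, 90))
  fc2 <- list(hkl = refl2$hkl, f = complex(real = fcal), d = refl2$d,
              cell = refl2$cell)
  rf2 <- suppressWarnings(r_factors(refl2, fc2, scale = sc))
  expect_equal(rf2$r_work, 4 / 30, tolerance = 1e-12)
  expect_true(is.na(rf2$r_free))
})
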