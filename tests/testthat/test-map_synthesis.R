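test_that("sigma-A estimation hits the perfect-model and random limits", {
  sys <- hairpin_system()
  refl <- assign_free_flags(sys$refl, 0.05, 3, overwrite = TRUE)
  fc <- calc_structure_factors(sys$target, refl)
  sa <- estimate_sigmaA(refl, fc, 8)
  expect_true(all(sa$shells$sigmaA >= 0.999 - 1e-9))
  expect_true(all(sa$shells$D > 0.95 & sa$shells$D < 1.05))
  expect_gt(mean(sa$m), 0.95)
  # permuted amplitudes: no correlation left
  set.seed(4)
  rperm <- reflection_set(refl$hkl, sample(Mod(fc$f)), refl$cell)
  sa0 <- estimate_sigmaA(rperm, fc, 5)
  expect_lt(mean(sa0$shells$sigmaA), 0.25)
  expect_lt(mean(sa0$m), 0.35)
})

test_that("sigma-A decreases monotonically with model coordinate noise", {
  sys <- hairpin_system()
  refl <- sys$refl
  means <- vapply(c(0, 0.5, 1.0), function(noise) {
    m <- sys$target
    if (noise > 0) {
      set.seed(10)
      m <- xmapfit:::set_model_xyz(m, xmapfit:::model_xyz(m) +
        matrix(rnorm(3 * nrow(m$atoms), sd = noise / sqrt(3)), ncol = 3))
    }
    sa <- estimate_sigmaA(refl, calc_structure_factors(m, refl), 6)
    mean(sa$shells$sigmaA)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("map coefficients follow the 2mFo-DFc algebra and free exclusion", {
  # m = 0.5, D = 0.8, |Fo| = 10, |Fc| = 5 -> amplitude 2*0.5*10 - 0.8*5 = 6
  cell <- c(10, 10, 10, 90, 90, 90)
  hkl <- cbind(c(1, 2, 3), 0, 0)
  refl <- list(hkl = hkl, fobs = c(10, 10, NA), free = c(FALSE, TRUE, FALSE),
               d = d_spacing(hkl, cell), cell = cell)
  phase <- exp(1i * c(0.3, 1.1, -2.0))
  fc <- list(hkl = hkl, f = 5 * phase, d = refl$d, cell = cell)
  sa <- list(m = rep(0.5, 3), D = rep(0.8, 3))
  cf <- map_coefficients(refl, fc, sa, exclude_free = TRUE)
  expect_equal(cf$f[1], 6 * phase[1], tolerance = 1e-12)
  expect_equal(cf$f[2], 0 + 0i)                   # free reflection zeroed
  expect_equal(cf$f[3], 0.8 * 5 * phase[3])       # missing Fo -> D*Fc fill
  cf2 <- map_coefficients(refl, fc, sa, exclude_free = FALSE)
  expect_equal(cf2$f[2], 6 * phase[2], tolerance = 1e-12)
  # perfect weights reproduce the model amplitude
  sa1 <- list(m = rep(1, 3), D = rep(1, 3))
  refl1 <- refl; refl1$fobs <- c(5, 5, 5); refl1$free <- rep(FALSE, 3)
  expect_equal(map_coefficients(refl1, fc, sa1)$f, fc$f, tolerance = 1e-12)
})

test_that("sharpening scales amplitudes by exp(B s^2), inverts, and is monotone", {
  cell <- c(20, 20, 20, 90, 90, 90)
  hkl <- cbind(c(1, 2, 4), 0, 0)   # d = 20, 10, 5 A
  cf <- list(hkl = hkl, f = c(1 + 0i, 1 + 0i, 1 + 0i),
             d = d_spacing(hkl, cell), cell = cell)
  s0 <- sharpen(cf, 0)
  expect_equal(s0$f, cf$f)
  s35 <- sharpen(cf, 35)
  st2 <- (1 / (2 * cf$d))^2
  expect_equal(Mod(s35$f), exp(35 * st2), tolerance = 1e-12)
  expect_true(all(diff(Mod(s35$f)) > 0))   # higher resolution boosted more
  back <- sharpen(s35, -35)
  expect_equal(back$f, cf$f, tolerance = 1e-12)
})

test_that("map synthesis matches a brute-force Fourier sum and the DC term", {
  cell <- c(10, 12, 14, 90, 90, 90)
  set.seed(8)
  hkl <- unique(xmapfit:::friedel_canonical(
    as.matrix(expand.grid(-3:3, -3:3, 0:3))))
  hkl <- hkl[!(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0), ]
  cf <- list(hkl = hkl, f = complex(real = rnorm(nrow(hkl)),
                                    imaginary = rnorm(nrow(hkl))),
             d = d_spacing(hkl, cell), cell = cell)
  mp <- synthesize_map(cf, grid_spacing = min(cf$d) / 3)
  dims <- dim(mp$values)
  g <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1), 0:(dims[3] - 1)))
  H <- rbind(cf$hkl, -cf$hkl)
  Fv <- c(cf$f, Conj(cf$f))
  slow <- rep(0 + 0i, nrow(g))
  for (r in seq_len(nrow(H)))
    slow <- slow + Fv[r] * exp(-2i * pi * (g[, 1] * H[r, 1] / dims[1] +
                                           g[, 2] * H[r, 2] / dims[2] +
                                           g[, 3] * H[r, 3] / dims[3]))
  slow <- Re(slow) / cell_volume(cell)
  expect_lt(max(abs(slow - as.numeric(mp$values))) / max(abs(slow)), 1e-8)
  # a lone (0,0,0) coefficient gives the constant c/V
  cf0 <- list(hkl = cbind(0, 0, 0), f = 7 + 0i, d = Inf, cell = cell)
  mp0 <- synthesize_map(cf0, grid_spacing = 2)
  expect_equal(as.numeric(mp0$values), rep(7 / cell_volume(cell), length(mp0$values)),
               tolerance = 1e-12)
})

test_that("a perfect-model map peaks at the atoms", {
  sys <- hairpin_system()
  refl <- sys$refl
  fc <- calc_structure_factors(sys$target, refl)
  sa <- estimate_sigmaA(refl, fc)
  mp <- synthesize_map(map_coefficients(refl, fc, sa, exclude_free = FALSE))
  xyz <- xmapfit:::model_xyz(sys$target)
  val_at_atoms <- xmapfit:::interp_trilinear(mp, xyz)$value
  # density at atoms well above the map's bulk
  expect_gt(mean(val_at_atoms), mean(mp$values) + 2 * sd(mp$values))
  # local maxima within 1 voxel of >= 95% of atoms
  dims <- dim(mp$values)
  frac <- xmapfit:::cart_to_frac(xyz, mp$cell)
  near_peak <- vapply(seq_len(nrow(xyz)), function(j) {
    u <- round(frac[j, ] * dims)
    idx <- as.matrix(expand.grid((u[1] - 1):(u[1] + 1), (u[2] - 1):(u[2] + 1),
                                 (u[3] - 1):(u[3] + 1)))
    idx <- (idx %% matrix(dims, nrow(idx), 3, byrow = TRUE)) + 1L
    centre <- mp$values[matrix(((u %% dims) + 1L), 1)]
    vals <- mp$values[idx]
    max(vals) >= centre && max(vals) > mean(mp$values) + sd(mp$values)
  }, logical(1))
  expect_gt(mean(near_peak), 0.95)
})

test_that("excluding free reflections changes the map but keeps atom coverage", {
  sys <- hairpin_system()
  refl <- assign_free_flags(sys$refl, 0.05, 3, overwrite = TRUE)
  m_excl <- model_phased_map(sys$target, refl, exclude_free = TRUE)
  m_all <- model_phased_map(sys$target, refl, exclude_free = FALSE)
  expect_gt(max(abs(m_excl$values - m_all$values)), 0)
  xyz <- xmapfit:::model_xyz(sys$target)
  v <- xmapfit:::interp_trilinear(m_excl, xyz)$value
  expect_gt(mean(v > mean(m_excl$values) + sd(m_excl$values)), 0.95)
})

test_that("kicked maps are seeded, averaged and spread with kick size", {
  sys <- hairpin_system()
  refl <- sys$refl
  a <- kicked_map(sys$search, refl, kick_rms = 0.3, n_kicks = 4, seed = 5)
  b <- kicked_map(sys$search, refl, kick_rms = 0.3, n_kicks = 4, seed = 5)
  expect_identical(a$values, b$values)
  plain <- model_phased_map(sys$search, refl)
  # kick-averaged map differs from the unkicked map, less so for tiny kicks
  d_small <- mean(abs(kicked_map(sys$search, refl, 0.05, 4, seed = 5)$values -
                      plain$values))
  d_big <- mean(abs(kicked_map(sys$search, refl, 0.4, 4, seed = 5)$values -
                    plain$values))
  expect_lt(d_small, d_big)
  expect_error(kicked_map(sys$search, refl, 0, 4), "kick_rms")
  expect_error(kicked_map(sys$search, refl, 0.3, 1), "kicks")
})

test_that("the grid potential clamps, spans [0, xi] and scales linearly", {
  cell <- c(10, 10, 10, 90, 90, 90)
  v <- array(seq(-2, 6, length.out = 4^3), dim = c(4, 4, 4))
  mp <- map_grid(v, cell)
  pot <- density_to_potential(mp, xi = 0.3, phi_thr = 0)
  expect_equal(min(pot$values), 0)
  expect_equal(max(pot$values), 0.3)
  expect_true(all(pot$values[v <= 0] == 0.3))       # clamped plateau
  expect_equal(pot$values[which(v == max(v))], 0)   # zero at the maximum
  # halfway density -> xi/2
  vmid <- array(c(0, 3, 6), dim = c(3, 1, 1))
  pmid <- density_to_potential(map_grid(vmid, cell), xi = 0.4, phi_thr = 0)
  expect_equal(pmid$values[2, 1, 1], 0.2, tolerance = 1e-12)
  # doubling xi doubles the potential
  pot2 <- density_to_potential(mp, xi = 0.6, phi_thr = 0)
  expect_equal(pot2$values, 2 * pot$values, tolerance = 1e-12)
  # voxel-wise non-increasing in density
  o <- order(as.numeric(v))
  expect_true(all(diff(as.numeric(pot$values)[o]) <= 1e-12))
  # quantile thresholding and the degenerate flat map
  potq <- density_to_potential(mp, xi = 0.3, phi_thr = 0.9, thr_quantile = TRUE)
  expect_equal(mean(potq$values == 0.3), 0.9, tolerance = 0.02)
  expect_error(density_to_potential(map_grid(array(1, c(2, 2, 2)), cell), 0.3,
                                    phi_thr = 1), "threshold")
})
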