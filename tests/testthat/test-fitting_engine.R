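test_that("a linear density ramp produces a constant force toward high density", {
  cell <- c(10, 10, 10, 90, 90, 90)
  nx <- 20
  # potential decreasing linearly in x (density increasing): V = xi * (1 - x/L)
  v <- array(rep(seq(1, 0, length.out = nx), times = 10 * 10) * 0.3,
             dim = c(nx, 10, 10))
  pot <- map_grid(v, cell)
  pot$xi <- 0.3
  class(pot) <- c("grid_potential", class(pot))
  p <- peptide_system()
  coup <- coupling_spec(p$topo, "all-heavy")
  # place atoms away from the wrap seam
  xyz <- p$xyz
  xyz[, 1] <- 2 + (xyz[, 1] - min(xyz[, 1])) * 0.3
  em <- map_energy_forces(xyz, pot, coup)
  # expected: the ramp descends xi over (nx-1) voxels of size L/nx, so
  # f_x = w * xi / ((nx-1) L / nx) per atom; f_y = f_z = 0
  grad <- 0.3 / ((nx - 1) * cell[1] / nx)
  expect_equal(em$forces[, 1], coup$w * grad, tolerance = 1e-6)
  expect_lt(max(abs(em$forces[, 2:3])), 1e-10)
})

test_that("atoms in the clamped flat region feel no map force", {
  cell <- c(10, 10, 10, 90, 90, 90)
  v <- array(0, dim = c(10, 10, 10))
  v[8:10, 8:10, 8:10] <- 5   # density blob far from the atoms
  pot <- density_to_potential(map_grid(v, cell), xi = 0.5, phi_thr = 0)
  p <- peptide_system()
  coup <- coupling_spec(p$topo, "all-heavy")
  xyz <- matrix(2, p$topo$n_atoms, 3) + matrix(runif(p$topo$n_atoms * 3), ncol = 3)
  em <- map_energy_forces(xyz, pot, coup)
  expect_equal(max(abs(em$forces)), 0)
  expect_equal(em$energy, 0.5 * sum(coup$w))   # plateau value xi per weight
})

test_that("interpolated map forces match finite differences of the energy", {
  sys <- hairpin_system()
  pot <- density_to_potential(model_phased_map(sys$target, sys$refl), xi = 0.3)
  topo <- build_topology(sys$target)
  coup <- coupling_spec(topo, "all-heavy")
  set.seed(2)
  xyz <- xmapfit:::model_xyz(sys$target) +
    matrix(rnorm(3 * topo$n_atoms, sd = 0.2), ncol = 3)
  em <- map_energy_forces(xyz, pot, coup)
  err <- fd_force_check(function(x) map_energy_forces(x, pot, coup)$energy,
                        xyz, em$forces, idx = sample(topo$n_atoms, 10))
  expect_lt(err, 1e-5)
  # U_EM bounds and coupling selectivity
  expect_gte(em$energy, 0)
  expect_lte(em$energy, pot$xi * sum(coup$w))
  bb <- coupling_spec(topo, "backbone")
  em_bb <- map_energy_forces(xyz, pot, bb)
  expect_true(all(em_bb$forces[!bb$coupled, ] == 0))
  # doubling xi doubles energy and forces
  pot2 <- density_to_potential(model_phased_map(sys$target, sys$refl), xi = 0.6)
  em2 <- map_energy_forces(xyz, pot2, coup)
  expect_equal(em2$energy, 2 * em$energy, tolerance = 1e-9)
  expect_equal(em2$forces, 2 * em$forces, tolerance = 1e-9)
})

test_that("compiled and reference force paths agree to double precision", {
  sys <- hairpin_system()
  topo <- build_topology(sys$search)
  restr <- assign_secondary_structure(sys$search, topo)
  pot <- density_to_potential(model_phased_map(sys$search, sys$refl), xi = 0.4)
  coup <- coupling_spec(topo, "backbone")
  set.seed(6)
  xyz <- xmapfit:::model_xyz(sys$search) +
    matrix(rnorm(3 * topo$n_atoms, sd = 0.25), ncol = 3)
  er <- xmapfit:::total_energy_forces(xyz, topo, restr, pot, coup)
  ec <- xmapfit:::energy_forces_cpp(xyz, topo, restr, pot, coup)
  expect_equal(ec$energy, er$energy, tolerance = 1e-12)
  expect_lt(max(abs(ec$forces - er$forces)), 1e-10)
})

test_that("dynamics stay put at a minimum and conserve energy without friction", {
  p <- peptide_system()
  # T = 0, gamma = 0, tiny perturbation damped out: effectively static
  x0 <- minimize(p$xyz, p$topo, p$restr)$xyz
  run0 <- run_dynamics(x0, p$topo, p$restr,
                       params = dynamics_params(1, 0, 0, 50, 1))
  expect_lt(max(abs(run0$xyz - x0)), 5e-3)
  # NVE: total energy drift < 0.1% over 1000 half-fs steps
  run <- run_dynamics(p$xyz, p$topo, p$restr,
                      params = dynamics_params(0.5, 300, 0, 1000, 11))
  n <- nrow(p$xyz)
  totE <- run$energies + 1.5 * n * 0.0019872041 * run$temperature
  expect_lt(abs(totE[1000] - totE[2]) / abs(totE[2]), 0.001)
})

test_that("trajectories are bit-reproducible per seed on both engines", {
  p <- peptide_system()
  for (eng in c("cpp", "r")) {
    a <- run_dynamics(p$xyz, p$topo, p$restr,
                      params = dynamics_params(1, 300, 5, 60, 9), engine = eng)
    b <- run_dynamics(p$xyz, p$topo, p$restr,
                      params = dynamics_params(1, 300, 5, 60, 9), engine = eng)
    expect_identical(a$xyz, b$xyz)
    c2 <- run_dynamics(p$xyz, p$topo, p$restr,
                       params = dynamics_params(1, 300, 5, 60, 10), engine = eng)
    expect_gt(max(abs(a$xyz - c2$xyz)), 0)
  }
})

test_that("the thermostat equipartitions a harmonic dimer", {
  topo <- structure(list(
    bonds = matrix(c(1, 2, 1.5, 100), 1, 4), angles = matrix(0, 0, 5),
    dihedrals = matrix(0, 0, 6), masses = c(12, 12), radii = c(1, 1),
    k_rep = 0, rep_scale = 0.85, excl = "1_2", n_atoms = 2L, heavy = 1:2,
    names = c("C", "C"), resno = c(1, 1), chain = c("A", "A"),
    resname = c("UNK", "UNK")), class = "topology")
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  run <- run_dynamics(x, topo, params = dynamics_params(0.5, 300, 10, 20000, 3))
  # mean instantaneous temperature within 10% of the target
  expect_equal(mean(run$temperature[5000:20000]), 300, tolerance = 0.1)
})

test_that("minimization restores a stretched bond and finds a density well", {
  p <- peptide_system()
  xyz <- p$xyz
  io <- which(p$topo$names == "O")[1]
  b <- p$topo$bonds
  row <- which(b[, 1] == io | b[, 2] == io)[1]
  j <- setdiff(b[row, 1:2], io); r0 <- b[row, 3]
  dirv <- (xyz[io, ] - xyz[j, ]) / sqrt(sum((xyz[io, ] - xyz[j, ])^2))
  xyz[io, ] <- xyz[io, ] + 0.4 * dirv
  mres <- minimize(xyz, p$topo, p$restr)
  d <- sqrt(sum((mres$xyz[io, ] - mres$xyz[j, ])^2))
  expect_equal(d, r0, tolerance = 1e-3)
  # immediate convergence when starting at the minimum
  again <- minimize(mres$xyz, p$topo, p$restr)
  expect_lt(max(abs(again$xyz - mres$xyz)), 1e-4)
  # single atom descends into a quadratic density well
  cell <- c(10, 10, 10, 90, 90, 90)
  g <- as.matrix(expand.grid(0:19, 0:19, 0:19)) / 2
  d2 <- rowSums(sweep(g, 2, c(5, 5, 5))^2)
  pot <- density_to_potential(map_grid(array(-d2, c(20, 20, 20)), cell),
                              xi = 2, phi_thr = min(-d2) - 1)
  at <- toy_model(1)$atoms; at$x <- 3.4; at$y <- 5.3; at$z <- 6.1
  m1 <- atomic_model(at, cell)
  t1 <- suppressWarnings(build_topology(m1))
  cp <- coupling_spec(t1, "all-heavy")
  got <- minimize(cbind(at$x, at$y, at$z), t1, NULL, pot, cp)$xyz
  expect_equal(as.numeric(got), c(5, 5, 5), tolerance = 0.1)
})

test_that("annealing reduces to plain dynamics for a one-segment schedule", {
  p <- peptide_system()
  base <- dynamics_params(1, 300, 5, 100, seed = 4)
  ann <- anneal(p$xyz, p$topo, p$restr,
                schedule = data.frame(temperature = 300, n_steps = 100),
                base_params = base)
  ref <- run_dynamics(p$xyz, p$topo, p$restr,
                      params = dynamics_params(1, 300, 5, 100, seed = 4 + 1))
  expect_identical(ann$xyz, ref$xyz)
  # a cooling ladder executes all phases and ends at low kinetic energy
  lad <- anneal(p$xyz, p$topo, p$restr,
                schedule = data.frame(temperature = c(600, 300, 0),
                                      n_steps = c(100, 100, 200)),
                base_params = base)
  expect_equal(length(lad$history), 3)
  expect_equal(lad$history[[3]]$temperature, 0)
})

test_that("annealing escapes a shallow density minimum more often than quenching", {
  # single atom in a double-well potential along x: deep well at x=7,
  # shallow at x=3, barrier between
  cell <- c(10, 6, 6, 90, 90, 90)
  nx <- 40
  xs <- (0:(nx - 1)) / nx * 10
  prof <- 0.55 * exp(-(xs - 3)^2 / 0.8) + 1.0 * exp(-(xs - 7)^2 / 0.8)
  v <- array(rep(prof, times = 6 * 6), dim = c(nx, 6, 6))
  pot <- density_to_potential(map_grid(v, cell), xi = 3)
  at <- toy_model(1)$atoms; at$x <- 3; at$y <- 3; at$z <- 3
  m1 <- atomic_model(at, cell)
  t1 <- suppressWarnings(build_topology(m1))
  # unit weight so the barrier (~1.6 kcal/mol) is comparable to kT at the
  # annealing temperatures; mass weighting would scale it 12-fold
  cp <- coupling_spec(t1, "all-heavy", weights = 1)
  esc <- function(seed, schedule) {
    out <- anneal(cbind(3, 3, 3), t1, NULL, pot, cp, schedule,
                  base_params = dynamics_params(1, 300, 5, 100, seed = seed))
    fin <- minimize(out$xyz, t1, NULL, pot, cp)$xyz
    abs(fin[1] - 7) < 1
  }
  hot <- data.frame(temperature = c(900, 500, 300), n_steps = 2000)
  cold <- data.frame(temperature = c(1e-6, 1e-6, 1e-6), n_steps = 2000)
  n_hot <- sum(vapply(1:12, esc, logical(1), schedule = hot))
  n_cold <- sum(vapply(1:12, esc, logical(1), schedule = cold))
  expect_gt(n_hot, n_cold)
})
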