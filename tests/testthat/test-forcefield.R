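test_that("topology counts follow the residue templates", {
  spec <- toy_system_spec(n_res = 5, architecture = "extended", seed = 1)
  m <- make_target(spec)   # 5 residues x (N, CA, C, O, CB)
  topo <- build_topology(m)
  # per residue: N-CA, CA-C, C-O, CA-CB = 4 bonds; plus 4 peptide links
  expect_equal(nrow(topo$bonds), 5 * 4 + 4)
  # impropers: 5 chirality + 4 peptide planes
  expect_equal(nrow(topo$dihedrals), 9)
  expect_equal(topo$n_atoms, 25)
  expect_equal(topo$masses, atomic_mass(m$atoms$element))
})

test_that("glycine gets no chirality improper", {
  spec <- toy_system_spec(n_res = 5, architecture = "extended", seed = 1)
  m <- make_target(spec)
  # drop one CB to make residue 3 glycine
  drop <- which(m$atoms$resno == 3 & m$atoms$name == "CB")
  m$atoms <- m$atoms[-drop, ]
  m$atoms$resname[m$atoms$resno == 3] <- "GLY"
  topo <- build_topology(m)
  expect_equal(nrow(topo$dihedrals), 8)   # one chirality improper fewer
})

test_that("ideal template geometry scores zero bonded energy", {
  p <- peptide_system()
  ef <- compute_energy_forces(p$xyz, p$topo)
  expect_lt(ef$breakdown[["bond"]], 1e-8)
  expect_lt(ef$breakdown[["angle"]], 1e-6)
  expect_lt(ef$breakdown[["improper"]], 1e-6)
  expect_lt(ef$energy, 0.5)   # only nonbonded noise remains
})

test_that("a stretched bond stores k delta^2 with force 2 k delta", {
  p <- peptide_system()
  xyz <- p$xyz
  # stretch the terminal C-O bond along its axis
  b <- p$topo$bonds
  io <- which(p$topo$names == "O")[1]
  row <- which(b[, 1] == io | b[, 2] == io)[1]
  j <- setdiff(b[row, 1:2], io)
  dirv <- (xyz[io, ] - xyz[j, ]) / sqrt(sum((xyz[io, ] - xyz[j, ])^2))
  delta <- 0.2
  xyz[io, ] <- xyz[io, ] + delta * dirv
  e0 <- compute_energy_forces(p$xyz, p$topo)$breakdown[["bond"]]
  ef <- compute_energy_forces(xyz, p$topo)
  expect_equal(ef$breakdown[["bond"]] - e0, 300 * delta^2, tolerance = 1e-6)
  fproj <- abs(sum(ef$forces[io, ] * dirv))
  expect_equal(fproj, 2 * 300 * delta, tolerance = 1e-3)
})

test_that("analytic forces match finite differences for every term", {
  p <- peptide_system()
  set.seed(9)
  xyz <- p$xyz + matrix(rnorm(length(p$xyz), sd = 0.15), ncol = 3)
  ef <- compute_energy_forces(xyz, p$topo, p$restr)
  err <- fd_force_check(function(x) compute_energy_forces(x, p$topo, p$restr)$energy,
                        xyz, ef$forces, idx = sample(nrow(xyz), 12))
  expect_lt(err, 1e-4)
  # all terms at their targets: near-zero force
  ef0 <- compute_energy_forces(p$xyz, p$topo)
  b0 <- ef0$breakdown
  expect_lt(b0[["bond"]] + b0[["angle"]] + b0[["improper"]], 1e-6)
})

test_that("forces sum to zero and energy is rotation/translation invariant", {
  p <- peptide_system()
  set.seed(3)
  xyz <- p$xyz + matrix(rnorm(length(p$xyz), sd = 0.2), ncol = 3)
  ef <- compute_energy_forces(xyz, p$topo, p$restr)
  expect_lt(max(abs(colSums(ef$forces))), 1e-8)
  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- xyz %*% t(R) + matrix(c(3, -2, 5), nrow(xyz), 3, byrow = TRUE)
  ef2 <- compute_energy_forces(xyz2, p$topo, p$restr)
  expect_equal(ef2$energy, ef$energy, tolerance = 1e-8)
})

test_that("overlapping atoms warn and yield a capped, finite force", {
  p <- peptide_system()
  xyz <- p$xyz
  far <- which(p$topo$names == "CB")[c(1, 5)]   # not bonded to each other
  xyz[far[2], ] <- xyz[far[1], ] + c(0.05, 0, 0)
  expect_warning(ef <- compute_energy_forces(xyz, p$topo), "overlap")
  expect_true(all(is.finite(ef$forces)))
})

test_that("geometric secondary-structure assignment finds ideal helices", {
  # helix / left-handed loop / helix with unambiguous torsion classes
  tors <- c(rep(list(c(-57, -47)), 8), rep(list(c(60, 60)), 3),
            rep(list(c(-57, -47)), 8))
  ch <- xmapfit:::build_polyala(tors)
  xyz <- as.matrix(ch[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, apply(xyz, 2, min) - 10)
  atoms <- data.frame(serial = seq_len(nrow(ch)), name = ch$name,
                      element = substr(ch$name, 1, 1), resname = "ALA",
                      resno = ch$resno, chain = "A", insert = "", alt = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 20)
  m <- atomic_model(atoms, c(apply(xyz, 2, max) + 10, 90, 90, 90))
  topo <- build_topology(m)
  rs <- assign_secondary_structure(m, topo)
  ss <- rs$assignment$ss
  expect_gt(sum(ss == "helix"), 10)
  # the left-handed connector receives no phi/psi restraint
  expect_true(all(ss[10:11] == "loop"))
  loop_ca <- which(m$atoms$resno %in% 10:11 & m$atoms$name == "CA")
  expect_false(any(rs$dihedrals[, 3] %in% loop_ca))
  # restraint energy of an ideal helix is ~0 apart from the O..N targets
  ef <- compute_energy_forces(xmapfit:::model_xyz(m), topo, rs)
  expect_lt(ef$breakdown[["ss_dihedral"]] / max(1, nrow(rs$dihedrals)), 0.15)
  # annotation mode rejects absent residues
  expect_error(assign_secondary_structure(m, topo, mode = "from-annotation",
    annotation = data.frame(chain = "A", resno = 99, type = "helix")), "absent")
})

test_that("NCS restraints ignore rigid moves and restore displaced atoms", {
  p <- peptide_system()
  n <- p$topo$n_atoms
  # two identical copies side by side
  xyz <- rbind(p$xyz, sweep(p$xyz, 2, c(30, 0, 0), `+`))
  grp <- list(list(seq_len(n), n + seq_len(n)))
  e0 <- ncs_restraint_forces(xyz, grp)
  expect_lt(e0$energy, 1e-12)
  # rigid rotation of copy 2: still zero after superposition
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  xyz2 <- xyz
  xyz2[n + seq_len(n), ] <- p$xyz %*% t(R) + matrix(c(40, 5, 0), n, 3, byrow = TRUE)
  expect_lt(ncs_restraint_forces(xyz2, grp)$energy, 1e-10)
  # displace one atom in copy 2: restoring force matches finite differences
  xyz3 <- xyz2
  xyz3[n + 3, ] <- xyz3[n + 3, ] + c(0.6, -0.3, 0.2)
  en <- ncs_restraint_forces(xyz3, grp, k_ncs = 5)
  expect_gt(en$energy, 0)
  err <- fd_force_check(function(x) ncs_restraint_forces(x, grp, k_ncs = 5)$energy,
                        xyz3, en$forces, idx = c(3, n + 3), h = 1e-5)
  expect_lt(err, 1e-3)
  # single-copy group is a no-op
  expect_equal(ncs_restraint_forces(xyz, list(list(1:n)))$energy, 0)
})

test_that("unknown residues are restrained to their starting geometry", {
  m <- toy_model(4, seed = 13)
  m$atoms$resname <- "LIG"
  m$atoms$resno <- 1
  m$atoms$name <- c("C1", "C2", "C3", "C4")
  # chain of three 1.5-A bonds
  m$atoms$x <- c(0, 1.5, 3.0, 4.5) + 5
  m$atoms$y <- 5 + c(0, 0, 0.4, 0.4)
  m$atoms$z <- 5
  expect_warning(topo <- build_topology(m), "non-standard")
  expect_gte(nrow(topo$bonds), 3)
  ef <- compute_energy_forces(cbind(m$atoms$x, m$atoms$y, m$atoms$z), topo)
  expect_lt(ef$energy, 1e-8)   # starting geometry is the restraint target
})
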