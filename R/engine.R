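# Packs topology + restraints + grid potential into the flat list the
# compiled evaluator consumes: restraint distances are appended to the bond
# table, restraint torsions to the dihedral table, and the nonbonded term
# becomes an explicit non-excluded pair list with precomputed cutoffs.
pack_forcefield <- function(topo, restraints = NULL, potential = NULL,
                            coupling = NULL) {
  bonds <- topo$bonds
  dihedrals <- topo$dihedrals
  if (!is.null(restraints)) {
    if (nrow(restraints$distances)) bonds <- rbind(bonds, restraints$distances)
    if (nrow(restraints$dihedrals)) dihedrals <- rbind(dihedrals, restraints$dihedrals)
  }
  n <- topo$n_atoms
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (nrow(prs)) {
    keys <- paste0(prs[, 1], "_", prs[, 2])
    prs <- prs[!(keys %in% topo$excl), , drop = FALSE]
  }
  rc <- (topo$radii[prs[, 1]] + topo$radii[prs[, 2]]) * topo$rep_scale
  ff <- list(bonds = bonds, angles = topo$angles, dihedrals = dihedrals,
             pairs = matrix(as.integer(prs), ncol = 2), rc = rc,
             k_rep = topo$k_rep, grid = numeric(0))
  if (!is.null(potential)) {
    if (is.null(coupling)) stop("potential supplied without a coupling spec")
    ff$grid <- as.numeric(potential$values)
    ff$dims <- as.integer(dim(potential$values))
    ff$fracmat <- cell_frac_matrix(potential$cell)
    ff$origin <- as.numeric(potential$origin)
    ff$w <- as.numeric(coupling$w)
  }
  ff
}

# compiled single-point evaluation (same contract as total_energy_forces
# minus NCS); the R and C++ paths are cross-checked in the test suite
energy_forces_cpp <- function(xyz, topo, restraints = NULL, potential = NULL,
                              coupling = NULL, ff = NULL) {
  if (is.null(ff)) ff <- pack_forcefield(topo, restraints, potential, coupling)
  .cpp_energy_forces(matrix(xyz, ncol = 3), ff)
}
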