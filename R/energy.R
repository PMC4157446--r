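# Bonded + nonbonded energy and analytic forces for the simplified
# restrained molecular-mechanics potential.  All terms are internal
# (rotation/translation invariant) and every gradient is checked against
# finite differences in the test suite.  Energy convention: k * delta^2.

# scatter-add row vectors into the force accumulator
acc_force <- function(F, idx, contrib) {
  s <- rowsum(contrib, idx)
  ii <- as.integer(rownames(s))
  F[ii, ] <- F[ii, ] + s
  F
}

energy_bonds <- function(xyz, tab) {
  if (!nrow(tab)) return(list(e = 0, F = NULL))
  i <- tab[, 1]; j <- tab[, 2]; r0 <- tab[, 3]; k <- tab[, 4]
  d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  r <- row_norm(d)
  delta <- r - r0
  e <- sum(k * delta^2)
  g <- (2 * k * delta / pmax(r, 1e-8)) * d     # dE/dr_i
  list(e = e, idx = c(i, j), g = rbind(g, -g))
}

energy_angles <- function(xyz, tab) {
  if (!nrow(tab)) return(list(e = 0, F = NULL))
  i <- tab[, 1]; j <- tab[, 2]; k3 <- tab[, 3]; th0 <- tab[, 4]; k <- tab[, 5]
  ag <- angle_and_grad(xyz[i, , drop = FALSE], xyz[j, , drop = FALSE],
                       xyz[k3, , drop = FALSE])
  delta <- ag$theta - th0
  e <- sum(k * delta^2)
  w <- 2 * k * delta
  gi <- w * ag$gi; gk <- w * ag$gk
  list(e = e, idx = c(i, j, k3), g = rbind(gi, -(gi + gk), gk))
}

energy_dihedrals <- function(xyz, tab) {
  if (!nrow(tab)) return(list(e = 0, F = NULL))
  i <- tab[, 1]; j <- tab[, 2]; k3 <- tab[, 3]; l <- tab[, 4]
  phi0 <- tab[, 5]; k <- tab[, 6]
  dg <- dihedral_and_grad(xyz[i, , drop = FALSE], xyz[j, , drop = FALSE],
                          xyz[k3, , drop = FALSE], xyz[l, , drop = FALSE])
  delta <- wrap_angle(dg$phi - phi0)
  e <- sum(k * delta^2)
  w <- 2 * k * delta
  list(e = e, idx = c(i, j, k3, l),
       g = rbind(w * dg$gi, w * dg$gj, w * dg$gk, w * dg$gl))
}

# soft-core harmonic repulsion for non-excluded pairs closer than the
# scaled radius sum; overlaps below 0.1 A get a capped (linearized) force
energy_repulsion <- function(xyz, topo) {
  n <- nrow(xyz)
  if (n < 2) return(list(e = 0, F = NULL))
  rc_max <- 2 * max(topo$radii) * topo$rep_scale
  D <- as.matrix(stats::dist(xyz))
  cand <- which(D < rc_max & upper.tri(D), arr.ind = TRUE)
  if (!nrow(cand)) return(list(e = 0, F = NULL))
  keys <- paste0(cand[, 1], "_", cand[, 2])
  cand <- cand[!(keys %in% topo$excl), , drop = FALSE]
  if (!nrow(cand)) return(list(e = 0, F = NULL))
  i <- cand[, 1]; j <- cand[, 2]
  rc <- (topo$radii[i] + topo$radii[j]) * topo$rep_scale
  d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  r <- row_norm(d)
  act <- r < rc
  if (!any(act)) return(list(e = 0, F = NULL))
  i <- i[act]; j <- j[act]; rc <- rc[act]; d <- d[act, , drop = FALSE]; r <- r[act]
  if (any(r < 0.1)) {
    warning("overlapping atoms (r < 0.1 A); repulsion force capped")
    r <- pmax(r, 0.1)
  }
  k <- topo$k_rep
  e <- sum(k * (rc - r)^2)
  g <- (-2 * k * (rc - r) / r) * d
  list(e = e, idx = c(i, j), g = rbind(g, -g))
}

#' Energy and forces of the restrained force field
#'
#' Evaluates the simplified molecular-mechanics potential (harmonic bonds,
#' angles, improper/omega torsions, soft-core repulsion) plus the
#' secondary-structure restraint terms, with analytic forces
#' (`forces = -grad U`).
#'
#' @param xyz coordinate matrix (n x 3, Angstrom), rows matching the
#'   topology's atoms.
#' @param topo a [build_topology()] result.
#' @param restraints optional [assign_secondary_structure()] result.
#' @return list with total `energy` (kcal/mol), `forces` (n x 3,
#'   kcal/mol/A) and a named `breakdown` of term energies.
#' @export
compute_energy_forces <- function(xyz, topo, restraints = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  if (nrow(xyz) != topo$n_atoms) stop("coordinate count does not match topology")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  F <- matrix(0, nrow(xyz), 3)
  terms <- list(
    bond = energy_bonds(xyz, topo$bonds),
    angle = energy_angles(xyz, topo$angles),
    improper = energy_dihedrals(xyz, topo$dihedrals),
    repulsion = energy_repulsion(xyz, topo))
  if (!is.null(restraints)) {
    terms$ss_dihedral <- energy_dihedrals(xyz, restraints$dihedrals)
    terms$ss_hbond <- energy_bonds(xyz, restraints$distances)
  }
  e <- 0
  for (t in terms) {
    e <- e + t$e
    if (!is.null(t$g)) F <- acc_force(F, t$idx, -t$g)   # force = -grad
  }
  list(energy = e, forces = F,
       breakdown = vapply(terms, `[[`, numeric(1), "e"))
}

#' Noncrystallographic-symmetry restraint energy and forces
#'
#' Each copy of an NCS group is superposed (least squares) onto the mean of
#' all superposed copies; deviations from that consensus are penalized
#' harmonically.  Rigid-body differences between copies carry no energy.
#'
#' @param xyz coordinate matrix (n x 3).
#' @param ncs_groups list of groups; each group is a list of equal-length
#'   atom index vectors, one per copy.
#' @param k_ncs force constant (kcal/mol/A^2).
#' @return list with `energy` and `forces` (n x 3).
#' @export
ncs_restraint_forces <- function(xyz, ncs_groups, k_ncs = 5) {
  F <- matrix(0, nrow(xyz), 3)
  e <- 0
  for (grp in ncs_groups) {
    m <- length(grp)
    if (m < 2) next
    len <- unique(lengths(grp))
    if (length(len) != 1) stop("NCS copies must have equal atom counts")
    # iterate: align all copies to the running mean (2 rounds suffice)
    ref <- xyz[grp[[1]], , drop = FALSE]
    fits <- NULL
    for (it in 1:2) {
      fits <- lapply(grp, function(ix) kabsch(xyz[ix, , drop = FALSE], ref))
      ref <- Reduce(`+`, lapply(fits, `[[`, "xyz")) / m
    }
    for (c_i in seq_len(m)) {
      dev <- fits[[c_i]]$xyz - ref
      e <- e + k_ncs * sum(dev^2)
      # force via the rotation applied to this copy (alignment is at its
      # least-squares optimum, so rotational variation is second order)
      g <- 2 * k_ncs * dev %*% fits[[c_i]]$R
      F <- acc_force(F, grp[[c_i]], -g)
    }
  }
  list(energy = e, forces = F)
}
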