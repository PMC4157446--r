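# AKMA time unit: with masses in amu, energies in kcal/mol and lengths in
# Angstrom, accelerations F/m are consistent when time is measured in units
# of 48.88821 fs.
AKMA_FS <- 48.88821
KB <- 0.0019872041  # kcal/mol/K

#' Coupling of atoms to the density potential
#'
#' Selects which atoms feel the map and with what weight.  Weights default
#' to atomic masses, which keeps accelerations due to the map comparable
#' across elements.
#'
#' @param topo a [build_topology()] result.
#' @param mode `"all-heavy"` or `"backbone"` (N, CA, C, O only).
#' @param weights optional per-atom weights (positive for coupled atoms).
#' @return a `coupling_spec`: logical `coupled` plus numeric `w` (zero for
#'   uncoupled atoms).
#' @export
coupling_spec <- function(topo, mode = c("all-heavy", "backbone"), weights = NULL) {
  mode <- match.arg(mode)
  coupled <- if (mode == "backbone") topo$names %in% BACKBONE_NAMES
             else rep(TRUE, topo$n_atoms)
  w <- if (is.null(weights)) topo$masses else weights
  if (length(w) != topo$n_atoms) stop("weights length must match atom count")
  if (any(w[coupled] <= 0)) stop("coupled atoms need positive weights")
  w[!coupled] <- 0
  structure(list(coupled = coupled, w = w, mode = mode), class = "coupling_spec")
}

#' Map energy and steering forces
#'
#' `U_EM = sum_j w_j V(r_j)` with the grid potential interpolated
#' trilinearly at each coupled atom (periodic wrap into the cell); the
#' force is `-w_i grad V(r_i)` with the gradient taken analytically from
#' the trilinear form, equivalent to finite differences of the eight
#' surrounding grid values.  Uncoupled atoms receive zero force.
#'
#' @param xyz coordinates (n x 3, Angstrom).
#' @param potential a [density_to_potential()] result.
#' @param coupling a [coupling_spec()].
#' @return list with `energy` and `forces` (n x 3).
#' @export
map_energy_forces <- function(xyz, potential, coupling) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  F <- matrix(0, n, 3)
  sel <- which(coupling$coupled)
  if (!length(sel)) return(list(energy = 0, forces = F))
  iv <- interp_trilinear(potential, xyz[sel, , drop = FALSE])
  w <- coupling$w[sel]
  e <- sum(w * iv$value)
  F[sel, ] <- -w * iv$grad
  list(energy = e, forces = F)
}

# trilinear value + Cartesian gradient of a map_grid at arbitrary points
interp_trilinear <- function(map, xyz) {
  dims <- dim(map$values)
  Fm <- cell_frac_matrix(map$cell)
  u <- (xyz %*% t(Fm) - matrix(map$origin, nrow(xyz), 3, byrow = TRUE)) *
    matrix(dims, nrow(xyz), 3, byrow = TRUE)
  i0 <- floor(u)
  tt <- u - i0
  idx <- function(da, db, dc) {
    ii <- (i0[, 1] + da) %% dims[1] + 1L
    jj <- (i0[, 2] + db) %% dims[2] + 1L
    kk <- (i0[, 3] + dc) %% dims[3] + 1L
    map$values[cbind(ii, jj, kk)]
  }
  c000 <- idx(0, 0, 0); c100 <- idx(1, 0, 0); c010 <- idx(0, 1, 0); c110 <- idx(1, 1, 0)
  c001 <- idx(0, 0, 1); c101 <- idx(1, 0, 1); c011 <- idx(0, 1, 1); c111 <- idx(1, 1, 1)
  tx <- tt[, 1]; ty <- tt[, 2]; tz <- tt[, 3]
  c00 <- c000 + (c100 - c000) * tx
  c10 <- c010 + (c110 - c010) * tx
  c01 <- c001 + (c101 - c001) * tx
  c11 <- c011 + (c111 - c011) * tx
  c0 <- c00 + (c10 - c00) * ty
  c1 <- c01 + (c11 - c01) * ty
  val <- c0 + (c1 - c0) * tz
  # partials w.r.t. the fractional grid coordinate u
  dx <- ((c100 - c000) * (1 - ty) + (c110 - c010) * ty) * (1 - tz) +
        ((c101 - c001) * (1 - ty) + (c111 - c011) * ty) * tz
  dy <- ((c010 - c000) * (1 - tx) + (c110 - c100) * tx) * (1 - tz) +
        ((c011 - c001) * (1 - tx) + (c111 - c101) * tx) * tz
  dz <- ((c001 - c000) * (1 - tx) + (c101 - c100) * tx) * (1 - ty) +
        ((c011 - c010) * (1 - tx) + (c111 - c110) * tx) * ty
  gfrac <- cbind(dx, dy, dz) * matrix(dims, nrow(xyz), 3, byrow = TRUE)
  list(value = val, grad = gfrac %*% Fm)
}

# combined potential: force field + restraints + map (+ optional NCS)
total_energy_forces <- function(xyz, topo, restraints = NULL, potential = NULL,
                                coupling = NULL, ncs = NULL, k_ncs = 5) {
  ef <- compute_energy_forces(xyz, topo, restraints)
  if (!is.null(potential) && !is.null(coupling)) {
    em <- map_energy_forces(xyz, potential, coupling)
    ef$energy <- ef$energy + em$energy
    ef$forces <- ef$forces + em$forces
    ef$breakdown <- c(ef$breakdown, map = em$energy)
  }
  if (!is.null(ncs)) {
    en <- ncs_restraint_forces(xyz, ncs, k_ncs)
    ef$energy <- ef$energy + en$energy
    ef$forces <- ef$forces + en$forces
    ef$breakdown <- c(ef$breakdown, ncs = en$energy)
  }
  ef
}

#' Parameters for Langevin dynamics
#'
#' @param timestep_fs integration step in femtoseconds, in (0, 2].
#' @param temperature target temperature in Kelvin (>= 0).
#' @param friction_ps Langevin friction in 1/ps (0 gives NVE).
#' @param n_steps number of steps.
#' @param seed integer seed for velocities and the thermostat.
#' @return a `dynamics_params` list.
#' @export
dynamics_params <- function(timestep_fs = 1, temperature = 300,
                            friction_ps = 5, n_steps = 500, seed = 1L) {
  if (timestep_fs <= 0 || timestep_fs > 2) stop("timestep must be in (0, 2] fs")
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(timestep_fs = timestep_fs, temperature = temperature,
                 friction_ps = friction_ps, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)), class = "dynamics_params")
}

#' Langevin dynamics under the combined potential
#'
#' BAOAB-discretized Langevin integration of `U_MD + U_SS + U_EM` (one
#' force evaluation per step; `friction_ps = 0` reduces to velocity
#' Verlet/NVE).  Velocities start from a Maxwell-Boltzmann draw at the
#' target temperature.  Fully reproducible from the seed.
#'
#' @param xyz starting coordinates (n x 3).
#' @param topo a [build_topology()] result.
#' @param restraints optional [assign_secondary_structure()] result.
#' @param potential optional [density_to_potential()] grid.
#' @param coupling optional [coupling_spec()].
#' @param params a [dynamics_params()].
#' @param ncs optional NCS groups (see [ncs_restraint_forces()]).
#' @param velocities optional starting velocities (A per AKMA time unit),
#'   e.g. carried over between annealing segments.
#' @param snapshot_every record a trajectory frame every this many steps
#'   (0 = final frame only).
#' @param engine `"cpp"` (compiled fast path, the default) or `"r"`
#'   (reference implementation).  Both integrate the same BAOAB scheme and
#'   identical potentials; the test suite asserts their forces agree.
#'   Trajectories are reproducible per engine and seed (the two engines
#'   consume random numbers in different orders).  NCS restraints require
#'   the `"r"` engine.
#' @return list with final `xyz`, final `velocities`, `energies` (per-step
#'   potential energy), `trajectory` (list of frames) and `temperature`
#'   (instantaneous, per step).
#' @export
run_dynamics <- function(xyz, topo, restraints = NULL, potential = NULL,
                         coupling = NULL, params = dynamics_params(),
                         ncs = NULL, velocities = NULL, snapshot_every = 0L,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  m <- topo$masses
  dt <- params$timestep_fs / AKMA_FS
  gamma <- params$friction_ps * AKMA_FS / 1000   # 1/ps -> 1/AKMA
  kT <- KB * params$temperature
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(pmax(1 - c1^2, 0))
  sd_v <- sqrt(kT / m)

  if (engine == "cpp") {
    if (!is.null(ncs)) stop("NCS restraints currently require engine = 'r'")
    ff <- pack_forcefield(topo, restraints, potential, coupling)
    out <- with_seed(params$seed, {
      v <- if (is.null(velocities)) matrix(stats::rnorm(3 * n), n, 3) * sd_v
           else matrix(velocities, ncol = 3)
      .cpp_run_md(xyz, v, ff, m, dt, c1, kT, params$n_steps,
                  as.integer(snapshot_every))
    })
    if (out$diverged) {
      worst <- names(which.max(out$breakdown))
      stop(sprintf("energy diverged (%.3g kcal/mol); worst term: %s",
                   out$energy, worst))
    }
    return(list(xyz = out$xyz, velocities = out$velocities,
                energies = out$pe, temperature = out$temperature,
                trajectory = out$frames))
  }

  with_seed(params$seed, {
    v <- if (is.null(velocities)) matrix(stats::rnorm(3 * n), n, 3) * sd_v
         else matrix(velocities, ncol = 3)
    ef <- total_energy_forces(xyz, topo, restraints, potential, coupling, ncs)
    energies <- numeric(params$n_steps)
    temps <- numeric(params$n_steps)
    traj <- list()
    for (step in seq_len(params$n_steps)) {
      v <- v + (dt / 2) * ef$forces / m            # B
      xyz <- xyz + (dt / 2) * v                    # A
      if (gamma > 0 && kT >= 0) {                  # O
        noise <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
        v <- c1 * v + c2 * noise
      }
      xyz <- xyz + (dt / 2) * v                    # A
      ef <- total_energy_forces(xyz, topo, restraints, potential, coupling, ncs)
      if (!is.finite(ef$energy) || ef$energy > 1e6) {
        worst <- names(which.max(ef$breakdown))
        stop(sprintf("energy diverged at step %d (%.3g kcal/mol); worst term: %s",
                     step, ef$energy, worst))
      }
      v <- v + (dt / 2) * ef$forces / m            # B
      energies[step] <- ef$energy
      temps[step] <- sum(m * rowSums(v^2)) / (3 * n * KB)
      if (snapshot_every > 0 && step %% snapshot_every == 0)
        traj[[length(traj) + 1L]] <- xyz
    }
    list(xyz = xyz, velocities = v, energies = energies,
         temperature = temps, trajectory = traj)
  })
}

#' Energy minimization under the combined potential
#'
#' L-BFGS minimization with analytic gradients; stops on gradient
#' convergence or `max_steps` evaluations.  Used for the final 0 K stage
#' of refinement schedules.
#'
#' @inheritParams run_dynamics
#' @param max_steps iteration cap.
#' @param tol projected-gradient tolerance (kcal/mol/A).
#' @return list with minimized `xyz`, final `energy` and `converged` flag.
#' @export
minimize <- function(xyz, topo, restraints = NULL, potential = NULL,
                     coupling = NULL, ncs = NULL, max_steps = 500, tol = 1e-4) {
  xyz <- matrix(xyz, ncol = 3)
  if (is.null(ncs)) {
    ff <- pack_forcefield(topo, restraints, potential, coupling)
    fn <- function(p) .cpp_energy_forces(matrix(p, ncol = 3), ff)$energy
    gr <- function(p) -as.numeric(.cpp_energy_forces(matrix(p, ncol = 3), ff)$forces)
  } else {
    fn <- function(p) total_energy_forces(matrix(p, ncol = 3), topo, restraints,
                                          potential, coupling, ncs)$energy
    gr <- function(p) -as.numeric(total_energy_forces(matrix(p, ncol = 3), topo,
                                                      restraints, potential,
                                                      coupling, ncs)$forces)
  }
  e0 <- fn(as.numeric(xyz))
  if (!is.finite(e0)) stop("non-finite starting energy")
  opt <- stats::optim(as.numeric(xyz), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_steps, factr = 1e4, pgtol = tol))
  if (opt$value > e0 + 1e-9) {
    warning("minimization did not improve the energy; returning start point")
    return(list(xyz = xyz, energy = e0, converged = FALSE))
  }
  list(xyz = matrix(opt$par, ncol = 3), energy = opt$value,
       converged = opt$convergence == 0)
}

#' Simulated annealing
#'
#' Runs consecutive Langevin segments over a temperature ladder, carrying
#' velocities across segments (rescaled to each new target temperature).
#' A 0 K entry finishes with [minimize()].
#'
#' @inheritParams run_dynamics
#' @param schedule data frame or list with `temperature` (K) and `n_steps`
#'   per segment.
#' @param base_params a [dynamics_params()] supplying timestep, friction
#'   and seed.
#' @return list with final `xyz`, `velocities` and per-segment `history`.
#' @export
anneal <- function(xyz, topo, restraints = NULL, potential = NULL,
                   coupling = NULL, schedule, base_params = dynamics_params(),
                   ncs = NULL) {
  if (is.data.frame(schedule)) schedule <- split(schedule, seq_len(nrow(schedule)))
  if (!length(schedule)) stop("empty annealing schedule")
  v <- NULL
  hist <- list()
  for (si in seq_along(schedule)) {
    seg <- schedule[[si]]
    Tseg <- seg$temperature; nstep <- seg$n_steps
    if (Tseg <= 0) {
      mres <- minimize(xyz, topo, restraints, potential, coupling, ncs,
                       max_steps = max(nstep, 100))
      xyz <- mres$xyz; v <- NULL
      hist[[si]] <- list(temperature = 0, energy = mres$energy)
      next
    }
    if (!is.null(v)) {
      kin <- sum(topo$masses * rowSums(v^2)) / (3 * nrow(v) * KB)
      if (kin > 0) v <- v * sqrt(Tseg / kin)
    }
    p <- dynamics_params(base_params$timestep_fs, Tseg, base_params$friction_ps,
                         nstep, base_params$seed + si)
    run <- run_dynamics(xyz, topo, restraints, potential, coupling, p,
                        ncs = ncs, velocities = v)
    xyz <- run$xyz; v <- run$velocities
    hist[[si]] <- list(temperature = Tseg, energy = run$energies[nstep])
  }
  list(xyz = xyz, velocities = v, history = hist)
}
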