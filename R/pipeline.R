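#' Refinement schedule
#'
#' An ordered list of stages driving the iterative refinement loop.  Each
#' stage sets which atoms couple to the density (`"backbone"` or
#' `"all-heavy"`), the steering strength `xi` (kcal/mol per unit weight),
#' the temperature (K; 0 means energy minimization), the number of MD
#' steps per map regeneration, how many times the map is regenerated
#' within the stage, plus optional kicked-map averaging and sharpening.
#'
#' @param stages list of stage lists with fields `coupling`, `xi`,
#'   `temperature`, `md_steps`, `maps_per_stage`, and optionally `kick`
#'   (list with `rms`, `n`), `sharpen_b`, `anneal` (temperature ladder for
#'   the segment).
#' @param tol R-free improvement below which iterations count as stalled.
#' @param patience stalled (or diverging) map iterations tolerated before
#'   stopping.
#' @param r_free_floor stop immediately once best R-free drops below this.
#' @return a `refine_schedule`.
#' @export
refine_schedule <- function(stages, tol = 0.002, patience = 3L,
                            r_free_floor = 0.02) {
  if (!length(stages)) stop("schedule needs at least one stage")
  for (s in stages) {
    if (!s$coupling %in% c("backbone", "all-heavy"))
      stop("stage coupling must be 'backbone' or 'all-heavy'")
    if (s$xi < 0) stop("stage xi must be >= 0")
  }
  structure(list(stages = stages, tol = tol, patience = as.integer(patience),
                 r_free_floor = r_free_floor), class = "refine_schedule")
}

#' @export
print.refine_schedule <- function(x, ...) {
  cat(sprintf("<refine_schedule> %d stage(s):\n", length(x$stages)))
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf("  %d: %-9s xi=%.2f T=%s steps=%d maps=%d%s%s\n", i, s$coupling,
                s$xi, if (s$temperature == 0) "min" else paste0(s$temperature, "K"),
                s$md_steps, s$maps_per_stage,
                if (!is.null(s$kick)) sprintf(" kick(%.1fA x%d)", s$kick$rms, s$kick$n) else "",
                if (!is.null(s$sharpen_b) && s$sharpen_b != 0)
                  sprintf(" sharpen=%g", s$sharpen_b) else ""))
  }
  invisible(x)
}

new_stage <- function(coupling, xi, temperature, md_steps, maps_per_stage,
                      kick = NULL, sharpen_b = 0, anneal = NULL) {
  list(coupling = coupling, xi = xi, temperature = temperature,
       md_steps = as.integer(md_steps), maps_per_stage = as.integer(maps_per_stage),
       kick = kick, sharpen_b = sharpen_b, anneal = anneal)
}

#' Default staged refinement protocol
#'
#' Encodes the standard progression: when the search model is expected to
#' be far from the target (> ~2 A r.m.s.d.), start by coupling only the
#' backbone at low steering strength (xi ~ 0.1) so the fold stays mobile,
#' then couple all heavy atoms and raise xi to 0.3-0.5 as the fit
#' stabilizes, and finish by cooling to 0 K (minimization).  For data
#' worse than 4 A a simulated-annealing stage is inserted before cooling
#' to help escape local minima.
#'
#' @param resolution data resolution d_min in Angstrom.
#' @param large_displacement expect a large initial deviation (prepends
#'   the backbone-only low-xi stage).
#' @param md_steps MD steps per map regeneration (1 fs steps; map
#'   regeneration every ~1 ps keeps the fit quasi-static, which proved far
#'   more stable than long excursions against a stale map).
#' @return a [refine_schedule()].
#' @export
default_schedule <- function(resolution, large_displacement = TRUE,
                             md_steps = 1000L) {
  if (resolution <= 0) stop("resolution must be positive")
  stages <- list()
  if (large_displacement)
    stages <- c(stages, list(new_stage("backbone", 0.1, 300, md_steps, 8L)))
  stages <- c(stages, list(new_stage("all-heavy", 0.3, 300, md_steps, 12L)))
  stages <- c(stages, list(new_stage("all-heavy", 0.5, 300, md_steps, 25L)))
  if (resolution > 4)
    stages <- c(stages, list(new_stage("all-heavy", 0.5, 300, md_steps, 4L,
                                       anneal = c(600, 450, 300))))
  stages <- c(stages, list(new_stage("all-heavy", 0.5, 0, 800L, 10L)))
  refine_schedule(stages, tol = 0.0005, patience = 15L)
}

#' Iterative real-space refinement against model-phased maps
#'
#' The core loop: from the current phasing model compute structure
#' factors, scale them to the observed amplitudes, estimate sigma-A
#' weights, build 2mFo-DFc coefficients with the free set excluded,
#' synthesize the map, convert it to a steering potential, and relax the
#' model under force field + restraints + map forces by Langevin dynamics
#' (or minimization at 0 K).  The refitted model re-phases the next map.
#' Iterations continue through the schedule's stages until the best R-free
#' stops improving (by < `tol` over `patience` map iterations), diverges
#' (> 0.05 above the best for `patience` iterations), or the stages are
#' exhausted.  The best-R-free model is retained.
#'
#' @param model starting (search/phasing) [atomic_model()].
#' @param refl observed [reflection_set()]; free flags are auto-assigned
#'   (5%, from `seed`) if absent.
#' @param schedule a [refine_schedule()]; default from [default_schedule()].
#' @param seed master seed; velocities, kicks and flag assignment derive
#'   from it.
#' @param reference optional target [atomic_model()] for r.m.s.d. tracking.
#' @param grid_spacing map grid spacing (default `d_min/3`).
#' @param exclude_free keep free reflections out of all maps (default).
#' @param verbose print per-iteration progress.
#' @return a `refinement_record`: `model` (best by R-free), `history`
#'   (one row per map iteration: stage, R factors, backbone r.m.s.d. if a
#'   reference was given, energies), `initial` and `final` R factors,
#'   `seed`, `converged`, `stopped_early`.
#' @export
mdff_refine <- function(model, refl, schedule = NULL, seed = 1L,
                        reference = NULL, grid_spacing = NULL,
                        exclude_free = TRUE, verbose = FALSE) {
  check_same_cell(model$cell, refl$cell)
  d_min <- min(refl$d)
  if (is.null(schedule)) schedule <- default_schedule(d_min)
  if (is.null(grid_spacing)) grid_spacing <- d_min / 3
  if (!any(refl$free)) refl <- assign_free_flags(refl, 0.05, seed)

  model$atoms <- model$atoms[model$atoms$element != "H", ]
  topo <- build_topology(model)
  restr <- assign_secondary_structure(model, topo)
  xyz <- model_xyz(model)

  eval_r <- function(xyz) {
    m <- set_model_xyz(model, xyz)
    fc <- calc_structure_factors(m, refl)
    c(r_factors(refl, fc), list(fc = fc, model = m))
  }
  # superposed: amplitude data cannot fix the global origin (and in P1 the
  # origin is fully floating), so recovery is judged after rigid alignment
  bb_rmsd <- function(xyz) {
    if (is.null(reference)) return(NA_real_)
    as.numeric(rmsd(set_model_xyz(model, xyz), reference, "backbone",
                    superpose = TRUE))
  }

  st0 <- eval_r(xyz)
  best <- list(xyz = xyz, r_free = st0$r_free)
  history <- list()
  iter <- 0L; stalled <- 0L; diverged <- 0L
  stopped_early <- FALSE; converged <- FALSE
  if (verbose)
    message(sprintf("start: R_work %.4f R_free %.4f", st0$r_work, st0$r_free))

  for (si in seq_along(schedule$stages)) {
    stage <- schedule$stages[[si]]
    coup <- coupling_spec(topo, stage$coupling)
    for (mi in seq_len(stage$maps_per_stage)) {
      iter <- iter + 1L
      cur <- eval_r(xyz)
      sa <- estimate_sigmaA(refl, cur$fc)
      mseed <- seed + 1000L * iter
      if (!is.null(stage$kick)) {
        dmap <- kicked_map(cur$model, refl, kick_rms = stage$kick$rms,
                           n_kicks = stage$kick$n, seed = mseed,
                           exclude_free = exclude_free,
                           b_sharp = stage$sharpen_b %||% 0,
                           grid_spacing = grid_spacing)
      } else {
        cf <- map_coefficients(refl, cur$fc, sa, exclude_free = exclude_free)
        if (!is.null(stage$sharpen_b) && stage$sharpen_b != 0)
          cf <- sharpen(cf, stage$sharpen_b)
        dmap <- synthesize_map(cf, grid_spacing)
      }
      pot <- density_to_potential(dmap, xi = stage$xi)

      if (!is.null(stage$anneal)) {
        sched <- data.frame(temperature = stage$anneal,
                            n_steps = stage$md_steps)
        run <- anneal(xyz, topo, restr, pot, coup, sched,
                      base_params = dynamics_params(seed = mseed))
        xyz <- run$xyz
      } else if (stage$temperature == 0) {
        xyz <- minimize(xyz, topo, restr, pot, coup,
                        max_steps = stage$md_steps)$xyz
      } else {
        run <- run_dynamics(xyz, topo, restr, pot, coup,
                            dynamics_params(temperature = stage$temperature,
                                            n_steps = stage$md_steps,
                                            seed = mseed))
        xyz <- run$xyz
      }

      post <- eval_r(xyz)
      ef <- compute_energy_forces(xyz, topo, restr)
      history[[iter]] <- data.frame(
        iteration = iter, stage = si, coupling = stage$coupling,
        xi = stage$xi, r_work = post$r_work, r_free = post$r_free,
        backbone_rmsd = bb_rmsd(xyz), energy = ef$energy)
      if (verbose)
        message(sprintf("iter %2d (stage %d %-9s xi %.2f): R_work %.4f R_free %.4f rmsd %.2f",
                        iter, si, stage$coupling, stage$xi, post$r_work,
                        post$r_free, history[[iter]]$backbone_rmsd))

      if (post$r_free < best$r_free - schedule$tol) {
        best <- list(xyz = xyz, r_free = post$r_free)
        stalled <- 0L; diverged <- 0L
      } else {
        stalled <- stalled + 1L
        if (post$r_free < best$r_free) best <- list(xyz = xyz, r_free = post$r_free)
        diverged <- if (post$r_free > best$r_free + 0.05) diverged + 1L else 0L
      }
      if (best$r_free < schedule$r_free_floor) { converged <- TRUE; break }
      if (diverged >= schedule$patience) { stopped_early <- TRUE; break }
      if (stalled >= schedule$patience && si == length(schedule$stages)) {
        converged <- TRUE; break
      }
    }
    if (converged || stopped_early) break
  }

  final <- eval_r(best$xyz)
  structure(list(
    model = final$model,
    history = do.call(rbind, history),
    initial = list(r_work = st0$r_work, r_free = st0$r_free,
                   backbone_rmsd = bb_rmsd(model_xyz(model))),
    final = list(r_work = final$r_work, r_free = final$r_free,
                 backbone_rmsd = bb_rmsd(best$xyz)),
    seed = seed, schedule = schedule,
    converged = converged, stopped_early = stopped_early),
    class = "refinement_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.refinement_record <- function(x, ...) {
  cat(sprintf("<refinement_record> %d map iteration(s)\n", nrow(x$history)))
  cat(sprintf("  R_work %.4f -> %.4f   R_free %.4f -> %.4f\n",
              x$initial$r_work, x$final$r_work, x$initial$r_free, x$final$r_free))
  if (!is.na(x$initial$backbone_rmsd))
    cat(sprintf("  backbone rmsd %.2f -> %.2f A\n",
                x$initial$backbone_rmsd, x$final$backbone_rmsd))
  if (x$stopped_early) cat("  stopped early (R_free divergence guard)\n")
  invisible(x)
}
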