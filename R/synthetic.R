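#' Specification of a synthetic test system
#'
#' Defines a desk-scale ground-truth experiment: an ideal-geometry
#' poly-alanine fold (the "target"), diffraction amplitudes computed from
#' it at a chosen resolution, and a hinge-bent "search" model several
#' Angstrom away that refinement should drive back onto the target.
#'
#' @param n_res residues per helical arm (>= 5).
#' @param architecture `"helix-hairpin"` (two helices joined by a tight
#'   turn), `"two-domain-hinge"` (two helices joined by an extended
#'   linker), or `"extended"` (a single strand).
#' @param padding empty solvent margin around the model when boxing it into
#'   its P1 cell, Angstrom.
#' @param hinge_deg rigid rotation of the second arm applied to make the
#'   search model, degrees in [0, 90].
#' @param jitter_rms r.m.s. Gaussian coordinate jitter added to the search
#'   model, Angstrom.
#' @param d_min resolution limit of the simulated amplitudes, Angstrom.
#' @param smooth_b amplitude-smoothing B factor in A^2 (0 = off); mimics
#'   the loss of high-resolution contrast in weak low-resolution data.
#' @param noise_frac multiplicative log-normal amplitude noise fraction.
#' @param free_fraction free-set fraction for cross-validation flags.
#' @param seed integer seed driving every random choice.
#' @return a `toy_system_spec` list.
#' @export
toy_system_spec <- function(n_res = 15, architecture = c("helix-hairpin",
                            "two-domain-hinge", "extended"),
                            padding = 12, hinge_deg = 30, jitter_rms = 0.3,
                            d_min = 4, smooth_b = 0, noise_frac = 0,
                            free_fraction = 0.05, seed = 1L) {
  architecture <- match.arg(architecture)
  if (n_res < 5) stop("need at least 5 residues per segment")
  if (d_min <= 1) stop("d_min must exceed 1 A")
  if (hinge_deg < 0 || hinge_deg > 90) stop("hinge angle must be in [0, 90] degrees")
  structure(list(n_res = n_res, architecture = architecture, padding = padding,
                 hinge_deg = hinge_deg, jitter_rms = jitter_rms, d_min = d_min,
                 smooth_b = smooth_b, noise_frac = noise_frac,
                 free_fraction = free_fraction, seed = as.integer(seed)),
            class = "toy_system_spec")
}

# per-residue (phi, psi) for each architecture; the hinge residue is the
# middle of the connector
arch_torsions <- function(spec) {
  n <- spec$n_res
  helix <- c(-57, -47); ext <- c(-120, 130)
  switch(spec$architecture,
    "helix-hairpin" = {
      # tight connector folding the second helix back against the first
      loop <- list(c(-60, -30), c(-90, 0), c(80, 20), c(-100, -40))
      list(tors = c(rep(list(helix), n), loop, rep(list(helix), n)),
           hinge = n + 2L)
    },
    "two-domain-hinge" = {
      loop <- rep(list(ext), 3)
      list(tors = c(rep(list(helix), n), loop, rep(list(helix), n)),
           hinge = n + 2L)
    },
    "extended" = list(tors = rep(list(ext), n), hinge = max(2L, n %/% 2L))
  )
}

# Build an ideal-geometry poly-alanine chain (N, CA, C, O, CB per residue;
# no CB would make it glycine) from a list of (phi, psi) pairs.
build_polyala <- function(torsions) {
  nres <- length(torsions)
  coords <- list(); names <- c(); resno <- c()
  # seed frame for residue 1
  N1 <- c(0, 0, 0); CA1 <- c(GEOM$b_n_ca, 0, 0)
  ang <- GEOM$a_n_ca_c * pi / 180
  prevC <- NULL
  N <- N1; CA <- CA1
  C <- CA1 + GEOM$b_ca_c * c(-cos(ang), sin(ang), 0)   # phi of residue 1 is free
  for (r in seq_len(nres)) {
    phi <- torsions[[r]][1]; psi <- torsions[[r]][2]
    if (r > 1) {
      N <- place_atom(prev$N, prev$CA, prev$C, GEOM$b_c_n, GEOM$a_ca_c_n, psi_prev)
      CA <- place_atom(prev$CA, prev$C, N, GEOM$b_n_ca, GEOM$a_c_n_ca, 180)  # omega trans
      C <- place_atom(prev$C, N, CA, GEOM$b_ca_c, GEOM$a_n_ca_c, phi)
    }
    CB <- place_atom(C, N, CA, GEOM$b_ca_cb, GEOM$a_n_ca_cb, GEOM$t_cb)
    if (r < nres) {
      Nnext <- place_atom(N, CA, C, GEOM$b_c_n, GEOM$a_ca_c_n, psi)
      O <- place_atom(Nnext, CA, C, GEOM$b_c_o, GEOM$a_ca_c_o, 180)
    } else {
      O <- place_atom(N, CA, C, GEOM$b_c_o, GEOM$a_ca_c_o, psi + 180)
    }
    coords[[r]] <- rbind(N = N, CA = CA, C = C, O = O, CB = CB)
    prev <- list(N = N, CA = CA, C = C)
    psi_prev <- psi
  }
  xyz <- do.call(rbind, coords)
  data.frame(name = rep(c("N", "CA", "C", "O", "CB"), nres),
             resno = rep(seq_len(nres), each = 5),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Generate the target (ground-truth) model
#'
#' Ideal-geometry poly-alanine backbone + C-beta in the requested
#' architecture, boxed into a P1 cell with `padding` Angstrom of empty
#' margin on every side.  B factors are uniform 20 A^2.
#'
#' @param spec a [toy_system_spec()].
#' @return an [atomic_model()]; attribute `"hinge_res"` marks the hinge
#'   residue used by [make_search_model()].
#' @export
make_target <- function(spec) {
  arch <- arch_torsions(spec)
  ch <- build_polyala(arch$tors)
  xyz <- as.matrix(ch[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, apply(xyz, 2, min) - spec$padding)
  cell <- c(apply(xyz, 2, max) + spec$padding, 90, 90, 90)
  atoms <- data.frame(serial = seq_len(nrow(ch)), name = ch$name,
                      element = substr(ch$name, 1, 1), resname = "ALA",
                      resno = ch$resno, chain = "A", insert = "", alt = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = 20)
  m <- atomic_model(atoms, cell)
  attr(m, "hinge_res") <- arch$hinge
  m
}

# Rodrigues rotation matrix: angle (rad) about unit axis
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate the displaced search model
#'
#' Rotates everything downstream of the hinge residue rigidly by the
#' specified angle about an axis through the hinge C-alpha (chosen
#' perpendicular to the second arm so the rotation swings the arm), then
#' adds seeded Gaussian jitter.  The resulting backbone r.m.s.d. to the
#' target is returned as attribute `"rmsd_backbone"`.
#'
#' @param target a [make_target()] model.
#' @param spec the same [toy_system_spec()].
#' @return an [atomic_model()] in the target's cell.
#' @export
make_search_model <- function(target, spec) {
  hinge <- attr(target, "hinge_res")
  if (is.null(hinge)) stop("target lacks a hinge annotation")
  at <- target$atoms
  xyz <- model_xyz(target)
  pivot <- xyz[which(at$resno == hinge & at$name == "CA")[1], ]
  moving <- at$resno > hinge
  arm2 <- colMeans(xyz[moving, , drop = FALSE]) - pivot
  arm1 <- colMeans(xyz[at$resno < hinge, , drop = FALSE]) - pivot
  # hinge-bend axis: normal to the plane of the two arms, so the rotation
  # opens/closes the inter-arm angle; fall back to any perpendicular if the
  # arms are nearly collinear
  axis <- c(arm1[2] * arm2[3] - arm1[3] * arm2[2],
            arm1[3] * arm2[1] - arm1[1] * arm2[3],
            arm1[1] * arm2[2] - arm1[2] * arm2[1])
  if (sqrt(sum(axis^2)) < 1e-6 * sqrt(sum(arm1^2) * sum(arm2^2))) {
    basis <- diag(3)[, which.min(abs(arm2))]
    axis <- c(arm2[2] * basis[3] - arm2[3] * basis[2],
              arm2[3] * basis[1] - arm2[1] * basis[3],
              arm2[1] * basis[2] - arm2[2] * basis[1])
  }
  # symmetric opening: each arm rotates by half the hinge angle in opposite
  # senses, so the inter-arm angle changes by the full amount
  Rp <- rotation_about_axis(axis, spec$hinge_deg * pi / 360)
  Rm <- rotation_about_axis(axis, -spec$hinge_deg * pi / 360)
  fixed <- at$resno < hinge
  xyz2 <- xyz
  xyz2[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, pivot) %*% t(Rp),
                          2, pivot, `+`)
  xyz2[fixed, ] <- sweep(sweep(xyz[fixed, , drop = FALSE], 2, pivot) %*% t(Rm),
                         2, pivot, `+`)
  if (spec$jitter_rms > 0)
    xyz2 <- xyz2 + with_seed(spec$seed,
      matrix(stats::rnorm(length(xyz2), sd = spec$jitter_rms / sqrt(3)),
             ncol = 3))
  search <- set_model_xyz(target, xyz2)
  attr(search, "hinge_res") <- hinge
  bb <- at$name %in% BACKBONE_NAMES
  attr(search, "rmsd_backbone") <-
    sqrt(mean(rowSums((xyz2[bb, ] - xyz[bb, ])^2)))
  search
}

#' Simulate diffraction amplitudes from the target
#'
#' Enumerates all unique reflections to the resolution limit and sets
#' `|F_obs| = |F_calc(target)|`, optionally smoothed by
#' `exp(-B_smooth s^2)` (s = sin theta/lambda) and perturbed by
#' multiplicative log-normal noise; free flags are assigned at the spec's
#' fraction from its seed.
#'
#' @param target a [make_target()] model.
#' @param spec the [toy_system_spec()].
#' @return a [reflection_set()].
#' @export
simulate_reflections <- function(target, spec) {
  cell <- target$cell
  hmax <- floor(cell[1:3] / spec$d_min) + 1L
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = 0:hmax[3]))
  hkl <- friedel_canonical(hkl)
  hkl <- unique(hkl)
  keep <- d_spacing(hkl, cell) >= spec$d_min &
    !(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0)
  hkl <- hkl[keep, , drop = FALSE]
  shell <- reflection_set(hkl, rep(1, nrow(hkl)), cell)
  fc <- calc_structure_factors(target, shell)
  f <- Mod(fc$f)
  if (spec$smooth_b > 0) f <- f * exp(-spec$smooth_b * stol(shell$hkl, cell)^2)
  if (spec$noise_frac > 0)
    f <- f * with_seed(spec$seed + 1L,
                       exp(stats::rnorm(length(f), sd = spec$noise_frac)))
  refl <- reflection_set(shell$hkl, f, cell)
  assign_free_flags(refl, spec$free_fraction, spec$seed + 2L)
}
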