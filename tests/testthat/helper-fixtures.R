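# Shared fixtures, built once per test session and cached.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# small random model in an orthorhombic P1 cell
toy_model <- function(n = 10, seed = 42, cell = c(20, 25, 30, 90, 90, 90)) {
  set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA",
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    resname = "ALA", resno = seq_len(n), chain = "A", insert = "", alt = "",
    x = runif(n, 5, cell[1] - 5), y = runif(n, 5, cell[2] - 5),
    z = runif(n, 5, cell[3] - 5), occ = 1, b = runif(n, 10, 30))
  atomic_model(atoms, cell)
}

# complete reflection enumeration of a cell to d_min (one hemisphere)
full_reflections <- function(cell, d_min, fobs = NULL) {
  hmax <- floor(cell[1:3] / d_min) + 1L
  hkl <- as.matrix(expand.grid(-hmax[1]:hmax[1], -hmax[2]:hmax[2], 0:hmax[3]))
  hkl <- unique(xmapfit:::friedel_canonical(hkl))
  keep <- d_spacing(hkl, cell) >= d_min &
    !(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0)
  hkl <- hkl[keep, , drop = FALSE]
  reflection_set(hkl, if (is.null(fobs)) rep(1, nrow(hkl)) else fobs, cell)
}

# standard helix-hairpin ground-truth system at 4 A (the workhorse fixture)
hairpin_system <- function(seed = 1) {
  cached(paste0("hairpin", seed), {
    spec <- toy_system_spec(n_res = 15, architecture = "helix-hairpin",
                            hinge_deg = 30, d_min = 4, seed = seed)
    tgt <- make_target(spec)
    list(spec = spec, target = tgt,
         refl = simulate_reflections(tgt, spec),
         search = make_search_model(tgt, spec))
  })
}

# small extended peptide + topology + restraints for force-field tests
peptide_system <- function() {
  cached("peptide", {
    spec <- toy_system_spec(n_res = 6, architecture = "extended", seed = 2)
    tgt <- make_target(spec)
    topo <- build_topology(tgt)
    list(spec = spec, model = tgt, topo = topo,
         restr = assign_secondary_structure(tgt, topo),
         xyz = xmapfit:::model_xyz(tgt))
  })
}

# central finite-difference force check against an energy functional
fd_force_check <- function(efun, xyz, forces, idx = NULL, h = 1e-5) {
  if (is.null(idx)) idx <- seq_len(nrow(xyz))
  maxerr <- 0
  for (i in idx) for (d in 1:3) {
    xp <- xyz; xp[i, d] <- xp[i, d] + h
    xm <- xyz; xm[i, d] <- xm[i, d] - h
    fnum <- -(efun(xp) - efun(xm)) / (2 * h)
    maxerr <- max(maxerr, abs(fnum - forces[i, d]) /
                    max(abs(fnum), abs(forces[i, d]), 1))
  }
  maxerr
}
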