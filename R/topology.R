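# Ideal peptide-backbone geometry (Engh-Huber-style values, Angstrom and
# degrees).  The last two entries are derived once from the same internal
# coordinates the synthetic-model builder uses, so a freshly built ideal
# chain scores zero bonded energy.
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_o = 1.231, b_c_n = 1.329, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_o = 120.8, a_ca_c_n = 116.2, a_o_c_n = 123.0,
  a_c_n_ca = 121.7, a_n_ca_cb = 110.5,
  a_c_ca_cb = 110.073,     # implied by the CB placement torsion below
  t_cb = -122.55,          # improper torsion C-N-CA-CB placing CB (L config)
  imp_ca = 122.796         # equilibrium improper N-C-CA-CB at an L-Calpha
)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# per-element soft-core repulsion radii (Angstrom)
REP_RADIUS <- c(C = 1.70, N = 1.55, O = 1.50, S = 1.80, P = 1.80)

rep_radius <- function(element) {
  r <- REP_RADIUS[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# default force constants (kcal/mol / A^2 or rad^2); energies are written as
# k * delta^2 (no 1/2), so a bond stretched by delta stores k_b delta^2
K_BOND <- 300; K_ANGLE <- 60; K_IMPROPER <- 40; K_OMEGA <- 40
K_REPULSION <- 25; REP_SCALE <- 0.85
K_SIDECHAIN_BOND <- 300; K_SIDECHAIN_ANGLE <- 60; K_RIGID <- 20

#' Build a molecular-mechanics topology from a model
#'
#' Produces the bonded terms of the simplified force field: harmonic bonds
#' and angles, improper torsions for C-alpha chirality and peptide-plane
#' planarity, and a soft-core repulsive nonbonded term with 1-2/1-3
#' exclusions.  Backbone terms (N, CA, C, O, CB) take ideal template
#' geometry; side-chain connectivity is detected from the input distances
#' and restrained to the starting geometry (input models are assumed to
#' carry stereochemically sensible side chains).  Unknown residues and
#' hetero groups are restrained to their initial internal geometry, with a
#' warning.  Hydrogens are ignored throughout.
#'
#' @param model an [atomic_model()].
#' @return a `topology`: list of term tables (`bonds`, `angles`,
#'   `dihedrals`), per-atom `masses` and repulsion `radii`, exclusion keys
#'   and the index of retained (heavy) atoms.
#' @export
build_topology <- function(model) {
  at <- model$atoms
  heavy <- which(at$element != "H")
  at <- at[heavy, ]
  n <- nrow(at)
  xyz <- cbind(at$x, at$y, at$z)
  idx_of <- function(sel) which(sel)   # within heavy subset

  bonds <- list(); angles <- list(); dihedrals <- list()
  add_bond <- function(i, j, r0, k = K_BOND)
    bonds[[length(bonds) + 1L]] <<- c(i, j, r0, k)
  add_angle <- function(i, j, k3, th0_deg, kk = K_ANGLE)
    angles[[length(angles) + 1L]] <<- c(i, j, k3, th0_deg * pi / 180, kk)
  add_dih <- function(i, j, k3, l, phi0_deg, kk)
    dihedrals[[length(dihedrals) + 1L]] <<- c(i, j, k3, l, phi0_deg * pi / 180, kk)

  res_key <- paste(at$chain, at$resno, at$insert)
  res_order <- unique(res_key)
  res_atoms <- split(seq_len(n), factor(res_key, levels = res_order))
  res_chain <- vapply(res_atoms, function(i) at$chain[i[1]], character(1))
  res_name <- vapply(res_atoms, function(i) at$resname[i[1]], character(1))

  getn <- function(ia, nm) { w <- ia[at$name[ia] == nm]; if (length(w)) w[1] else NA_integer_ }
  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  unknown <- character(0)
  for (r in seq_along(res_atoms)) {
    ia <- res_atoms[[r]]
    known <- res_name[r] %in% AA3
    if (!known) unknown <- c(unknown, res_name[r])
    iN <- getn(ia, "N"); iCA <- getn(ia, "CA"); iC <- getn(ia, "C")
    iO <- getn(ia, "O"); iCB <- getn(ia, "CB")
    bb <- c(iN, iCA, iC, iO, if (!is.na(iCB)) iCB)
    if (known && !anyNA(c(iN, iCA, iC))) {
      add_bond(iN, iCA, GEOM$b_n_ca)
      add_bond(iCA, iC, GEOM$b_ca_c)
      add_angle(iN, iCA, iC, GEOM$a_n_ca_c)
      if (!is.na(iO)) {
        add_bond(iC, iO, GEOM$b_c_o)
        add_angle(iCA, iC, iO, GEOM$a_ca_c_o)
      }
      if (!is.na(iCB)) {
        add_bond(iCA, iCB, GEOM$b_ca_cb)
        add_angle(iN, iCA, iCB, GEOM$a_n_ca_cb)
        add_angle(iC, iCA, iCB, GEOM$a_c_ca_cb)
        # L-chirality improper at CA (glycine has none)
        add_dih(iN, iC, iCA, iCB, GEOM$imp_ca, K_IMPROPER)
      }
      # side-chain: bonds by distance among non-backbone atoms (+ CB stub)
      sc <- setdiff(ia, c(iN, iCA, iC, iO))
      sc_all <- c(if (!is.na(iCB)) iCB, setdiff(sc, iCB))
      if (length(sc_all) > 1) {
        link_by_distance(sc_all, at, xyz, add_bond, add_angle,
                         anchor = c(iCA, iN, iC))
      }
    } else {
      # unknown residue: restrain its initial internal geometry
      link_by_distance(ia, at, xyz, add_bond, add_angle, anchor = integer(0),
                       rigidify = TRUE, add_dih = add_dih)
    }
    # peptide link to the next residue in the same chain
    if (r < length(res_atoms) && res_chain[r + 1] == res_chain[r]) {
      ja <- res_atoms[[r + 1]]
      jN <- getn(ja, "N"); jCA <- getn(ja, "CA")
      if (!anyNA(c(iC, jN)) && dist_ij(iC, jN) < 2.5) {
        add_bond(iC, jN, GEOM$b_c_n)
        if (!is.na(iCA)) add_angle(iCA, iC, jN, GEOM$a_ca_c_n)
        if (!is.na(iO)) add_angle(iO, iC, jN, GEOM$a_o_c_n)
        if (!is.na(jCA)) add_angle(iC, jN, jCA, GEOM$a_c_n_ca)
        # peptide-plane improper: O and the next N flank the CA-C axis
        if (!anyNA(c(jN, iCA, iC, iO)))
          add_dih(jN, iCA, iC, iO, 180, K_IMPROPER)
      }
    }
  }
  if (length(unknown))
    warning("non-standard residue(s) restrained to initial geometry: ",
            paste(unique(unknown), collapse = ", "))

  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 4)
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(0, 0, 5)
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else matrix(0, 0, 6)

  # 1-2 and 1-3 exclusions from the bond graph
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  excl <- new.env(hash = TRUE, size = 4L * n)
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      assign(ekey(i, j), TRUE, envir = excl)
      for (k3 in nb[[j]]) if (k3 != i) assign(ekey(i, k3), TRUE, envir = excl)
    }
  }
  excl_keys <- ls(excl)

  structure(list(
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    masses = atomic_mass(at$element), radii = rep_radius(at$element),
    k_rep = K_REPULSION, rep_scale = REP_SCALE,
    excl = excl_keys, n_atoms = n, heavy = heavy,
    names = at$name, resno = at$resno, chain = at$chain,
    resname = at$resname), class = "topology")
}

# distance-based connectivity for side chains / unknown residues; bonds and
# angles restrained to the observed starting geometry.  With `rigidify`,
# 1-4 distances are also pinned, freezing internal torsions.
link_by_distance <- function(ia, at, xyz, add_bond, add_angle, anchor,
                             rigidify = FALSE, add_dih = NULL) {
  all_i <- unique(c(anchor, ia))
  if (length(all_i) < 2) return(invisible())
  sub <- xyz[all_i, , drop = FALSE]
  D <- as.matrix(stats::dist(sub))
  cut <- outer(at$element[all_i] == "S", at$element[all_i] == "S", `|`) * 0.35 + 1.95
  adj <- D < cut & upper.tri(D)
  prs <- which(adj, arr.ind = TRUE)
  seen_anchor <- length(anchor)
  nbr <- lapply(seq_along(all_i), function(i) integer(0))
  for (p in seq_len(nrow(prs))) {
    i <- prs[p, 1]; j <- prs[p, 2]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    # skip bonds entirely inside the anchor set (owned by the backbone terms)
    if (i <= seen_anchor && j <= seen_anchor) next
    add_bond(all_i[i], all_i[j], D[i, j],
             if (rigidify) K_RIGID * 10 else K_SIDECHAIN_BOND)
  }
  for (j in seq_along(all_i)) {
    ns <- nbr[[j]]
    if (length(ns) < 2) next
    cmb <- utils::combn(ns, 2)
    for (q in seq_len(ncol(cmb))) {
      i <- cmb[1, q]; k <- cmb[2, q]
      if (all(c(i, j, k) <= seen_anchor)) next
      v1 <- sub[i, ] - sub[j, ]; v2 <- sub[k, ] - sub[j, ]
      th <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1))
      add_angle(all_i[i], all_i[j], all_i[k], th * 180 / pi,
                if (rigidify) K_RIGID else K_SIDECHAIN_ANGLE)
    }
  }
  if (rigidify) {
    # pin 1-4 distances to freeze torsions of flexible rings/chains
    g <- D < cut
    for (i in seq_along(all_i)) for (j in seq_along(all_i)) {
      if (j <= i || g[i, j]) next
      # path length 3 check via neighbor sets
      if (any(vapply(nbr[[i]], function(m) any(nbr[[m]] %in% nbr[[j]]), logical(1))))
        add_bond(all_i[i], all_i[j], D[i, j], K_RIGID)
    }
  }
  invisible()
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms: %d bonds, %d angles, %d impropers/torsions\n",
              x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}
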