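#' Secondary-structure and stereochemical restraints
#'
#' Builds the restraint set that protects the fold during fitting: phi/psi
#' dihedral restraints for residues assigned to helix or sheet, i -> i+4
#' O..N hydrogen-bond distance restraints inside helices, and trans (or
#' flagged cis) omega restraints on every peptide bond.  The assignment is
#' made once, on the starting model, and is not updated during refinement;
#' a fit cannot change secondary structure, it can only preserve it.
#'
#' Geometric assignment uses backbone torsion windows on the initial
#' coordinates: helix for phi in (-100, -30) and psi in (-80, -5) over runs
#' of >= 4 residues, sheet for phi in (-170, -80) and psi in (90, 180) over
#' runs of >= 3.  Helix residues are restrained toward
#' (phi, psi) = (-57, -47) degrees, sheet residues toward (-119, 113).
#'
#' @param model an [atomic_model()] (hydrogens ignored).
#' @param topo its [build_topology()] result (supplies atom indexing).
#' @param mode `"geometric"` (default) or `"from-annotation"`.
#' @param annotation for `"from-annotation"`: data frame with columns
#'   `chain`, `resno`, `type` (`"helix"`/`"sheet"`).
#' @param cis_residues optional data frame (`chain`, `resno`) of residues
#'   whose preceding peptide bond is cis (omega target 0 instead of 180).
#' @param k_ss,k_hbond,k_omega force constants (kcal/mol per rad^2 or A^2).
#' @return a `restraint_set`: `dihedrals` (i, j, k, l, target rad, k),
#'   `distances` (i, j, r0, k), and the per-residue `assignment`.
#' @export
assign_secondary_structure <- function(model, topo, mode = c("geometric", "from-annotation"),
                                       annotation = NULL, cis_residues = NULL,
                                       k_ss = 100, k_hbond = 25, k_omega = K_OMEGA) {
  mode <- match.arg(mode)
  at <- model$atoms[topo$heavy, ]
  xyz <- cbind(at$x, at$y, at$z)
  res_key <- paste(at$chain, at$resno, at$insert)
  res_order <- unique(res_key)
  res_atoms <- split(seq_len(nrow(at)), factor(res_key, levels = res_order))
  nres <- length(res_atoms)
  res_chain <- vapply(res_atoms, function(i) at$chain[i[1]], character(1))
  res_no <- vapply(res_atoms, function(i) at$resno[i[1]], numeric(1))
  getn <- function(ia, nm) { w <- ia[at$name[ia] == nm]; if (length(w)) w[1] else NA_integer_ }
  iN <- vapply(res_atoms, getn, integer(1), "N")
  iCA <- vapply(res_atoms, getn, integer(1), "CA")
  iC <- vapply(res_atoms, getn, integer(1), "C")
  iO <- vapply(res_atoms, getn, integer(1), "O")

  # chain continuity between consecutive residues (peptide C-N < 2.5 A)
  linked <- rep(FALSE, nres)   # linked[r]: residue r bonded to r+1
  for (r in seq_len(nres - 1)) {
    linked[r] <- res_chain[r] == res_chain[r + 1] &&
      !anyNA(c(iC[r], iN[r + 1])) &&
      sqrt(sum((xyz[iC[r], ] - xyz[iN[r + 1], ])^2)) < 2.5
  }

  phi <- rep(NA_real_, nres); psi <- rep(NA_real_, nres)
  for (r in seq_len(nres)) {
    if (r > 1 && linked[r - 1] && !anyNA(c(iC[r - 1], iN[r], iCA[r], iC[r])))
      phi[r] <- dihedral_value(xyz[iC[r - 1], , drop = FALSE], xyz[iN[r], , drop = FALSE],
                               xyz[iCA[r], , drop = FALSE], xyz[iC[r], , drop = FALSE]) * 180 / pi
    if (r < nres && linked[r] && !anyNA(c(iN[r], iCA[r], iC[r], iN[r + 1])))
      psi[r] <- dihedral_value(xyz[iN[r], , drop = FALSE], xyz[iCA[r], , drop = FALSE],
                               xyz[iC[r], , drop = FALSE], xyz[iN[r + 1], , drop = FALSE]) * 180 / pi
  }

  ss <- rep("loop", nres)
  if (mode == "geometric") {
    ok <- !is.na(phi) & !is.na(psi)
    hel <- ok & phi > -110 & phi < -25 & psi > -90 & psi < 10
    sht <- ok & phi > -170 & phi < -80 & psi > 90 & psi <= 180
    # close single-residue gaps caused by thermal/noise wobble, but only
    # when the gap residue is at least loosely in the same torsion basin —
    # a genuine turn residue must split the run
    hel_loose <- ok & phi > -140 & phi < 0 & psi > -120 & psi < 40
    sht_loose <- ok & phi > -180 & phi < -50 & psi > 60 & psi <= 180
    hel <- close_gaps(hel) & (hel | hel_loose)
    sht <- close_gaps(sht) & (sht | sht_loose)
    ss[run_filter(hel, 4)] <- "helix"
    ss[run_filter(sht & ss == "loop", 3)] <- "sheet"
  } else {
    if (is.null(annotation)) stop("annotation required for mode 'from-annotation'")
    for (q in seq_len(nrow(annotation))) {
      hit <- which(res_chain == annotation$chain[q] & res_no == annotation$resno[q])
      if (!length(hit))
        stop("annotation references absent residue ", annotation$chain[q],
             " ", annotation$resno[q])
      ss[hit] <- annotation$type[q]
    }
  }

  dih <- list(); dst <- list()
  tgt <- list(helix = c(-57, -47), sheet = c(-119, 113))
  for (r in seq_len(nres)) {
    if (ss[r] %in% names(tgt)) {
      tg <- tgt[[ss[r]]]
      if (r > 1 && linked[r - 1] && !anyNA(c(iC[r - 1], iN[r], iCA[r], iC[r])))
        dih[[length(dih) + 1L]] <- c(iC[r - 1], iN[r], iCA[r], iC[r], tg[1] * pi / 180, k_ss)
      if (r < nres && linked[r] && !anyNA(c(iN[r], iCA[r], iC[r], iN[r + 1])))
        dih[[length(dih) + 1L]] <- c(iN[r], iCA[r], iC[r], iN[r + 1], tg[2] * pi / 180, k_ss)
    }
    # helix i -> i+4 O..N hydrogen bonds (whole span helical and linked)
    if (r + 4 <= nres && all(ss[r:(r + 4)] == "helix") &&
        all(linked[r:(r + 3)]) && !anyNA(c(iO[r], iN[r + 4])))
      dst[[length(dst) + 1L]] <- c(iO[r], iN[r + 4], 2.9, k_hbond)
  }

  # omega restraints on every peptide bond (trans unless flagged cis)
  for (r in seq_len(nres - 1)) {
    if (!linked[r] || anyNA(c(iCA[r], iC[r], iN[r + 1], iCA[r + 1]))) next
    is_cis <- !is.null(cis_residues) &&
      any(cis_residues$chain == res_chain[r + 1] & cis_residues$resno == res_no[r + 1])
    dih[[length(dih) + 1L]] <- c(iCA[r], iC[r], iN[r + 1], iCA[r + 1],
                                 if (is_cis) 0 else pi, k_omega)
  }

  structure(list(
    dihedrals = if (length(dih)) do.call(rbind, dih) else matrix(0, 0, 6),
    distances = if (length(dst)) do.call(rbind, dst) else matrix(0, 0, 4),
    assignment = data.frame(chain = res_chain, resno = res_no, ss = ss,
                            phi = phi, psi = psi)), class = "restraint_set")
}

# TRUE for elements whose FALSE neighbors on both sides are TRUE
close_gaps <- function(flag) {
  n <- length(flag)
  if (n < 3) return(flag)
  inner <- which(!flag[2:(n - 1)]) + 1L
  fill <- inner[flag[inner - 1L] & flag[inner + 1L]]
  flag[fill] <- TRUE
  flag
}

# indices belonging to runs of TRUE of at least `min_len`
run_filter <- function(flag, min_len) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= min_len
  rep(keep, r$lengths)
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d dihedral, %d distance restraints; %d helix, %d sheet of %d residues\n",
              nrow(x$dihedrals), nrow(x$distances),
              sum(x$assignment$ss == "helix"), sum(x$assignment$ss == "sheet"),
              nrow(x$assignment)))
  invisible(x)
}
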