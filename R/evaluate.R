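#' Root-mean-square deviation between two models
#'
#' Atoms are matched by (chain, residue number, insertion code, atom name);
#' unmatched atoms are dropped with a message.  With `superpose = TRUE`
#' the deviation is measured after least-squares rigid superposition of the
#' selection (appropriate when the two models sit in different crystal
#' frames); without it, coordinates are compared as-is.
#'
#' @param model_a,model_b [atomic_model()]s sharing residue numbering.
#' @param selection `"all-heavy"` or `"backbone"` (N, CA, C, O).
#' @param superpose superpose before measuring (default TRUE).
#' @return r.m.s.d. in Angstrom, with attributes `n_matched`,
#'   `per_residue` (named vector of per-residue r.m.s.d.) and `superposed`.
#' @export
rmsd <- function(model_a, model_b, selection = c("all-heavy", "backbone"),
                 superpose = TRUE) {
  selection <- match.arg(selection)
  a <- model_a$atoms; b <- model_b$atoms
  if (selection == "backbone") {
    a <- a[a$name %in% BACKBONE_NAMES, ]
    b <- b[b$name %in% BACKBONE_NAMES, ]
  } else {
    a <- a[a$element != "H", ]; b <- b[b$element != "H", ]
  }
  key_a <- paste(a$chain, a$resno, a$insert, a$name)
  key_b <- paste(b$chain, b$resno, b$insert, b$name)
  common <- intersect(key_a, key_b)
  n_un <- (nrow(a) - length(common)) + (nrow(b) - length(common))
  if (n_un > 0) message(sprintf("rmsd: %d unmatched atom(s) excluded", n_un))
  if (length(common) < 3) stop("fewer than 3 matched atoms")
  ia <- match(common, key_a); ib <- match(common, key_b)
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(b[ib, c("x", "y", "z")])
  if (superpose) xb <- kabsch(xb, xa)$xyz
  dev2 <- rowSums((xa - xb)^2)
  out <- sqrt(mean(dev2))
  res_key <- paste(a$chain[ia], a$resno[ia])
  attr(out, "per_residue") <- sqrt(tapply(dev2, res_key, mean))
  attr(out, "n_matched") <- length(common)
  attr(out, "superposed") <- superpose
  out
}

#' Real-space correlation between two maps
#'
#' Pearson correlation over voxels of two maps on identical grids.  An
#' optional atom selection restricts the comparison to voxels within
#' `mask_radius` of any listed position (local CC).
#'
#' @param map_a,map_b [map_grid()]s with identical geometry.
#' @param mask_xyz optional (n x 3) Cartesian positions defining the mask.
#' @param mask_radius sphere radius in Angstrom (default 3).
#' @return correlation in [-1, 1].
#' @export
real_space_cc <- function(map_a, map_b, mask_xyz = NULL, mask_radius = 3) {
  if (!identical(dim(map_a$values), dim(map_b$values)))
    stop("maps must share grid dimensions (resample first)")
  check_same_cell(map_a$cell, map_b$cell)
  va <- as.numeric(map_a$values); vb <- as.numeric(map_b$values)
  if (!is.null(mask_xyz)) {
    sel <- map_mask(map_a, mask_xyz, mask_radius)
    va <- va[sel]; vb <- vb[sel]
    if (!length(va)) stop("mask selects no voxels")
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance map region; correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

# logical voxel mask: union of spheres around the given positions
# (minimum-image distances in the periodic cell)
map_mask <- function(map, xyz, radius) {
  dims <- dim(map$values)
  g <- as.matrix(expand.grid(seq_len(dims[1]) - 1L, seq_len(dims[2]) - 1L,
                             seq_len(dims[3]) - 1L))
  gf <- sweep(g, 2, dims, `/`)
  frac_at <- cart_to_frac(xyz, map$cell)
  O <- cell_orth_matrix(map$cell)
  sel <- rep(FALSE, nrow(g))
  for (j in seq_len(nrow(frac_at))) {
    df <- sweep(gf, 2, frac_at[j, ] - map$origin)
    df <- df - round(df)
    d2 <- rowSums((df %*% t(O))^2)
    sel <- sel | d2 <= radius^2
  }
  sel
}

#' Resolution-limited density map of a model
#'
#' Computes structure factors of the model to the given resolution limit
#' and synthesizes the corresponding map: the best density the model could
#' explain at that resolution, used as the reference for map correlation.
#'
#' @param model an [atomic_model()].
#' @param resolution d_min in Angstrom.
#' @param grid_spacing map spacing (default `resolution/3`).
#' @return a [map_grid()].
#' @export
simulated_map <- function(model, resolution, grid_spacing = resolution / 3) {
  cell <- model$cell
  hmax <- floor(cell[1:3] / resolution) + 1L
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = 0:hmax[3]))
  hkl <- unique(friedel_canonical(hkl))
  keep <- d_spacing(hkl, cell) >= resolution &
    !(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0)
  shell <- reflection_set(hkl[keep, , drop = FALSE], rep(1, sum(keep)), cell)
  fc <- calc_structure_factors(model, shell)
  synthesize_map(fc, grid_spacing)
}

#' Structured comparison of a refined model against a reference
#'
#' @param model refined [atomic_model()].
#' @param reference target [atomic_model()].
#' @param refl optional [reflection_set()] for R factors.
#' @param superpose passed to [rmsd()].
#' @return a `comparison_report` list: heavy-atom and backbone r.m.s.d.,
#'   per-residue profile, optional R factors and map correlation.
#' @export
comparison_report <- function(model, reference, refl = NULL, superpose = TRUE) {
  all_r <- rmsd(model, reference, "all-heavy", superpose)
  bb_r <- rmsd(model, reference, "backbone", superpose)
  rep <- list(all_heavy_rmsd = as.numeric(all_r),
              backbone_rmsd = as.numeric(bb_r),
              per_residue = attr(all_r, "per_residue"),
              superposed = superpose)
  if (!is.null(refl)) {
    fc <- calc_structure_factors(model, refl)
    rep[c("r_work", "r_free")] <- r_factors(refl, fc)[c("r_work", "r_free")]
    d_min <- min(refl$d)
    mref <- simulated_map(reference, d_min)
    mmod <- model_phased_map(model, refl, grid_spacing = d_min / 3)
    if (identical(dim(mref$values), dim(mmod$values)))
      rep$map_cc <- real_space_cc(mmod, mref)
  }
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> all-heavy rmsd %.2f A, backbone %.2f A%s\n",
              x$all_heavy_rmsd, x$backbone_rmsd,
              if (x$superposed) " (superposed)" else ""))
  if (!is.null(x$r_work))
    cat(sprintf("  R_work %.3f  R_free %.3f%s\n", x$r_work, x$r_free,
                if (!is.null(x$map_cc)) sprintf("  map CC %.3f", x$map_cc) else ""))
  invisible(x)
}
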