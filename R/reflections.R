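#' Reflection data container
#'
#' A `reflection_set` stores unique Miller indices with observed amplitudes,
#' optional sigmas and free-R flags, reduced to one Friedel hemisphere
#' (h > 0, or h = 0 and k > 0, or h = k = 0 and l >= 0).
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @param fobs observed amplitudes (arbitrary units), length n.
#' @param cell unit cell `(a, b, c, alpha, beta, gamma)`.
#' @param sigf optional amplitude sigmas.
#' @param free optional logical free-R flags.
#' @return object of class `reflection_set` with fields `hkl`, `fobs`,
#'   `sigf`, `free`, `d`, `cell`.
#' @export
reflection_set <- function(hkl, fobs, cell, sigf = NULL, free = NULL) {
  validate_cell(cell)
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  n <- nrow(hkl)
  if (length(fobs) != n) stop("fobs length must match hkl rows")
  if (any(fobs[!is.na(fobs)] < 0) || any(is.infinite(fobs)))
    stop("amplitudes must be >= 0 (NA allowed for unmeasured reflections)")
  if (is.null(sigf)) sigf <- rep(NA_real_, n)
  if (is.null(free)) free <- rep(FALSE, n)
  red <- reduce_friedel(hkl, fobs, sigf, free)
  d <- d_spacing(red$hkl, cell)
  structure(list(hkl = red$hkl, fobs = red$fobs, sigf = red$sigf,
                 free = red$free, d = d, cell = as.numeric(cell)),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d unique reflections, d %.2f-%.2f A, %d free (%.1f%%)\n",
              length(x$fobs), min(x$d), max(x$d[is.finite(x$d)]),
              sum(x$free), 100 * mean(x$free)))
  invisible(x)
}

n_refl <- function(refl) length(refl$fobs)

# canonical Friedel representative of each index
friedel_canonical <- function(hkl) {
  neg <- hkl[, 1] < 0 |
    (hkl[, 1] == 0 & hkl[, 2] < 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] < 0)
  hkl[neg, ] <- -hkl[neg, , drop = FALSE]
  hkl
}

reduce_friedel <- function(hkl, fobs, sigf, free, tol = 1e-3) {
  hkl <- friedel_canonical(hkl)
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) {
    idx <- split(seq_along(key), key)
    merged <- lapply(idx, function(i) {
      f <- fobs[i][!is.na(fobs[i])]
      if (!length(f)) f <- NA_real_
      if (length(f) > 1L && diff(range(f)) > tol * (mean(f) + 1e-12))
        stop("duplicate reflection (", key[i[1]],
             ") with inconsistent amplitudes: ", paste(signif(f, 6), collapse = ", "))
      list(i = i[1], f = mean(f), s = mean(sigf[i]), fr = any(free[i]))
    })
    first <- vapply(merged, `[[`, numeric(1), "i")
    o <- order(first)
    merged <- merged[o]
    hkl <- hkl[vapply(merged, `[[`, numeric(1), "i"), , drop = FALSE]
    fobs <- vapply(merged, `[[`, numeric(1), "f")
    sigf <- vapply(merged, `[[`, numeric(1), "s")
    free <- vapply(merged, `[[`, logical(1), "fr")
  }
  keep <- !(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0)
  list(hkl = hkl[keep, , drop = FALSE], fobs = fobs[keep],
       sigf = sigf[keep], free = free[keep])
}

#' Read reflection amplitudes
#'
#' Reads whitespace-delimited text with columns `h k l F [sigF] [free]` and
#' `#` comments.  Duplicate indices (including Friedel mates) are merged;
#' inconsistent duplicate amplitudes are an error.  A `cell` is required to
#' compute d-spacings.  Binary MTZ is not parsed natively; convert to the
#' text form first (e.g. with `gemmi mtz2csv` or any reflection-file tool).
#'
#' @param path input file.
#' @param cell unit cell `(a, b, c, alpha, beta, gamma)`.
#' @param d_min,d_max optional resolution cutoffs in Angstrom.
#' @param intensities set `TRUE` if column 4 holds intensities; they are
#'   converted as `|F| = sqrt(max(I, 0))` (no French-Wilson treatment).
#' @return a [reflection_set()].
#' @export
read_reflections <- function(path, cell, d_min = NULL, d_max = NULL,
                             intensities = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtz$", path, ignore.case = TRUE))
    stop("binary MTZ is not read natively; export columns H K L F [SIGF] [FreeR_flag] ",
         "to whitespace-delimited text and re-run")
  tab <- utils::read.table(path, comment.char = "#", fill = TRUE)
  if (ncol(tab) < 4) stop("need at least 4 columns: h k l F")
  f <- as.numeric(tab[[4]])
  if (intensities) f <- sqrt(pmax(f, 0))
  if (any(f < 0, na.rm = TRUE))
    stop("negative amplitudes; if these are intensities, set intensities=TRUE")
  sigf <- if (ncol(tab) >= 5) as.numeric(tab[[5]]) else NULL
  free <- if (ncol(tab) >= 6) !is.na(tab[[6]]) & tab[[6]] != 0 else NULL
  refl <- reflection_set(as.matrix(tab[, 1:3]), f, cell, sigf, free)
  resolution_cut(refl, d_min, d_max)
}

#' Restrict a reflection set to a resolution range
#' @param refl a [reflection_set()].
#' @param d_min,d_max resolution limits in Angstrom (`NULL` = no cut).
#' @return the truncated [reflection_set()].
#' @export
resolution_cut <- function(refl, d_min = NULL, d_max = NULL) {
  keep <- rep(TRUE, n_refl(refl))
  if (!is.null(d_min)) keep <- keep & refl$d >= d_min
  if (!is.null(d_max)) keep <- keep & refl$d <= d_max
  refl$hkl <- refl$hkl[keep, , drop = FALSE]
  refl$fobs <- refl$fobs[keep]; refl$sigf <- refl$sigf[keep]
  refl$free <- refl$free[keep]; refl$d <- refl$d[keep]
  refl
}

#' Write a reflection set as hkl text
#' @param refl a [reflection_set()].
#' @param path output file.
#' @export
write_reflections <- function(refl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# h k l F sigF free", con)
  sig <- ifelse(is.na(refl$sigf), 0, refl$sigf)
  writeLines(sprintf("%d %d %d %.6g %.6g %d",
                     refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3],
                     refl$fobs, sig, as.integer(refl$free)), con)
  invisible(path)
}

#' Assign cross-validation (free-R) flags
#'
#' Marks a random subset of reflections as the free set, reproducibly from a
#' seed.  Existing flags are preserved unless `overwrite = TRUE`.
#'
#' @param refl a [reflection_set()].
#' @param fraction free-set fraction, in (0, 0.25].
#' @param seed integer seed.
#' @param overwrite replace any existing flags.
#' @return the flagged [reflection_set()].
#' @export
assign_free_flags <- function(refl, fraction = 0.05, seed = 1L, overwrite = FALSE) {
  if (fraction <= 0 || fraction > 0.25)
    stop("free fraction must lie in (0, 0.25]")
  if (any(refl$free) && !overwrite) return(refl)
  n <- n_refl(refl)
  refl$free <- with_seed(seed, {
    fl <- stats::runif(n) < fraction
    if (!any(fl)) fl[sample.int(n, 1L)] <- TRUE
    fl
  })
  refl
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
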