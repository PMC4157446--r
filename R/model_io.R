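#' Atomic model container
#'
#' An `atomic_model` holds the atoms of a crystallographic model together
#' with the unit cell and (real-space) symmetry operators.  Coordinates are
#' Cartesian Angstrom.  Symmetry operators act on fractional coordinates as
#' `x' = R x + t`; the default is the identity (space group P1), which is the
#' only setting the synthetic test systems use.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `insert`, `alt`, `x`, `y`, `z`, `occ`, `b`.
#' @param cell numeric `(a, b, c, alpha, beta, gamma)`.
#' @param symmetry list of operators, each `list(R = 3x3 matrix, t = length-3)`
#'   in fractional coordinates.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, cell, symmetry = list(sym_identity())) {
  validate_cell(cell)
  req <- c("serial", "name", "element", "resname", "resno", "chain",
           "insert", "alt", "x", "y", "z", "occ", "b")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("model has no atoms")
  if (anyNA(atoms[, c("x", "y", "z", "occ", "b")]))
    stop("atoms contain NA coordinates, occupancies or B factors")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancies must lie in [0, 1]")
  norm_element(atoms$element)  # errors on unknown elements
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 cell = as.numeric(cell), symmetry = symmetry),
            class = "atomic_model")
}

sym_identity <- function() list(R = diag(3), t = c(0, 0, 0))

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d chain(s), cell %.2f %.2f %.2f / %.1f %.1f %.1f, %d symmetry op(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
              length(x$symmetry)))
  invisible(x)
}

model_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

set_model_xyz <- function(model, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# Element symbol from a PDB atom name when the element column is blank:
# two-letter elements only when the name starts in column 13 (rare in
# protein work); otherwise first alphabetic character.
guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "SE", "CU"), two, el)
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) and the CRYST1 record for the
#' unit cell.  Alternate locations are resolved to the highest-occupancy
#' conformer per atom, as refinement requires a single conformer.  Only space
#' group P1 receives symmetry operators automatically; other groups fall back
#' to the identity with a warning (operators can be attached manually).
#'
#' @param path PDB file.
#' @param require_cell error when no CRYST1 record is present (the default;
#'   refinement is meaningless without a cell).
#' @return an [atomic_model()].
#' @export
read_model <- function(path, require_cell = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  cry <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; sgroup <- "P 1"
  if (length(cry)) {
    cry <- cry[1]
    cell <- suppressWarnings(as.numeric(c(substr(cry, 7, 15), substr(cry, 16, 24),
                                          substr(cry, 25, 33), substr(cry, 34, 40),
                                          substr(cry, 41, 47), substr(cry, 48, 54))))
    if (anyNA(cell)) stop("malformed CRYST1 record: ", cry)
    sgroup <- trimws(substr(cry, 56, 66))
  } else if (require_cell) {
    stop("PDB file has no CRYST1 record; a unit cell is required for refinement")
  } else {
    cell <- c(1, 1, 1, 90, 90, 90)
  }

  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  el <- trimws(at$elesy)
  el[el == "" | is.na(el)] <- guess_element(at$elety[el == "" | is.na(el)])
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = toupper(el),
    resname = trimws(at$resid), resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    alt = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE)

  # resolve alternate locations: keep the highest-occupancy conformer
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1L) return(i)
      i[which.max(atoms$occ[i])]
    }), use.names = FALSE)
    n_drop <- nrow(atoms) - length(keep)
    if (n_drop > 0)
      message(sprintf("resolved alternate locations: dropped %d atom record(s)", n_drop))
    atoms <- atoms[sort(keep), , drop = FALSE]
    atoms$alt <- ""
    atoms$occ <- pmin(atoms$occ, 1)
  }

  sym <- list(sym_identity())
  if (!(toupper(gsub(" ", "", sgroup)) %in% c("P1", "")))
    warning("space group '", sgroup, "' not expanded automatically; ",
            "using identity operator (attach operators manually if needed)")
  atomic_model(atoms, cell, sym)
}

#' Write an atomic model to a PDB file
#'
#' Emits CRYST1 plus fixed-column ATOM records, coordinates at 3 decimals
#' and B factors at 2, terminated by TER/END.
#'
#' @param model an [atomic_model()].
#' @param path output file.
#' @export
write_model <- function(model, path) {
  at <- model$atoms
  if (any(abs(at[, c("x", "y", "z")]) >= 10000))
    stop("coordinate overflow: |xyz| must be < 10000 Angstrom for PDB columns")
  con <- file(path, "w")
  on.exit(close(con))
  cl <- model$cell
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                     cl[1], cl[2], cl[3], cl[4], cl[5], cl[6], "P 1", 1), con)
  nm <- at$name
  # atom-name column convention: 1-letter elements start in column 14
  nm_fmt <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                   sprintf(" %-3s", nm))
  rec <- sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 at$serial %% 100000L, nm_fmt, " ", at$resname,
                 substr(at$chain, 1, 1), at$resno %% 10000L,
                 ifelse(at$insert == "", " ", at$insert),
                 at$x, at$y, at$z, at$occ, at$b, at$element)
  writeLines(rec, con)
  writeLines(c("TER", "END"), con)
  invisible(path)
}

# backbone atom names (protein)
BACKBONE_NAMES <- c("N", "CA", "C", "O")

is_backbone <- function(model) model$atoms$name %in% BACKBONE_NAMES
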