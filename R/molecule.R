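# Standard atomic masses (amu), most-abundant-isotope-weighted standard
# atomic weights for the elements the pipeline meets in practice.
.atomic_masses <- c(
  H = 1.00794, D = 2.014102, He = 4.002602,
  Li = 6.941, Be = 9.012182, B = 10.811, C = 12.0107, N = 14.0067,
  O = 15.9994, F = 18.9984032, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815386, Si = 28.0855,
  P = 30.973762, S = 32.065, Cl = 35.453, Ar = 39.948,
  K = 39.0983, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Br = 79.904, I = 126.90447
)

#' Create a molecule
#'
#' A molecule is a tibble with one row per atom: element symbol, mass (amu),
#' Cartesian coordinates (Angstrom) and, optionally, a partial charge (e) and
#' a dipole-derivative tensor d(mu)/d(r) (atomic units, stored as three
#' columns per Cartesian component of mu).
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinates in Angstrom.
#' @param mass atomic masses in amu; looked up from the element symbol when
#'   `NULL`. Supplying masses explicitly is how isotopologues (e.g. a
#'   deuterated odorant) are expressed.
#' @param charge optional per-atom partial charges in e.
#' @param dipole_derivative optional `3N x 3` matrix of d(mu_j)/d(r_i) in
#'   atomic units (rows: atom-wise x,y,z displacement; columns: dipole
#'   component).
#' @return A tibble of class `vibrolf_molecule`.
#' @examples
#' molecule(c("O", "H", "H"),
#'          x = c(0, 0.76, -0.76), y = c(0, 0.59, 0.59), z = c(0, 0, 0))
#' @export
molecule <- function(element, x, y, z, mass = NULL, charge = NULL,
                     dipole_derivative = NULL) {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (is.null(mass)) {
    mass <- unname(.atomic_masses[element])
    if (anyNA(mass)) {
      bad <- unique(element[is.na(mass)])
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           "; supply `mass` explicitly", call. = FALSE)
    }
  }
  if (any(!is.finite(c(x, y, z)))) stop("coordinates must be finite", call. = FALSE)
  if (any(mass <= 0)) stop("masses must be positive", call. = FALSE)
  if (!is.null(charge) && length(charge) != n) {
    stop("charge must have one entry per atom", call. = FALSE)
  }
  mol <- tibble::tibble(
    element = as.character(element),
    mass = as.numeric(mass),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = if (is.null(charge)) NA_real_ else as.numeric(charge)
  )
  if (!is.null(dipole_derivative)) {
    dipole_derivative <- as.matrix(dipole_derivative)
    if (!all(dim(dipole_derivative) == c(3 * n, 3))) {
      stop("dipole_derivative must be a (3N x 3) matrix", call. = FALSE)
    }
  }
  attr(mol, "dipole_derivative") <- dipole_derivative
  class(mol) <- c("vibrolf_molecule", class(mol))
  mol
}

#' @export
print.vibrolf_molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms (%s)%s>\n", nrow(x),
              paste(unique(x$element), collapse = ","),
              if (all(is.na(x$charge))) "" else ", charged"))
  NextMethod()
}

# coordinates as an N x 3 matrix (Angstrom)
coords <- function(mol) as.matrix(mol[, c("x", "y", "z")])

# centre of mass (Angstrom)
center_of_mass <- function(mol) {
  drop(crossprod(coords(mol), mol$mass)) / sum(mol$mass)
}

#' Read a molecular geometry
#'
#' Reads an XYZ file (standard: atom count, comment line, `symbol x y z`
#' records) or a PDB file (ATOM/HETATM coordinates only; no topology is
#' inferred). Element symbols are mapped to standard atomic masses; partial
#' charges are left absent.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @param frame for multi-frame XYZ files, which frame to return (1-based).
#' @return A [molecule()].
#' @export
read_geometry <- function(path, format = c("auto", "xyz", "pdb"), frame = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, xyz = .read_xyz(path, frame), pdb = .read_pdb(path))
}

.parse_xyz_block <- function(lines, start, path) {
  n <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(n) || n < 1) {
    stop(sprintf("%s:%d: expected an atom count, got '%s'",
                 path, start, lines[start]), call. = FALSE)
  }
  if (start + 1 + n > length(lines)) {
    stop(sprintf("%s: truncated frame starting at line %d (need %d atoms)",
                 path, start, n), call. = FALSE)
  }
  rec <- lines[(start + 2):(start + 1 + n)]
  parts <- strsplit(trimws(rec), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad)) {
    stop(sprintf("%s:%d: malformed XYZ record '%s'",
                 path, start + 1 + bad[1], rec[bad[1]]), call. = FALSE)
  }
  el <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                  numeric(3)))
  if (anyNA(xyz)) {
    bad <- which(apply(is.na(xyz), 1, any))[1]
    stop(sprintf("%s:%d: non-numeric coordinate in '%s'",
                 path, start + 1 + bad, rec[bad]), call. = FALSE)
  }
  list(mol = molecule(el, xyz[, 1], xyz[, 2], xyz[, 3]),
       comment = lines[start + 1], next_line = start + 2 + n)
}

.read_xyz <- function(path, frame = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) stop(path, ": empty XYZ file", call. = FALSE)
  pos <- 1L
  for (k in seq_len(frame)) {
    if (pos > length(lines)) {
      stop(sprintf("%s: only %d frame(s) present, frame %d requested",
                   path, k - 1L, frame), call. = FALSE)
    }
    blk <- .parse_xyz_block(lines, pos, path)
    pos <- blk$next_line
  }
  blk$mol
}

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop(path, ": no ATOM/HETATM records", call. = FALSE)
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  if (anyNA(c(x, y, z))) {
    stop(path, ": malformed coordinate field in a PDB record", call. = FALSE)
  }
  el <- trimws(substr(rec, 77, 78))
  if (any(el == "")) {
    # fall back to the first letter of the atom name column
    nm <- trimws(substr(rec, 13, 16))
    el[el == ""] <- sub("^[0-9]*([A-Za-z]).*", "\\1", nm[el == ""])
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  el <- trimws(el)
  molecule(el, x, y, z)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [molecule()] or an N x 3 coordinate matrix plus `element`.
#' @param path output path.
#' @param comment comment line.
#' @param digits coordinate precision.
#' @param append append as an additional frame (multi-frame XYZ).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "", digits = 10, append = FALSE) {
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  lines <- c(
    as.character(nrow(mol)), comment,
    sprintf(fmt, mol$element, mol$x, mol$y, mol$z)
  )
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
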