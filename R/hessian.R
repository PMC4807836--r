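#' Construct a Hessian object
#'
#' Holds the matrix of second derivatives of the energy with respect to
#' Cartesian coordinates, in atomic units (Hartree/Bohr^2), together with
#' the molecule it refers to. The matrix is symmetrized on construction.
#'
#' @param matrix a 3N x 3N numeric matrix (Hartree/Bohr^2).
#' @param molecule the reference [molecule()] (N atoms).
#' @param asym_tol warn if the max asymmetry |H - t(H)| exceeds this (au).
#' @return An object of class `vibrolf_hessian` with elements `matrix`
#'   (symmetrized) and `molecule`.
#' @export
hessian_data <- function(matrix, molecule, asym_tol = 1e-4) {
  matrix <- as.matrix(matrix)
  n3 <- 3L * nrow(molecule)
  if (!all(dim(matrix) == n3)) {
    stop(sprintf("Hessian dimension mismatch: expected %dx%d, found %dx%d",
                 n3, n3, nrow(matrix), ncol(matrix)), call. = FALSE)
  }
  asym <- max(abs(matrix - t(matrix)))
  if (asym > asym_tol) {
    warning(sprintf("Hessian asymmetry %.3g au exceeds %.1g; symmetrizing",
                    asym, asym_tol), call. = FALSE)
  }
  structure(
    list(matrix = (matrix + t(matrix)) / 2, molecule = molecule),
    class = "vibrolf_hessian"
  )
}

#' @export
print.vibrolf_hessian <- function(x, ...) {
  cat(sprintf("<hessian: %dx%d (au), %d atoms>\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$molecule)))
  invisible(x)
}

#' Read a Cartesian Hessian from a plain-text matrix file
#'
#' Accepts a whitespace-separated full 3N x 3N matrix or its lower triangle
#' (row-wise, diagonal included), as typically exported from
#' quantum-chemistry runs. The matrix is symmetrized and converted to atomic
#' units internally.
#'
#' @param path file path; `#` comment lines are ignored.
#' @param molecule the reference [molecule()]; fixes N.
#' @param units `"au"` (Hartree/Bohr^2) or `"kcal_mol_A2"` (kcal/mol/A^2).
#' @return A [hessian_data()] object (atomic units).
#' @export
read_hessian <- function(path, molecule, units = c("au", "kcal_mol_A2")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  n3 <- 3L * nrow(molecule)
  H <- if (length(vals) == n3 * n3) {
    matrix(vals, n3, n3, byrow = TRUE)
  } else if (length(vals) == n3 * (n3 + 1) / 2) {
    m <- matrix(0, n3, n3)
    m[upper.tri(m, diag = TRUE)] <- vals   # row-wise lower tri == col-wise upper
    m + t(m) - diag(diag(m))
  } else {
    stop(sprintf(
      "Hessian in %s has %d values; expected %d (full 3Nx3N) or %d (lower triangle) for N = %d atoms",
      path, length(vals), n3 * n3, n3 * (n3 + 1) / 2, nrow(molecule)),
      call. = FALSE)
  }
  if (units == "kcal_mol_A2") {
    H <- H / vibrolf_constants$hartree_to_kcal_mol *
      vibrolf_constants$bohr_to_angstrom^2
  }
  hessian_data(H, molecule)
}

#' Write a Hessian to a plain-text matrix file
#'
#' @param hess a [hessian_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hessian <- function(hess, path) {
  write.table(format(hess$matrix, digits = 17, scientific = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column potential-energy time series
#'
#' Tab- or whitespace-separated columns time (ns) and potential energy
#' (kcal/mol); lines starting with `#` are comments. A header comment of the
#' form `# units: <time> <energy>` is recognized but only the default
#' ns / kcal/mol combination is interpreted numerically.
#'
#' @param path file path.
#' @param state state label, `"donor"` or `"acceptor"`.
#' @return An `energy_trace` tibble: columns `time` (ns), `energy`
#'   (kcal/mol), attribute `state`.
#' @export
read_energy_trace <- function(path, state = c("donor", "acceptor")) {
  state <- match.arg(state)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop(path, ": no samples in energy trace", call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  m <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[1:2])),
                numeric(2)))
  if (anyNA(m)) stop(path, ": non-numeric field in energy trace", call. = FALSE)
  energy_trace(time = m[, 1], energy = m[, 2], state = state)
}

#' Construct an energy trace
#'
#' @param time time stamps in ns, strictly increasing.
#' @param energy potential-energy samples in kcal/mol.
#' @param state state label, `"donor"` or `"acceptor"`.
#' @return A tibble of class `vibrolf_energy_trace`.
#' @export
energy_trace <- function(time, energy, state = c("donor", "acceptor")) {
  state <- match.arg(state)
  if (length(time) < 2) stop("energy trace needs at least 2 samples", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
  tr <- tibble::tibble(time = as.numeric(time), energy = as.numeric(energy))
  attr(tr, "state") <- state
  class(tr) <- c("vibrolf_energy_trace", class(tr))
  tr
}

#' Write an energy trace as TSV
#'
#' @param trace an [energy_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: ns kcal/mol",
               sprintf("# state: %s", attr(trace, "state") %||% "donor")), con)
  utils::write.table(as.data.frame(trace[, c("time", "energy")]), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
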