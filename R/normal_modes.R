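# Orthonormal basis of the translation/rotation (Eckart) subspace in
# mass-weighted coordinates. Masses in amu, coordinates in Angstrom (only
# directions matter). Returns a 3N x k matrix, k <= 6 (5 for linear).
.eckart_basis <- function(mol) {
  n <- nrow(mol)
  m <- mol$mass
  xyz <- sweep(coords(mol), 2, center_of_mass(mol))
  sq <- sqrt(m)
  V <- matrix(0, 3 * n, 6)
  for (a in 1:3) V[seq(a, 3 * n, by = 3), a] <- sq           # translations
  for (a in 1:3) {                                           # rotations
    e <- diag(3)[a, ]
    rot <- t(vapply(seq_len(n), function(i) {
      sq[i] * c(e[2] * xyz[i, 3] - e[3] * xyz[i, 2],
                e[3] * xyz[i, 1] - e[1] * xyz[i, 3],
                e[1] * xyz[i, 2] - e[2] * xyz[i, 1])
    }, numeric(3)))
    V[, 3 + a] <- as.vector(t(rot))
  }
  qr_ <- qr(V)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  Q
}

# projector onto the internal (vibration) subspace, mass-weighted coords;
# attribute "n_tr" records the removed translation/rotation dimension
.internal_projector <- function(mol) {
  B <- .eckart_basis(mol)
  P <- diag(3 * nrow(mol)) - tcrossprod(B)
  attr(P, "n_tr") <- ncol(B)
  P
}

#' Harmonic normal modes from a Cartesian Hessian
#'
#' Builds the mass-weighted Hessian, optionally projects out the six (five
#' for linear molecules) Eckart translation/rotation vectors, diagonalizes,
#' and converts eigenvalues to wavenumbers. Imaginary frequencies are
#' reported as negative wavenumbers with a warning. Cartesian mode vectors
#' are normalized so that sum_n m(n) |y_mu(n)|^2 = 1 (units amu^-1/2), and
#' each vector's sign is fixed so its largest-magnitude component is
#' positive.
#'
#' @param hessian a [hessian_data()] object (au).
#' @param project_tr project out translations and Eckart rotations before
#'   diagonalizing (default `TRUE`).
#' @param zero_tol modes with |wavenumber| below this (cm^-1) are treated as
#'   translation/rotation remnants and dropped from the internal set.
#' @return An object of class `vibrolf_modes`: list with `frequency` (cm^-1,
#'   ascending), `vectors` (3N x n_modes, Cartesian, amu^-1/2 normalization),
#'   `reduced_mass` (amu), `intensity` (km/mol or NA), `molecule`,
#'   `n_projected` (count of removed TR modes).
#' @export
compute_normal_modes <- function(hessian, project_tr = TRUE, zero_tol = 1) {
  mol <- hessian$molecule
  n <- nrow(mol)
  m_me <- rep(mol$mass, each = 3) * vibrolf_constants$amu_to_me
  Hmw <- hessian$matrix / sqrt(outer(m_me, m_me))
  n_tr <- 0L
  if (project_tr) {
    P <- .internal_projector(mol)
    n_tr <- attr(P, "n_tr")
    Hmw <- P %*% Hmw %*% P
  }
  eig <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  if (any(!is.finite(eig$values))) stop("non-finite Hessian eigenvalues", call. = FALSE)
  # eigenvalues in au of omega^2; hbar*omega in Hartree since hbar = 1
  wn <- sign(eig$values) * sqrt(abs(eig$values)) * vibrolf_constants$hartree_to_cm1
  ord <- order(wn)
  wn <- wn[ord]
  L <- eig$vectors[, ord, drop = FALSE]
  if (project_tr) {
    tr_like <- abs(wn) < zero_tol
    if (sum(tr_like) > n_tr) {
      warning(sprintf(
        "%d near-zero modes after projection (expected %d): geometry may not be at a stationary point",
        sum(tr_like), n_tr), call. = FALSE)
    }
    keep <- !tr_like
    wn <- wn[keep]
    L <- L[, keep, drop = FALSE]
  }
  if (any(wn < 0)) {
    warning(sprintf("%d imaginary frequencies (reported negative)", sum(wn < 0)),
            call. = FALSE)
  }
  # Cartesian displacement vectors: y = M^-1/2 l, normalized to sum m y^2 = 1
  m_amu <- rep(mol$mass, each = 3)
  Y <- L / sqrt(m_amu)
  norms <- sqrt(colSums(m_amu * Y^2))
  Y <- sweep(Y, 2, norms, "/")
  # sign convention: largest-|component| positive
  for (j in seq_len(ncol(Y))) {
    k <- which.max(abs(Y[, j]))
    if (Y[k, j] < 0) Y[, j] <- -Y[, j]
  }
  red_mass <- 1 / colSums(Y^2)   # amu, Y in amu^-1/2
  structure(
    list(frequency = wn, vectors = Y, reduced_mass = red_mass,
         intensity = rep(NA_real_, length(wn)), molecule = mol,
         n_projected = if (project_tr) n_tr else 0L),
    class = "vibrolf_modes"
  )
}

#' @export
print.vibrolf_modes <- function(x, ...) {
  cat(sprintf("<normal modes: %d modes, %d atoms, %s intensities>\n",
              length(x$frequency), nrow(x$molecule),
              if (all(is.na(x$intensity))) "no" else "with"))
  print(utils::head(tidy(x), 10))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normal-mode set
#'
#' @param x a `vibrolf_modes` object.
#' @param ... unused.
#' @return Tibble with columns `mode`, `frequency` (cm^-1), `reduced_mass`
#'   (amu), `intensity` (km/mol, NA until [ir_intensities()] is run).
#' @method tidy vibrolf_modes
#' @export
tidy.vibrolf_modes <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$frequency),
    frequency = x$frequency,
    reduced_mass = x$reduced_mass,
    intensity = x$intensity
  )
}

#' @method glance vibrolf_modes
#' @export
glance.vibrolf_modes <- function(x, ...) {
  tibble::tibble(
    n_modes = length(x$frequency),
    n_atoms = nrow(x$molecule),
    n_imaginary = sum(x$frequency < 0),
    freq_min = min(x$frequency),
    freq_max = max(x$frequency)
  )
}

#' IR intensities from dipole derivatives
#'
#' For each mode, the dipole derivative along the normal coordinate is
#' dmu/dQ = sum_n (dmu/dr_n) . y_mu(n); the double-harmonic IR intensity is
#' proportional to |dmu/dQ|^2 with the standard km/mol prefactor.
#'
#' @param modes a `vibrolf_modes` object.
#' @param molecule a [molecule()] carrying a `dipole_derivative` attribute
#'   (3N x 3, au); defaults to the modes' own molecule.
#' @return The modes object with the `intensity` field filled (km/mol).
#' @export
ir_intensities <- function(modes, molecule = modes$molecule) {
  D <- attr(molecule, "dipole_derivative")
  if (is.null(D)) {
    stop("molecule carries no dipole-derivative tensor; supply one via ",
         "molecule(..., dipole_derivative = )", call. = FALSE)
  }
  # dmu/dQ in e * amu^-1/2 (D in au = e, Y in amu^-1/2)
  dmdq <- t(modes$vectors) %*% D          # n_modes x 3
  modes$intensity <- rowSums(dmdq^2) * vibrolf_constants$ir_km_mol_per_e2_amu
  modes
}

# Hungarian algorithm (Munkres) for a square cost matrix; returns for each
# row the assigned column minimizing total cost. O(n^3); n here is the mode
# count (tens), so a plain R implementation is adequate.
.solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                           v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Match vacuum and embedded normal modes
#'
#' Pairs each vacuum mode with an embedded mode by solving the linear
#' assignment problem that maximizes the total squared mass-weighted mode
#' overlap, then reports the frequency shift of each pair. The shift of mode
#' mu is delta-nu = nu_embedded - nu_vacuum, given in cm^-1 and meV
#' (1 cm^-1 = 0.12398 meV).
#'
#' @param vacuum,embedded `vibrolf_modes` for the same molecule (same atom
#'   count and order).
#' @return A tibble of class `vibrolf_mode_match`: columns `mode_vacuum`,
#'   `mode_embedded`, `freq_vacuum`, `freq_embedded`, `overlap` (in [0,1]),
#'   `shift_cm1`, `shift_mev`.
#' @export
match_modes <- function(vacuum, embedded) {
  if (nrow(vacuum$molecule) != nrow(embedded$molecule)) {
    stop("mode sets refer to molecules with different atom counts", call. = FALSE)
  }
  m_amu <- rep(vacuum$molecule$mass, each = 3)
  # mass-weighted overlap matrix: entries in [-1, 1]
  Lv <- vacuum$vectors * sqrt(m_amu)
  Le <- embedded$vectors * sqrt(m_amu)
  ov <- crossprod(Lv, Le)
  nv <- length(vacuum$frequency); ne <- length(embedded$frequency)
  if (nv != ne) stop("mode counts differ (", nv, " vs ", ne, ")", call. = FALSE)
  assign <- .solve_assignment(-(ov^2))
  ovl <- abs(ov[cbind(seq_len(nv), assign)])
  out <- tibble::tibble(
    mode_vacuum = seq_len(nv),
    mode_embedded = assign,
    freq_vacuum = vacuum$frequency,
    freq_embedded = embedded$frequency[assign],
    overlap = pmin(ovl, 1),
    shift_cm1 = embedded$frequency[assign] - vacuum$frequency
  )
  out$shift_mev <- out$shift_cm1 * vibrolf_constants$cm1_to_mev
  class(out) <- c("vibrolf_mode_match", class(out))
  out
}

#' Broadened vibrational spectrum
#'
#' Sum of Lorentzians centered at the mode frequencies, weighted by IR
#' intensity (unit weight when intensities are absent). Each Lorentzian is
#' area-normalized, so the integral over a sufficiently wide grid equals the
#' summed stick intensity.
#'
#' @param modes a `vibrolf_modes` object.
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param grid wavenumber grid (cm^-1); default spans the modes with a
#'   50*fwhm margin at 1 cm^-1 spacing.
#' @return Tibble with columns `wavenumber` (cm^-1) and `absorbance`
#'   (intensity per cm^-1).
#' @export
broaden_spectrum <- function(modes, fwhm = 10, grid = NULL) {
  stopifnot(fwhm > 0)
  freq <- modes$frequency
  w <- modes$intensity
  if (all(is.na(w))) w <- rep(1, length(freq))
  keep <- freq > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive-frequency mode(s) excluded from spectrum",
            call. = FALSE)
  }
  freq <- freq[keep]; w <- w[keep]
  if (is.null(grid)) {
    grid <- seq(max(0, min(freq) - 50 * fwhm), max(freq) + 50 * fwhm, by = 1)
  }
  if (!length(freq) || max(freq) < min(grid) || min(freq) > max(grid)) {
    warning("grid excludes all modes; returning a flat spectrum", call. = FALSE)
    return(tibble::tibble(wavenumber = grid, absorbance = rep(0, length(grid))))
  }
  gamma <- fwhm / 2
  y <- rep(0, length(grid))
  for (i in seq_along(freq)) {
    y <- y + w[i] * gamma / pi / ((grid - freq[i])^2 + gamma^2)
  }
  tibble::tibble(wavenumber = grid, absorbance = y)
}
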