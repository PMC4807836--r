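#' Field-induced atomic displacements by linear response
#'
#' Given a molecule with partial charges in the local field of a redox
#' state, the force on atom n is F_n = q_n E(n). The new equilibrium of the
#' harmonic molecule solves H x = F restricted to the internal subspace, so
#' the displacement is obtained by applying the Moore-Penrose pseudo-inverse
#' of the Eckart-projected mass-weighted Hessian to the mass-weighted force
#' and mapping back to Cartesian coordinates. The result lies in the
#' translation/rotation-free subspace by construction.
#'
#' @param hessian a [hessian_data()] (au).
#' @param molecule a [molecule()] with partial charges; defaults to the
#'   Hessian's molecule.
#' @param field a `field_map` from [field_at_points()] evaluated at the
#'   molecule's atoms (au).
#' @return A `displacement_set` tibble: per-atom columns `dx,dy,dz` (Bohr),
#'   attributes `provenance = "linear_response"` and `state`.
#' @export
displacements_linear_response <- function(hessian, molecule = hessian$molecule,
                                          field) {
  if (all(is.na(molecule$charge))) {
    stop("molecule carries no partial charges; linear-response displacements ",
         "need them (q_n E_n forces)", call. = FALSE)
  }
  n <- nrow(molecule)
  if (nrow(field) != n) stop("field map does not match the molecule", call. = FALSE)
  m_me <- rep(molecule$mass, each = 3) * vibrolf_constants$amu_to_me
  P <- .internal_projector(molecule)
  Hmw <- P %*% (hessian$matrix / sqrt(outer(m_me, m_me))) %*% P
  eig <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  n_tr <- attr(P, "n_tr")
  vals <- eig$values
  scale <- max(abs(vals))
  zero <- abs(vals) < 1e-10 * max(scale, 1e-30)
  if (sum(zero) > n_tr) {
    stop(sprintf("Hessian is singular beyond the %d translation/rotation modes (%d null directions)",
                 n_tr, sum(zero)), call. = FALSE)
  }
  inv_vals <- ifelse(zero, 0, 1 / vals)
  Fc <- molecule$charge * as.matrix(field[, c("Ex", "Ey", "Ez")])  # au force
  f_mw <- as.vector(t(Fc)) / sqrt(m_me)
  x_mw <- eig$vectors %*% (inv_vals * crossprod(eig$vectors, f_mw))
  x_cart <- as.vector(x_mw) / sqrt(m_me)                            # Bohr
  d <- matrix(x_cart, ncol = 3, byrow = TRUE)
  out <- tibble::tibble(dx = d[, 1], dy = d[, 2], dz = d[, 3])
  attr(out, "provenance") <- "linear_response"
  attr(out, "state") <- attr(field, "state") %||% "donor"
  class(out) <- c("vibrolf_displacements", class(out))
  out
}

#' Displacements from two optimized geometries
#'
#' Aligns the displaced structure onto the reference by mass-weighted
#' rigid-body superposition (Kabsch on mass-weighted coordinates, the
#' Eckart-like frame), then takes the per-atom coordinate difference,
#' converted from Angstrom to Bohr.
#'
#' @param ref,displaced [molecule()]s with identical atom count and order.
#' @param state state label for the result.
#' @return A `displacement_set` tibble (Bohr), provenance
#'   `"geometry_difference"`.
#' @export
displacements_from_geometries <- function(ref, displaced, state = "donor") {
  if (nrow(ref) != nrow(displaced) ||
      !identical(ref$element, displaced$element)) {
    stop("reference and displaced molecules do not match atom-for-atom",
         call. = FALSE)
  }
  fit <- .kabsch(coords(displaced), coords(ref), ref$mass)
  d <- (fit - coords(ref)) / vibrolf_constants$bohr_to_angstrom
  out <- tibble::tibble(dx = d[, 1], dy = d[, 2], dz = d[, 3])
  attr(out, "provenance") <- "geometry_difference"
  attr(out, "state") <- state
  class(out) <- c("vibrolf_displacements", class(out))
  out
}

# weighted Kabsch: rotate+translate `mobile` onto `target`; returns the
# transformed mobile coordinates (same units as input)
.kabsch <- function(mobile, target, weights = rep(1, nrow(mobile))) {
  w <- weights / sum(weights)
  cm_m <- drop(crossprod(mobile, w))
  cm_t <- drop(crossprod(target, w))
  A <- sweep(mobile, 2, cm_m)
  B <- sweep(target, 2, cm_t)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cm_t, "+")
}

#' Mass-weighted normal-coordinate shifts
#'
#' Projects a set of field-induced Cartesian displacements onto each normal
#' mode: delta-Pi_mu = sum_n m(n) y_mu(n) . Delta(n), with y mass-weight
#' normalized (sum m |y|^2 = 1), giving delta-Pi in amu^1/2 Bohr.
#'
#' @param modes a `vibrolf_modes` object.
#' @param disp a `displacement_set` (Bohr) for the same molecule.
#' @return Numeric vector of delta-Pi_mu (amu^1/2 Bohr), one per mode.
#' @export
mode_shift <- function(modes, disp) {
  n <- nrow(modes$molecule)
  if (nrow(disp) != n) stop("displacement set does not match the molecule", call. = FALSE)
  m_amu <- rep(modes$molecule$mass, each = 3)
  dvec <- as.vector(t(as.matrix(disp[, c("dx", "dy", "dz")])))
  drop(crossprod(modes$vectors * m_amu, dvec))
}

#' Electron-phonon coupling strength of a mode
#'
#' For a displaced harmonic oscillator, the dimensionless coupling of mode
#' mu in redox state i is u_i(mu) = -sqrt(omega_mu / 2 hbar) * delta-Pi_mu,
#' evaluated in atomic units: the wavenumber is converted to the angular
#' frequency in au (hbar = 1) and delta-Pi from amu^1/2 Bohr to
#' m_e^1/2 Bohr.
#'
#' @param freq_cm1 mode wavenumber(s), cm^-1, > 0.
#' @param dpi delta-Pi_mu in amu^1/2 Bohr (same length).
#' @return Dimensionless coupling strength(s) u.
#' @export
coupling_strength <- function(freq_cm1, dpi) {
  if (any(freq_cm1 <= 0)) {
    stop("coupling strength requires positive frequencies; ",
         "imaginary/TR modes must be excluded upstream", call. = FALSE)
  }
  omega_au <- freq_cm1 / vibrolf_constants$hartree_to_cm1
  dpi_au <- dpi * sqrt(vibrolf_constants$amu_to_me)
  -sqrt(omega_au / 2) * dpi_au
}

#' Huang-Rhys factors of a displaced mode
#'
#' With S = (u_D - u_A)^2, the probability of emitting n vibrational quanta
#' during the electron transfer is the Franck-Condon weight
#' sigma_n = S^n / n! * exp(-S), a normalized Poisson distribution in n.
#' `normalized = FALSE` evaluates the divergent sign variant exp(+S) instead
#' (for inspection only; the factors then do not sum to 1).
#'
#' @param u_D,u_A dimensionless coupling strengths of the donor and
#'   acceptor states.
#' @param n_max highest vibrational quantum reported (>= 1).
#' @param normalized use exp(-S) (default) so that sum_n sigma_n = 1.
#' @return Tibble with columns `n` (0..n_max) and `sigma`; the total
#'   coupling `S` is attached as attribute `"S"`.
#' @export
huang_rhys <- function(u_D, u_A, n_max = 10L, normalized = TRUE) {
  stopifnot(n_max >= 1)
  S <- (u_D - u_A)^2
  n <- 0:n_max
  log_sigma <- n * log(ifelse(S > 0, S, 1)) - lfactorial(n) +
    (if (normalized) -S else S)
  sigma <- if (S == 0) as.numeric(n == 0) else exp(log_sigma)
  out <- tibble::tibble(n = n, sigma = sigma)
  attr(out, "S") <- S
  out
}

#' Per-mode electron-phonon coupling table
#'
#' End-to-end assembly for a donor/acceptor pair of local fields: for every
#' internal mode it computes the mass-weighted normal-coordinate shifts in
#' both states, the coupling strengths u_D and u_A, the Huang-Rhys
#' S = (u_D - u_A)^2 and the single-phonon emission weight
#' sigma_1 = S exp(-S). Modes with non-positive frequencies are excluded
#' with a warning.
#'
#' @param modes a `vibrolf_modes` object.
#' @param disp_D,disp_A `displacement_set`s for the donor and acceptor
#'   fields (from [displacements_linear_response()] or
#'   [displacements_from_geometries()]).
#' @return A tibble of class `vibrolf_coupling`: columns `mode`, `frequency`
#'   (cm^-1), `dpi_D`, `dpi_A` (amu^1/2 Bohr), `u_D`, `u_A`, `S`, `sigma1`.
#' @export
electron_phonon_coupling <- function(modes, disp_D, disp_A) {
  keep <- modes$frequency > 0
  if (any(!keep)) {
    warning(sum(!keep), " mode(s) with non-positive frequency excluded from coupling",
            call. = FALSE)
  }
  dpi_D <- mode_shift(modes, disp_D)[keep]
  dpi_A <- mode_shift(modes, disp_A)[keep]
  freq <- modes$frequency[keep]
  u_D <- coupling_strength(freq, dpi_D)
  u_A <- coupling_strength(freq, dpi_A)
  S <- (u_D - u_A)^2
  out <- tibble::tibble(
    mode = which(keep),
    frequency = freq,
    dpi_D = dpi_D, dpi_A = dpi_A,
    u_D = u_D, u_A = u_A,
    S = S,
    sigma1 = S * exp(-S)
  )
  class(out) <- c("vibrolf_coupling", class(out))
  out
}

#' Huang-Rhys factor table up to n_max for every mode
#'
#' @param coupling a `vibrolf_coupling` table.
#' @param n_max highest vibrational quantum.
#' @return Long tibble: `mode`, `frequency`, `n`, `sigma`.
#' @export
huang_rhys_table <- function(coupling, n_max = 10L) {
  purrr::map_dfr(seq_len(nrow(coupling)), function(i) {
    hr <- huang_rhys(coupling$u_D[i], coupling$u_A[i], n_max = n_max)
    tibble::tibble(mode = coupling$mode[i], frequency = coupling$frequency[i],
                   n = hr$n, sigma = hr$sigma)
  })
}
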