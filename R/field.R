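#' Electric field of a multipole environment at a set of points
#'
#' Sums the fields of all site monopoles, point dipoles and traceless
#' quadrupoles at each evaluation point. Positions enter in Angstrom and are
#' converted to Bohr internally; the returned field is in atomic units.
#' The environment's own polarizabilities contribute only after
#' [induce_dipoles()] has folded induced dipoles into the dipole columns.
#'
#' @param env a [multipole_environment()].
#' @param points an `n x 3` matrix of evaluation points (Angstrom), or a
#'   [molecule()] whose atom positions are used.
#' @param state optional state label for the result; defaults to the
#'   environment's.
#' @return A `field_map` tibble: columns `x,y,z` (Angstrom, the points) and
#'   `Ex,Ey,Ez` (au), attribute `state`.
#' @export
field_at_points <- function(env, points, state = NULL) {
  pts <- if (inherits(points, "vibrolf_molecule")) coords(points) else as.matrix(points)
  stopifnot(ncol(pts) == 3)
  b <- vibrolf_constants$bohr_to_angstrom
  P <- pts / b                              # Bohr
  S <- as.matrix(env[, c("x", "y", "z")]) / b
  E <- matrix(0, nrow(P), 3)
  for (i in seq_len(nrow(P))) {
    R <- sweep(S, 2, P[i, ])                # site -> point ... actually point - site below
    R <- -R                                 # R = point - site
    r2 <- rowSums(R^2)
    if (any(r2 < (1e-6 / b)^2)) {
      j <- which(r2 < (1e-6 / b)^2)[1]
      stop(sprintf("evaluation point %d coincides with site %d (distance < 1e-6 A)",
                   i, j), call. = FALSE)
    }
    r <- sqrt(r2)
    # monopoles: q R / r^3
    E[i, ] <- E[i, ] + colSums(env$q / r^3 * R)
    # dipoles: (3 (p.Rhat) Rhat - p) / r^3
    pmat <- as.matrix(env[, c("dx", "dy", "dz")])
    if (any(pmat != 0)) {
      pr <- rowSums(pmat * R) / r           # p . Rhat
      E[i, ] <- E[i, ] + colSums((3 * pr / r^3 / r) * R - pmat / r^3)
    }
    # traceless quadrupoles: E = 5/2 (Rhat.Q.Rhat) R / r^4 /r ... derived from
    # phi = (1/2) R.Q.R / r^5:  E_k = -Q_kj R_j / r^5 + (5/2)(R.Q.R) R_k / r^7
    qm <- as.matrix(env[, c("qxx", "qxy", "qxz", "qyy", "qyz", "qzz")])
    if (any(qm != 0)) {
      QR <- cbind(
        qm[, 1] * R[, 1] + qm[, 2] * R[, 2] + qm[, 3] * R[, 3],
        qm[, 2] * R[, 1] + qm[, 4] * R[, 2] + qm[, 5] * R[, 3],
        qm[, 3] * R[, 1] + qm[, 5] * R[, 2] + qm[, 6] * R[, 3]
      )
      RQR <- rowSums(R * QR)
      E[i, ] <- E[i, ] + colSums((5 / 2) * RQR / r^7 * R - QR / r^5)
    }
  }
  fm <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       Ex = E[, 1], Ey = E[, 2], Ez = E[, 3])
  attr(fm, "state") <- state %||% attr(env, "state") %||% "donor"
  class(fm) <- c("vibrolf_field_map", class(fm))
  fm
}

#' Electrostatic potential of an environment at points (au)
#'
#' Companion to [field_at_points()]; mainly used for consistency checks
#' (the field is minus the gradient of this potential).
#'
#' @inheritParams field_at_points
#' @return numeric vector of potentials (au), one per point.
#' @export
potential_at_points <- function(env, points) {
  pts <- if (inherits(points, "vibrolf_molecule")) coords(points) else as.matrix(points)
  b <- vibrolf_constants$bohr_to_angstrom
  P <- pts / b
  S <- as.matrix(env[, c("x", "y", "z")]) / b
  pmat <- as.matrix(env[, c("dx", "dy", "dz")])
  qm <- as.matrix(env[, c("qxx", "qxy", "qxz", "qyy", "qyz", "qzz")])
  vapply(seq_len(nrow(P)), function(i) {
    R <- sweep(-S, 2, -P[i, ])              # point - site
    r <- sqrt(rowSums(R^2))
    phi <- sum(env$q / r)
    phi <- phi + sum(rowSums(pmat * R) / r^3)
    QR <- cbind(
      qm[, 1] * R[, 1] + qm[, 2] * R[, 2] + qm[, 3] * R[, 3],
      qm[, 2] * R[, 1] + qm[, 4] * R[, 2] + qm[, 5] * R[, 3],
      qm[, 3] * R[, 1] + qm[, 5] * R[, 2] + qm[, 6] * R[, 3]
    )
    phi + sum(rowSums(R * QR) / (2 * r^5))
  }, 0)
}

#' Self-consistent induced dipoles
#'
#' Iterates mu_ind(i) = alpha(i) . E(i) where E(i) is the field at site i
#' from all other sites' monopoles, permanent dipoles, quadrupoles and the
#' current induced dipoles, until the largest component change falls below
#' `tol`. The returned environment carries permanent + induced dipoles in
#' its dipole columns (and zeroed polarizabilities are left untouched).
#' No Thole-style damping is applied.
#'
#' @param env a [multipole_environment()] with polarizabilities.
#' @param tol convergence threshold on the max induced-dipole component
#'   change (au).
#' @param max_iter iteration cap; exceeding it signals a polarization
#'   catastrophe.
#' @return The environment with converged total dipoles; the induced part is
#'   attached as attribute `"induced"` (n x 3, au).
#' @export
induce_dipoles <- function(env, tol = 1e-10, max_iter = 200L) {
  alpha <- as.matrix(env[, c("axx", "axy", "axz", "ayy", "ayz", "azz")])
  n <- nrow(env)
  if (all(alpha == 0)) {
    attr(env, "induced") <- matrix(0, n, 3)
    return(env)
  }
  b <- vibrolf_constants$bohr_to_angstrom
  S <- as.matrix(env[, c("x", "y", "z")]) / b
  perm_mu <- as.matrix(env[, c("dx", "dy", "dz")])
  mu_ind <- matrix(0, n, 3)
  field_at_site <- function(i, mu_extra) {
    R <- sweep(-S, 2, -S[i, ])              # site i - other sites
    r2 <- rowSums(R^2)
    keep <- seq_len(n) != i
    R <- R[keep, , drop = FALSE]
    r <- sqrt(r2[keep])
    mu <- (perm_mu + mu_extra)[keep, , drop = FALSE]
    Eq <- colSums(env$q[keep] / r^3 * R)
    pr <- rowSums(mu * R) / r
    Ed <- colSums((3 * pr / r^4) * R - mu / r^3)
    qm <- as.matrix(env[keep, c("qxx", "qxy", "qxz", "qyy", "qyz", "qzz")])
    EQ <- c(0, 0, 0)
    if (any(qm != 0)) {
      QR <- cbind(
        qm[, 1] * R[, 1] + qm[, 2] * R[, 2] + qm[, 3] * R[, 3],
        qm[, 2] * R[, 1] + qm[, 4] * R[, 2] + qm[, 5] * R[, 3],
        qm[, 3] * R[, 1] + qm[, 5] * R[, 2] + qm[, 6] * R[, 3]
      )
      RQR <- rowSums(R * QR)
      EQ <- colSums((5 / 2) * RQR / r^7 * R - QR / r^5)
    }
    Eq + Ed + EQ
  }
  for (it in seq_len(max_iter)) {
    mu_new <- t(vapply(seq_len(n), function(i) {
      drop(.unpack_sym(alpha[i, ]) %*% field_at_site(i, mu_ind))
    }, numeric(3)))
    delta <- max(abs(mu_new - mu_ind))
    mu_ind <- mu_new
    if (delta < tol) {
      out <- env
      out$dx <- perm_mu[, 1] + mu_ind[, 1]
      out$dy <- perm_mu[, 2] + mu_ind[, 2]
      out$dz <- perm_mu[, 3] + mu_ind[, 3]
      attr(out, "induced") <- mu_ind
      return(out)
    }
  }
  stop(sprintf(
    "induced dipoles did not converge in %d iterations (residual %.3g au): polarization catastrophe?",
    max_iter, delta), call. = FALSE)
}

#' Difference between two field maps
#'
#' Pointwise vector difference `a - b` between the fields of two redox
#' states, e.g. donor minus acceptor. Also records the mean difference
#' vector and its magnitude as attributes `mean_field` and
#' `mean_magnitude`.
#'
#' @param map_a,map_b `field_map`s on identical evaluation points.
#' @param tol tolerance for the point-identity check (Angstrom).
#' @return A `field_map` of the difference, state label `"difference"`.
#' @export
field_difference <- function(map_a, map_b, tol = 1e-8) {
  pa <- as.matrix(map_a[, c("x", "y", "z")])
  pb <- as.matrix(map_b[, c("x", "y", "z")])
  if (nrow(pa) != nrow(pb) || max(abs(pa - pb)) > tol) {
    stop("field maps are not on the same evaluation points", call. = FALSE)
  }
  d <- tibble::tibble(
    x = map_a$x, y = map_a$y, z = map_a$z,
    Ex = map_a$Ex - map_b$Ex,
    Ey = map_a$Ey - map_b$Ey,
    Ez = map_a$Ez - map_b$Ez
  )
  mean_vec <- c(mean(d$Ex), mean(d$Ey), mean(d$Ez))
  attr(d, "state") <- "difference"
  attr(d, "mean_field") <- mean_vec
  attr(d, "mean_magnitude") <- sqrt(sum(mean_vec^2))
  class(d) <- c("vibrolf_field_map", class(d))
  d
}

#' Average field at the center of a molecule
#'
#' Mass-weighted average of the atomic field vectors, reported as the field
#' "at the center" of the molecule; a geometric (unweighted) mean is
#' available via `weighting = "geometric"`.
#'
#' @param map a `field_map` whose points are the molecule's atoms.
#' @param molecule the [molecule()].
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return A list with `field` (length-3, au) and `magnitude` (au).
#' @export
mean_field_at_center <- function(map, molecule,
                                 weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (nrow(map) != nrow(molecule)) {
    stop("field map and molecule have different numbers of points", call. = FALSE)
  }
  w <- if (weighting == "mass") molecule$mass else rep(1, nrow(molecule))
  w <- w / sum(w)
  f <- c(sum(w * map$Ex), sum(w * map$Ey), sum(w * map$Ez))
  list(field = f, magnitude = sqrt(sum(f^2)))
}
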