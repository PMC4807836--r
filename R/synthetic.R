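#' Toy harmonic molecule with analytic vibrational structure
#'
#' Builds a small molecule whose Hessian is assembled from harmonic bond
#' springs (plus a harmonic angle spring for bent/chain topologies, which
#' would otherwise have a zero-curvature internal bend), together with the
#' exact analytic mode list where a closed form exists. These are the
#' ground-truth fixtures for the vibrational and electron-phonon stages.
#'
#' Topologies:
#' \describe{
#'   \item{diatomic}{two atoms on the x axis; one stretch mode with
#'     omega = sqrt(k/mu_red).}
#'   \item{linear_triatomic}{symmetric A-B-A on the x axis; longitudinal
#'     stretches omega_s = sqrt(k/m_A) and
#'     omega_a = sqrt(k (m_B + 2 m_A) / (m_A m_B)).}
#'   \item{bent_triatomic}{A-B-A with a bond angle (default 104.5 deg) and
#'     an angle spring.}
#'   \item{chain}{linear N-atom chain with equal bonds; longitudinal modes
#'     follow the free-chain closed form omega_j = 2 sqrt(k/m) sin(j pi / 2N)
#'     for equal masses.}
#' }
#'
#' @param topology one of `"diatomic"`, `"linear_triatomic"`,
#'   `"bent_triatomic"`, `"chain"`.
#' @param k bond force constant(s), atomic units (Hartree/Bohr^2).
#' @param masses atomic masses (amu); length fixed by the topology (`n_atoms`
#'   for chains).
#' @param charges per-atom partial charges (e); default alternating +/-.
#' @param bond_length equilibrium bond length (Angstrom).
#' @param k_angle angle force constant (Hartree/rad^2) for bent/chain
#'   topologies.
#' @param angle equilibrium angle in degrees (bent topology).
#' @param n_atoms chain length (chain topology).
#' @param dipole_derivative_scale if nonzero, atoms get dipole derivatives
#'   q_n * I * scale (a charge-model pattern), enabling IR intensities.
#' @return A list with `molecule`, `hessian` ([hessian_data()]),
#'   `analytic` (tibble of closed-form wavenumbers in cm^-1, NA where no
#'   closed form applies), `linear` (logical).
#' @export
make_toy_molecule <- function(topology = c("diatomic", "linear_triatomic",
                                           "bent_triatomic", "chain"),
                              k = 0.3, masses = NULL, charges = NULL,
                              bond_length = 1.1, k_angle = 0.15,
                              angle = 104.5, n_atoms = 4L,
                              dipole_derivative_scale = 1) {
  topology <- match.arg(topology)
  b2a <- vibrolf_constants$bohr_to_angstrom
  geom <- switch(topology,
    diatomic = {
      masses <- masses %||% c(1, 1)
      stopifnot(length(masses) == 2)
      list(el = c("X", "X"), xyz = rbind(c(0, 0, 0), c(bond_length, 0, 0)),
           bonds = rbind(c(1, 2)), angles = NULL, linear = TRUE)
    },
    linear_triatomic = {
      masses <- masses %||% c(1, 2, 1)
      stopifnot(length(masses) == 3)
      list(el = c("X", "Y", "X"),
           xyz = rbind(c(0, 0, 0), c(bond_length, 0, 0), c(2 * bond_length, 0, 0)),
           bonds = rbind(c(1, 2), c(2, 3)), angles = rbind(c(1, 2, 3)),
           linear = TRUE)
    },
    bent_triatomic = {
      masses <- masses %||% c(1, 16, 1)
      stopifnot(length(masses) == 3)
      th <- angle * pi / 180
      list(el = c("X", "Y", "X"),
           xyz = rbind(
             c(bond_length * sin(th / 2), bond_length * cos(th / 2), 0),
             c(0, 0, 0),
             c(-bond_length * sin(th / 2), bond_length * cos(th / 2), 0)),
           bonds = rbind(c(1, 2), c(2, 3)), angles = rbind(c(1, 2, 3)),
           linear = FALSE)
    },
    chain = {
      stopifnot(n_atoms >= 2)
      masses <- masses %||% rep(1, n_atoms)
      stopifnot(length(masses) == n_atoms)
      bonds <- cbind(seq_len(n_atoms - 1), seq_len(n_atoms - 1) + 1)
      angles <- if (n_atoms >= 3) {
        cbind(seq_len(n_atoms - 2), seq_len(n_atoms - 2) + 1,
              seq_len(n_atoms - 2) + 2)
      } else NULL
      list(el = rep("X", n_atoms),
           xyz = cbind((seq_len(n_atoms) - 1) * bond_length, 0, 0),
           bonds = bonds, angles = angles, linear = TRUE)
    }
  )
  n <- nrow(geom$xyz)
  if (is.null(charges)) charges <- rep_len(c(0.3, -0.3), n)
  dd <- NULL
  if (dipole_derivative_scale != 0) {
    dd <- matrix(0, 3 * n, 3)
    for (i in seq_len(n)) {
      dd[(3 * i - 2):(3 * i), ] <- diag(3) * charges[i] * dipole_derivative_scale
    }
  }
  mol <- molecule(geom$el, geom$xyz[, 1], geom$xyz[, 2], geom$xyz[, 3],
                  mass = masses, charge = charges, dipole_derivative = dd)
  H <- matrix(0, 3 * n, 3 * n)
  kb <- rep_len(k, nrow(geom$bonds))
  xyz_bohr <- geom$xyz / b2a
  for (bidx in seq_len(nrow(geom$bonds))) {
    i <- geom$bonds[bidx, 1]; j <- geom$bonds[bidx, 2]
    u <- xyz_bohr[j, ] - xyz_bohr[i, ]
    u <- u / sqrt(sum(u^2))
    blk <- kb[bidx] * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  if (!is.null(geom$angles) && k_angle > 0) {
    for (aidx in seq_len(nrow(geom$angles))) {
      tri <- geom$angles[aidx, ]
      B <- .angle_bend_gradient(xyz_bohr, tri)
      if (!is.null(B)) {
        idx <- as.vector(vapply(tri, function(a) (3 * a - 2):(3 * a), integer(3)))
        H[idx, idx] <- H[idx, idx] + k_angle * tcrossprod(B)
      }
    }
  }
  hess <- hessian_data(H, mol)
  analytic <- .analytic_modes(topology, kb, masses, geom, k_angle)
  list(molecule = mol, hessian = hess, analytic = analytic,
       linear = geom$linear)
}

# gradient of the bond angle at (i, j, k) w.r.t. the 9 Cartesian coords; for
# a *linear* angle the in-plane gradient is undefined, so two perpendicular
# bending coordinates are returned column-bound (the caller adds k * B B^T).
.angle_bend_gradient <- function(xyz, tri) {
  i <- tri[1]; j <- tri[2]; k <- tri[3]
  a <- xyz[i, ] - xyz[j, ]
  b <- xyz[k, ] - xyz[j, ]
  ra <- sqrt(sum(a^2)); rb <- sqrt(sum(b^2))
  costh <- sum(a * b) / (ra * rb)
  if (abs(costh) > 1 - 1e-10) {
    # linear: two degenerate bends, one per axis perpendicular to the chain
    u <- a / ra
    perp <- .two_perpendicular(u)
    B <- matrix(0, 9, 0)
    for (p in seq_len(2)) {
      e <- perp[, p]
      gi <- e / ra
      gk <- e / rb
      gj <- -(gi + gk)
      B <- cbind(B, c(gi, gj, gk))
    }
    return(B)
  }
  sinth <- sqrt(1 - costh^2)
  gi <- (costh * a / ra - b / rb) / (ra * sinth)
  gk <- (costh * b / rb - a / ra) / (rb * sinth)
  gj <- -(gi + gk)
  matrix(c(gi, gj, gk), ncol = 1)
}

.two_perpendicular <- function(u) {
  t <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- t - sum(t * u) * u
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  cbind(v1, v2)
}

# closed-form wavenumbers (cm^-1) where available; NA rows mark modes with
# no closed form (they are still counted)
.analytic_modes <- function(topology, kb, masses, geom, k_angle) {
  to_cm1 <- function(omega_au) omega_au * vibrolf_constants$hartree_to_cm1
  me <- vibrolf_constants$amu_to_me
  switch(topology,
    diatomic = {
      mu <- prod(masses) / sum(masses) * me
      tibble::tibble(label = "stretch", wavenumber = to_cm1(sqrt(kb[1] / mu)))
    },
    linear_triatomic = {
      mA <- masses[1] * me; mB <- masses[2] * me
      tibble::tibble(
        label = c("sym_stretch", "asym_stretch", "bend", "bend"),
        wavenumber = c(
          to_cm1(sqrt(kb[1] / mA)),
          to_cm1(sqrt(kb[1] * (mB + 2 * mA) / (mA * mB))),
          NA, NA)
      )
    },
    bent_triatomic = tibble::tibble(label = character(), wavenumber = numeric()),
    chain = {
      if (length(unique(masses)) == 1 && length(unique(kb)) == 1) {
        N <- length(masses); m <- masses[1] * me
        j <- seq_len(N - 1)
        tibble::tibble(
          label = sprintf("longitudinal_%d", j),
          wavenumber = to_cm1(2 * sqrt(kb[1] / m) * sin(j * pi / (2 * N))))
      } else tibble::tibble(label = character(), wavenumber = numeric())
    }
  )
}

#' Two redox states of a point-charge environment
#'
#' State D (donor) is the baseline environment; state A (acceptor) is the
#' baseline with `+q_transfer` added at the donor site and `-q_transfer` at
#' the acceptor site, modelling the transfer of one electron between two
#' fixed sites with everything else unchanged.
#'
#' @param geometry the odorant [molecule()] (sites may not coincide with
#'   its atoms).
#' @param donor_site,acceptor_site length-3 positions (Angstrom).
#' @param q_transfer transferred charge (e, default 1).
#' @param baseline optional baseline [multipole_environment()]; default is
#'   two neutral sites at the donor/acceptor positions.
#' @return A list with elements `donor` and `acceptor`
#'   ([multipole_environment()]s).
#' @export
make_two_state_environment <- function(geometry, donor_site, acceptor_site,
                                       q_transfer = 1, baseline = NULL) {
  if (sqrt(sum((donor_site - acceptor_site)^2)) < 1e-6) {
    stop("donor and acceptor sites coincide", call. = FALSE)
  }
  pts <- coords(geometry)
  for (s in list(donor_site, acceptor_site)) {
    dmin <- min(sqrt(rowSums(sweep(pts, 2, s)^2)))
    if (dmin < 1e-6) stop("a transfer site coincides with an odorant atom", call. = FALSE)
  }
  if (is.null(baseline)) {
    baseline <- multipole_environment(
      x = c(donor_site[1], acceptor_site[1]),
      y = c(donor_site[2], acceptor_site[2]),
      z = c(donor_site[3], acceptor_site[3]),
      q = c(0, 0)
    )
  }
  donor <- baseline
  attr(donor, "state") <- "donor"
  acceptor <- dplyr::bind_rows(
    baseline,
    multipole_environment(
      x = c(donor_site[1], acceptor_site[1]),
      y = c(donor_site[2], acceptor_site[2]),
      z = c(donor_site[3], acceptor_site[3]),
      q = c(q_transfer, -q_transfer))
  )
  attr(acceptor, "state") <- "acceptor"
  class(acceptor) <- class(baseline)
  list(donor = donor, acceptor = acceptor)
}

#' Synthetic two-state potential-energy traces
#'
#' Independent Gaussian potential-energy samples for the donor and acceptor
#' states, in the width convention of the density model (SD = width/2).
#' The generating parameters are attached to each trace as attribute
#' `"generator"` so that recovery tests never re-derive them.
#'
#' The defaults mimic the regime observed for the receptor model: equal
#' means and widths for the two states (vanishing reorganization energy).
#'
#' @param mean_D,mean_A state means (kcal/mol).
#' @param width_D,width_A state widths (kcal/mol, > 0; SD = width/2).
#' @param n samples per state.
#' @param seed RNG seed.
#' @param dt time step between samples (ns).
#' @return List with `donor` and `acceptor` [energy_trace()]s.
#' @export
make_energy_traces <- function(mean_D = -10000, mean_A = -10000,
                               width_D = 100, width_A = 100,
                               n = 1e5, seed = 1L, dt = 0.001) {
  stopifnot(width_D > 0, width_A > 0)
  set.seed(seed)
  t <- seq_len(n) * dt
  mk <- function(mean, width, state) {
    tr <- energy_trace(t, stats::rnorm(n, mean, width / 2), state)
    attr(tr, "generator") <- list(mean = mean, width = width, n = n, seed = seed)
    tr
  }
  list(donor = mk(mean_D, width_D, "donor"),
       acceptor = mk(mean_A, width_A, "acceptor"))
}

#' Scripted synthetic trajectories with closed-form ground truth
#'
#' @param base the starting [molecule()].
#' @param motion `"static"`, `"drift"` (rigid translation at constant
#'   velocity), `"oscillate"` (one atom oscillates along x), or
#'   `"random_walk"` (Gaussian steps on every coordinate).
#' @param n_frames number of frames.
#' @param seed RNG seed (random_walk).
#' @param velocity drift velocity (Angstrom/frame) along x.
#' @param amplitude,period oscillation amplitude (Angstrom) and period
#'   (frames) for `"oscillate"` (atom 1).
#' @param step_sd random-walk step SD (Angstrom).
#' @param dt frame spacing (ns).
#' @return A [trajectory()]; attribute `"expected"` holds the closed-form
#'   RMSD series (and displacement series) implied by the script.
#' @export
make_trajectory <- function(base, motion = c("static", "drift", "oscillate",
                                             "random_walk"),
                            n_frames = 100L, seed = 1L, velocity = 0.1,
                            amplitude = 0.5, period = 20, step_sd = 0.05,
                            dt = 0.001) {
  motion <- match.arg(motion)
  x0 <- coords(base)
  n <- nrow(x0)
  set.seed(seed)
  idx <- seq_len(n_frames) - 1
  frames <- switch(motion,
    static = replicate(n_frames, x0, simplify = FALSE),
    drift = lapply(idx, function(i) sweep(x0, 2, c(-velocity * i, 0, 0))),
    oscillate = lapply(idx, function(i) {
      f <- x0
      f[1, 1] <- f[1, 1] + amplitude * sin(2 * pi * i / period)
      f
    }),
    random_walk = {
      acc <- x0
      out <- vector("list", n_frames)
      out[[1]] <- acc
      for (i in seq_len(n_frames - 1)) {
        acc <- acc + matrix(stats::rnorm(3 * n, 0, step_sd), n, 3)
        out[[i + 1]] <- acc
      }
      out
    }
  )
  expected <- switch(motion,
    static = tibble::tibble(frame = idx + 1, rmsd = 0),
    drift = tibble::tibble(frame = idx + 1, rmsd = velocity * idx),
    oscillate = tibble::tibble(
      frame = idx + 1,
      rmsd = abs(amplitude * sin(2 * pi * idx / period)) / sqrt(n)),
    random_walk = NULL
  )
  traj <- trajectory(frames, time = idx * dt, molecule = base)
  attr(traj, "expected") <- expected
  attr(traj, "generator") <- list(motion = motion, seed = seed,
                                  velocity = velocity, amplitude = amplitude,
                                  period = period, step_sd = step_sd)
  traj
}
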