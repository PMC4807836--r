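uniform_field_map <- function(mol, E) {
  fm <- tibble::tibble(x = mol$x, y = mol$y, z = mol$z,
                       Ex = E[1], Ey = E[2], Ez = E[3])
  class(fm) <- c("vibrolf_field_map", class(fm))
  fm
}

test_that("linear-response displacements: zero field, diatomic closed form, argmin oracle", {
  toy <- make_toy_molecule("diatomic", k = 0.3, charges = c(0.4, -0.4))
  zero <- displacements_linear_response(toy$hessian, toy$molecule,
                                        uniform_field_map(toy$molecule, c(0, 0, 0)))
  expect_equal(max(abs(as.matrix(zero))), 0)

  # diatomic, charges +-q, axial field E: bond-length change qE/k (au)
  q <- 0.4; E <- 0.02; k <- 0.3
  d <- displacements_linear_response(toy$hessian, toy$molecule,
                                     uniform_field_map(toy$molecule, c(E, 0, 0)))
  expect_equal(abs(d$dx[2] - d$dx[1]), q * E / k, tolerance = 1e-10)

  # toy triatomic: displacement equals the argmin of 1/2 x'Hx - F'x found by
  # an independent numerical minimizer, within the internal subspace
  toy3 <- make_toy_molecule("bent_triatomic", charges = c(0.3, -0.6, 0.3))
  f3 <- uniform_field_map(toy3$molecule, c(0.01, -0.005, 0.002))
  d3 <- displacements_linear_response(toy3$hessian, toy3$molecule, f3)
  H <- toy3$hessian$matrix
  Fv <- as.vector(t(toy3$molecule$charge *
                      as.matrix(f3[, c("Ex", "Ey", "Ez")])))
  P <- vibrolf:::.internal_projector(toy3$molecule)
  m <- rep(toy3$molecule$mass, each = 3) * vibrolf_constants$amu_to_me
  # minimize over internal coordinates: x = M^-1/2 P s
  obj <- function(s) {
    x <- (P %*% s) / sqrt(m)
    0.5 * sum(x * (H %*% x)) - sum(Fv * x)
  }
  opt <- optim(rep(0, 9), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  x_opt <- (P %*% opt$par) / sqrt(m)
  d3_vec <- as.vector(t(as.matrix(d3)))
  expect_lt(max(abs(d3_vec - x_opt)), 1e-8)

  # missing charges error
  plain <- molecule(toy$molecule$element, toy$molecule$x, toy$molecule$y,
                    toy$molecule$z, mass = toy$molecule$mass)
  expect_error(
    displacements_linear_response(toy$hessian, plain,
                                  uniform_field_map(plain, c(0.01, 0, 0))),
    "charges")
})

test_that("geometry-difference displacements remove rigid motion, keep stretches", {
  mol <- seventeen_atom_molecule()
  same <- displacements_from_geometries(mol, mol)
  expect_equal(max(abs(as.matrix(same))), 0)

  # rigidly rotated + translated copy: zero after alignment
  th <- 0.5
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  xyz <- as.matrix(mol[, c("x", "y", "z")]) %*% t(R)
  rot <- molecule(mol$element, xyz[, 1] + 2, xyz[, 2], xyz[, 3] - 1,
                  mass = mol$mass)
  drot <- displacements_from_geometries(mol, rot)
  expect_lt(max(abs(as.matrix(drot))), 1e-8)

  # a known 0.05 A stretch of one bond along its axis is recovered
  toy <- make_toy_molecule("diatomic", k = 0.3, masses = c(12, 12))
  stretched <- toy$molecule
  stretched$x[2] <- stretched$x[2] + 0.05
  dstr <- displacements_from_geometries(toy$molecule, stretched)
  rel <- (dstr$dx[2] - dstr$dx[1]) * vibrolf_constants$bohr_to_angstrom
  expect_equal(rel, 0.05, tolerance = 1e-6)
  expect_equal(attr(dstr, "provenance"), "geometry_difference")

  expect_error(displacements_from_geometries(mol, toy$molecule), "atom-for-atom")
})

test_that("mode shifts: single-mode selectivity, translation nullity, completeness", {
  mol <- seventeen_atom_molecule()
  nm <- compute_normal_modes(synthetic_internal_hessian(mol))
  m <- rep(mol$mass, each = 3)

  # displacement proportional to one mode's Cartesian pattern
  j <- 10
  dv <- nm$vectors[, j] * 0.02
  disp <- tibble::tibble(dx = dv[seq(1, length(dv), 3)],
                         dy = dv[seq(2, length(dv), 3)],
                         dz = dv[seq(3, length(dv), 3)])
  dpi <- mode_shift(nm, disp)
  expect_equal(dpi[j], 0.02, tolerance = 1e-10)
  expect_lt(max(abs(dpi[-j])), 1e-10)

  # pure translation projects to zero on every internal mode
  tr <- tibble::tibble(dx = rep(0.1, 17), dy = rep(-0.2, 17), dz = rep(0.05, 17))
  expect_lt(max(abs(mode_shift(nm, tr))), 1e-10)

  # completeness: sum_mu dpi_mu (m-weighted y_mu) reconstructs m-weighted
  # internal displacement
  set.seed(8)
  rand <- rnorm(51, sd = 0.01)
  P <- vibrolf:::.internal_projector(mol)
  internal_mw <- drop(P %*% (sqrt(m) * rand))
  dint <- internal_mw / sqrt(m)
  dd <- tibble::tibble(dx = dint[seq(1, 51, 3)], dy = dint[seq(2, 51, 3)],
                       dz = dint[seq(3, 51, 3)])
  dpi2 <- mode_shift(nm, dd)
  recon <- drop((nm$vectors * sqrt(m)) %*% dpi2)   # mass-weighted
  expect_lt(max(abs(recon - internal_mw)), 1e-8)
})

test_that("coupling strength follows the displaced-oscillator closed form", {
  expect_equal(coupling_strength(1500, 0), 0)
  expect_error(coupling_strength(-5, 0.1), "positive frequencies")

  # 1-D oscillator: |u| = delta sqrt(m omega / 2 hbar); here via dpi = sqrt(m) delta
  m_amu <- 3; omega_cm1 <- 900; delta_bohr <- 0.02
  dpi <- sqrt(m_amu) * delta_bohr
  u <- coupling_strength(omega_cm1, dpi)
  m_au <- m_amu * vibrolf_constants$amu_to_me
  om_au <- omega_cm1 / vibrolf_constants$hartree_to_cm1
  expect_equal(abs(u), delta_bohr * sqrt(m_au * om_au / 2), tolerance = 1e-12)

  # linearity in the field through the linear-response path
  toy <- make_toy_molecule("diatomic", k = 0.3, charges = c(0.4, -0.4))
  nm <- compute_normal_modes(toy$hessian)
  u_at <- function(E) {
    d <- displacements_linear_response(toy$hessian, toy$molecule,
                                       uniform_field_map(toy$molecule, c(E, 0, 0)))
    coupling_strength(nm$frequency, mode_shift(nm, d))
  }
  expect_equal(u_at(0.02), 2 * u_at(0.01), tolerance = 1e-10)
})

test_that("Huang-Rhys factors: limits, normalization, Poisson mode, symmetry", {
  # u_D = u_A: all weight in sigma_0
  hr0 <- huang_rhys(0.4, 0.4)
  expect_equal(hr0$sigma[1], 1)
  expect_equal(sum(hr0$sigma[-1]), 0)

  # S = 1: sigma_1 = exp(-1)
  hr1 <- huang_rhys(1, 0)
  expect_equal(hr1$sigma[2], exp(-1), tolerance = 1e-12)

  # normalization for S across [0, 10]
  for (S in c(0, 0.3, 1, 2.5, 5, 10)) {
    hr <- huang_rhys(sqrt(S), 0, n_max = 50)
    expect_lt(abs(sum(hr$sigma) - 1), 1e-12)
  }

  # distribution peaks near n ~ S
  for (S in c(0.5, 2, 5)) {
    hr <- huang_rhys(sqrt(S), 0, n_max = 30)
    n_peak <- hr$n[which.max(hr$sigma)]
    expect_lte(abs(n_peak - floor(S)), 1)
  }

  # donor/acceptor swap leaves S and all sigma unchanged
  a <- huang_rhys(0.7, -0.2, n_max = 12)
  b <- huang_rhys(-0.2, 0.7, n_max = 12)
  expect_equal(a$sigma, b$sigma)
  expect_equal(attr(a, "S"), attr(b, "S"))

  # literal printed sign variant does not normalize
  lit <- huang_rhys(1, 0, n_max = 50, normalized = FALSE)
  expect_gt(sum(lit$sigma), 1)
})

test_that("end-to-end diatomic sigma_1 equals the hand-assembled closed form", {
  q <- 0.35; k <- 0.25; E_D <- 0.012; E_A <- -0.012
  toy <- make_toy_molecule("diatomic", k = k, masses = c(2, 2),
                           charges = c(q, -q))
  nm <- compute_normal_modes(toy$hessian)
  dD <- displacements_linear_response(toy$hessian, toy$molecule,
                                      uniform_field_map(toy$molecule, c(E_D, 0, 0)))
  dA <- displacements_linear_response(toy$hessian, toy$molecule,
                                      uniform_field_map(toy$molecule, c(E_A, 0, 0)))
  ct <- electron_phonon_coupling(nm, dD, dA)
  expect_equal(nrow(ct), 1)

  # independent closed form: relative shift per state dr_i = q E_i / k, the
  # normal-coordinate shift is sqrt(mu) dr_i (mu = reduced mass), and
  # u_i = -sqrt(omega/2) dpi_i in au, S = (u_D - u_A)^2, sigma_1 = S e^-S
  mu_au <- 1 * vibrolf_constants$amu_to_me          # reduced mass of (2,2)
  om_au <- sqrt(k / mu_au)
  dr <- function(E) q * E / k
  # the sign of dpi depends on the mode-vector sign convention; S is invariant
  S_exact <- (sqrt(om_au / 2) * sqrt(mu_au) * (dr(E_D) - dr(E_A)))^2
  expect_rel_equal(ct$S, S_exact, 1e-8)
  expect_rel_equal(ct$sigma1, S_exact * exp(-S_exact), 1e-8)

  # doubling the field difference quadruples S
  dA2 <- displacements_linear_response(toy$hessian, toy$molecule,
                                       uniform_field_map(toy$molecule, c(-3 * E_D, 0, 0)))
  ct2 <- electron_phonon_coupling(nm, dD, dA2)
  expect_rel_equal(ct2$S, 4 * ct$S, 1e-10)

  # full sigma_n table is consistent with huang_rhys()
  tab <- huang_rhys_table(ct, n_max = 6)
  hr <- huang_rhys(ct$u_D, ct$u_A, n_max = 6)
  expect_equal(tab$sigma, hr$sigma)
})
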