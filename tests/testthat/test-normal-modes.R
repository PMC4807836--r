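test_that("diatomic frequency matches the closed form sqrt(k/mu)", {
  for (k in c(0.1, 0.3, 0.8)) {
    for (m in list(c(1, 1), c(1, 12), c(12, 16))) {
      toy <- make_toy_molecule("diatomic", k = k, masses = m)
      nm <- compute_normal_modes(toy$hessian)
      expect_length(nm$frequency, 1)
      mu <- prod(m) / sum(m) * vibrolf_constants$amu_to_me
      omega_cm1 <- sqrt(k / mu) * vibrolf_constants$hartree_to_cm1
      expect_equal(nm$frequency, omega_cm1, tolerance = 1e-8)
      expect_equal(nm$frequency, toy$analytic$wavenumber, tolerance = 1e-10)
    }
  }
})

test_that("Eckart projection removes exactly six (five if linear) modes", {
  mol <- seventeen_atom_molecule()
  hess <- synthetic_internal_hessian(mol)
  nm <- compute_normal_modes(hess, project_tr = TRUE)
  expect_equal(nm$n_projected, 6L)
  expect_length(nm$frequency, 45)           # 3*17 - 6
  expect_true(all(nm$frequency > 0))
  expect_false(is.unsorted(nm$frequency))

  lin <- make_toy_molecule("linear_triatomic")
  nml <- compute_normal_modes(lin$hessian)
  expect_equal(nml$n_projected, 5L)
  expect_length(nml$frequency, 4)           # 3*3 - 5
})

test_that("mass-weighted eigenvectors are orthonormal on the internal subspace", {
  mol <- seventeen_atom_molecule()
  nm <- compute_normal_modes(synthetic_internal_hessian(mol))
  m <- rep(mol$mass, each = 3)
  L <- nm$vectors * sqrt(m)
  G <- crossprod(L)
  expect_lt(max(abs(G - diag(ncol(L)))), 1e-8)
  # normalization convention sum_n m |y|^2 = 1
  expect_lt(max(abs(colSums(m * nm$vectors^2) - 1)), 1e-10)
})

test_that("frequencies are invariant under rigid rotation of geometry + Hessian", {
  mol <- seventeen_atom_molecule()
  hess <- synthetic_internal_hessian(mol)
  nm <- compute_normal_modes(hess)
  # rotation about z by 40 deg and a translation
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(mol[, c("x", "y", "z")]) %*% t(R)
  mol_rot <- molecule(mol$element, xyz[, 1] + 3, xyz[, 2] - 1, xyz[, 3],
                      mass = mol$mass)
  Rbig <- kronecker(diag(nrow(mol)), R)
  hess_rot <- hessian_data(Rbig %*% hess$matrix %*% t(Rbig), mol_rot)
  nm_rot <- compute_normal_modes(hess_rot)
  expect_lt(max(abs(nm$frequency - nm_rot$frequency)), 1e-6)
})

test_that("doubling all masses scales every frequency by 1/sqrt(2)", {
  mol <- seventeen_atom_molecule()
  hess <- synthetic_internal_hessian(mol)
  nm1 <- compute_normal_modes(hess)
  mol2 <- molecule(mol$element, mol$x, mol$y, mol$z, mass = 2 * mol$mass)
  nm2 <- compute_normal_modes(hessian_data(hess$matrix, mol2))
  expect_rel_equal(nm2$frequency, nm1$frequency / sqrt(2), 1e-8)
})

test_that("negative curvature is reported as a negative frequency with warning", {
  mol <- molecule(c("H", "H"), x = c(0, 1), y = c(0, 0), z = c(0, 0))
  toy <- make_toy_molecule("diatomic", k = 0.3)
  H <- -toy$hessian$matrix
  expect_warning(nm <- compute_normal_modes(hessian_data(H, toy$molecule)),
                 "imaginary")
  expect_lt(nm$frequency[1], 0)
})

test_that("IR intensities: zeros, symmetric-stretch cancellation, FD oracle", {
  # all-zero dipole derivatives -> all-zero intensities
  toy <- make_toy_molecule("bent_triatomic", dipole_derivative_scale = 0)
  dd0 <- matrix(0, 9, 3)
  mol0 <- molecule(toy$molecule$element, toy$molecule$x, toy$molecule$y,
                   toy$molecule$z, mass = toy$molecule$mass,
                   dipole_derivative = dd0)
  nm <- compute_normal_modes(toy$hessian)
  expect_equal(ir_intensities(nm, mol0)$intensity, rep(0, length(nm$frequency)))

  # missing derivatives is an informative error
  expect_error(ir_intensities(nm, toy$molecule), "dipole-derivative")

  # homonuclear diatomic, equal-and-opposite derivative blocks: stretch dark
  dtoy <- make_toy_molecule("diatomic", k = 0.3, charges = c(0.5, 0.5))
  dd <- rbind(diag(3) * 0.5, diag(3) * -0.5)
  molh <- molecule(dtoy$molecule$element, dtoy$molecule$x, dtoy$molecule$y,
                   dtoy$molecule$z, mass = dtoy$molecule$mass,
                   dipole_derivative = dd)
  # equal masses: stretch pattern is (+e, -e); dmu/dQ = 0.5*(+y1) + (-0.5)*(y2)
  # with y2 = -y1 gives a maximal signal; equal-sign blocks cancel instead
  dd_sym <- rbind(diag(3) * 0.5, diag(3) * 0.5)
  mol_sym <- molecule(dtoy$molecule$element, dtoy$molecule$x, dtoy$molecule$y,
                      dtoy$molecule$z, mass = dtoy$molecule$mass,
                      dipole_derivative = dd_sym)
  nmd <- compute_normal_modes(dtoy$hessian)
  expect_equal(ir_intensities(nmd, mol_sym)$intensity, 0, tolerance = 1e-20)
  expect_gt(ir_intensities(nmd, molh)$intensity, 0)

  # finite-difference dipole oracle on a toy triatomic with prescribed ddmu
  toy3 <- make_toy_molecule("bent_triatomic", dipole_derivative_scale = 2)
  nm3 <- compute_normal_modes(toy3$hessian)
  nm3 <- ir_intensities(nm3, toy3$molecule)
  D <- attr(toy3$molecule, "dipole_derivative")
  h <- 1e-6
  dipole_of <- function(dx) drop(crossprod(D, dx))   # linear model: mu = D' x
  oracle <- vapply(seq_along(nm3$frequency), function(j) {
    y <- nm3$vectors[, j]
    dmdq <- (dipole_of(h * y) - dipole_of(-h * y)) / (2 * h)
    sum(dmdq^2) * vibrolf_constants$ir_km_mol_per_e2_amu
  }, 0)
  expect_rel_equal(nm3$intensity, oracle, 1e-6)
})

test_that("mode matching recovers identity, permutations and uniform shifts", {
  mol <- seventeen_atom_molecule()
  nm <- compute_normal_modes(synthetic_internal_hessian(mol))

  m_ident <- match_modes(nm, nm)
  expect_equal(m_ident$mode_embedded, m_ident$mode_vacuum)
  expect_equal(m_ident$shift_cm1, rep(0, nrow(m_ident)))
  expect_equal(m_ident$overlap, rep(1, nrow(m_ident)), tolerance = 1e-10)

  # permute the embedded mode order: assignment recovers the permutation
  set.seed(11)
  perm <- sample(length(nm$frequency))
  nm_perm <- nm
  nm_perm$frequency <- nm$frequency[perm]
  nm_perm$vectors <- nm$vectors[, perm]
  nm_perm$reduced_mass <- nm$reduced_mass[perm]
  m_perm <- match_modes(nm, nm_perm)
  expect_equal(m_perm$mode_embedded, order(perm))
  expect_equal(m_perm$overlap, rep(1, nrow(m_perm)), tolerance = 1e-10)
  expect_equal(m_perm$shift_cm1, rep(0, nrow(m_perm)))

  # uniform +5 cm-1 shift
  nm_shift <- nm
  nm_shift$frequency <- nm$frequency + 5
  m_shift <- match_modes(nm, nm_shift)
  expect_equal(m_shift$shift_cm1, rep(5, nrow(m_shift)))
  expect_equal(m_shift$shift_mev,
               rep(5 * vibrolf_constants$cm1_to_mev, nrow(m_shift)))

  # atom-count mismatch errors
  other <- compute_normal_modes(make_toy_molecule("diatomic")$hessian)
  expect_error(match_modes(nm, other), "atom counts")
})

test_that("broadened spectrum peaks at sticks, conserves area, is linear", {
  toy <- make_toy_molecule("diatomic", k = 0.3)
  nm <- compute_normal_modes(toy$hessian)
  fwhm <- 8
  grid <- seq(nm$frequency - 50 * fwhm, nm$frequency + 50 * fwhm, by = 0.5)
  spec <- broaden_spectrum(nm, fwhm = fwhm, grid = grid)
  expect_equal(spec$wavenumber[which.max(spec$absorbance)], nm$frequency,
               tolerance = 0.5)
  area <- sum(spec$absorbance) * 0.5
  expect_lt(abs(area - 1) / 1, 0.01)   # unit stick weight

  # two sticks = sum of single-stick curves (linearity)
  toy2 <- make_toy_molecule("linear_triatomic")
  nm2 <- compute_normal_modes(toy2$hessian)
  grid2 <- seq(0, 6000, by = 1)
  spec_all <- broaden_spectrum(nm2, fwhm = fwhm, grid = grid2)
  parts <- rep(0, length(grid2))
  for (j in seq_along(nm2$frequency)) {
    one <- nm2
    one$frequency <- nm2$frequency[j]
    one$vectors <- nm2$vectors[, j, drop = FALSE]
    one$intensity <- nm2$intensity[j]
    one$reduced_mass <- nm2$reduced_mass[j]
    parts <- parts + broaden_spectrum(one, fwhm = fwhm, grid = grid2)$absorbance
  }
  expect_rel_equal(spec_all$absorbance + 1, parts + 1, 1e-10)

  # grid excluding all modes warns and returns a flat curve
  expect_warning(flat <- broaden_spectrum(nm, fwhm = 5, grid = 1:10),
                 "flat")
  expect_equal(flat$absorbance, rep(0, 10))
})
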