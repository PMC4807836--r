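b2a <- vibrolf_constants$bohr_to_angstrom

test_that("unit point charge gives |E| = 1 au at 1 Bohr, directed away", {
  env <- multipole_environment(0, 0, 0, q = 1)
  fm <- field_at_points(env, matrix(c(b2a, 0, 0), 1))
  expect_equal(c(fm$Ex, fm$Ey, fm$Ez), c(1, 0, 0), tolerance = 1e-12)
})

test_that("axial point-dipole field is 2p/r^3", {
  p <- 0.7; r <- 3  # Bohr
  env <- multipole_environment(0, 0, 0, q = 0,
                               dipole = matrix(c(0, 0, p), 1))
  fm <- field_at_points(env, matrix(c(0, 0, r * b2a), 1))
  expect_equal(fm$Ez, 2 * p / r^3, tolerance = 1e-12)
  expect_equal(c(fm$Ex, fm$Ey), c(0, 0), tolerance = 1e-14)
})

test_that("field equals minus the gradient of the summed potential", {
  set.seed(5)
  env <- multipole_environment(
    x = rnorm(20, sd = 2) + 8, y = rnorm(20, sd = 2), z = rnorm(20, sd = 2),
    q = runif(20, -1, 1),
    dipole = matrix(rnorm(60, sd = 0.3), 20),
    quadrupole = {
      qq <- matrix(rnorm(120, sd = 0.2), 20)
      qq[, 6] <- -(qq[, 1] + qq[, 4])   # traceless
      qq
    })
  pts <- matrix(rnorm(9), 3)
  fm <- field_at_points(env, pts)
  h <- 1e-5  # Angstrom step
  for (i in 1:3) {
    grad <- vapply(1:3, function(k) {
      e <- diag(3)[k, ] * h
      dphi <- potential_at_points(env, pts[i, , drop = FALSE] + e) -
        potential_at_points(env, pts[i, , drop = FALSE] - e)
      -dphi / (2 * h / b2a)             # au field (per Bohr)
    }, 0)
    expect_rel_equal(as.numeric(fm[i, c("Ex", "Ey", "Ez")]) + 1e-12,
                     grad + 1e-12, 1e-6)
  }
})

test_that("coincident point and site is an error naming the pair", {
  env <- multipole_environment(1, 2, 3, q = 1)
  expect_error(field_at_points(env, matrix(c(1, 2, 3), 1)), "site 1")
})

test_that("field is additive over environments and rotationally covariant", {
  e1 <- random_charge_environment(10, seed = 21)
  e2 <- random_charge_environment(10, seed = 22)
  both <- multipole_environment(c(e1$x, e2$x), c(e1$y, e2$y), c(e1$z, e2$z),
                                q = c(e1$q, e2$q))
  pts <- matrix(rnorm(6, sd = 0.5), 2)
  f1 <- field_at_points(e1, pts); f2 <- field_at_points(e2, pts)
  fb <- field_at_points(both, pts)
  expect_equal(as.matrix(fb[, 4:6]), as.matrix(f1[, 4:6]) + as.matrix(f2[, 4:6]),
               tolerance = 1e-12)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot_env <- multipole_environment(
    t(R %*% t(as.matrix(e1[, 1:3])))[, 1],
    t(R %*% t(as.matrix(e1[, 1:3])))[, 2],
    t(R %*% t(as.matrix(e1[, 1:3])))[, 3], q = e1$q)
  f_rot <- field_at_points(rot_env, pts %*% t(R))
  expect_lt(max(abs(as.matrix(f_rot[, 4:6]) - as.matrix(f1[, 4:6]) %*% t(R))),
            1e-10)
})

test_that("charge-only field reproduces a brute-force Coulomb sum exactly", {
  env <- random_charge_environment(15, seed = 9)
  pts <- matrix(rnorm(9, sd = 0.4), 3)
  fm <- field_at_points(env, pts)
  S <- as.matrix(env[, 1:3]) / b2a
  for (i in 1:3) {
    E <- c(0, 0, 0)
    for (j in seq_len(nrow(env))) {
      R <- pts[i, ] / b2a - S[j, ]
      E <- E + env$q[j] * R / sum(R^2)^1.5
    }
    expect_equal(as.numeric(fm[i, c("Ex", "Ey", "Ez")]), unname(E),
                 tolerance = 1e-14)
  }
})

test_that("induced dipoles: zero alpha no-op, single-site alpha*E, two-site closed form", {
  env0 <- random_charge_environment(5, seed = 2)
  out0 <- induce_dipoles(env0)
  expect_equal(as.matrix(out0[, c("dx", "dy", "dz")]),
               as.matrix(env0[, c("dx", "dy", "dz")]))

  # one isotropic polarizable site in the field of one distant charge
  alpha <- 3
  d_bohr <- 10
  env1 <- multipole_environment(
    x = c(0, d_bohr * b2a), y = c(0, 0), z = c(0, 0), q = c(1, 0),
    polarizability = rbind(rep(0, 6), c(alpha, 0, 0, alpha, 0, alpha)))
  out1 <- induce_dipoles(env1, tol = 1e-14)
  expect_equal(out1$dx[2], alpha * 1 / d_bohr^2, tolerance = 1e-10)

  # two isotropic sites on an axis, one external charge: analytic 2x2 solve
  a1 <- 2; a2 <- 1.5; r12 <- 6  # Bohr between polarizable sites
  qpos <- -8                    # charge on the same axis
  env2 <- multipole_environment(
    x = c(qpos, 0, r12) * b2a, y = c(0, 0, 0), z = c(0, 0, 0),
    q = c(1, 0, 0),
    polarizability = rbind(rep(0, 6),
                           c(a1, 0, 0, a1, 0, a1),
                           c(a2, 0, 0, a2, 0, a2)))
  out2 <- induce_dipoles(env2, tol = 1e-14)
  # axial external fields at the two sites, axial dipole coupling T = 2/r^3
  E1 <- 1 / (0 - qpos)^2; E2 <- 1 / (r12 - qpos)^2
  T12 <- 2 / r12^3
  # mu1 = a1 (E1 + T mu2); mu2 = a2 (E2 + T mu1): linear 2x2 system
  A <- matrix(c(1, -a1 * T12, -a2 * T12, 1), 2, byrow = TRUE)
  mu <- solve(A, c(a1 * E1, a2 * E2))
  expect_equal(c(out2$dx[2], out2$dx[3]), mu, tolerance = 1e-8)

  # polarization catastrophe reports non-convergence
  env_bad <- multipole_environment(
    x = c(0, 1 * b2a), y = c(0, 0), z = c(0, 0), q = c(1, 0),
    polarizability = rbind(c(50, 0, 0, 50, 0, 50), c(50, 0, 0, 50, 0, 50)))
  expect_error(induce_dipoles(env_bad, max_iter = 30), "converge")
})

test_that("field difference: worked 0.02 au example, antisymmetry, mismatch error", {
  mol <- seventeen_atom_molecule()
  pts <- as.matrix(mol[, c("x", "y", "z")])
  mk_uniform <- function(E) {
    fm <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         Ex = E, Ey = 0, Ez = 0)
    class(fm) <- c("vibrolf_field_map", class(fm))
    fm
  }
  plus <- mk_uniform(0.01); minus <- mk_uniform(-0.01)
  d <- field_difference(plus, minus)
  expect_equal(attr(d, "mean_magnitude"), 0.02, tolerance = 1e-12)

  d0 <- field_difference(plus, plus)
  expect_equal(max(abs(as.matrix(d0[, 4:6]))), 0)

  dswap <- field_difference(minus, plus)
  expect_equal(as.matrix(dswap[, 4:6]), -as.matrix(d[, 4:6]))

  other <- mk_uniform(0.01); other$x <- other$x + 1
  expect_error(field_difference(plus, other), "same evaluation points")
})

test_that("mean field at center: uniform field, symmetric cancellation, Taylor bound", {
  mol2 <- molecule(c("H", "H"), x = c(-1, 1), y = c(0, 0), z = c(0, 0))
  fm <- tibble::tibble(x = c(-1, 1), y = 0, z = 0, Ex = c(0.5, -0.5),
                       Ey = 0, Ez = 0)
  res <- mean_field_at_center(fm, mol2)
  expect_equal(res$magnitude, 0)

  fmu <- tibble::tibble(x = c(-1, 1), y = 0, z = 0, Ex = 0.3, Ey = 0.1, Ez = 0)
  res_u <- mean_field_at_center(fmu, mol2)
  expect_equal(res_u$field, c(0.3, 0.1, 0))

  # point-charge field: mass-weighted atomic average vs direct evaluation at
  # the COM agrees within the field's second-order Taylor remainder
  env <- multipole_environment(30, 0, 0, q = 1)
  mol3 <- seventeen_atom_molecule(seed = 4)
  fm3 <- field_at_points(env, mol3)
  avg <- mean_field_at_center(fm3, mol3)
  com <- drop(crossprod(as.matrix(mol3[, c("x", "y", "z")]), mol3$mass)) /
    sum(mol3$mass)
  direct <- field_at_points(env, matrix(com, 1))
  # remainder bound: max |second derivative of E| * spread^2; E ~ 1/r^2 so
  # |E''| ~ 6/r^4 per Bohr
  spread2 <- max(rowSums(sweep(as.matrix(mol3[, c("x", "y", "z")]), 2, com)^2)) /
    b2a^2
  rmin <- min(sqrt(rowSums(sweep(as.matrix(mol3[, c("x", "y", "z")]), 2,
                                 c(30, 0, 0))^2))) / b2a
  bound <- 12 / rmin^4 * spread2
  expect_lt(sqrt(sum((avg$field - as.numeric(direct[1, 4:6]))^2)), bound)
})
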