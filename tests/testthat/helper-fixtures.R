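# shared fixtures built in code; no binary files

# water-like bent triatomic XYZ text
water_xyz_lines <- function() {
  c("3", "bent triatomic",
    "O 0.000000 0.000000 0.000000",
    "H 0.757000 0.586000 0.000000",
    "H -0.757000 0.586000 0.000000")
}

# a 17-atom nonlinear molecule standing in for a C8H8O odorant: random
# (seeded) coordinates, correct stoichiometry
seventeen_atom_molecule <- function(seed = 42) {
  set.seed(seed)
  el <- c(rep("C", 8), rep("H", 8), "O")
  molecule(el, x = rnorm(17, sd = 2), y = rnorm(17, sd = 2),
           z = rnorm(17, sd = 2))
}

# dense synthetic positive-definite internal Hessian for a molecule: random
# symmetric PSD matrix projected onto the internal subspace so that all
# 3N-6 internal curvatures are positive
synthetic_internal_hessian <- function(mol, seed = 7, scale = 0.3) {
  set.seed(seed)
  n3 <- 3 * nrow(mol)
  A <- matrix(rnorm(n3 * n3, sd = scale), n3)
  H <- crossprod(A) / n3 + diag(n3) * 0.05
  m <- rep(mol$mass, each = 3) * vibrolf_constants$amu_to_me
  P <- vibrolf:::.internal_projector(mol)
  # build in mass-weighted space then unweight, so TR modes are exactly zero
  Hmw <- P %*% H %*% P
  hessian_data(sqrt(outer(m, m)) * Hmw, mol)
}

# random point-charge environment away from the origin region
random_charge_environment <- function(n = 20, seed = 3, offset = 6) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * n, sd = 2), n)
  pos <- pos + sign(pos) * offset
  multipole_environment(pos[, 1], pos[, 2], pos[, 3], q = runif(n, -1, 1))
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
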