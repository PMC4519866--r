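test_that("overlap matrix has unit diagonal and vanishes at long range", {
  m <- reference_molecules()$methane
  S <- overlap_matrix(m)
  expect_equal(diag(S), rep(1, 8))
  expect_equal(S, t(S))

  far <- som_molecule(data.frame(element = c("H", "H"), x = c(0, 50),
                                 y = 0, z = 0), NULL, "far H2",
                      check_hydrogens = FALSE)
  expect_lt(abs(overlap_matrix(far)[1, 2]), 1e-12)
})

test_that("analytic overlaps agree with numerical quadrature and closed forms", {
  # two H 1s (zeta 1.2) at 1.0 A: closed form and grid oracle
  R <- 1.0 * ang2bohr
  mine <- somcyp:::sto_overlap_local("ss", 1, 1.2, 1, 1.2, R)
  expect_equal(mine, overlap_1s1s_exact(1.2, R), tolerance = 1e-12)
  expect_equal(mine, grid_overlap_ss(1, 1.2, 1, 1.2, R), tolerance = 1e-6)
  # mixed principal quantum numbers (H 1s vs C 2s) against the grid
  R2 <- 1.09 * ang2bohr
  expect_equal(somcyp:::sto_overlap_local("ss", 1, 1.2, 2, 1.625, R2),
               grid_overlap_ss(1, 1.2, 2, 1.625, R2), tolerance = 1e-6)
})

test_that("two-centre Coulomb integrals match the 1s closed form", {
  expect_equal(somcyp:::sto_gamma(1, 1.2, 1, 1.2, 0), 5 * 1.2 / 8,
               tolerance = 1e-9)
  for (R in c(0.5, 1.5, 3, 8))
    expect_equal(somcyp:::sto_gamma(1, 1.2, 1, 1.2, R),
                 gamma_1s1s_exact(1.2, R), tolerance = 1e-8)
})

test_that("the hydrogen atom reproduces the one-orbital closed form", {
  h <- som_molecule(data.frame(element = "H", x = 0, y = 0, z = 0),
                    name = "H", check_hydrogens = FALSE)
  r <- scf_energy(h, multiplicity = 2)
  expect_equal(r$energy, h_atom_energy_exact(), tolerance = 1e-8)
  expect_equal(hydrogen_atom_energy(), h_atom_energy_exact(), tolerance = 1e-8)
})

test_that("H2 matches an independent brute-force SCF oracle", {
  h2 <- som_molecule(data.frame(element = c("H", "H"), x = 0, y = 0,
                                z = c(0, 0.746)),
                     data.frame(i = 1, j = 2, order = 1), "H2")
  r <- scf_energy(h2, tol = 1e-10)
  expect_equal(r$energy, h2_energy_oracle(0.746), tolerance = 1e-8)
})

test_that("energies are invariant under rotation and translation", {
  mols <- reference_molecules()
  set.seed(19)
  for (nm in c("methane", "trimethylamine")) {
    m <- mols[[nm]]
    e0 <- scf_energy(m)$energy
    for (rep in 1:2) {
      m2 <- apply_rigid(m, random_rotation(), stats::rnorm(3, sd = 5))
      expect_lt(abs(scf_energy(m2)$energy - e0), 1e-8)
    }
  }
})

test_that("the density trace equals the electron count at convergence", {
  mols <- reference_molecules()
  cases <- list(list(m = mols$methane, mult = 1L),
                list(m = mols$cyclohexanone, mult = 1L),
                list(m = somcyp:::delete_hydrogen(mols$methane, 2L),
                     mult = 2L))
  expect_equal(scf_energy(mols$methane)$nelec, 8L)   # 4 + 4x1 valence
  for (cs in cases) {
    r <- scf_energy(cs$m, multiplicity = cs$mult)
    expect_true(r$converged)
    expect_lt(abs(r$density_trace - r$nelec), 1e-8)
  }
})

test_that("the vectorized Fock build equals a naive loop reference", {
  params <- cndo_parameters()
  small <- list(
    som_molecule(data.frame(element = c("O", "H", "H"),
                            x = c(0, 0.76, -0.76), y = c(0, 0.59, 0.59),
                            z = 0), data.frame(i = 1, j = 2:3, order = 1),
                 "water", check_hydrogens = FALSE),
    som_molecule(data.frame(element = c("N", "H", "H", "H"),
                            x = c(0, 0.94, -0.47, -0.47),
                            y = c(0, 0, 0.81, -0.81),
                            z = c(0, 0.38, 0.38, 0.38)),
                 data.frame(i = 1, j = 2:4, order = 1), "ammonia",
                 check_hydrogens = FALSE))
  set.seed(5)
  for (m in small) {
    basis <- somcyp:::cndo_basis(m, params)
    mats <- somcyp:::cndo_matrices(m, params, basis)
    H <- somcyp:::cndo_core_hamiltonian(m, params, basis, mats)
    # symmetric pseudo-density exercises every term
    A <- matrix(stats::rnorm(basis$norb^2, sd = 0.3), basis$norb)
    P <- (A + t(A)) / 2 + diag(basis$norb)
    F_fast <- somcyp:::cndo_fock_rhf(P, H, basis, mats$gamma)
    F_ref <- naive_fock_rhf(P, m, params)
    expect_lt(max(abs(F_fast - F_ref)), 1e-10)
  }
})

test_that("electron-count / multiplicity inconsistencies are rejected", {
  m <- reference_molecules()$methane
  expect_error(scf_energy(m, multiplicity = 2), "inconsistent")
  rad <- somcyp:::delete_hydrogen(m, 2L)
  expect_error(scf_energy(rad, multiplicity = 1), "inconsistent")
  xe <- som_molecule(data.frame(element = "Xe", x = 0, y = 0, z = 0),
                     NULL, "Xe", check_hydrogens = FALSE)
  expect_error(scf_energy(xe), "parameters")
})
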