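# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by different routes than the
# package (closed forms, explicit loops, brute-force enumeration).

ang2bohr <- 1 / 0.52917721067
ev2hartree <- 1 / 27.211386245988

# closed-form 1s-1s overlap and Coulomb integral for equal exponents (bohr)
overlap_1s1s_exact <- function(zeta, R) {
  w <- zeta * R
  exp(-w) * (1 + w + w^2 / 3)
}
gamma_1s1s_exact <- function(zeta, R) {
  if (R < 1e-12) return(5 * zeta / 8)
  1 / R - exp(-2 * zeta * R) *
    (1 / R + 11 * zeta / 8 + 3 * zeta^2 * R / 4 + zeta^3 * R^2 / 6)
}

# one-orbital hydrogen-atom energy implied directly by the parameter table
h_atom_energy_exact <- function() {
  -7.176 * ev2hartree - 0.5 * (5 * 1.2 / 8)
}

# brute-force minimal SCF for H2 built only from the closed forms above,
# with explicit scalar loops: completely independent of the package path
h2_energy_oracle <- function(R_angstrom, tol = 1e-12) {
  zeta <- 1.2
  R <- R_angstrom * ang2bohr
  S12 <- overlap_1s1s_exact(zeta, R)
  gAA <- gamma_1s1s_exact(zeta, 0)
  gAB <- gamma_1s1s_exact(zeta, R)
  U <- -7.176 * ev2hartree - (1 - 0.5) * gAA
  H <- matrix(0, 2, 2)
  H[1, 1] <- U - 1 * gAB
  H[2, 2] <- U - 1 * gAB
  H[1, 2] <- H[2, 1] <- -9 * ev2hartree * S12
  P <- diag(2)
  for (it in 1:500) {
    F <- matrix(0, 2, 2)
    for (mu in 1:2) for (nu in 1:2) {
      g_mn <- if (mu == nu) gAA else gAB
      F[mu, nu] <- H[mu, nu] - 0.5 * P[mu, nu] * g_mn
      if (mu == nu)
        for (B in 1:2) F[mu, nu] <- F[mu, nu] +
            P[B, B] * (if (B == mu) gAA else gAB)
    }
    e <- eigen(F, symmetric = TRUE)
    c1 <- e$vectors[, which.min(e$values)]
    Pn <- 2 * tcrossprod(c1)
    if (max(abs(Pn - P)) < tol) { P <- Pn; break }
    P <- Pn
  }
  F <- matrix(0, 2, 2)
  for (mu in 1:2) for (nu in 1:2) {
    g_mn <- if (mu == nu) gAA else gAB
    F[mu, nu] <- H[mu, nu] - 0.5 * P[mu, nu] * g_mn
    if (mu == nu)
      for (B in 1:2) F[mu, nu] <- F[mu, nu] +
          P[B, B] * (if (B == mu) gAA else gAB)
  }
  0.5 * sum(P * (H + F)) + 1 / R
}

# naive CNDO closed-shell Fock build with explicit loops over orbitals/atoms
naive_fock_rhf <- function(P, m, params = cndo_parameters()) {
  basis <- somcyp:::cndo_basis(m, params)
  mats <- somcyp:::cndo_matrices(m, params, basis)
  H <- somcyp:::cndo_core_hamiltonian(m, params, basis, mats)
  gam <- mats$gamma
  n <- basis$norb
  F <- matrix(0, n, n)
  for (mu in seq_len(n)) for (nu in seq_len(n)) {
    A <- basis$atom[mu]; B <- basis$atom[nu]
    if (mu == nu) {
      PAA <- 0
      for (lam in seq_len(n)) if (basis$atom[lam] == A) PAA <- PAA + P[lam, lam]
      F[mu, mu] <- H[mu, mu] + (PAA - 0.5 * P[mu, mu]) * gam[A, A]
      for (C in seq_len(somcyp::n_atoms(m))) {
        if (C == A) next
        PCC <- 0
        for (lam in seq_len(n)) if (basis$atom[lam] == C) PCC <- PCC + P[lam, lam]
        F[mu, mu] <- F[mu, mu] + PCC * gam[A, C]
      }
    } else {
      F[mu, nu] <- H[mu, nu] - 0.5 * P[mu, nu] * gam[A, B]
    }
  }
  F
}

# numerical overlap of two STOs by 2D Gauss-Legendre quadrature in
# cylindrical coordinates (axially symmetric s-s case)
grid_overlap_ss <- function(n1, z1, n2, z2, R_bohr,
                            nrho = 400L, nz = 600L) {
  glr <- somcyp:::gauss_legendre_01(nrho)
  glz <- somcyp:::gauss_legendre_01(nz)
  rho_max <- 14; z_lo <- -12; z_hi <- R_bohr + 12
  rho <- glr$x * rho_max; wr <- glr$w * rho_max
  zz <- z_lo + glz$x * (z_hi - z_lo); wz <- glz$w * (z_hi - z_lo)
  N1 <- somcyp:::sto_radial_norm(n1, z1) / sqrt(4 * pi)
  N2 <- somcyp:::sto_radial_norm(n2, z2) / sqrt(4 * pi)
  acc <- 0
  for (iz in seq_along(zz)) {
    r1 <- sqrt(rho^2 + zz[iz]^2)
    r2 <- sqrt(rho^2 + (zz[iz] - R_bohr)^2)
    f <- N1 * r1^(n1 - 1) * exp(-z1 * r1) * N2 * r2^(n2 - 1) * exp(-z2 * r2)
    acc <- acc + wz[iz] * sum(wr * rho * f)
  }
  2 * pi * acc
}

# brute-force qualified-site enumeration over (site x pose) pairs
brute_force_qualify <- function(sites, poses, site_model, config) {
  poses <- poses[seq_len(min(config$poses_kept, length(poses)))]
  keep <- logical(nrow(sites))
  for (r in seq_len(nrow(sites))) {
    for (p in poses) {
      d <- site_heme_distance(p, sites$carbon_index[r], site_model)
      if (d < config$distance_window[1] || d > config$distance_window[2]) next
      if (!config$require_feature) { keep[r] <- TRUE; break }
      hb <- detect_hydrogen_bonds(p, site_model, config$hbond)
      lp <- detect_lipophilic_contacts(p, site_model, config$lipophilic,
                                       heme_carbons = unique(sites$carbon_index))
      if (nrow(hb) > 0L || nrow(lp) > 0L) { keep[r] <- TRUE; break }
    }
  }
  sites[keep, , drop = FALSE]
}

# random rigid rotation (uniform via QR), deterministic under set.seed
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(m, R, t) {
  set_coords(m, coords(m) %*% t(R) + matrix(t, n_atoms(m), 3, byrow = TRUE))
}

# minimal hand-written SDF texts
methane_sdf_text <- function() c(
  "methane", "  test", "",
  "  5  4  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.6294    0.6294    0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.6294   -0.6294    0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.6294    0.6294   -0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.6294   -0.6294   -0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0", "  1  3  1  0  0  0  0",
  "  1  4  1  0  0  0  0", "  1  5  1  0  0  0  0",
  "M  END", "$$$$")

bare_carbon_sdf_text <- function() c(
  "carbon only", "  test", "",
  "  1  0  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "M  END", "$$$$")

propane_mol2_text <- function() {
  m <- reference_molecules()$propane
  a <- m$atoms
  ty <- ifelse(a$element == "C", "C.3", "H")
  c("@<TRIPOS>MOLECULE", "propane",
    sprintf(" %d %d 1 0 0", nrow(a), nrow(m$bonds)),
    "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf(" %2d %s%d %9.4f %9.4f %9.4f %-4s 1 MOL 0.0",
            seq_len(nrow(a)), a$element, seq_len(nrow(a)), a$x, a$y, a$z, ty),
    "@<TRIPOS>BOND",
    sprintf(" %2d %2d %2d 1", seq_len(nrow(m$bonds)), m$bonds$i, m$bonds$j))
}

write_tmp <- function(lines, ext) {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
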