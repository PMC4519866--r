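# CNDO/2 semi-empirical SCF over valence Slater orbitals.
# Closed-shell (RHF-like) for singlets, spin-unrestricted for doublet radicals.

#' CNDO/2 element parameters
#'
#' Pople--Segal CNDO/2 parameterization: valence Slater exponents,
#' electronegativity terms 1/2(I+A) per orbital type (eV), bonding parameters
#' beta0 (eV) and valence core charges, for H, C, N, O, F plus S and Cl in an
#' sp-only third-row extension.  Override entries to experiment with other
#' parameter sets.
#'
#' @return named list keyed by element symbol; each entry has `n` (principal
#'   quantum number), `zeta`, `eneg_s`, `eneg_p` (eV), `beta0` (eV, negative)
#'   and `zcore`.
#' @export
cndo_parameters <- function() {
  list(
    H  = list(n = 1L, zeta = 1.2,    eneg_s = 7.176,  eneg_p = NA,     beta0 = -9,      zcore = 1),
    C  = list(n = 2L, zeta = 1.625,  eneg_s = 14.051, eneg_p = 5.572,  beta0 = -21,     zcore = 4),
    N  = list(n = 2L, zeta = 1.950,  eneg_s = 19.316, eneg_p = 7.275,  beta0 = -25,     zcore = 5),
    O  = list(n = 2L, zeta = 2.275,  eneg_s = 25.390, eneg_p = 9.111,  beta0 = -31,     zcore = 6),
    F  = list(n = 2L, zeta = 2.600,  eneg_s = 32.272, eneg_p = 11.080, beta0 = -39,     zcore = 7),
    S  = list(n = 3L, zeta = 1.8167, eneg_s = 17.650, eneg_p = 6.989,  beta0 = -18.150, zcore = 6),
    Cl = list(n = 3L, zeta = 2.0333, eneg_s = 21.591, eneg_p = 8.708,  beta0 = -22.330, zcore = 7)
  )
}

# orbital table for a molecule: one s orbital for H, s+3p otherwise
cndo_basis <- function(m, params) {
  el <- m$atoms$element
  bad <- setdiff(unique(el), names(params))
  if (length(bad) > 0L)
    stop("no CNDO parameters for element(s): ", paste(bad, collapse = ", "))
  atom <- integer(0); type <- character(0)
  for (i in seq_along(el)) {
    tt <- if (el[i] == "H") "s" else c("s", "px", "py", "pz")
    atom <- c(atom, rep(i, length(tt)))
    type <- c(type, tt)
  }
  list(atom = atom, type = type, norb = length(atom))
}

# pairwise matrices: overlap S (norb x norb), gamma (natom x natom), R (bohr)
cndo_matrices <- function(m, params, basis) {
  xyz <- coords(m) * ANG2BOHR
  el <- m$atoms$element
  n <- nrow(xyz)
  Rm <- as.matrix(stats::dist(xyz))
  gam <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    pi_ <- params[[el[i]]]; pj <- params[[el[j]]]
    gam[i, j] <- gam[j, i] <-
      sto_gamma(pi_$n, pi_$zeta, pj$n, pj$zeta, Rm[i, j])
  }
  S <- diag(basis$norb)
  orb_of_atom <- split(seq_len(basis$norb), basis$atom)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    pi_ <- params[[el[i]]]; pj <- params[[el[j]]]
    u <- (xyz[j, ] - xyz[i, ]) / Rm[i, j]
    blk <- sto_overlap_block(pi_$n, pi_$zeta, pi_$zeta,
                             pj$n, pj$zeta, pj$zeta, u, Rm[i, j])
    oi <- orb_of_atom[[i]]; oj <- orb_of_atom[[j]]
    S[oi, oj] <- blk[seq_along(oi), seq_along(oj)]
    S[oj, oi] <- t(S[oi, oj, drop = FALSE])
  }
  list(S = S, gamma = gam, R = Rm, orb_of_atom = orb_of_atom)
}

# core Hamiltonian (hartree)
cndo_core_hamiltonian <- function(m, params, basis, mats) {
  el <- m$atoms$element
  n <- n_atoms(m)
  zc <- unname(vapply(el, function(e) params[[e]]$zcore, numeric(1)))
  U <- numeric(basis$norb)
  for (mu in seq_len(basis$norb)) {
    a <- basis$atom[mu]
    p <- params[[el[a]]]
    eneg <- if (basis$type[mu] == "s") p$eneg_s else p$eneg_p
    U[mu] <- -eneg * EV2HARTREE - (p$zcore - 0.5) * mats$gamma[a, a]
  }
  H <- matrix(0, basis$norb, basis$norb)
  # off-diagonal: beta_AB * S (zero within an atom since S block is identity)
  beta_atom <- unname(vapply(el, function(e) params[[e]]$beta0, numeric(1))) * EV2HARTREE
  beta_orb <- beta_atom[basis$atom]
  Bmat <- outer(beta_orb, beta_orb, function(a, b) (a + b) / 2)
  H <- Bmat * mats$S
  same_atom <- outer(basis$atom, basis$atom, "==")
  H[same_atom] <- 0
  diag(H) <- U
  for (mu in seq_len(basis$norb)) {
    a <- basis$atom[mu]
    other <- setdiff(seq_len(n), a)
    if (length(other) > 0L)
      H[mu, mu] <- H[mu, mu] - sum(zc[other] * mats$gamma[a, other])
  }
  H
}

# gamma expanded to orbital resolution
gamma_orb <- function(basis, gam) gam[basis$atom, basis$atom, drop = FALSE]

# closed-shell Fock matrix from total density P
cndo_fock_rhf <- function(P, H, basis, gam) {
  Gorb <- gamma_orb(basis, gam)
  Patom <- as.numeric(rowsum(diag(P), basis$atom))
  coulomb <- as.numeric(gam %*% Patom)[basis$atom]
  F <- H - 0.5 * P * Gorb
  diag(F) <- diag(F) + coulomb
  F
}

# spin Fock matrix: total density P, same-spin density Ps
cndo_fock_uhf <- function(P, Ps, H, basis, gam) {
  Gorb <- gamma_orb(basis, gam)
  Patom <- as.numeric(rowsum(diag(P), basis$atom))
  coulomb <- as.numeric(gam %*% Patom)[basis$atom]
  F <- H - Ps * Gorb
  diag(F) <- diag(F) + coulomb
  F
}

# eigen(symmetric = TRUE) orders eigenvalues decreasingly; occupy the lowest
density_from_mos <- function(e, nocc) {
  norb <- nrow(e$vectors)
  if (nocc == 0L) return(matrix(0, norb, norb))
  Cocc <- e$vectors[, order(e$values)[seq_len(nocc)], drop = FALSE]
  tcrossprod(Cocc)
}

#' Single-point CNDO/2 SCF energy
#'
#' Self-consistent field in the CNDO/2 approximation.  Closed-shell
#' (`multiplicity = 1`) uses a spin-restricted build; doublet radicals
#' (`multiplicity = 2`) a spin-unrestricted one.  Convergence is on the
#' maximum absolute density-matrix change, with simple linear damping.
#' The calculation is a single point at the supplied geometry.
#'
#' @param m a `som_molecule` (explicit hydrogens; supported elements
#'   H, C, N, O, F, S, Cl)
#' @param charge total molecular charge
#' @param multiplicity 1 (closed shell) or 2 (one unpaired electron)
#' @param params parameter list from [cndo_parameters()]
#' @param tol convergence threshold on max |Delta P| (default 1e-6)
#' @param max_iter iteration cap (default 200)
#' @param damping fraction of the previous density retained each step
#'   (default 0.4)
#' @return a `cndo_scf` object: `energy` (total, hartree), `electronic`,
#'   `core_repulsion`, `iterations`, `converged`, `density_trace`, `nelec`,
#'   `norb`, `orbital_energies` (hartree; list with alpha/beta for UHF).
#' @export
scf_energy <- function(m, charge = 0L, multiplicity = 1L,
                       params = cndo_parameters(),
                       tol = 1e-6, max_iter = 200L, damping = 0.4) {
  stopifnot(multiplicity %in% c(1L, 2L))
  basis <- cndo_basis(m, params)
  el <- m$atoms$element
  zc <- unname(vapply(el, function(e) params[[e]]$zcore, numeric(1)))
  nelec <- sum(zc) - charge
  if (nelec < 1 || nelec != round(nelec))
    stop("invalid electron count ", nelec)
  nelec <- as.integer(round(nelec))
  if (multiplicity == 1L && nelec %% 2L != 0L)
    stop("odd electron count (", nelec, ") is inconsistent with multiplicity 1")
  if (multiplicity == 2L && nelec %% 2L != 1L)
    stop("even electron count (", nelec, ") is inconsistent with multiplicity 2")

  mats <- cndo_matrices(m, params, basis)
  H <- cndo_core_hamiltonian(m, params, basis, mats)
  gam <- mats$gamma
  n <- n_atoms(m)
  Ecore <- 0
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    Ecore <- Ecore + zc[i] * zc[j] / mats$R[i, j]

  # initial guess: neutral-atom diagonal density
  norb_per_atom <- lengths(mats$orb_of_atom)
  P0 <- diag(rep(zc / norb_per_atom, times = norb_per_atom),
             basis$norb, basis$norb)

  open_shell <- multiplicity == 2L
  if (!open_shell) {
    nocc <- nelec %/% 2L
    P <- P0
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      F <- cndo_fock_rhf(P, H, basis, gam)
      e <- eigen(F, symmetric = TRUE)
      Pnew <- 2 * density_from_mos(e, nocc)
      dmax <- max(abs(Pnew - P))
      P <- (1 - damping) * Pnew + damping * P
      if (dmax <= tol) { converged <- TRUE; P <- Pnew; break }
      if (iter >= max_iter) break
    }
    F <- cndo_fock_rhf(P, H, basis, gam)
    Eel <- 0.5 * sum(P * (H + F))
    res <- list(energy = Eel + Ecore, electronic = Eel, core_repulsion = Ecore,
                iterations = iter, converged = converged,
                density_trace = sum(diag(P)), nelec = nelec, norb = basis$norb,
                multiplicity = 1L,
                orbital_energies = eigen(F, symmetric = TRUE)$values)
  } else {
    na_ <- (nelec + 1L) %/% 2L
    nb_ <- nelec - na_
    Pa <- P0 * (na_ / nelec); Pb <- P0 * (nb_ / nelec)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      P <- Pa + Pb
      Fa <- cndo_fock_uhf(P, Pa, H, basis, gam)
      Fb <- cndo_fock_uhf(P, Pb, H, basis, gam)
      ea <- eigen(Fa, symmetric = TRUE)
      eb <- eigen(Fb, symmetric = TRUE)
      Pa_new <- density_from_mos(ea, na_)
      Pb_new <- density_from_mos(eb, nb_)
      dmax <- max(abs(Pa_new - Pa), abs(Pb_new - Pb))
      Pa <- (1 - damping) * Pa_new + damping * Pa
      Pb <- (1 - damping) * Pb_new + damping * Pb
      if (dmax <= tol) { converged <- TRUE; Pa <- Pa_new; Pb <- Pb_new; break }
      if (iter >= max_iter) break
    }
    P <- Pa + Pb
    Fa <- cndo_fock_uhf(P, Pa, H, basis, gam)
    Fb <- cndo_fock_uhf(P, Pb, H, basis, gam)
    Eel <- 0.5 * (sum(P * H) + sum(Pa * Fa) + sum(Pb * Fb))
    res <- list(energy = Eel + Ecore, electronic = Eel, core_repulsion = Ecore,
                iterations = iter, converged = converged,
                density_trace = sum(diag(P)), nelec = nelec, norb = basis$norb,
                multiplicity = 2L,
                orbital_energies = list(
                  alpha = eigen(Fa, symmetric = TRUE)$values,
                  beta = eigen(Fb, symmetric = TRUE)$values))
  }
  if (!res$converged)
    stop("CNDO SCF for '", m$name, "' did not converge in ", max_iter,
         " iterations (last max|dP| = ", signif(dmax, 3),
         ", last energy = ", signif(res$energy, 10), " hartree)")
  structure(res, class = "cndo_scf")
}

#' @export
print.cndo_scf <- function(x, ...) {
  cat(sprintf(
    "<cndo_scf> E = %.8f hartree (electronic %.8f + core %.8f)\n",
    x$energy, x$electronic, x$core_repulsion))
  cat(sprintf("  %d electrons in %d orbitals, multiplicity %d, %d iterations%s\n",
              x$nelec, x$norb, x$multiplicity, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Overlap matrix over valence orbitals
#'
#' Exposes the analytic Slater s/p overlap matrix the SCF uses: unit diagonal
#' (orthonormal on-centre basis), analytic two-centre s/p overlaps elsewhere.
#'
#' @inheritParams scf_energy
#' @return symmetric matrix, one row/column per valence orbital; attributes
#'   `atom` and `type` give each orbital's atom index and kind.
#' @export
overlap_matrix <- function(m, params = cndo_parameters()) {
  basis <- cndo_basis(m, params)
  mats <- cndo_matrices(m, params, basis)
  structure(mats$S, atom = basis$atom, type = basis$type)
}
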