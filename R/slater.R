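# Analytic integrals over valence Slater-type orbitals (STOs).
# All lengths in bohr, energies in hartree.

ANG2BOHR <- 1 / 0.52917721067
EV2HARTREE <- 1 / 27.211386245988
HARTREE2KCAL <- 627.5094740631

# -- auxiliary functions for prolate-spheroidal overlap ----------------------

# A_k(p) = int_1^Inf xi^k exp(-p xi) dxi, upward recursion
aux_A <- function(kmax, p) {
  A <- numeric(kmax + 1L)
  ep <- exp(-p)
  A[1L] <- ep / p
  for (k in seq_len(kmax)) A[k + 1L] <- (k * A[k] + ep) / p
  A
}

# B_k(q) = int_{-1}^{1} eta^k exp(-q eta) deta; series near q = 0 for stability
aux_B <- function(kmax, q) {
  B <- numeric(kmax + 1L)
  if (abs(q) < 0.5) {
    for (k in 0:kmax) {
      s <- 0
      term <- 1 # (-q)^m / m!
      for (m in 0:40) {
        if ((k + m) %% 2L == 0L) s <- s + term * 2 / (k + m + 1)
        term <- term * (-q) / (m + 1)
        if (abs(term) < 1e-18 && m > 4) break
      }
      B[k + 1L] <- s
    }
  } else {
    epq <- exp(q); emq <- exp(-q)
    B[1L] <- (epq - emq) / q
    for (k in seq_len(kmax)) {
      sgn <- if (k %% 2L == 0L) 1 else -1
      B[k + 1L] <- (k * B[k] + sgn * epq - emq) / q
    }
  }
  B
}

# polynomial in (xi, eta) as coefficient matrix P[i+1, j+1] ~ xi^i eta^j
pmul <- function(P, Q) {
  R <- matrix(0, nrow(P) + nrow(Q) - 1L, ncol(P) + ncol(Q) - 1L)
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] != 0)
      R[i:(i + nrow(Q) - 1L), j:(j + ncol(Q) - 1L)] <-
        R[i:(i + nrow(Q) - 1L), j:(j + ncol(Q) - 1L)] + P[i, j] * Q
  }
  R
}

ppow <- function(P, k) {
  R <- matrix(1, 1, 1)
  for (t in seq_len(k)) R <- pmul(R, P)
  R
}

sto_radial_norm <- function(n, zeta) (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))

# local-frame overlap primitive between STOs on atoms A (origin) and
# B (at +R on the z axis); kind in {"ss","ssigma","sigmas","sigmasigma","pipi"}
# where sigma = p_z along the global +z axis for BOTH centres.
sto_overlap_local <- function(kind, na, za, nb, zb, R) {
  stopifnot(R > 1e-10)
  rho <- R / 2
  r_a <- matrix(0, 2, 2); r_a[2, 1] <- rho; r_a[1, 2] <- rho     # rho*(xi+eta)
  r_b <- matrix(0, 2, 2); r_b[2, 1] <- rho; r_b[1, 2] <- -rho    # rho*(xi-eta)
  z_a <- matrix(0, 2, 2); z_a[1, 1] <- rho; z_a[2, 2] <- rho     # rho*(1+xi eta)
  z_b <- matrix(0, 2, 2); z_b[1, 1] <- -rho; z_b[2, 2] <- rho    # rho*(xi eta-1)
  rho2 <- matrix(0, 3, 3)                                        # cyl radius^2
  rho2[3, 1] <- rho^2; rho2[3, 3] <- -rho^2
  rho2[1, 1] <- -rho^2; rho2[1, 3] <- rho^2
  vol <- matrix(0, 3, 3); vol[3, 1] <- 1; vol[1, 3] <- -1        # xi^2-eta^2

  P <- switch(kind,
    ss         = pmul(ppow(r_a, na - 1L), ppow(r_b, nb - 1L)),
    ssigma     = pmul(ppow(r_a, na - 1L), pmul(ppow(r_b, nb - 2L), z_b)),
    sigmas     = pmul(pmul(ppow(r_a, na - 2L), z_a), ppow(r_b, nb - 1L)),
    sigmasigma = pmul(pmul(ppow(r_a, na - 2L), z_a),
                      pmul(ppow(r_b, nb - 2L), z_b)),
    pipi       = pmul(pmul(ppow(r_a, na - 2L), ppow(r_b, nb - 2L)), rho2),
    stop("unknown overlap kind ", kind))
  P <- pmul(P, vol)

  phifac <- if (kind == "pipi") pi else 2 * pi
  angfac <- switch(kind, ss = 1 / (4 * pi),
                   ssigma = , sigmas = sqrt(3) / (4 * pi),
                   sigmasigma = , pipi = 3 / (4 * pi))
  alpha <- rho * (za + zb)
  beta  <- rho * (za - zb)
  A <- aux_A(nrow(P) - 1L, alpha)
  B <- aux_B(ncol(P) - 1L, beta)
  val <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    if (P[i, j] != 0) val <- val + P[i, j] * A[i] * B[j]
  sto_radial_norm(na, za) * sto_radial_norm(nb, zb) *
    angfac * phifac * (R^3 / 8) * val
}

# 4x4 overlap block (s, px, py, pz on A) x (s, px, py, pz on B), global axes.
# u = unit vector from A to B, R in bohr.  `has_p_*` flags suppress the p
# primitives for hydrogen (only row/column 1 is then meaningful).
sto_overlap_block <- function(na, za_s, za_p, nb, zb_s, zb_p, u, R,
                              has_p_a = na > 1L, has_p_b = nb > 1L) {
  S <- matrix(0, 4, 4)
  S[1, 1] <- sto_overlap_local("ss", na, za_s, nb, zb_s, R)
  s_sig <- if (has_p_b) sto_overlap_local("ssigma", na, za_s, nb, zb_p, R) else 0
  sig_s <- if (has_p_a) sto_overlap_local("sigmas", na, za_p, nb, zb_s, R) else 0
  sig_sig <- if (has_p_a && has_p_b)
    sto_overlap_local("sigmasigma", na, za_p, nb, zb_p, R) else 0
  pi_pi <- if (has_p_a && has_p_b)
    sto_overlap_local("pipi", na, za_p, nb, zb_p, R) else 0
  for (k in 1:3) {
    S[1, 1 + k] <- u[k] * s_sig
    S[1 + k, 1] <- u[k] * sig_s
  }
  for (k in 1:3) for (l in 1:3)
    S[1 + k, 1 + l] <- (if (k == l) pi_pi else 0) + u[k] * u[l] * (sig_sig - pi_pi)
  S
}

# -- two-centre Coulomb integrals over s densities ---------------------------

# electrostatic potential (hartree/e) of a normalised ns STO density at r;
# Q(r) inside-charge, T(r) outer term: V = Q/r + T, all via regularized
# incomplete gammas (pgamma).
sto_s_potential <- function(r, n, zeta) {
  a <- 2 * zeta
  Q <- stats::pgamma(r, shape = 2 * n + 1, rate = a)
  Tt <- (zeta / n) * (1 - stats::pgamma(r, shape = 2 * n, rate = a))
  # r -> 0 limit: Q/r vanishes (Q ~ r^(2n+1)), leaving T(0) = zeta/n
  ifelse(r < 1e-12, zeta / n, Q / r + Tt)
}

# G(x) = int_0^x t V(t) dt, closed form
sto_s_potential_G <- function(x, n, zeta) {
  a <- 2 * zeta
  m <- 2 * n + 1
  intQ <- x * stats::pgamma(x, m, rate = a) -
    (m / a) * stats::pgamma(x, m + 1, rate = a)
  k <- 2 * n
  int_tP <- x^2 / 2 * stats::pgamma(x, k, rate = a) -
    (k * (k + 1) / (2 * a^2)) * stats::pgamma(x, k + 2, rate = a)
  intQ + (zeta / n) * (x^2 / 2 - int_tP)
}

gl_cache <- new.env(parent = emptyenv())

gauss_legendre_01 <- function(npts) {
  key <- as.character(npts)
  if (!is.null(gl_cache[[key]])) return(gl_cache[[key]])
  gl <- pracma::gaussLegendre(npts, 0, 1)
  res <- list(x = gl$x, w = gl$w)
  gl_cache[[key]] <- res
  res
}

# gamma_AB between valence s densities (na, za) and (nb, zb), R in bohr
sto_gamma <- function(na, za, nb, zb, R, npts = 120L) {
  gl <- gauss_legendre_01(npts)
  smax <- (2 * nb + 30) / (2 * zb)
  s <- gl$x * smax
  w <- gl$w * smax
  dens <- stats::dgamma(s, shape = 2 * nb + 1, rate = 2 * zb)
  if (R < 1e-9) {
    V <- sto_s_potential(s, na, za)
  } else {
    V <- (sto_s_potential_G(R + s, na, za) -
          sto_s_potential_G(abs(R - s), na, za)) / (2 * R * s)
  }
  sum(w * dens * V)
}
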