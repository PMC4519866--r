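# Deterministic synthetic fixtures: exact-symmetry small molecules, toy
# active sites and placed pose ensembles.  Everything is a pure function of
# its arguments, so every stage of the pipeline is testable offline.

unit3 <- function(v) v / sqrt(sum(v^2))

# complete a (near-)tetrahedral centre: given existing substituent positions,
# return `n_new` new substituent positions at `blen` from `center`.
# Deterministic: the perpendicular frame is derived from fixed reference axes.
tetra_complete <- function(center, neighbors, n_new, blen = 1.09) {
  k <- length(neighbors)
  us <- lapply(neighbors, function(p) unit3(p - center))
  cosT <- -1 / 3
  sinT <- sqrt(8) / 3
  perp_frame <- function(axis) {
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- unit3(ref - sum(ref * axis) * axis)
    list(e1 = e1, e2 = cross3(axis, e1))
  }
  dirs <- if (k == 1L) {
    u <- us[[1]]
    f <- perp_frame(u)
    lapply((0:2) * 2 * pi / 3, function(phi)
      cosT * u + sinT * (cos(phi) * f$e1 + sin(phi) * f$e2))
  } else if (k == 2L) {
    b <- -unit3(us[[1]] + us[[2]])
    nrm <- unit3(cross3(us[[1]], us[[2]]))
    ch <- 1 / sqrt(3); sh <- sqrt(2 / 3)     # half the tetrahedral angle
    list(ch * b + sh * nrm, ch * b - sh * nrm)
  } else if (k == 3L) {
    list(-unit3(us[[1]] + us[[2]] + us[[3]]))
  } else stop("tetra_complete supports 1-3 existing neighbours")
  if (n_new > length(dirs))
    stop("cannot place ", n_new, " substituents with ", k, " neighbours")
  lapply(dirs[seq_len(n_new)], function(d) center + blen * d)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Reference molecules with embedded geometry
#'
#' A named set of small molecules with explicit hydrogens and deterministic
#' coordinates built from ideal internal coordinates: exact-Td methane,
#' exactly eclipsed ethane, propane, trimethylamine, toluene and
#' cyclohexanone (chair).  Methane and ethane have machine-exact point-group
#' symmetry so that symmetry-equivalent hydrogens give bitwise-comparable
#' abstraction energies.
#'
#' @return named list of `som_molecule`
#' @export
reference_molecules <- function() {
  mols <- list()

  # methane, exact Td: H along the cube diagonals
  d <- 1.09 / sqrt(3)
  mols$methane <- som_molecule(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, d, -d, -d, d), y = c(0, d, -d, d, -d),
               z = c(0, d, d, -d, -d)),
    data.frame(i = 1L, j = 2:5, order = 1), "methane")

  # eclipsed ethane: both methyls at the same dihedral phases
  cc <- 1.536; ch <- 1.09
  cosT <- -1 / 3; sinT <- sqrt(8) / 3
  phis <- (0:2) * 2 * pi / 3
  c1 <- c(0, 0, 0); c2 <- c(0, 0, cc)
  h1 <- t(vapply(phis, function(p)
    c1 + ch * c(sinT * cos(p), sinT * sin(p), cosT), numeric(3)))
  h2 <- t(vapply(phis, function(p)
    c2 + ch * c(sinT * cos(p), sinT * sin(p), -cosT), numeric(3)))
  xyz <- rbind(c1, c2, h1, h2)
  mols$ethane_eclipsed <- som_molecule(
    data.frame(element = c("C", "C", rep("H", 6)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = c(1, 1, 1, 1, 2, 2, 2), j = c(2, 3, 4, 5, 6, 7, 8),
               order = 1), "ethane (eclipsed)")

  # propane: C2 central
  u1 <- c(1, 1, 1) / sqrt(3); u2 <- c(-1, -1, 1) / sqrt(3)
  C2 <- c(0, 0, 0); C1 <- 1.53 * u1; C3 <- 1.53 * u2
  h_c2 <- tetra_complete(C2, list(C1, C3), 2)
  h_c1 <- tetra_complete(C1, list(C2), 3)
  h_c3 <- tetra_complete(C3, list(C2), 3)
  xyz <- do.call(rbind, c(list(C1, C2, C3), h_c1, h_c2, h_c3))
  mols$propane <- som_molecule(
    data.frame(element = c("C", "C", "C", rep("H", 8)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3, 3, 3),
               j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11), order = 1),
    "propane")

  # trimethylamine: N with three methyls on tetrahedral directions
  Nc <- c(0, 0, 0)
  tds <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1))
  Cs <- lapply(tds, function(t) 1.458 * unit3(t))
  Hs <- lapply(Cs, function(C) tetra_complete(C, list(Nc), 3))
  xyz <- do.call(rbind, c(list(Nc), Cs, Hs[[1]], Hs[[2]], Hs[[3]]))
  mols$trimethylamine <- som_molecule(
    data.frame(element = c("N", "C", "C", "C", rep("H", 9)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4),
               j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13), order = 1),
    "trimethylamine")

  # toluene: aromatic ring in the xy-plane + methyl on C1
  rring <- 1.3915
  ang <- (0:5) * pi / 3
  ring <- cbind(rring * cos(ang), rring * sin(ang), 0)
  C7 <- c((rring + 1.51), 0, 0)
  ringH <- cbind((rring + 1.08) * cos(ang[-1]), (rring + 1.08) * sin(ang[-1]), 0)
  metH <- tetra_complete(C7, list(ring[1, ]), 3)
  xyz <- rbind(ring, C7, ringH, do.call(rbind, metH))
  mols$toluene <- som_molecule(
    data.frame(element = c(rep("C", 7), rep("H", 8)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6, 7, 7, 7),
               j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14, 15),
               order = c(rep(4, 6), rep(1, 9))),
    "toluene")

  # cyclohexanone: chair ring, C1 carbonyl
  a <- 1.46; q <- 0.25
  ringc <- t(vapply(0:5, function(k)
    c(a * cos(k * pi / 3), a * sin(k * pi / 3), q * (-1)^k), numeric(3)))
  O <- ringc[1, ] + 1.22 * unit3(ringc[1, ] - (ringc[2, ] + ringc[6, ]) / 2)
  hs <- lapply(2:6, function(k) {
    nb <- list(ringc[ifelse(k == 1, 6, k - 1), ], ringc[ifelse(k == 6, 1, k + 1), ])
    tetra_complete(ringc[k, ], nb, 2)
  })
  xyz <- rbind(ringc, O, do.call(rbind, lapply(hs, function(h) do.call(rbind, h))))
  hidx <- 8:17
  mols$cyclohexanone <- som_molecule(
    data.frame(element = c(rep("C", 6), "O", rep("H", 10)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = c(1, 2, 3, 4, 5, 6, 1, rep(2:6, each = 2)),
               j = c(2, 3, 4, 5, 6, 1, 7, hidx),
               order = c(rep(1, 6), 2, rep(1, 10))),
    "cyclohexanone")

  mols
}

# -- toy active sites --------------------------------------------------------

# residue templates in local coordinates; the anchor atom (first row, or ring
# centroid for PHE) is translated onto the requested position.  Only atoms
# the feature detectors read are guaranteed to be meaningful.
.residue_templates <- list(
  SER = data.frame(
    atom = c("OG", "CB", "CA", "N", "C", "O"),
    x = c(0, 0, 1.2, 1.3, 2.5, 3.5), y = c(0, 0, 0, 1.2, -0.5, 0.1),
    z = c(0, -1.42, -2.2, -3.0, -1.8, -2.1)),
  ARG = data.frame(
    atom = c("NE", "CZ", "NH1", "NH2", "CD", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, 1.33, 2.0, 2.0, -0.8, -2.3, -3.0, -4.5, -5.1, -5.2, -6.4),
    y = c(0, 0, 1.1, -1.1, -1.2, -1.0, -2.3, -2.2, -1.2, -3.5, -3.6),
    z = c(0, 0, 0, 0, 0, 0.2, 0.4, 0.6, 1.4, 0.7, 0.8)),
  ILE = data.frame(
    atom = c("O", "C", "CA", "N", "CB", "CG1", "CG2", "CD1"),
    x = c(0, 0.7, 2.2, 2.8, 2.8, 4.3, 2.2, 4.9),
    y = c(0, 1.0, 1.0, 1.2, -0.3, -0.3, -1.5, -1.6),
    z = c(0, 0, 0, 1.3, -0.6, -0.7, 0.2, -1.2)),
  GLU = data.frame(
    atom = c("OE1", "CD", "OE2", "CG", "CB", "CA", "N", "C", "O"),
    x = c(0, 0.65, 1.9, -0.05, 0.8, 0.0, -0.9, 0.9, 2.1),
    y = c(0, 1.05, 1.1, 2.35, 3.6, 4.9, 5.0, 6.1, 6.0),
    z = c(0, 0, 0, 0, 0.1, 0.2, 1.3, 0.2, 0.1)),
  PHE = local({
    ang <- (0:5) * pi / 3 + pi   # CG at angle pi
    data.frame(
      atom = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CB", "CA", "N", "C", "O"),
      x = c(1.39 * cos(ang[c(1, 2, 6, 3, 5, 4)]), -2.9, -3.6, -3.5, -5.1, -5.7),
      y = c(1.39 * sin(ang[c(1, 2, 6, 3, 5, 4)]), 0, 1.3, 2.2, 1.2, 2.3),
      z = c(rep(0, 6), 0, 0, 1.1, 0, 0))
  }),
  HOH = data.frame(atom = "O", x = 0, y = 0, z = 0)
)

.heme_template <- local({
  ang8 <- (0:7) * pi / 4 + pi / 8
  data.frame(
    atom = c("FE", "NA", "NB", "NC", "ND",
             "CHA", "C1A", "CHB", "C1B", "CHC", "C1C", "CHD", "C1D"),
    x = c(0, 2.0, 0, -2.0, 0, 3.1 * cos(ang8)),
    y = c(0, 0, 2.0, 0, -2.0, 3.1 * sin(ang8)),
    z = rep(0, 13))
})

parse_residue_key <- function(key) {
  mm <- regmatches(key, regexec("^([A-Za-z]{3})[ -]?([0-9]+)$", key))[[1]]
  if (length(mm) != 3L)
    stop("cannot parse residue key '", key, "' (expected e.g. 'Ser119')")
  list(resname = toupper(mm[2]), resno = as.integer(mm[3]))
}

pdb_record <- function(type, serial, atom, resname, chain, resno, pos) {
  elem <- if (atom == "FE") "FE" else substr(atom, 1, 1)
  name_field <- if (nchar(atom) >= 4L) substr(atom, 1, 4) else
    sprintf(" %-3s", atom)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_field, resname, chain, resno,
          pos[1], pos[2], pos[3], 1.00, 0.00, elem)
}

#' Write a minimal synthetic CYP3A4-like active site as PDB
#'
#' Generates a toy complex containing a heme group (FE plus pyrrole nitrogens
#' and ring carbons, anchored at `fe`), the requested protein residues with
#' ideal-geometry side chains (anchored by their key polar atom -- Ser OG,
#' Arg NE, Ile backbone O, Glu OE1 -- or the ring centroid for Phe), and
#' numbered waters.  Output is byte-deterministic; this is a synthetic
#' stand-in for a crystal structure, not a CYP3A4 mimic.
#'
#' @param path output PDB path
#' @param fe 3-vector, heme iron position (required; the generator refuses to
#'   omit it because downstream extraction would fail)
#' @param residues named list, e.g. `list(Ser119 = c(3, 0, 0))`: residue key
#'   -> anchor position
#' @param waters named list, e.g. `list("623" = c(0, 4, 0))`: water residue
#'   number -> oxygen position
#' @param chain chain identifier for protein residues
#' @return `path`, invisibly
#' @export
make_toy_active_site <- function(path, fe, residues = list(),
                                 waters = list(), chain = "A") {
  if (is.null(fe) || length(fe) != 3L || !all(is.finite(fe)))
    stop("a finite 3-vector heme iron position `fe` is required")
  lines <- character(0)
  serial <- 0L
  emit <- function(type, atom, resname, resno, pos) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_record(type, serial, atom, resname, chain, resno, pos))
  }
  keys <- names(residues)
  parsed <- lapply(keys, parse_residue_key)
  ord <- order(vapply(parsed, `[[`, integer(1), "resno"))
  for (k in ord) {
    pr <- parsed[[k]]
    tmpl <- .residue_templates[[pr$resname]]
    if (is.null(tmpl))
      stop("unsupported residue type '", pr$resname, "' in toy site spec")
    anchor <- residues[[keys[k]]]
    if (pr$resname == "PHE") {
      ring <- as.matrix(tmpl[1:6, c("x", "y", "z")])
      shift <- anchor - colMeans(ring)
    } else {
      shift <- anchor - unlist(tmpl[1L, c("x", "y", "z")])
    }
    for (r in seq_len(nrow(tmpl)))
      emit("ATOM", tmpl$atom[r], pr$resname, pr$resno,
           unlist(tmpl[r, c("x", "y", "z")]) + shift)
  }
  for (r in seq_len(nrow(.heme_template)))
    emit("HETATM", .heme_template$atom[r], "HEM", 508L,
         unlist(.heme_template[r, c("x", "y", "z")]) + fe)
  for (wid in names(waters))
    emit("HETATM", "O", "HOH", as.integer(wid), waters[[wid]])
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# -- pose placement ----------------------------------------------------------

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Build a pose ensemble by rigid placement of a substrate
#'
#' Each placement is a rigid transform given either directly
#' (`list(rotation = R, translation = t)`: coordinates become `X R' + t`) or
#' by a target (`list(atom = i, at = c(x, y, z), rotation = R)`: rotate, then
#' translate so atom `i` lands exactly on `at`), or by a site--iron distance
#' (`list(carbon = i, distance = d, direction = u, rotation = R)`: atom `i`
#' lands at `fe + d * u/|u|`).  Non-rigid rotation matrices are refused.
#' Record order defines pose rank; a descending synthetic ChemScore is
#' attached.
#'
#' @param substrate a `som_molecule`
#' @param placements list of placement specs (see above)
#' @param fe heme iron position used by distance placements
#' @param path optional SDF output path (multi-record V2000 with a ChemScore
#'   data field)
#' @return list of `som_pose`, invisibly when `path` is given
#' @export
make_pose_set <- function(substrate, placements, fe = c(0, 0, 0), path = NULL) {
  X <- coords(substrate)
  poses <- vector("list", length(placements))
  for (k in seq_along(placements)) {
    pl <- placements[[k]]
    R <- if (is.null(pl$rotation)) diag(3) else pl$rotation
    if (!is_rotation(R))
      stop("placement ", k, ": `rotation` is not a proper rigid rotation")
    Xr <- X %*% t(R)
    tvec <- if (!is.null(pl$translation)) {
      pl$translation
    } else if (!is.null(pl$atom)) {
      pl$at - Xr[pl$atom, ]
    } else if (!is.null(pl$carbon)) {
      if (substrate$atoms$element[pl$carbon] != "C")
        stop("placement ", k, ": atom ", pl$carbon, " is not a carbon")
      u <- if (is.null(pl$direction)) c(0, 0, 1) else unit3(pl$direction)
      (fe + pl$distance * u) - Xr[pl$carbon, ]
    } else stop("placement ", k, ": give translation, atom/at or carbon/distance")
    mk <- set_coords(substrate, Xr + matrix(tvec, nrow(X), 3, byrow = TRUE))
    mk$name <- paste0(substrate$name, " pose ", k)
    attr(mk, "properties") <- list(ChemScore = sprintf("%.2f", -20 - k))
    poses[[k]] <- structure(list(molecule = mk, rank = k, score = -20 - k),
                            class = "som_pose")
  }
  if (!is.null(path)) {
    write_molecule(lapply(poses, `[[`, "molecule"), path)
    return(invisible(poses))
  }
  poses
}

# -- end-to-end demo ---------------------------------------------------------

#' Deterministic end-to-end demonstration
#'
#' Builds a toy active site and a 10-pose ensemble of cyclohexanone around
#' it, extracts the site model, runs the full predictor and returns the
#' ranked prediction.  Poses 1-6 place ring carbons at catalytically
#' plausible iron distances (4-7 Angstrom) with the carbonyl oxygen near the
#' Ser119 hydroxyl; poses 7-10 drift out of range.  Entirely deterministic:
#' repeated runs produce byte-identical outputs.
#'
#' @param dir directory for intermediate files (default: a tempdir)
#' @param config a [som_config()]
#' @return a `som_prediction`
#' @export
som_demo <- function(dir = tempfile("somdemo"), config = som_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol <- reference_molecules()$cyclohexanone
  fe <- c(0, 0, 0)

  # place the pose ensemble first, then anchor Ser119/water near where the
  # carbonyl oxygen of the first pose lands
  rot_y <- function(th) matrix(c(cos(th), 0, sin(th), 0, 1, 0,
                                 -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  dists <- c(4.0, 4.5, 5.0, 5.5, 6.5, 7.0, 8.5, 9.0, 9.5, 10.0)
  carbons <- c(3, 3, 4, 4, 5, 2, 3, 3, 4, 5)
  placements <- lapply(seq_along(dists), function(k)
    list(carbon = carbons[k], distance = dists[k], direction = c(0, 0, 1),
         rotation = rot_y((k - 1) * 0.1)))
  pose_path <- file.path(dir, "poses.sdf")
  make_pose_set(mol, placements, fe = fe, path = pose_path)
  poses0 <- read_pose_set(pose_path, mol)

  o_pos <- coords(poses0[[1]]$molecule)[7, ]   # carbonyl oxygen, pose 1
  site_path <- file.path(dir, "site.pdb")
  make_toy_active_site(
    site_path, fe = fe,
    residues = list(Ser119 = o_pos + c(0, 2.9, 0),
                    Arg105 = o_pos + c(8, 0, 3),
                    Phe108 = c(0, 0, 11)),
    waters = list("623" = o_pos + c(2.9, 0, 0)))
  site <- extract_active_site(site_path)

  pred <- predict_sites(mol, poses0, site, config = config)
  write_prediction(pred, file.path(dir, "prediction.tsv"))
  pred
}

#' Write a prediction as TSV or JSON
#'
#' @param pred a `som_prediction`
#' @param path output path; format chosen by extension (.json for JSON,
#'   otherwise TSV)
#' @return `path`, invisibly
#' @export
write_prediction <- function(pred, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(substrate = pred$substrate, k = pred$k,
                n_poses = pred$n_poses, sites = pred$sites)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else {
    utils::write.table(pred$sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
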