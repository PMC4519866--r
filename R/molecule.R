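#' Construct a molecule
#'
#' The basic container used throughout the package: a flat atom table, a bond
#' table and a name.  All hydrogens must be explicit -- the reactivity engine
#' abstracts specific hydrogen atoms, so silently adding hydrogens would hide a
#' modelling choice.  Aromatic bonds are stored with `order = 4` (the SDF
#' V2000 convention) and count 1.5 toward valence checks.
#'
#' @param atoms data.frame with columns `element` (character symbol), `x`,
#'   `y`, `z` (numeric, Angstrom) and optionally `charge` (integer formal
#'   charge, default 0).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 4 = aromatic).  May have zero rows.
#' @param name character identifier.
#' @param check_hydrogens if `TRUE` (default), error when any carbon has an
#'   implicit-valence deficit, i.e. its hydrogens cannot all be explicit.
#' @return An object of class `som_molecule`.
#' @export
som_molecule <- function(atoms, bonds = NULL, name = "molecule",
                         check_hydrogens = TRUE) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  atoms <- data.frame(
    element = normalize_element(atoms$element),
    x = as.numeric(atoms$x), y = as.numeric(atoms$y), z = as.numeric(atoms$z),
    charge = if ("charge" %in% names(atoms)) as.integer(atoms$charge) else 0L,
    stringsAsFactors = FALSE
  )
  n <- nrow(atoms)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("molecule '", name, "': non-finite coordinates")
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.numeric(bonds$order))
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("molecule '", name, "': bond references a non-existent atom")
    if (any(bonds$i == bonds$j))
      stop("molecule '", name, "': self-bond")
    if (!all(bonds$order %in% c(1, 2, 3, 4)))
      stop("molecule '", name, "': bond order outside {1,2,3,aromatic(4)}")
  }
  m <- structure(list(atoms = atoms, bonds = bonds, name = name),
                 class = "som_molecule")
  if (check_hydrogens) assert_explicit_hydrogens(m)
  m
}

normalize_element <- function(el) {
  el <- trimws(as.character(el))
  # MOL2 atom types carry hybridisation suffixes (C.3, N.ar, O.2 ...)
  el <- sub("\\..*$", "", el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' @export
print.som_molecule <- function(x, ...) {
  comp <- table(x$atoms$element)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat("<som_molecule> ", x$name, ": ", formula, ", ",
      nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of atoms
#' @param m a `som_molecule`
#' @return integer count
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Coordinates as an n x 3 matrix (Angstrom)
#' @param m a `som_molecule`
#' @return numeric matrix
#' @export
coords <- function(m) as.matrix(m$atoms[, c("x", "y", "z")])

#' Replace coordinates
#' @param m a `som_molecule`
#' @param xyz n x 3 numeric matrix
#' @return the molecule with new coordinates
#' @export
set_coords <- function(m, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == n_atoms(m), ncol(xyz) == 3L)
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m
}

# neighbour index list; aromatic bonds count 1.5 toward valence
adjacency_list <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

valence_sum <- function(m) {
  ord <- ifelse(m$bonds$order == 4, 1.5, m$bonds$order)
  v <- numeric(n_atoms(m))
  for (k in seq_len(nrow(m$bonds))) {
    v[m$bonds$i[k]] <- v[m$bonds$i[k]] + ord[k]
    v[m$bonds$j[k]] <- v[m$bonds$j[k]] + ord[k]
  }
  v
}

assert_explicit_hydrogens <- function(m) {
  carbons <- which(m$atoms$element == "C")
  if (length(carbons) == 0L) return(invisible(m))
  v <- valence_sum(m)
  expected <- 4 - abs(m$atoms$charge[carbons])
  short <- carbons[round(v[carbons] * 2) / 2 < expected]
  if (length(short) > 0L)
    stop("molecule '", m$name, "': carbons ", paste(short, collapse = ", "),
         " have an implicit-valence deficit; hydrogens must be explicit")
  invisible(m)
}

#' Carbons one bond away from an atom
#'
#' @param m a `som_molecule`
#' @param atom_index 1-based atom index
#' @return integer vector of carbon atom indices directly bonded to
#'   `atom_index` (possibly empty), sorted.
#' @export
adjacent_carbons <- function(m, atom_index) {
  atom_index <- as.integer(atom_index)
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > n_atoms(m))
    stop("atom_index ", atom_index, " out of range 1..", n_atoms(m))
  nb <- adjacency_list(m)[[atom_index]]
  nb[m$atoms$element[nb] == "C"]
}

#' Hydrogen equivalence classes
#'
#' Hydrogens attached to the same carbon give the same radical on abstraction,
#' so they form one equivalence class per H-bearing carbon.  Classes are
#' ordered (and `class_id` assigned) by carbon index.  Each class also carries
#' a `symmetry_label`: carbons that are equivalent under iterative
#' Morgan-style neighbourhood refinement share a label, which callers may use
#' to skip duplicate energy evaluations -- the class unit itself remains
#' "hydrogens on one carbon".
#'
#' @param m a `som_molecule` with explicit hydrogens
#' @return list of classes; each a list with `class_id`, `carbon_index`,
#'   `hydrogen_indices`, `symmetry_label`.
#' @export
hydrogen_equivalence_classes <- function(m) {
  adj <- adjacency_list(m)
  el <- m$atoms$element
  sym <- morgan_symmetry_labels(m, adj = adj)
  classes <- list()
  cid <- 0L
  for (c_idx in which(el == "C")) {
    hs <- adj[[c_idx]][el[adj[[c_idx]]] == "H"]
    if (length(hs) == 0L) next
    cid <- cid + 1L
    classes[[cid]] <- list(class_id = cid, carbon_index = c_idx,
                           hydrogen_indices = hs,
                           symmetry_label = sym[c_idx])
  }
  classes
}

#' Graph-symmetry labels by iterative neighbourhood refinement
#'
#' Morgan-style refinement over (element, degree, sorted incident bond
#' orders), iterated with neighbour-label multisets until the partition is
#' stable.  Atoms sharing a label are topologically equivalent (the refinement
#' never splits a true automorphism orbit; on typical acyclic/small-ring
#' molecules it equals the orbit partition).
#'
#' @param m a `som_molecule`
#' @param adj optional precomputed adjacency list
#' @return integer vector of labels, one per atom; labels are dense 1..k in
#'   order of first appearance.
#' @export
morgan_symmetry_labels <- function(m, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_list(m)
  n <- n_atoms(m)
  bond_key <- vapply(seq_len(n), function(i) {
    ords <- sort(c(m$bonds$order[m$bonds$i == i], m$bonds$order[m$bonds$j == i]))
    paste(ords, collapse = ",")
  }, character(1))
  key <- paste(m$atoms$element, lengths(adj), bond_key, sep = "|")
  lab <- match(key, unique(key))
  repeat {
    key2 <- vapply(seq_len(n), function(i) {
      paste(lab[i], paste(sort(lab[adj[[i]]]), collapse = ","), sep = ":")
    }, character(1))
    lab2 <- match(key2, unique(key2))
    if (identical(lab2, lab)) break
    lab <- lab2
  }
  lab
}
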