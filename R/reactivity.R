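# Hydrogen-abstraction reaction energies per hydrogen equivalence class.
#
# dH_rxn = E(radical) + E(H atom) - E(parent), all single-point CNDO/2 total
# energies at the parent geometry (the radical is the parent minus one
# hydrogen, unrelaxed).  E(H atom) is a constant of the engine, so rankings
# depend only on E(radical) - E(parent).

#' Energy of an isolated hydrogen atom under the engine parameters
#'
#' One electron in one orbital: the SCF reduces to the core term, so this is
#' evaluated by the engine itself and doubles as a closed-form check
#' (`-eneg_s(H)/27.2114 - gamma_HH/2` hartree).
#'
#' @param params parameter list from [cndo_parameters()]
#' @return energy in hartree
#' @export
hydrogen_atom_energy <- function(params = cndo_parameters()) {
  h <- som_molecule(data.frame(element = "H", x = 0, y = 0, z = 0),
                    name = "H atom")
  scf_energy(h, multiplicity = 2L, params = params)$energy
}

# parent minus one hydrogen, frozen geometry; bonds to that H dropped
delete_hydrogen <- function(m, h_index) {
  stopifnot(m$atoms$element[h_index] == "H")
  keep <- setdiff(seq_len(n_atoms(m)), h_index)
  remap <- integer(n_atoms(m)); remap[keep] <- seq_along(keep)
  b <- m$bonds[m$bonds$i != h_index & m$bonds$j != h_index, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  som_molecule(m$atoms[keep, , drop = FALSE], b,
               name = paste0(m$name, " radical(-H", h_index, ")"),
               check_hydrogens = FALSE)
}

#' Hydrogen-abstraction reaction energy of one hydrogen class
#'
#' Evaluates every member hydrogen of the class (radical = parent geometry
#' minus that hydrogen, single point, spin-unrestricted doublet) and reports
#' the class value as the minimum over members: the most labile accessible
#' hydrogen governs abstraction.
#'
#' @param m closed-shell parent `som_molecule`
#' @param cls one element of [hydrogen_equivalence_classes()]
#' @param params CNDO parameters
#' @param parent_scf optional precomputed `cndo_scf` of the parent (avoids
#'   recomputation when ranking many classes)
#' @param e_hydrogen optional precomputed [hydrogen_atom_energy()]
#' @param ... further arguments to [scf_energy()] (tol, max_iter, damping)
#' @return a `som_abstraction` object: `class_id`, `carbon_index`,
#'   `delta_h` (hartree), `delta_h_kcal`, `parent_energy`, `radical_energy`
#'   (of the minimal member), `member_delta_h` (named per hydrogen index).
#' @export
abstraction_energy <- function(m, cls, params = cndo_parameters(),
                               parent_scf = NULL, e_hydrogen = NULL, ...) {
  if (is.null(parent_scf)) parent_scf <- scf_energy(m, params = params, ...)
  if (is.null(e_hydrogen)) e_hydrogen <- hydrogen_atom_energy(params)
  member <- vapply(cls$hydrogen_indices, function(h) {
    rad <- delete_hydrogen(m, h)
    sr <- tryCatch(
      scf_energy(rad, multiplicity = 2L, params = params, ...),
      error = function(e) stop("radical SCF failed for H", h, " of '",
                               m$name, "': ", conditionMessage(e)))
    sr$energy
  }, numeric(1))
  names(member) <- as.character(cls$hydrogen_indices)
  dh_members <- member + e_hydrogen - parent_scf$energy
  best <- which.min(dh_members)
  structure(list(
    class_id = cls$class_id,
    carbon_index = cls$carbon_index,
    hydrogen_indices = cls$hydrogen_indices,
    delta_h = unname(dh_members[best]),
    delta_h_kcal = unname(dh_members[best]) * HARTREE2KCAL,
    parent_energy = parent_scf$energy,
    radical_energy = unname(member[best]),
    member_delta_h = dh_members
  ), class = "som_abstraction")
}

#' @export
print.som_abstraction <- function(x, ...) {
  cat(sprintf("<som_abstraction> class %d (C%d): dHrxn = %.6f hartree (%.2f kcal/mol)\n",
              x$class_id, x$carbon_index, x$delta_h, x$delta_h_kcal))
  invisible(x)
}

#' Rank hydrogen classes by abstraction energy
#'
#' Lowest dH_rxn (most labile hydrogen) first; ties broken by lower carbon
#' index.  When `elide_symmetry = TRUE`, classes sharing a Morgan symmetry
#' label are computed once and the value reused -- appropriate only when the
#' geometry respects the topological symmetry.
#'
#' @param m closed-shell parent molecule
#' @param classes list from [hydrogen_equivalence_classes()]; default all
#' @param params CNDO parameters
#' @param elide_symmetry reuse energies across symmetry-equivalent carbons
#' @param ... passed to [scf_energy()]
#' @return data.frame ordered by rank with columns `rank`, `class_id`,
#'   `carbon_index`, `n_hydrogens`, `delta_h`, `delta_h_kcal`,
#'   `symmetry_label`; the `som_abstraction` objects are attached as the
#'   `energies` attribute (keyed by class_id).
#' @export
rank_hydrogen_classes <- function(m, classes = hydrogen_equivalence_classes(m),
                                  params = cndo_parameters(),
                                  elide_symmetry = FALSE, ...) {
  if (length(classes) == 0L) stop("no hydrogen classes to rank")
  parent_scf <- scf_energy(m, params = params, ...)
  e_h <- hydrogen_atom_energy(params)
  energies <- vector("list", length(classes))
  sym_seen <- list()
  for (k in seq_along(classes)) {
    cl <- classes[[k]]
    key <- as.character(cl$symmetry_label)
    if (elide_symmetry && !is.null(sym_seen[[key]])) {
      tmpl <- energies[[sym_seen[[key]]]]
      energies[[k]] <- tmpl
      energies[[k]]$class_id <- cl$class_id
      energies[[k]]$carbon_index <- cl$carbon_index
      energies[[k]]$hydrogen_indices <- cl$hydrogen_indices
      next
    }
    energies[[k]] <- abstraction_energy(m, cl, params = params,
                                        parent_scf = parent_scf,
                                        e_hydrogen = e_h, ...)
    sym_seen[[key]] <- k
  }
  dh <- vapply(energies, `[[`, numeric(1), "delta_h")
  cidx <- vapply(energies, `[[`, numeric(1), "carbon_index")
  o <- order(dh, cidx)
  out <- data.frame(
    rank = seq_along(o),
    class_id = vapply(energies, `[[`, numeric(1), "class_id")[o],
    carbon_index = cidx[o],
    n_hydrogens = vapply(classes, function(c) length(c$hydrogen_indices),
                         numeric(1))[o],
    delta_h = dh[o],
    delta_h_kcal = dh[o] * HARTREE2KCAL,
    symmetry_label = vapply(classes, `[[`, numeric(1), "symmetry_label")[o]
  )
  names(energies) <- vapply(energies, function(e) as.character(e$class_id), "")
  attr(out, "energies") <- energies
  attr(out, "parent_scf") <- parent_scf
  out
}

#' Read a user-supplied per-class energy table
#'
#' External-energy mode: results from another quantum-chemistry package can
#' drive the predictor in place of the built-in engine.  The TSV must have
#' columns `carbon_index` and `delta_h` (hartree).
#'
#' @param path TSV file
#' @return data.frame with `carbon_index`, `delta_h`
#' @export
read_energy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("carbon_index", "delta_h") %in% names(df)))
    stop("energy table needs columns carbon_index, delta_h: ", path)
  df$carbon_index <- as.integer(df$carbon_index)
  df$delta_h <- as.numeric(df$delta_h)
  df
}
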