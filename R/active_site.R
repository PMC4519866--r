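# Geometric model of the CYP3A4 active site, extracted from a holo PDB:
# heme iron, named hydrogen-bond donor residues, ordered waters, Phe-cluster,
# heme heavy atoms.

#' Active-site extraction configuration
#'
#' Defaults name the features the predictor measures against: hydrogen-bond
#' partners Arg105, Arg106, Ser119, Ile301, Glu308; ordered waters 619, 623,
#' 637; the Phe-cluster 57/108/219/220/241/304 forming the hydrophobic roof.
#' Residue numbers follow the PDB author numbering; the chain defaults to the
#' first chain containing the heme.
#'
#' @param hbond_residues named integer vector: residue name -> author residue
#'   number
#' @param waters integer residue numbers of HOH/WAT records
#' @param phe_cluster integer residue numbers of the phenylalanine cluster
#' @param chain chain identifier, or `NA` to use the heme's chain
#' @param heme_resname HETATM residue name of the heme group
#' @return an `active_site_config` list
#' @export
active_site_config <- function(
    hbond_residues = c(ARG = 105, ARG = 106, SER = 119, ILE = 301, GLU = 308),
    waters = c(619, 623, 637),
    phe_cluster = c(57, 108, 219, 220, 241, 304),
    chain = NA_character_,
    heme_resname = "HEM") {
  structure(list(hbond_residues = hbond_residues, waters = waters,
                 phe_cluster = phe_cluster, chain = chain,
                 heme_resname = heme_resname),
            class = "active_site_config")
}

# polar atoms considered per residue type: side-chain N/O, plus backbone O/N
# for Ile301 and Glu308 (the backbone carbonyl/amide is their relevant donor
# surface; which atoms accept or donate is decided by the geometric criteria)
.residue_polar_atoms <- list(
  ARG = c("NE", "NH1", "NH2"),
  SER = c("OG"),
  ILE = c("O", "N"),
  GLU = c("OE1", "OE2", "O", "N")
)
.phe_ring_atoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

#' Extract the active-site model from a PDB file
#'
#' Requires a heme group with an FE atom (fatal otherwise).  Configured
#' residues or waters that are absent are recorded as warnings in the model's
#' `provenance` and skipped, not fatal.
#'
#' @param pdb path to a PDB file
#' @param config an [active_site_config()]
#' @return an `active_site_model`: `fe_position`, `hbond_residues` (named list
#'   of data.frames with `atom`, `x`, `y`, `z`), `waters` (named list of
#'   3-vectors), `phe_cluster` (named list of ring-carbon matrices),
#'   `heme_atoms` (heavy-atom matrix), `provenance` (character warnings)
#' @export
extract_active_site <- function(pdb, config = active_site_config()) {
  p <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- p$atom
  fe_rows <- which(toupper(trimws(at$elety)) == "FE" &
                   toupper(trimws(at$resid)) == toupper(config$heme_resname))
  if (length(fe_rows) == 0L)
    fe_rows <- which(toupper(trimws(at$elety)) == "FE")
  if (length(fe_rows) == 0L)
    stop("no FE atom found in '", pdb, "': cannot locate the heme iron")
  fe <- fe_rows[1L]
  chain <- config$chain
  if (is.na(chain)) chain <- at$chain[fe]
  provenance <- character(0)

  fe_position <- c(at$x[fe], at$y[fe], at$z[fe])

  # heme heavy atoms: same residue instance as the FE
  heme_sel <- at$resid == at$resid[fe] & at$resno == at$resno[fe] &
    (is.na(at$chain) | is.na(chain) | at$chain == chain) &
    toupper(trimws(at$elesy)) != "H" & !grepl("^H", trimws(at$elety))
  heme_atoms <- as.matrix(at[heme_sel, c("x", "y", "z")])
  rownames(heme_atoms) <- trimws(at$elety[heme_sel])

  in_chain <- is.na(chain) | is.na(at$chain) | at$chain == chain

  hb <- list()
  for (k in seq_along(config$hbond_residues)) {
    rname <- names(config$hbond_residues)[k]
    rnum <- config$hbond_residues[k]
    label <- paste0(substr(rname, 1, 1),
                    tolower(substr(rname, 2, nchar(rname))), rnum)
    wanted <- .residue_polar_atoms[[toupper(rname)]]
    if (is.null(wanted)) wanted <- c("O", "N")
    sel <- at$resno == rnum & toupper(at$resid) == toupper(rname) & in_chain &
      trimws(at$elety) %in% wanted
    if (!any(sel)) {
      provenance <- c(provenance,
                      paste0("residue ", label, " not found; skipped"))
      next
    }
    hb[[label]] <- data.frame(atom = trimws(at$elety[sel]),
                              x = at$x[sel], y = at$y[sel], z = at$z[sel])
  }

  waters <- list()
  for (wid in config$waters) {
    sel <- toupper(at$resid) %in% c("HOH", "WAT") & at$resno == wid &
      trimws(at$elety) %in% c("O", "OW", "OH2")
    if (!any(sel)) {
      provenance <- c(provenance, paste0("water ", wid, " not found; skipped"))
      next
    }
    w <- which(sel)[1L]
    waters[[as.character(wid)]] <- c(at$x[w], at$y[w], at$z[w])
  }

  phe <- list()
  for (rnum in config$phe_cluster) {
    label <- paste0("Phe", rnum)
    sel <- toupper(at$resid) == "PHE" & at$resno == rnum & in_chain &
      trimws(at$elety) %in% .phe_ring_atoms
    if (!any(sel)) {
      provenance <- c(provenance,
                      paste0("residue ", label, " not found; skipped"))
      next
    }
    ring <- as.matrix(at[sel, c("x", "y", "z")])
    rownames(ring) <- trimws(at$elety[sel])
    phe[[label]] <- ring
  }

  structure(list(fe_position = fe_position, hbond_residues = hb,
                 waters = waters, phe_cluster = phe, heme_atoms = heme_atoms,
                 chain = chain, provenance = provenance,
                 source = basename(pdb)),
            class = "active_site_model")
}

#' @export
print.active_site_model <- function(x, ...) {
  cat("<active_site_model> from ", x$source, "\n", sep = "")
  cat(sprintf("  Fe at (%.3f, %.3f, %.3f)\n", x$fe_position[1],
              x$fe_position[2], x$fe_position[3]))
  cat("  H-bond residues:", paste(names(x$hbond_residues), collapse = ", "),
      "\n  waters:", paste(names(x$waters), collapse = ", "),
      "\n  Phe-cluster:", paste(names(x$phe_cluster), collapse = ", "),
      "\n  heme heavy atoms:", nrow(x$heme_atoms), "\n")
  for (w in x$provenance) cat("  warning:", w, "\n")
  invisible(x)
}

#' Dump an active-site model to JSON for inspection
#'
#' @param site an `active_site_model`
#' @param path output file; when `NULL` the JSON string is returned
#' @return `path` (invisibly) or a JSON string
#' @export
active_site_json <- function(site, path = NULL) {
  obj <- list(
    source = site$source,
    fe_position = site$fe_position,
    hbond_residues = site$hbond_residues,
    waters = site$waters,
    phe_cluster = lapply(site$phe_cluster, function(m)
      as.data.frame(cbind(atom = rownames(m), as.data.frame(m)))),
    heme_atoms = as.data.frame(site$heme_atoms),
    provenance = site$provenance
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
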