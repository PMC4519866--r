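#' Read a small molecule from SDF (V2000) or MOL2
#'
#' SDF V2000 connection tables are cut by fixed-width column (with
#' line-numbered parse errors); MOL2 parsing is delegated to \pkg{bio3d}.  Only the
#' first record of a multi-record file is returned (use [read_pose_set()] for
#' pose ensembles).  V3000 connection tables are rejected.  Explicit hydrogens
#' are required: a carbon whose bond orders sum to less than its expected
#' valence triggers a contract error rather than silent hydrogen addition.
#'
#' @param path file path
#' @param format "sdf" or "mol2"; guessed from the file extension by default
#' @param check_hydrogens passed on to [som_molecule()]
#' @return a `som_molecule`
#' @export
read_molecule <- function(path, format = c("auto", "sdf", "mol2"),
                          check_hydrogens = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mol2 = "mol2", sdf = "sdf", sd = "sdf",
                     stop("cannot guess format from extension of '", path,
                          "'; pass format="))
  }
  if (format == "mol2") return(read_mol2_records(path)[[1L]])
  read_sdf_records(path, check_hydrogens = check_hydrogens)[[1L]]
}

# -- SDF ---------------------------------------------------------------------

split_sdf_text <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  Filter(function(r) any(nzchar(trimws(r))), recs)
}

# structural pre-validation with line numbers; `offset` = line before record
validate_sdf_record <- function(rec, offset, idx) {
  if (length(rec) < 4L)
    stop("SDF record ", idx, ": truncated header (near line ", offset + length(rec), ")")
  counts <- rec[4L]
  if (grepl("V3000", counts))
    stop("SDF record ", idx, " (line ", offset + 4L,
         "): V3000 connection tables are not supported; supply V2000")
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb))
    stop("SDF record ", idx, " (line ", offset + 4L, "): unparseable counts line")
  if (length(rec) < 4L + na + nb)
    stop("SDF record ", idx, ": counts line declares ", na, " atoms / ", nb,
         " bonds but the block ends at line ", offset + length(rec))
  invisible(NULL)
}

# formal charges from "M  CHG" lines of one raw record (1-based atom index)
sdf_record_charges <- function(rec, natoms) {
  ch <- integer(natoms)
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    npair <- f[1]
    for (p in seq_len(npair)) ch[f[2 * p]] <- f[2 * p + 1]
  }
  ch
}

# "> <name>" data fields following M  END; values run to the next blank line
sdf_record_properties <- function(rec) {
  props <- list()
  tags <- grep("^> *<", rec)
  for (t in tags) {
    nm <- sub("^> *<([^>]+)>.*$", "\\1", rec[t])
    vals <- character(0)
    j <- t + 1L
    while (j <= length(rec) && nzchar(trimws(rec[j])) &&
           !startsWith(rec[j], "$$$$")) {
      vals <- c(vals, rec[j]); j <- j + 1L
    }
    props[[nm]] <- paste(vals, collapse = "\n")
  }
  props
}

# fixed-width V2000 connection-table parse of one raw record.  ChemmineR's
# reader rejects degenerate but well-formed records (single atoms, zero
# bonds) that the explicit-hydrogen contract must be able to diagnose, so
# the columns are cut here; tests cross-validate against ChemmineR.
parse_sdf_record <- function(rec, offset, idx, check_hydrogens, fallback_name) {
  validate_sdf_record(rec, offset, idx)
  na <- as.integer(substr(rec[4L], 1, 3))
  nb <- as.integer(substr(rec[4L], 4, 6))
  num <- function(ln, from, to, what, lineno) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (is.na(v))
      stop("SDF record ", idx, " (line ", lineno, "): unparseable ", what)
    v
  }
  atoms <- data.frame(element = character(na), x = numeric(na),
                      y = numeric(na), z = numeric(na))
  for (a in seq_len(na)) {
    ln <- rec[4L + a]; lineno <- offset + 4L + a
    atoms$x[a] <- num(ln, 1, 10, "x coordinate", lineno)
    atoms$y[a] <- num(ln, 11, 20, "y coordinate", lineno)
    atoms$z[a] <- num(ln, 21, 30, "z coordinate", lineno)
    el <- trimws(substr(ln, 31, 34))
    if (!nzchar(el))
      stop("SDF record ", idx, " (line ", lineno, "): missing element symbol")
    atoms$element[a] <- el
  }
  bonds <- NULL
  if (nb > 0L) {
    bonds <- data.frame(i = integer(nb), j = integer(nb), order = numeric(nb))
    for (b in seq_len(nb)) {
      ln <- rec[4L + na + b]; lineno <- offset + 4L + na + b
      bonds$i[b] <- num(ln, 1, 3, "bond atom index", lineno)
      bonds$j[b] <- num(ln, 4, 6, "bond atom index", lineno)
      bonds$order[b] <- num(ln, 7, 9, "bond order", lineno)
    }
  }
  atoms$charge <- sdf_record_charges(rec, na)
  nm <- trimws(rec[1L])
  if (!nzchar(nm)) nm <- fallback_name
  mol <- tryCatch(
    som_molecule(atoms, bonds, name = nm, check_hydrogens = check_hydrogens),
    error = function(e) stop("SDF record ", idx, ": ", conditionMessage(e)))
  props <- sdf_record_properties(rec)
  if (length(props)) attr(mol, "properties") <- props
  mol
}

read_sdf_records <- function(path, check_hydrogens = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split_sdf_text(lines)
  if (length(recs) == 0L) stop("SDF file '", path, "' contains no records")
  out <- vector("list", length(recs))
  off <- 0L
  for (k in seq_along(recs)) {
    out[[k]] <- parse_sdf_record(recs[[k]], off, k, check_hydrogens,
                                 fallback_name = paste0(basename(path), "#", k))
    off <- off + length(recs[[k]])
  }
  out
}

#' Write a molecule (or list of molecules) as SDF V2000
#'
#' Fixed-width V2000 with 4-decimal coordinates, `M  CHG` lines for non-zero
#' formal charges, and optional `> <name>` data fields taken from each
#' molecule's `properties` attribute.  Output is byte-deterministic.
#'
#' @param m a `som_molecule` or list of them
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_molecule <- function(m, path) {
  mols <- if (inherits(m, "som_molecule")) list(m) else m
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms; b <- mol$bonds
    writeLines(c(mol$name, "  somcyp", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, a$element), con)
    if (nrow(b) > 0L)
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, as.integer(b$order)),
                 con)
    chg <- which(a$charge != 0L)
    for (i in chg)
      writeLines(sprintf("M  CHG  1 %3d %3d", i, a$charge[i]), con)
    writeLines("M  END", con)
    props <- attr(mol, "properties")
    for (nm in names(props))
      writeLines(c(paste0("> <", nm, ">"), as.character(props[[nm]]), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

# -- MOL2 --------------------------------------------------------------------

read_mol2_records <- function(path, check_hydrogens = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0L)
    stop("MOL2 file '", path, "': no @<TRIPOS>MOLECULE block found")
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    tf <- tempfile(fileext = ".mol2")
    writeLines(lines[starts[k]:ends[k]], tf)
    x <- tryCatch(bio3d::read.mol2(tf),
                  error = function(e) stop("MOL2 record ", k, " of '", path,
                                           "': ", conditionMessage(e)))
    unlink(tf)
    atoms <- data.frame(element = x$atom$elety,
                        x = x$atom$x, y = x$atom$y, z = x$atom$z,
                        charge = 0L)
    bonds <- if (is.null(x$bond) || nrow(x$bond) == 0L) NULL else {
      ord <- vapply(tolower(x$bond$type), function(t)
        switch(t, "1" = 1, "2" = 2, "3" = 3, ar = 4, am = 1, du = 1,
               stop("MOL2 record ", k, ": unsupported bond type '", t, "'")),
        numeric(1), USE.NAMES = FALSE)
      data.frame(i = x$bond$origin, j = x$bond$target, order = ord)
    }
    nm <- if (is.null(x$name) || !nzchar(trimws(x$name[1]))) {
      paste0(basename(path), "#", k)
    } else trimws(x$name[1])
    out[[k]] <- som_molecule(atoms, bonds, name = nm,
                             check_hydrogens = check_hydrogens)
  }
  out
}

# -- pose sets ---------------------------------------------------------------

#' Read an ordered ensemble of docked poses
#'
#' Records are read in file order; `rank` is the record index starting at 1
#' (pose files from docking engines are conventionally score-sorted).  Every
#' record must match the reference substrate in atom count and element
#' sequence.  A per-pose docking score is taken from the SDF data field named
#' by `score_property` when present.
#'
#' @param path multi-record SDF or MOL2 file in the protein frame
#' @param reference the substrate `som_molecule` the poses re-position
#' @param format "sdf", "mol2" or "auto"
#' @param score_property SDF property field holding the docking fitness
#'   (default `"ChemScore"`); missing scores are `NA`
#' @return list of `som_pose` objects (fields `molecule`, `rank`, `score`)
#' @export
read_pose_set <- function(path, reference, format = c("auto", "sdf", "mol2"),
                          score_property = "ChemScore") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mol2 = "mol2", "sdf")
  }
  mols <- if (format == "mol2") read_mol2_records(path) else
    read_sdf_records(path, check_hydrogens = FALSE)
  poses <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    mk <- mols[[k]]
    if (n_atoms(mk) != n_atoms(reference))
      stop("pose-set record ", k, ": ", n_atoms(mk),
           " atoms, reference has ", n_atoms(reference))
    if (!identical(mk$atoms$element, reference$atoms$element))
      stop("pose-set record ", k, ": element sequence differs from reference")
    props <- attr(mk, "properties")
    score <- if (!is.null(props) && score_property %in% names(props)) {
      suppressWarnings(as.numeric(props[[score_property]]))
    } else NA_real_
    poses[[k]] <- structure(list(molecule = mk, rank = k, score = score),
                            class = "som_pose")
  }
  poses
}

#' @export
print.som_pose <- function(x, ...) {
  cat("<som_pose> rank", x$rank,
      if (!is.na(x$score)) paste0("score ", x$score) else "(no score)", "\n")
  invisible(x)
}
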