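# The mechanism-based predictor: enumerate candidate sites, qualify them by
# pose geometry + key interaction features, expand to adjacent carbons, rank
# by hydrogen-abstraction energy, report top-k.

#' Predictor configuration
#'
#' @param distance_window closed site--heme-iron window in Angstrom
#'   (default c(2.5, 7.5); the upper cutoff 7.5 is the combined-evaluation
#'   choice among 6.5/7.0/7.5)
#' @param poses_kept number of top-ranked poses used (default 10)
#' @param require_feature if `TRUE` (default) a qualifying pose must also show
#'   at least one key feature (hydrogen bond or lipophilic contact); if
#'   `FALSE` the distance window alone qualifies
#' @param adjacency_expansion also admit candidate sites one bond away from a
#'   qualified site (default `TRUE`)
#' @param k number of top-ranked sites marked in the prediction (default 3)
#' @param weight_scheme pose weighting for the accessibility fraction:
#'   "uniform" or "linear_rank"
#' @param hbond an [hbond_criteria()]
#' @param lipophilic a [lipophilic_criteria()]
#' @param reaction_types candidate reaction types to enumerate
#' @return a `som_config` list
#' @export
som_config <- function(distance_window = c(2.5, 7.5), poses_kept = 10L,
                       require_feature = TRUE, adjacency_expansion = TRUE,
                       k = 3L, weight_scheme = c("uniform", "linear_rank"),
                       hbond = hbond_criteria(),
                       lipophilic = lipophilic_criteria(),
                       reaction_types = c("aliphatic_hydroxylation",
                                          "n_dealkylation")) {
  stopifnot(length(distance_window) == 2L,
            distance_window[1] < distance_window[2],
            poses_kept >= 1L, k >= 1L)
  structure(list(distance_window = as.numeric(distance_window),
                 poses_kept = as.integer(poses_kept),
                 require_feature = isTRUE(require_feature),
                 adjacency_expansion = isTRUE(adjacency_expansion),
                 k = as.integer(k),
                 weight_scheme = match.arg(weight_scheme),
                 hbond = hbond, lipophilic = lipophilic,
                 reaction_types = reaction_types),
            class = "som_config")
}

#' Load a predictor configuration from YAML
#'
#' Top-level keys mirror the [som_config()] arguments; `hbond` and
#' `lipophilic` may be nested maps of their criteria arguments.
#'
#' @param path YAML file
#' @return a `som_config`
#' @export
read_som_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("distance_window", "poses_kept",
                                  "require_feature", "adjacency_expansion",
                                  "k", "weight_scheme", "reaction_types"))]
  if (!is.null(y$hbond)) args$hbond <- do.call(hbond_criteria, y$hbond)
  if (!is.null(y$lipophilic))
    args$lipophilic <- do.call(lipophilic_criteria, y$lipophilic)
  do.call(som_config, args)
}

#' Enumerate candidate metabolic sites
#'
#' Aliphatic hydroxylation: sp3 carbons (all incident bonds single) bearing at
#' least one hydrogen; aromatic C-H is out of scope.  N-dealkylation:
#' hydrogen-bearing non-aromatic carbons bonded to a nitrogen (the alpha
#' carbon).  A carbon may appear under both reaction types.
#'
#' @param m a `som_molecule` with explicit hydrogens
#' @param reaction_types subset of "aliphatic_hydroxylation", "n_dealkylation"
#' @return data.frame: `carbon_index`, `reaction_type`, `class_id`,
#'   `n_hydrogens` (zero rows when nothing qualifies)
#' @export
enumerate_candidate_sites <- function(m,
    reaction_types = c("aliphatic_hydroxylation", "n_dealkylation")) {
  reaction_types <- match.arg(reaction_types, several.ok = TRUE)
  classes <- hydrogen_equivalence_classes(m)
  adj <- adjacency_list(m)
  el <- m$atoms$element
  rows <- list()
  for (cl in classes) {
    ci <- cl$carbon_index
    inc <- m$bonds$order[m$bonds$i == ci | m$bonds$j == ci]
    sp3 <- all(inc == 1)
    aromatic <- any(inc == 4)
    if ("aliphatic_hydroxylation" %in% reaction_types && sp3)
      rows[[length(rows) + 1L]] <- data.frame(
        carbon_index = ci, reaction_type = "aliphatic_hydroxylation",
        class_id = cl$class_id, n_hydrogens = length(cl$hydrogen_indices))
    if ("n_dealkylation" %in% reaction_types && !aromatic &&
        any(el[adj[[ci]]] == "N"))
      rows[[length(rows) + 1L]] <- data.frame(
        carbon_index = ci, reaction_type = "n_dealkylation",
        class_id = cl$class_id, n_hydrogens = length(cl$hydrogen_indices))
  }
  if (length(rows) == 0L)
    return(data.frame(carbon_index = integer(), reaction_type = character(),
                      class_id = integer(), n_hydrogens = integer()))
  do.call(rbind, rows)
}

#' Qualify candidate sites against the pose ensemble
#'
#' A site qualifies when at least one kept pose has its site--heme distance
#' inside the window AND (when `require_feature`) that same pose exhibits at
#' least one key feature -- a qualifying hydrogen bond or lipophilic contact
#' anywhere on the ligand (whole-pose anchoring).  The accessibility
#' `pose_fraction` ([qualifying_pose_fraction()]) is attached to each
#' qualified site.
#'
#' @param sites data.frame from [enumerate_candidate_sites()]
#' @param poses nonempty list of `som_pose` (already truncated to the kept set)
#' @param site_model an `active_site_model`
#' @param config a [som_config()]
#' @return subset of `sites` with added columns `pose_fraction`, `dist_ok`,
#'   `hbond_ok`, `lipophilic_ok`, `adjacency_derived` (all `FALSE` here),
#'   `n_qualifying_poses`
#' @export
qualify_sites <- function(sites, poses, site_model, config = som_config()) {
  if (length(poses) == 0L) stop("empty pose set")
  poses <- poses[seq_len(min(config$poses_kept, length(poses)))]
  cand <- unique(sites$carbon_index)
  feats <- lapply(poses, pose_features, site = site_model,
                  crit = config$hbond, lipo_crit = config$lipophilic,
                  candidate_carbons = cand)
  has_hb <- vapply(feats, function(f) nrow(f$hbond_features) > 0L, logical(1))
  has_lp <- vapply(feats, function(f) nrow(f$lipophilic_features) > 0L,
                   logical(1))
  keep <- logical(nrow(sites))
  pf <- hb <- lp <- numeric(nrow(sites))
  nq <- integer(nrow(sites))
  dist_ok <- logical(nrow(sites))
  for (r in seq_len(nrow(sites))) {
    ci <- sites$carbon_index[r]
    d <- vapply(feats, function(f) f$site_distances[[as.character(ci)]],
                numeric(1))
    in_win <- d >= config$distance_window[1] & d <= config$distance_window[2]
    qual_pose <- if (config$require_feature) in_win & (has_hb | has_lp) else in_win
    dist_ok[r] <- any(in_win)
    nq[r] <- sum(qual_pose)
    keep[r] <- any(qual_pose)
    hb[r] <- any(qual_pose & has_hb)
    lp[r] <- any(qual_pose & has_lp)
    pf[r] <- qualifying_pose_fraction(ci, poses, site_model,
                                      window = config$distance_window,
                                      weights = config$weight_scheme)
  }
  out <- sites
  out$pose_fraction <- pf
  out$dist_ok <- dist_ok
  out$hbond_ok <- as.logical(hb)
  out$lipophilic_ok <- as.logical(lp)
  out$n_qualifying_poses <- nq
  out$adjacency_derived <- FALSE
  out[keep, , drop = FALSE]
}

#' Expand qualified sites to adjacent carbons
#'
#' A carbon one bond away from a qualified site is itself a plausible site.
#' Each directly qualified site contributes its candidate neighbours; derived
#' sites inherit the largest parent pose_fraction and are flagged.  Only one
#' expansion round is applied (derived sites do not seed further expansion),
#' so the operation is idempotent.
#'
#' @param qualified output of [qualify_sites()]
#' @param all_candidates output of [enumerate_candidate_sites()]
#' @param m the substrate `som_molecule`
#' @return `qualified` plus adjacency-derived rows
#' @export
expand_adjacent_sites <- function(qualified, all_candidates, m) {
  seeds <- qualified[!qualified$adjacency_derived, , drop = FALSE]
  if (nrow(seeds) == 0L) return(qualified)
  added <- list()
  for (r in seq_len(nrow(seeds))) {
    for (nb in adjacent_carbons(m, seeds$carbon_index[r])) {
      cand <- all_candidates[all_candidates$carbon_index == nb, , drop = FALSE]
      for (q in seq_len(nrow(cand))) {
        already <- any(qualified$carbon_index == cand$carbon_index[q] &
                       qualified$reaction_type == cand$reaction_type[q])
        pend <- any(vapply(added, function(a)
          a$carbon_index == cand$carbon_index[q] &&
          a$reaction_type == cand$reaction_type[q], logical(1)))
        if (already) next
        row <- cand[q, , drop = FALSE]
        row$pose_fraction <- seeds$pose_fraction[r]
        row$dist_ok <- FALSE
        row$hbond_ok <- FALSE
        row$lipophilic_ok <- FALSE
        row$n_qualifying_poses <- 0L
        row$adjacency_derived <- TRUE
        if (pend) {
          k <- which(vapply(added, function(a)
            a$carbon_index == cand$carbon_index[q] &&
            a$reaction_type == cand$reaction_type[q], logical(1)))[1]
          added[[k]]$pose_fraction <- max(added[[k]]$pose_fraction,
                                          row$pose_fraction)
        } else {
          added[[length(added) + 1L]] <- row
        }
      }
    }
  }
  if (length(added) == 0L) return(qualified)
  rbind(qualified, do.call(rbind, added))
}

#' Predict sites of metabolism
#'
#' The full mechanism-based model: candidate enumeration, pose-geometry
#' qualification, adjacency expansion, then ranking by the
#' hydrogen-abstraction energy of each site's hydrogen class (ascending:
#' the most labile hydrogen first).  Ties are broken by higher pose_fraction,
#' then lower carbon index.
#'
#' @param m substrate `som_molecule` (explicit hydrogens)
#' @param poses list of `som_pose` in the protein frame
#' @param site_model an `active_site_model`
#' @param config a [som_config()]
#' @param params CNDO parameters ([cndo_parameters()])
#' @param energy_table optional external per-carbon energy data.frame
#'   (columns `carbon_index`, `delta_h`) used instead of the built-in engine
#' @param ... passed to [scf_energy()]
#' @return a `som_prediction`: ranked data.frame of qualified sites plus
#'   provenance; empty (with a warning) when nothing qualifies
#' @export
predict_sites <- function(m, poses, site_model, config = som_config(),
                          params = cndo_parameters(), energy_table = NULL,
                          ...) {
  sites <- enumerate_candidate_sites(m, config$reaction_types)
  empty <- data.frame(rank = integer(), carbon_index = integer(),
                      reaction_type = character(), class_id = integer(),
                      delta_h = numeric(), delta_h_kcal = numeric(),
                      pose_fraction = numeric(), dist_ok = logical(),
                      hbond_ok = logical(), lipophilic_ok = logical(),
                      adjacency_derived = logical(), top_k = logical())
  as_prediction <- function(tab) {
    structure(list(sites = tab, substrate = m$name, k = config$k,
                   config = config, n_poses = min(config$poses_kept,
                                                  length(poses))),
              class = "som_prediction")
  }
  if (nrow(sites) == 0L) {
    warning("no candidate sites on '", m$name, "'; empty prediction")
    return(as_prediction(empty))
  }
  qual <- qualify_sites(sites, poses, site_model, config)
  if (config$adjacency_expansion)
    qual <- expand_adjacent_sites(qual, sites, m)
  if (nrow(qual) == 0L) {
    warning("no site on '", m$name, "' qualified under the configured ",
            "window/features; empty prediction")
    return(as_prediction(empty))
  }
  carbons <- unique(qual$carbon_index)
  if (is.null(energy_table)) {
    classes <- hydrogen_equivalence_classes(m)
    need <- Filter(function(cl) cl$carbon_index %in% carbons, classes)
    parent_scf <- scf_energy(m, params = params, ...)
    e_h <- hydrogen_atom_energy(params)
    dh <- vapply(need, function(cl)
      abstraction_energy(m, cl, params = params, parent_scf = parent_scf,
                         e_hydrogen = e_h, ...)$delta_h, numeric(1))
    names(dh) <- vapply(need, function(cl) as.character(cl$carbon_index), "")
  } else {
    dh <- energy_table$delta_h
    names(dh) <- as.character(energy_table$carbon_index)
    missing_c <- setdiff(as.character(carbons), names(dh))
    if (length(missing_c) > 0L)
      stop("external energy table lacks carbons ",
           paste(missing_c, collapse = ", "))
  }
  qual$delta_h <- dh[as.character(qual$carbon_index)]
  qual$delta_h_kcal <- qual$delta_h * HARTREE2KCAL
  o <- order(qual$delta_h, -qual$pose_fraction, qual$carbon_index)
  qual <- qual[o, , drop = FALSE]
  qual$rank <- seq_len(nrow(qual))
  qual$top_k <- qual$rank <= config$k
  rownames(qual) <- NULL
  cols <- c("rank", "carbon_index", "reaction_type", "class_id", "delta_h",
            "delta_h_kcal", "pose_fraction", "dist_ok", "hbond_ok",
            "lipophilic_ok", "adjacency_derived", "top_k")
  as_prediction(qual[, cols])
}

#' @export
print.som_prediction <- function(x, ...) {
  cat("<som_prediction> ", x$substrate, ": ", nrow(x$sites),
      " qualified site(s), top-", x$k, " marked\n", sep = "")
  if (nrow(x$sites) > 0L)
    print(x$sites[, c("rank", "carbon_index", "reaction_type", "delta_h_kcal",
                      "pose_fraction", "adjacency_derived", "top_k")],
          row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
summary.som_prediction <- function(object, ...) {
  s <- object$sites
  cat("Substrate:", object$substrate, "\n")
  cat("Poses used:", object$n_poses, "  window: [",
      paste(object$config$distance_window, collapse = ", "), "] A\n")
  cat("Qualified sites:", nrow(s),
      " (", sum(s$adjacency_derived), "adjacency-derived )\n")
  if (nrow(s) > 0L) {
    top <- s[s$top_k, , drop = FALSE]
    cat("Top-", object$k, " carbons: ",
        paste(top$carbon_index, collapse = ", "), "\n", sep = "")
    cat("dHrxn range (kcal/mol): ",
        sprintf("%.2f .. %.2f", min(s$delta_h_kcal), max(s$delta_h_kcal)),
        "\n", sep = "")
  }
  invisible(object)
}

#' @export
as.data.frame.som_prediction <- function(x, ...) x$sites

#' Top-k predicted carbons
#' @param pred a `som_prediction`
#' @param k override the configured k
#' @return integer vector of carbon indices in rank order
#' @export
top_sites <- function(pred, k = pred$k) {
  s <- pred$sites
  utils::head(s$carbon_index[order(s$rank)], k)
}
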