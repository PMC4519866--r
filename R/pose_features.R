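# Per-pose qualification signals: site--heme-iron distances and key
# interaction features (hydrogen bonds, lipophilic contacts).

#' Geometric hydrogen-bond criteria
#'
#' Standard cutoffs: donor--acceptor distance <= 3.5 Angstrom and
#' donor-H...acceptor angle >= 120 degrees.  Crystallographic waters carry no
#' hydrogens, so water contacts use the distance criterion alone.
#'
#' @param max_distance donor--acceptor distance cutoff (Angstrom)
#' @param min_angle donor-H...acceptor angle floor (degrees)
#' @return an `hbond_criteria` list
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 120) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' Lipophilic contact criteria
#'
#' A contact is a ligand-carbon/partner-carbon pair within `max_distance`;
#' a feature fires when at least `min_contacts` such pairs exist.
#'
#' @param max_distance C...C distance cutoff (Angstrom)
#' @param min_contacts minimum number of contact pairs
#' @return a `lipophilic_criteria` list
#' @export
lipophilic_criteria <- function(max_distance = 4.5, min_contacts = 3L) {
  stopifnot(max_distance > 0, min_contacts >= 1)
  structure(list(max_distance = max_distance,
                 min_contacts = as.integer(min_contacts)),
            class = "lipophilic_criteria")
}

pose_coords <- function(pose) {
  if (inherits(pose, "som_pose")) coords(pose$molecule) else coords(pose)
}
pose_molecule <- function(pose) {
  if (inherits(pose, "som_pose")) pose$molecule else pose
}

#' Distance from the heme iron to a substrate carbon
#'
#' @param pose a `som_pose` (or bare `som_molecule`) in the protein frame
#' @param carbon_index index of a carbon atom in the pose
#' @param site an `active_site_model`
#' @return Euclidean distance in Angstrom
#' @export
site_heme_distance <- function(pose, carbon_index, site) {
  m <- pose_molecule(pose)
  if (m$atoms$element[carbon_index] != "C")
    stop("atom ", carbon_index, " is ", m$atoms$element[carbon_index],
         ", not a carbon")
  sqrt(sum((pose_coords(pose)[carbon_index, ] - site$fe_position)^2))
}

# which residue polar atoms can donate a hydrogen (protein hydrogens are not
# present in the model, so the protein-donor direction is distance-only)
.partner_can_donate <- c(NE = TRUE, NH1 = TRUE, NH2 = TRUE, OG = TRUE,
                         N = TRUE, O = FALSE, OE1 = FALSE, OE2 = FALSE)

#' Detect hydrogen bonds between a pose and the active-site model
#'
#' Ligand polar atoms are N and O.  A residue pair qualifies when the
#' donor--acceptor distance is within the cutoff and either (a) the ligand
#' atom donates through one of its hydrogens with an acceptable
#' donor-H...acceptor angle, or (b) the partner atom is itself a donor
#' (Arg NE/NH1/NH2, Ser OG, backbone N), for which the protein-side hydrogen
#' positions are unknown and distance alone decides.  Water oxygens are
#' evaluated with the distance criterion only.
#'
#' @param pose a `som_pose` with explicit hydrogens
#' @param site an `active_site_model`
#' @param crit an [hbond_criteria()]
#' @return data.frame: `ligand_atom`, `partner`, `distance`, `angle`
#'   (degrees; `NA` when the distance-only rule applied), `type`
#'   ("hbond" or "water_hbond"); zero rows when none.
#' @export
detect_hydrogen_bonds <- function(pose, site, crit = hbond_criteria()) {
  m <- pose_molecule(pose)
  xyz <- coords(m)
  polar <- which(m$atoms$element %in% c("N", "O"))
  out <- list()
  if (length(polar) > 0L) {
    adj <- adjacency_list(m)
    for (p in polar) {
      hs <- adj[[p]][m$atoms$element[adj[[p]]] == "H"]
      # residue polar partners
      for (lab in names(site$hbond_residues)) {
        pa <- site$hbond_residues[[lab]]
        for (r in seq_len(nrow(pa))) {
          tgt <- c(pa$x[r], pa$y[r], pa$z[r])
          d <- sqrt(sum((xyz[p, ] - tgt)^2))
          if (d > crit$max_distance) next
          ang <- NA_real_
          ok <- FALSE
          if (length(hs) > 0L) {
            angs <- vapply(hs, function(h)
              vec_angle(xyz[p, ] - xyz[h, ], tgt - xyz[h, ]), numeric(1))
            ang <- max(angs)
            ok <- ang >= crit$min_angle
          }
          if (!ok && isTRUE(.partner_can_donate[pa$atom[r]])) {
            ok <- TRUE; ang <- NA_real_
          }
          if (ok)
            out[[length(out) + 1L]] <- data.frame(
              ligand_atom = p, partner = paste0(lab, ":", pa$atom[r]),
              distance = d, angle = ang, type = "hbond")
        }
      }
      # waters: oxygen position, distance criterion alone
      for (wid in names(site$waters)) {
        d <- sqrt(sum((xyz[p, ] - site$waters[[wid]])^2))
        if (d <= crit$max_distance)
          out[[length(out) + 1L]] <- data.frame(
            ligand_atom = p, partner = paste0("HOH", wid),
            distance = d, angle = NA_real_, type = "water_hbond")
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(ligand_atom = integer(), partner = character(),
                      distance = numeric(), angle = numeric(),
                      type = character()))
  do.call(rbind, out)
}

vec_angle <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cs))) * 180 / pi
}

#' Detect lipophilic contacts with the Phe-cluster and the heme
#'
#' Counts ligand-carbon / partner-carbon pairs within the distance cutoff,
#' pooled over the whole Phe-cluster (and, separately, over the heme heavy
#' atoms).  A feature is emitted for each partner class reaching
#' `min_contacts`.  For the heme, the ligand atom set may be restricted to
#' candidate-site carbons via `heme_carbons` -- "hydrophobic toward the heme"
#' concerns the prospective metabolic sites themselves.
#'
#' @param pose a `som_pose`
#' @param site an `active_site_model`
#' @param crit a [lipophilic_criteria()]
#' @param heme_carbons optional integer vector of ligand carbon indices used
#'   for the heme contact count (default: all carbons)
#' @return data.frame: `partner` ("Phe-cluster" or "heme"), `n_contacts`,
#'   `min_distance`; zero rows when neither feature fires.
#' @export
detect_lipophilic_contacts <- function(pose, site, crit = lipophilic_criteria(),
                                       heme_carbons = NULL) {
  m <- pose_molecule(pose)
  xyz <- coords(m)
  carbons <- which(m$atoms$element == "C")
  out <- list()
  count_contacts <- function(lig_idx, partner_xyz) {
    if (length(lig_idx) == 0L || is.null(partner_xyz) ||
        nrow(partner_xyz) == 0L)
      return(c(0L, Inf))
    X <- xyz[lig_idx, , drop = FALSE]
    d2 <- outer(rowSums(X^2), rowSums(partner_xyz^2), "+") - 2 * X %*% t(partner_xyz)
    d <- sqrt(pmax(d2, 0))
    c(sum(d <= crit$max_distance), min(d))
  }
  phe_xyz <- do.call(rbind, site$phe_cluster)
  cc <- count_contacts(carbons, phe_xyz)
  if (cc[1] >= crit$min_contacts)
    out[[length(out) + 1L]] <- data.frame(partner = "Phe-cluster",
                                          n_contacts = cc[1],
                                          min_distance = cc[2])
  heme_lig <- if (is.null(heme_carbons)) carbons else
    intersect(carbons, heme_carbons)
  hc <- count_contacts(heme_lig, site$heme_atoms)
  if (hc[1] >= crit$min_contacts)
    out[[length(out) + 1L]] <- data.frame(partner = "heme",
                                          n_contacts = hc[1],
                                          min_distance = hc[2])
  if (length(out) == 0L)
    return(data.frame(partner = character(), n_contacts = integer(),
                      min_distance = numeric()))
  do.call(rbind, out)
}

#' Weighted fraction of poses placing a carbon within the distance window
#'
#' The accessibility score of a candidate site: the weight-sum of poses whose
#' site--heme distance falls in the closed window, with weights normalised to
#' sum one over the kept pose set.  `"uniform"` gives the plain fraction;
#' `"linear_rank"` weights pose i of n by (n + 1 - i).
#'
#' @param carbon_index candidate carbon (index into the substrate)
#' @param poses nonempty list of `som_pose`
#' @param site an `active_site_model`
#' @param window closed distance window in Angstrom (default c(2.5, 7.5))
#' @param weights "uniform" or "linear_rank"
#' @return fraction in 0..1
#' @export
qualifying_pose_fraction <- function(carbon_index, poses, site,
                                     window = c(2.5, 7.5),
                                     weights = c("uniform", "linear_rank")) {
  if (length(poses) == 0L) stop("empty pose set")
  weights <- match.arg(weights)
  n <- length(poses)
  w <- switch(weights,
              uniform = rep(1, n),
              linear_rank = n + 1 - vapply(poses, `[[`, numeric(1), "rank"))
  w <- w / sum(w)
  d <- vapply(poses, site_heme_distance, numeric(1),
              carbon_index = carbon_index, site = site)
  sum(w[d >= window[1] & d <= window[2]])
}

#' Full feature record for one pose
#'
#' @inheritParams detect_hydrogen_bonds
#' @param lipo_crit a [lipophilic_criteria()]
#' @param candidate_carbons carbons whose site--heme distances are reported
#'   (and which count for the heme lipophilic contact); default all carbons
#' @return a `pose_feature_record` list: `pose_rank`, `hbond_features`,
#'   `lipophilic_features`, `site_distances` (named by carbon index)
#' @export
pose_features <- function(pose, site, crit = hbond_criteria(),
                          lipo_crit = lipophilic_criteria(),
                          candidate_carbons = NULL) {
  m <- pose_molecule(pose)
  if (is.null(candidate_carbons))
    candidate_carbons <- which(m$atoms$element == "C")
  d <- vapply(candidate_carbons, site_heme_distance, numeric(1),
              pose = pose, site = site)
  names(d) <- as.character(candidate_carbons)
  structure(list(
    pose_rank = if (inherits(pose, "som_pose")) pose$rank else NA_integer_,
    hbond_features = detect_hydrogen_bonds(pose, site, crit),
    lipophilic_features = detect_lipophilic_contacts(
      pose, site, lipo_crit, heme_carbons = candidate_carbons),
    site_distances = d
  ), class = "pose_feature_record")
}
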