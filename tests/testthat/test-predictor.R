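# cyclohexanone positioned around a toy site; returns molecule, poses, site
predictor_fixture <- function(dists = c(4, 5, 6, 8.5, 9),
                              carbon = 3L, with_feature = TRUE) {
  mol <- reference_molecules()$cyclohexanone
  poses <- make_pose_set(mol, lapply(dists, function(d)
    list(carbon = carbon, distance = d, direction = c(0, 0, 1))))
  og <- if (with_feature) coords(poses[[1]]$molecule)[7, ] + c(0, 2.9, 0)
  # keep the heme heavy atoms out of lipophilic-contact range so that the
  # hydrogen bond is the only key feature in play
  site <- bare_site(ser_og = og,
                    heme = matrix(c(0, 0, -50), 1, 3,
                                  dimnames = list("FE", NULL)))
  list(mol = mol, poses = poses, site = site)
}

test_that("candidate enumeration respects reaction-type scope", {
  mols <- reference_molecules()
  expect_equal(nrow(enumerate_candidate_sites(mols$propane,
                                              "aliphatic_hydroxylation")), 3L)
  tma <- enumerate_candidate_sites(mols$trimethylamine, "n_dealkylation")
  expect_equal(nrow(tma), 3L)
  expect_setequal(tma$carbon_index, 2:4)
  # aromatic C-H excluded: only the toluene methyl remains
  tol <- enumerate_candidate_sites(mols$toluene)
  expect_equal(tol$carbon_index, 7L)
  # the carbonyl carbon of cyclohexanone (no H, sp2) is not a candidate
  cyc <- enumerate_candidate_sites(mols$cyclohexanone)
  expect_setequal(cyc$carbon_index, 2:6)
})

test_that("qualification follows the distance window and feature rules", {
  fx <- predictor_fixture()
  sites <- enumerate_candidate_sites(fx$mol)
  q <- qualify_sites(sites, fx$poses, fx$site)
  expect_true(3L %in% q$carbon_index)      # 5.0 A with a Ser119 H-bond

  # a site at 8.0 A in all poses never qualifies under [2.5, 7.5]
  far <- predictor_fixture(dists = rep(8, 5))
  qf <- qualify_sites(enumerate_candidate_sites(far$mol)[
    enumerate_candidate_sites(far$mol)$carbon_index == 3L, ],
    far$poses, far$site)
  expect_equal(nrow(qf), 0L)

  # featureless poses: require_feature decides
  bare <- predictor_fixture(with_feature = FALSE)
  sb <- enumerate_candidate_sites(bare$mol)
  expect_equal(nrow(qualify_sites(sb, bare$poses, bare$site)), 0L)
  cfg_nf <- som_config(require_feature = FALSE)
  q_nf <- qualify_sites(sb, bare$poses, bare$site, cfg_nf)
  expect_true(3L %in% q_nf$carbon_index)

  expect_error(qualify_sites(sb, list(), bare$site), "empty")
})

test_that("qualified sites equal a brute-force (site x pose) enumeration", {
  cfgs <- list(som_config(), som_config(require_feature = FALSE),
               som_config(distance_window = c(2.5, 6.0)))
  for (with_f in c(TRUE, FALSE)) {
    fx <- predictor_fixture(dists = c(3, 5.5, 7.2, 8.1), with_feature = with_f)
    sites <- enumerate_candidate_sites(fx$mol)
    for (cfg in cfgs) {
      mine <- qualify_sites(sites, fx$poses, fx$site, cfg)
      ref <- brute_force_qualify(sites, fx$poses, fx$site, cfg)
      expect_equal(mine[, c("carbon_index", "reaction_type")],
                   ref[, c("carbon_index", "reaction_type")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("widening the distance window never shrinks the qualified set", {
  fx <- predictor_fixture(dists = c(3, 5, 6.9, 7.8, 9.2))
  sites <- enumerate_candidate_sites(fx$mol)
  prev <- NULL
  for (hi in c(5.5, 6.5, 7.5, 9.5)) {
    q <- qualify_sites(sites, fx$poses, fx$site,
                       som_config(distance_window = c(2.5, hi)))
    keys <- paste(q$carbon_index, q$reaction_type)
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("adjacency expansion adds ring neighbours once, idempotently", {
  fx <- predictor_fixture()
  sites <- enumerate_candidate_sites(fx$mol)
  q3 <- qualify_sites(sites[sites$carbon_index == 3L, ], fx$poses, fx$site)
  ex1 <- expand_adjacent_sites(q3, sites, fx$mol)
  # C3 qualified on the cyclohexanone ring: C2 and C4 are added
  expect_setequal(ex1$carbon_index, c(2L, 3L, 4L))
  expect_equal(sort(ex1$carbon_index[ex1$adjacency_derived]), c(2L, 4L))
  # derived sites inherit the parent pose fraction
  expect_equal(ex1$pose_fraction[ex1$carbon_index == 2L],
               q3$pose_fraction[1])
  ex2 <- expand_adjacent_sites(ex1, sites, fx$mol)
  expect_equal(ex2, ex1)

  # methane: nothing to add
  met <- reference_molecules()$methane
  ms <- enumerate_candidate_sites(met)
  poses <- make_pose_set(met, list(list(carbon = 1L, distance = 5)))
  qm <- qualify_sites(ms, poses, bare_site(), som_config(require_feature = FALSE))
  expect_equal(nrow(expand_adjacent_sites(qm, ms, met)), nrow(qm))
})

test_that("predictions are ranked by independently computed energies", {
  fx <- predictor_fixture(dists = c(4, 5, 6, 6.5, 7))
  pred <- predict_sites(fx$mol, fx$poses, fx$site)
  expect_s3_class(pred, "som_prediction")
  s <- pred$sites
  expect_true(all(diff(s$delta_h) >= 0))
  expect_equal(s$rank, seq_len(nrow(s)))
  expect_equal(sum(s$top_k), min(3L, nrow(s)))

  # ordering agrees with direct abstraction_energy calls
  cls <- hydrogen_equivalence_classes(fx$mol)
  dh <- vapply(cls, function(cl) abstraction_energy(fx$mol, cl)$delta_h,
               numeric(1))
  names(dh) <- vapply(cls, `[[`, numeric(1), "carbon_index")
  expect_equal(unname(dh[as.character(s$carbon_index)]), s$delta_h,
               tolerance = 1e-10)

  # an external energy table overrides the engine and flips the ranking
  tab <- data.frame(carbon_index = 2:6, delta_h = c(5, 4, 3, 2, 1) / 100)
  pred2 <- predict_sites(fx$mol, fx$poses, fx$site, energy_table = tab)
  expect_equal(pred2$sites$carbon_index[1],
               max(pred2$sites$carbon_index))
})

test_that("molecules without candidates give an empty prediction with warning", {
  cf4 <- som_molecule(
    data.frame(element = c("C", "F", "F", "F", "F"),
               x = c(0, 0.76, -0.76, -0.76, 0.76),
               y = c(0, 0.76, -0.76, 0.76, -0.76),
               z = c(0, 0.76, 0.76, -0.76, -0.76)),
    data.frame(i = 1, j = 2:5, order = 1), "CF4")
  poses <- make_pose_set(cf4, list(list(atom = 1L, at = c(0, 0, 5))))
  expect_warning(pred <- predict_sites(cf4, poses, bare_site()),
                 "no candidate")
  expect_equal(nrow(pred$sites), 0L)
})

test_that("the demo pipeline is byte-for-byte deterministic", {
  d1 <- tempfile("demo1"); d2 <- tempfile("demo2")
  p1 <- som_demo(d1)
  p2 <- som_demo(d2)
  expect_identical(readLines(file.path(d1, "prediction.tsv")),
                   readLines(file.path(d2, "prediction.tsv")))
  expect_identical(readLines(file.path(d1, "site.pdb")),
                   readLines(file.path(d2, "site.pdb")))
  expect_identical(readLines(file.path(d1, "poses.sdf")),
                   readLines(file.path(d2, "poses.sdf")))
  expect_gt(nrow(p1$sites), 0L)
})
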