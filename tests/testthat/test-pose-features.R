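test_that("site_heme_distance is plain Euclidean geometry", {
  m <- mol_at(data.frame(element = "C", x = 0, y = 0, z = 5))
  expect_equal(site_heme_distance(m, 1, bare_site()), 5.0)
  m2 <- mol_at(data.frame(element = "C", x = 1, y = 1, z = 1))
  expect_equal(site_heme_distance(m2, 1, bare_site(fe = c(1, 1, 1))), 0.0)
  m3 <- mol_at(data.frame(element = "C", x = 3, y = 4, z = 0))
  expect_equal(site_heme_distance(m3, 1, bare_site()), 5.0)
  m4 <- mol_at(data.frame(element = "O", x = 0, y = 0, z = 1))
  expect_error(site_heme_distance(m4, 1, bare_site()), "not a carbon")
})

test_that("hydrogen-bond detection follows distance and angle criteria", {
  # ligand O-H donor aimed at Ser OG: O at origin, H toward OG, angle ~170
  og <- c(2.86, 0, 0)
  hpos <- c(0.96 * cos(10 * pi / 180), 0.96 * sin(10 * pi / 180), 0)
  m <- som_molecule(data.frame(element = c("O", "H"),
                               x = c(0, hpos[1]), y = c(0, hpos[2]),
                               z = c(0, 0)),
                    data.frame(i = 1, j = 2, order = 1), "hydroxyl",
                    check_hydrogens = FALSE)
  f <- detect_hydrogen_bonds(m, bare_site(fe = c(0, 0, -20), ser_og = og))
  expect_equal(nrow(f), 1L)
  expect_gt(f$angle, 160)

  # stretched beyond the 3.5 A donor-acceptor cutoff: nothing
  f2 <- detect_hydrogen_bonds(m, bare_site(fe = c(0, 0, -20),
                                           ser_og = c(4.2, 0, 0)))
  expect_equal(nrow(f2), 0L)

  # carbonyl O (no attached H) at 2.9 A from water oxygen: distance-only rule
  mo <- mol_at(data.frame(element = "O", x = 0, y = 0, z = 0))
  f3 <- detect_hydrogen_bonds(mo, bare_site(fe = c(0, 0, -20),
                                            water623 = c(0, 2.9, 0)))
  expect_equal(nrow(f3), 1L)
  expect_equal(f3$type, "water_hbond")
  expect_equal(f3$distance, 2.9)
})

test_that("lipophilic contact detection counts C...C pairs", {
  ring <- matrix(c(3.9, 0, 0), 1, 3, dimnames = list("CG", NULL))
  m3c <- mol_at(data.frame(element = c("C", "C", "C"),
                           x = c(0, 0.05, -0.05), y = c(0, 0.1, -0.1),
                           z = c(0, 0.05, -0.05)))
  f <- detect_lipophilic_contacts(m3c, bare_site(fe = c(0, 0, -30),
                                                 phe_ring = ring,
                                                 heme = matrix(c(0, 0, -30), 1)))
  expect_equal(f$partner, "Phe-cluster")

  # everything far away: empty
  f2 <- detect_lipophilic_contacts(m3c, bare_site(fe = c(0, 0, -30),
                                                  phe_ring = ring + 10,
                                                  heme = matrix(c(0, 0, -30), 1)))
  expect_equal(nrow(f2), 0L)

  # contacts with heme atoms only
  heme <- matrix(rep(c(0, 0, 3.8), each = 2), 2, 3, byrow = FALSE)
  heme <- rbind(c(0, 0, 3.8), c(0.5, 0, 3.8), c(-0.5, 0, 3.8))
  m5c <- mol_at(data.frame(element = rep("C", 5),
                           x = c(0, 1, -1, 0.5, -0.5), y = 0, z = 0))
  f3 <- detect_lipophilic_contacts(m5c, bare_site(fe = c(0, 0, 3.8),
                                                  heme = heme))
  expect_equal(f3$partner, "heme")
})

test_that("qualifying_pose_fraction matches the weight formulas exactly", {
  mol <- reference_molecules()$propane
  dists <- c(3, 4, 5, 6, 8, 8.5, 9, 9.5, 10, 11)   # 4 of 10 within [2.5, 7.5]
  poses <- make_pose_set(mol, lapply(dists, function(d)
    list(carbon = 2L, distance = d)))
  site <- bare_site()
  expect_identical(qualifying_pose_fraction(2L, poses, site), 0.4)

  none <- make_pose_set(mol, lapply(8:12, function(d)
    list(carbon = 2L, distance = d)))
  expect_identical(qualifying_pose_fraction(2L, none, site), 0)

  # linear rank weights w_i ~ (11 - i): poses 1-3 inside -> 27/55
  d2 <- c(3, 4, 5, rep(9, 7))
  poses2 <- make_pose_set(mol, lapply(d2, function(d)
    list(carbon = 2L, distance = d)))
  fr <- qualifying_pose_fraction(2L, poses2, site, weights = "linear_rank")
  expect_equal(fr, 27 / 55, tolerance = 1e-12)

  expect_error(qualifying_pose_fraction(2L, list(), site), "empty")
})

test_that("fractions stay in [0,1], hit 1 when all qualify, and are window-monotone", {
  mol <- reference_molecules()$propane
  site <- bare_site()
  set.seed(3)
  for (rep in 1:5) {
    dists <- runif(8, 2, 12)
    poses <- make_pose_set(mol, lapply(dists, function(d)
      list(carbon = 1L, distance = d)))
    for (w in c("uniform", "linear_rank")) {
      fr <- qualifying_pose_fraction(1L, poses, site, weights = w)
      expect_gte(fr, 0); expect_lte(fr, 1)
      fr_wide <- qualifying_pose_fraction(1L, poses, site,
                                          window = c(1, 13), weights = w)
      expect_gte(fr_wide, fr)
      expect_equal(fr_wide, 1)
    }
  }
})

test_that("features and distances are invariant under a common rigid motion", {
  mol <- reference_molecules()$cyclohexanone
  pose <- make_pose_set(mol, list(list(carbon = 3L, distance = 5)))[[1]]
  og <- coords(pose$molecule)[7, ] + c(0, 2.9, 0)
  ring <- matrix(c(0, 0, 8, 1, 0, 8, 0, 1, 8), 3, 3, byrow = TRUE)
  site <- bare_site(ser_og = og, water623 = og + c(1, 1, 0), phe_ring = ring)

  set.seed(11)
  R <- random_rotation(); tv <- c(-3, 12, 0.5)
  move <- function(X) X %*% t(R) + matrix(tv, nrow(X), 3, byrow = TRUE)
  pose2 <- pose
  pose2$molecule <- apply_rigid(pose$molecule, R, tv)
  site2 <- bare_site(fe = as.numeric(R %*% site$fe_position + tv),
                     ser_og = as.numeric(R %*% og + tv),
                     water623 = as.numeric(R %*% site$waters[["623"]] + tv),
                     phe_ring = move(ring))
  site2$heme_atoms <- move(site$heme_atoms)

  expect_equal(site_heme_distance(pose2, 3L, site2),
               site_heme_distance(pose, 3L, site), tolerance = 1e-9)
  f1 <- detect_hydrogen_bonds(pose, site)
  f2 <- detect_hydrogen_bonds(pose2, site2)
  expect_equal(f2$distance, f1$distance, tolerance = 1e-9)
  expect_equal(f2$angle, f1$angle, tolerance = 1e-7)
  l1 <- detect_lipophilic_contacts(pose, site)
  l2 <- detect_lipophilic_contacts(pose2, site2)
  expect_equal(l2$n_contacts, l1$n_contacts)
  expect_equal(l2$min_distance, l1$min_distance, tolerance = 1e-9)
})

test_that("enlarging the H-bond cutoff never removes a feature", {
  mol <- reference_molecules()$cyclohexanone
  pose <- make_pose_set(mol, list(list(carbon = 3L, distance = 5)))[[1]]
  og <- coords(pose$molecule)[7, ] + c(0, 3.3, 0)
  site <- bare_site(ser_og = og, water623 = og + c(0.5, 0.5, 0))
  f_tight <- detect_hydrogen_bonds(pose, site, hbond_criteria(3.4, 120))
  f_loose <- detect_hydrogen_bonds(pose, site, hbond_criteria(3.9, 120))
  key <- function(f) paste(f$ligand_atom, f$partner)
  expect_true(all(key(f_tight) %in% key(f_loose)))
  expect_gte(nrow(f_loose), nrow(f_tight))
})
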