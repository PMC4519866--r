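fake_prediction <- function(carbons) {
  sites <- data.frame(rank = seq_along(carbons), carbon_index = carbons,
                      reaction_type = "aliphatic_hydroxylation",
                      class_id = seq_along(carbons),
                      delta_h = seq_along(carbons) / 100,
                      delta_h_kcal = seq_along(carbons),
                      pose_fraction = 1, dist_ok = TRUE, hbond_ok = TRUE,
                      lipophilic_ok = FALSE, adjacency_derived = FALSE,
                      top_k = seq_along(carbons) <= 3L)
  structure(list(sites = sites, substrate = "fake", k = 3L,
                 config = som_config(), n_poses = 10L),
            class = "som_prediction")
}

test_that("the top-3 rule scores single and multi-site substrates", {
  pred <- fake_prediction(c(6, 2, 9, 4))
  known_r3 <- data.frame(carbon_index = 9,
                         reaction_type = "aliphatic_hydroxylation")
  expect_true(score_substrate(pred, known_r3)$correct)

  known_r4 <- data.frame(carbon_index = 4,
                         reaction_type = "aliphatic_hydroxylation")
  expect_false(score_substrate(pred, known_r4)$correct)
  # ... unless k is raised
  expect_true(score_substrate(pred, known_r4, k = 4)$correct)

  # multi-metabolite substrate: one hit suffices
  multi <- data.frame(carbon_index = c(12, 2),
                      reaction_type = "aliphatic_hydroxylation")
  expect_true(score_substrate(pred, multi)$correct)

  expect_error(score_substrate(pred, data.frame(carbon_index = 40),
                               n_atoms_substrate = 17),
               "atom-label map")
})

test_that("verdict aggregation reproduces ratio arithmetic", {
  v <- rbind(
    verdicts_from_counts(data.frame(reaction_type = "aliphatic_hydroxylation",
                                    nc = 20, n = 25)),
    verdicts_from_counts(data.frame(reaction_type = "n_dealkylation",
                                    nc = 3, n = 3)))
  rep <- aggregate_verdicts(v)
  t <- rep$table
  expect_equal(t$ratio[t$reaction_type == "aliphatic_hydroxylation"], 80.00)
  expect_equal(t$ratio[t$reaction_type == "n_dealkylation"], 100.00)
  expect_equal(t$nc[t$reaction_type == "overall"], 23)
  expect_equal(t$n[t$reaction_type == "overall"], 28)
  expect_equal(t$ratio[t$reaction_type == "overall"], 82.14)

  zero <- aggregate_verdicts(verdicts_from_counts(
    data.frame(reaction_type = "aliphatic_hydroxylation", nc = 0, n = 5)))
  expect_equal(zero$table$ratio, c(0, 0))
})

test_that("aggregation identities hold", {
  # when reaction types partition substrates, type Nc sums to overall Nc
  set.seed(23)
  for (rep_i in 1:5) {
    v <- data.frame(
      substrate_id = paste0("s", 1:20),
      reaction_type = sample(c("aliphatic_hydroxylation", "n_dealkylation"),
                             20, replace = TRUE),
      correct = sample(c(TRUE, FALSE), 20, replace = TRUE))
    t <- aggregate_verdicts(v)$table
    expect_equal(t$nc[t$reaction_type == "overall"],
                 sum(t$nc[t$reaction_type != "overall"]))
    # recomputing the ratio from reported Nc and N matches
    expect_equal(t$ratio, round(100 * t$nc / t$n, 2))
  }
})

test_that("raising k never flips a correct verdict to incorrect", {
  set.seed(31)
  for (rep_i in 1:10) {
    pred <- fake_prediction(sample(1:15, 6))
    known <- data.frame(carbon_index = sample(1:15, 2),
                        reaction_type = "aliphatic_hydroxylation")
    prev <- FALSE
    for (k in 1:6) {
      cur <- score_substrate(pred, known, k = k)$correct
      if (prev) expect_true(cur)
      prev <- cur
    }
  }
})

test_that("annotation tables read and map to atom indices", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("substrate_id\tcarbon_label\treaction_type\tset_id",
               "testosterone\tC6\taliphatic_hydroxylation\ttraining",
               "testosterone\tC2\taliphatic_hydroxylation\ttraining"), tf)
  ann <- read_annotations(tf)
  expect_equal(nrow(ann), 2L)
  mapped <- map_annotation_labels(ann, c(C6 = 6L, C2 = 2L))
  expect_equal(mapped$carbon_index, c(6L, 2L))
  expect_error(map_annotation_labels(ann, c(C6 = 6L)), "C2")
})

test_that("the shipped benchmark counts table is consistent", {
  counts <- reported_accuracy_counts()
  expect_true(all(counts$nc <= counts$n))
  tr <- counts[counts$model == "mechanism_based" & counts$set_id == "training", ]
  expect_equal(sum(tr$n), 28L)
  te <- counts[counts$model == "mechanism_based" & counts$set_id == "test", ]
  expect_equal(sum(te$n), 22L)
})
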