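make_scores <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  tibble::tibble(experiment_key = sprintf("P:%d:1:1", seq_len(n)),
                 fused_p = runif(n))
}

test_that("detection partitions scored experiments exactly", {
  n <- 100
  sc <- make_scores(n, seed = 2)
  user <- tibble::tibble(experiment_key = sc$experiment_key,
                         user_binary = ifelse(sc$fused_p >= 0.5, "crystal", "other"))
  conflict_at <- c(3, 10, 20, 41, 55, 76, 99)
  user$user_binary[conflict_at] <- ifelse(user$user_binary[conflict_at] == "crystal",
                                          "other", "crystal")
  det <- detect_discrepancies(sc, user, tau = 0.5)
  expect_equal(nrow(det$agreements), 93)
  expect_equal(nrow(det$discrepancies), 7)
  expect_setequal(det$discrepancies$experiment_key, sc$experiment_key[conflict_at])
  expect_true(all(det$discrepancies$model_binary != det$discrepancies$user_binary))
  expect_equal(unique(det$discrepancies$status), "open")
  # experiments without a user score are neither agreement nor discrepancy
  det2 <- detect_discrepancies(sc, user[-(1:5), ], tau = 0.5)
  expect_equal(nrow(det2$unscored), 5)
  expect_equal(nrow(det2$agreements) + nrow(det2$discrepancies), 95)
  expect_error(detect_discrepancies(dplyr::bind_rows(sc, sc[1, ]), user),
               class = "dropvision_error_duplicate_keys")
})

test_that("detection accepts 7-class user scores through the binary mapping", {
  sc <- tibble::tibble(experiment_key = c("a", "b"), fused_p = c(0.9, 0.9))
  user <- tibble::tibble(experiment_key = c("a", "b"),
                         user_score = c("single_crystals", "precipitate"))
  det <- detect_discrepancies(sc, user)
  expect_equal(det$agreements$experiment_key, "a")
  expect_equal(det$discrepancies$experiment_key, "b")
})

test_that("adjudication resolves unanimity and excludes everything else", {
  sc <- make_scores(6, seed = 4)
  user <- tibble::tibble(experiment_key = sc$experiment_key,
                         user_binary = ifelse(sc$fused_p >= 0.5, "other", "crystal"))
  det <- detect_discrepancies(sc, user)
  q <- det$discrepancies
  labels <- dplyr::bind_rows(
    tibble::tibble(experiment_key = q$experiment_key[1], curator = c("c1", "c2"),
                   label = "crystal"),
    tibble::tibble(experiment_key = q$experiment_key[2], curator = c("c1", "c2"),
                   label = c("crystal", "other")),
    tibble::tibble(experiment_key = q$experiment_key[3], curator = "c1",
                   label = "uncertain"),
    tibble::tibble(experiment_key = q$experiment_key[-(1:3)], curator = "c1",
                   label = "other")
  )
  adj <- adjudicate(q, labels)
  expect_equal(adj$resolved$curator_label[adj$resolved$experiment_key ==
                                            q$experiment_key[1]], "crystal")
  expect_setequal(adj$excluded$experiment_key, q$experiment_key[2:3])
  expect_setequal(adj$excluded$reason,
                  c("curator_conflict", "uncertain_or_unusable"))
  expect_equal(nrow(adj$resolved) + nrow(adj$excluded), nrow(q))
  # majority consensus resolves two-vs-one conflicts instead
  labels3 <- tibble::tibble(experiment_key = q$experiment_key[2],
                            curator = c("c1", "c2", "c3"),
                            label = c("crystal", "crystal", "other"))
  adj2 <- adjudicate(q[2, ], labels3, consensus = "majority")
  expect_equal(adj2$resolved$curator_label, "crystal")
  expect_error(adjudicate(q, dplyr::mutate(labels, label = "meh")),
               class = "dropvision_error_unknown_label")
  expect_error(adjudicate(q, labels[-(1:2), ]),
               class = "dropvision_error_unlabelled")
})

test_that("assembly reconciles the accounting and respects the test set", {
  n <- 100
  sc <- make_scores(n, seed = 6)
  user <- tibble::tibble(experiment_key = sc$experiment_key,
                         user_binary = ifelse(sc$fused_p >= 0.5, "crystal", "other"))
  flip <- 1:10
  user$user_binary[flip] <- ifelse(user$user_binary[flip] == "crystal",
                                   "other", "crystal")
  det <- detect_discrepancies(sc, user)
  q <- det$discrepancies
  labels <- dplyr::bind_rows(
    tibble::tibble(experiment_key = q$experiment_key[1:6], curator = "c1",
                   label = ifelse(q$model_binary[1:6] == "crystal",
                                  "other", "crystal")),
    tibble::tibble(experiment_key = q$experiment_key[7:10], curator = "c1",
                   label = "unusable")
  )
  adj <- adjudicate(q, labels)
  man <- make_manifest(n, modalities = "visible")
  man$experiment_key <- sc$experiment_key  # align keys with the score table
  asm <- assemble_version(det, adj, man, test_manifest = NULL,
                          version_tag = "v2", parent = "v1")
  acc <- asm$accounting
  expect_equal(acc$n_scored, 100)
  expect_equal(acc$n_discrepancies, 10)
  expect_equal(acc$n_unresolved, 4)
  expect_equal(acc$n_included_in_training, 96)
  expect_equal(acc$n_agreements + acc$n_discrepancies, acc$n_scored)
  expect_equal(acc$n_model_false_crystal + acc$n_user_missed +
                 acc$n_model_missed + acc$n_user_false_crystal +
                 acc$n_unresolved, acc$n_discrepancies)
  expect_equal(length(unique(asm$version$manifest$experiment_key)), 96)
  # held-out experiments are excluded and the exclusion is accounted
  test_man <- man[man$experiment_key %in% sc$experiment_key[50:59], ]
  asm2 <- assemble_version(det, adj, man, test_manifest = test_man)
  expect_equal(asm2$accounting$n_excluded_test_overlap,
               sum(sc$experiment_key[50:59] %in%
                     c(det$agreements$experiment_key, adj$resolved$experiment_key)))
  expect_false(any(test_man$experiment_key %in%
                     asm2$version$manifest$experiment_key))
})

test_that("an empty queue assembles to the agreements alone", {
  sc <- make_scores(10, seed = 9)
  user <- tibble::tibble(experiment_key = sc$experiment_key,
                         user_binary = ifelse(sc$fused_p >= 0.5, "crystal", "other"))
  det <- detect_discrepancies(sc, user)
  expect_equal(nrow(det$discrepancies), 0)
  adj <- adjudicate(det$discrepancies,
                    tibble::tibble(experiment_key = character(0),
                                   curator = character(0), label = character(0)))
  man <- make_manifest(10, modalities = "visible")
  man$experiment_key <- sc$experiment_key
  asm <- assemble_version(det, adj, man)
  expect_equal(asm$accounting$n_discrepancies, 0)
  expect_equal(asm$accounting$n_included_in_training, 10)
  # re-detecting with unchanged tables reproduces the identical partition
  det2 <- detect_discrepancies(sc, user)
  expect_identical(det2, det)
})

test_that("the display colour scale is monotone with the stated anchors", {
  expect_equal(colour_scale(0), 0)
  expect_equal(colour_scale(1), 1)
  expect_equal(colour_scale(0.4), 0.1)
  grid <- seq(0, 1, by = 0.01)
  v <- colour_scale(grid)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v[grid <= 0.4] <= 0.1 + 1e-12))
  expect_gt(colour_scale(0.41), colour_scale(0.39))
  expect_error(colour_scale(1.1), class = "dropvision_error_config")
  expect_error(colour_scale(-0.1), class = "dropvision_error_config")
})
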