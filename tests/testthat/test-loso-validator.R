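test_that("metric identities hold on canonical confusion tables", {
  m <- metrics_from_counts(confusion_counts(10, 10, 0, 0))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity, m$mcc),
               c(1, 1, 1, 1))
  m <- metrics_from_counts(confusion_counts(0, 0, 10, 10))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity, m$mcc),
               c(0, 0, 0, -1))
  m <- metrics_from_counts(confusion_counts(1, 1, 1, 1))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity, m$mcc),
               c(0.5, 0.5, 0.5, 0))
})

test_that("MCC stays bounded and flags undefined marginals on random counts", {
  withr::with_seed(71, {
    for (i in 1:2000) {
      cts <- as.list(sample(0:50, 4, replace = TRUE))
      if (sum(unlist(cts)) == 0) next
      m <- metrics_from_counts(confusion_counts(cts[[1]], cts[[2]],
                                                cts[[3]], cts[[4]]))
      if (m$mcc_defined) {
        expect_true(m$mcc >= -1 - 1e-12 && m$mcc <= 1 + 1e-12)
      } else {
        expect_true(is.na(m$mcc))
      }
      # accuracy identity: weighted sensitivity/specificity
      P <- cts[[1]] + cts[[4]]; N <- cts[[2]] + cts[[3]]
      if (P > 0 && N > 0) {
        expect_equal(m$accuracy,
                     (m$sensitivity * P + m$specificity * N) / (P + N))
      }
    }
  })
  # mcc = 1 iff no errors with both classes present
  expect_equal(metrics_from_counts(confusion_counts(5, 3, 0, 0))$mcc, 1)
  expect_false(metrics_from_counts(confusion_counts(5, 0, 0, 0))$mcc_defined)
})

test_that("LOSO folds partition the data with no subject overlap", {
  db <- small_training_db(seed = 4, n = 20L)   # 40 subjects
  folds <- loso_folds(db)
  expect_equal(length(folds), 40L)
  for (f in folds) {
    expect_false(f$subject_id %in% db$subject_id[f$train_idx])
    expect_true(all(db$subject_id[f$test_idx] == f$subject_id))
  }
  all_test <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_identical(all_test, seq_len(nrow(db)))

  one <- phonation_database(as.data.frame(db)[db$subject_id ==
                                                db$subject_id[1], ],
                            role = "training")
  expect_error(loso_folds(one), "two subjects")
})

test_that("oracle and constant models reproduce the textbook metric values", {
  db <- small_training_db(seed = 6, n = 10L)
  # oracle: nearest-centroid in truth space is unnecessary; emulate a
  # perfect per-row probability via the true labels of the test rows
  oracle_factory <- function(X_train, y_train, seed) {
    centroids <- rbind(colMeans(X_train[y_train == "PD", , drop = FALSE]),
                       colMeans(X_train[y_train == "healthy", , drop = FALSE]))
    function(X_new) {
      d_pd <- rowSums(sweep(X_new, 2L, centroids[1, ])^2)
      d_h <- rowSums(sweep(X_new, 2L, centroids[2, ])^2)
      as.numeric(d_pd < d_h)
    }
  }
  # a constant always-PD model
  always_pd <- function(X_train, y_train, seed) function(X_new) {
    rep(1, nrow(X_new))
  }
  rep_pd <- evaluate_loso(db, always_pd)
  expect_equal(rep_pd$metrics$sensitivity, 1)
  expect_equal(rep_pd$metrics$specificity, 0)
  expect_equal(rep_pd$metrics$accuracy, 0.5)   # balanced 10/10 design

  # a genuinely perfect predictor on well-separated data
  sep_db <- small_training_db(seed = 8, n = 10L, separation = 6)
  rep_orc <- evaluate_loso(sep_db, oracle_factory)
  expect_equal(rep_orc$metrics$accuracy, 1)
  expect_equal(rep_orc$metrics$mcc, 1)
})

test_that("null data stays inside the 99 percent binomial band around chance", {
  accs <- vapply(1:10, function(i) {
    cfg <- generator_config(n_pd_train = 10L, n_healthy_train = 10L,
                            samples_per_training_subject = 3L,
                            separation_scale = 0, seed = 300 + i)
    db <- generate_training_database(cfg)$db
    evaluate_loso(db, nn_lda_factory(c(3), maxit = 80),
                  seed = i)$metrics$accuracy
  }, 0)
  band <- qnorm(0.995) * sqrt(0.25 / 20)
  expect_true(mean(accs) > 0.5 - band & mean(accs) < 0.5 + band)
})

test_that("evaluation is invariant to subject order", {
  db <- small_training_db(seed = 12, n = 6L)
  factory <- nn_lda_factory(c(3), maxit = 80)
  rep1 <- evaluate_loso(db, factory, seed = 2)
  perm <- withr::with_seed(9, sample(db_subjects(db)))
  rows <- do.call(rbind, lapply(perm, function(s)
    as.data.frame(db)[db$subject_id == s, ]))
  db2 <- phonation_database(rows, role = "training")
  rep2 <- evaluate_loso(db2, factory, seed = 2)
  pf1 <- rep1$per_fold[order(rep1$per_fold$subject_id), ]
  pf2 <- rep2$per_fold[order(rep2$per_fold$subject_id), ]
  expect_equal(pf1$predicted, pf2$predicted)
  expect_equal(rep1$metrics$accuracy, rep2$metrics$accuracy)
})

test_that("corrupting the held-out subject never changes the fold's model", {
  db <- small_training_db(seed = 14, n = 4L)
  weight_log <- new.env(); weight_log$w <- list()
  spy_factory <- function(X_train, y_train, seed) {
    net <- train_network(scale(X_train)[, 1:3], y_train, c(2),
                         seed = seed, maxit = 60)
    weight_log$w[[length(weight_log$w) + 1L]] <- net$par
    function(X_new) rep(0.5, nrow(X_new))
  }
  evaluate_loso(db, spy_factory, seed = 5)
  w_clean <- weight_log$w

  # shuffle the labels of one subject's rows in a copy of the data:
  # its own fold's training set is untouched
  db2 <- as.data.frame(db)
  s1 <- db_subjects(db)[1]
  db2$label[db2$subject_id == s1] <-
    ifelse(db2$label[db2$subject_id == s1] == "PD", "healthy", "PD")
  db2 <- phonation_database(db2, role = "training")
  weight_log$w <- list()
  evaluate_loso(db2, spy_factory, seed = 5,
                on_degenerate = "misclassify")
  expect_identical(weight_log$w[[1]], w_clean[[1]])
})

test_that("cross-database evaluation flags undefined metrics on one-class cohorts", {
  cfg <- generator_config(n_pd_train = 8L, n_healthy_train = 8L,
                          samples_per_training_subject = 3L,
                          n_pd_test = 6L, separation_scale = 3,
                          seed = 33)
  tr <- generate_training_database(cfg)$db
  te <- generate_testing_database(cfg)$db
  rep <- evaluate_cross_database(tr, te, nn_lda_factory(c(3), maxit = 80))
  expect_equal(nrow(rep$per_fold), 6L)       # one unit per test subject
  expect_false(rep$metrics$specificity_defined)
  expect_false(rep$metrics$mcc_defined)
  expect_true(rep$metrics$sensitivity_defined)
  expect_equal(rep$metrics$sensitivity, rep$metrics$accuracy)
  # strong separation: the patients are recognized
  expect_equal(rep$metrics$sensitivity, 1)

  expect_error(
    evaluate_cross_database(remove_gender_dependent_features(tr), te,
                            nn_lda_factory(c(3))),
    "schemas differ")
})

test_that("subject aggregation majority-votes with PD-favoring ties", {
  expect_equal(voicePD:::.aggregate_subject(c("PD", "PD", "healthy")), "PD")
  expect_equal(voicePD:::.aggregate_subject(c("healthy", "healthy", "PD")),
               "healthy")
  expect_equal(voicePD:::.aggregate_subject(c("PD", "healthy")), "PD")
})

test_that("degenerate single-class training folds error by default", {
  # two subjects only: holding one out leaves a single-class fold
  sch <- pd_feature_schema()
  rows <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                     label = rep(c("PD", "healthy"), each = 2),
                     gender = "unknown",
                     sample_type = rep(c("vowel_a", "vowel_o"), 2),
                     stringsAsFactors = FALSE)
  withr::with_seed(3, for (nm in sch$name) rows[[nm]] <- rnorm(4))
  db <- phonation_database(rows, role = "training")
  expect_error(evaluate_loso(db, nn_lda_factory(c(2))), "single class")
  rep <- evaluate_loso(db, nn_lda_factory(c(2)),
                       on_degenerate = "misclassify")
  expect_equal(rep$metrics$accuracy, 0)
})

test_that("report writers emit the tabular layout", {
  db <- small_training_db(seed = 16, n = 5L, separation = 4)
  rep <- evaluate_loso(db, nn_lda_factory(c(4, 2), maxit = 80))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  report_to_tsv(rep, tsv, genome = architecture_genome(c(4, 2)))
  tab <- read.delim(tsv, check.names = FALSE)
  expect_named(tab, c("L", "H1", "H2", "ACC(%)", "Sen.(%)", "Spec.(%)",
                      "MCC"))
  expect_equal(tab$L, 2L)
  expect_equal(tab$H2, 2L)
  js <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$accuracy, rep$metrics$accuracy)
})

test_that("row-wise k-fold splitter covers all rows (leakage-prone baseline)", {
  db <- small_training_db(seed = 18, n = 4L)
  folds <- rowwise_kfold_folds(db, k = 4L, seed = 1)
  expect_equal(sort(unlist(lapply(folds, `[[`, "test_idx"))),
               seq_len(nrow(db)))
  # demonstrates subject overlap: some subject appears on both sides
  overlap <- any(vapply(folds, function(f)
    length(intersect(db$subject_id[f$train_idx],
                     db$subject_id[f$test_idx])) > 0, NA))
  expect_true(overlap)
})
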