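test_that("rank-based AUC counts concordant pairs with ties at one half", {
  expect_equal(auc_scores(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc_scores(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_scores(rep(1, 3), rep(1, 4)), 0.5)
  expect_error(auc_scores(numeric(), 1), "non-empty")

  withr::with_seed(2, {
    for (rep in 1:5) {
      pos <- rnorm(7)
      neg <- rnorm(9)
      expect_equal(auc_scores(pos, neg) + auc_scores(neg, pos), 1)
    }
  })
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (rep in 1:5) {
      pos <- rnorm(20, mean = 0.5)
      neg <- rnorm(30)
      ref <- as.numeric(pROC::auc(
        c(rep(1, 20), rep(0, 30)), c(pos, neg),
        direction = "<", quiet = TRUE
      ))
      expect_equal(auc_scores(pos, neg), ref)
    }
  })
})

test_that("the contrast score rewards top-ranked verified candidates", {
  expect_equal(contrast_score(1:7), 1)
  expect_equal(contrast_score(2), exp(1 / 2 - 1))
  expect_error(contrast_score(integer()), "non-empty")
  expect_error(contrast_score(c(1, 0)), "positive integers")
  expect_error(contrast_score(c(1.5, 2)), "positive integers")

  # strictly decreasing when any single rank worsens
  base <- c(1, 3, 5, 8)
  for (i in seq_along(base)) {
    worse <- base
    worse[i] <- worse[i] + 1
    expect_lt(contrast_score(worse), contrast_score(base))
  }
})

test_that("candidate ranking excludes known pairs and breaks ties stably", {
  ld <- cbind(d1 = c(1, 0, 0, 0), d2 = c(1, 1, 1, 1))
  rownames(ld) <- paste0("l", 1:4)
  scores <- cbind(d1 = c(0, 0.9, 0.2, 0.5), d2 = rep(0, 4))
  rownames(scores) <- rownames(ld)

  expect_identical(nrow(rank_candidates(scores, "d2", ld)), 0L)

  ranked <- rank_candidates(scores, "d1", ld)
  expect_identical(ranked$lncrna, c("l2", "l4", "l3"))
  expect_identical(ranked$rank, 1:3)

  tie_scores <- scores
  tie_scores[, "d1"] <- c(0, 0.5, 0.5, 0.1)
  tied <- rank_candidates(tie_scores, "d1", ld)
  expect_identical(tied$lncrna, c("l2", "l3", "l4"))
})

test_that("cross-validation is deterministic under a fixed seed", {
  fit <- fvtlda_fit(fixture_data(), "mlr", fixture_params())
  a <- cv_associations(fit, "kfold", k = 5, seed = 3)
  b <- cv_associations(fit, "kfold", k = 5, seed = 3)
  expect_identical(a$positives, b$positives)
  expect_error(cv_associations(fit, "kfold", k = 5000), "fold count")
})

test_that("singleton folds reproduce leave-one-out exactly", {
  small <- as_fvtlda_data(
    simulate_tripartite(n_mirna = 15, n_lncrna = 8, n_disease = 6,
                        n_groups = 2, seed = 5)
  )
  fit <- fvtlda_fit(small, "mlr", fixture_params())
  loo <- cv_associations(fit, "loocv")
  n_known <- sum(small$ld)
  kfold_n <- cv_associations(fit, "kfold", k = n_known, seed = 1)
  expect_equal(mean(loo$summary$auc), mean(kfold_n$summary$auc))
  expect_equal(
    dplyr::arrange(loo$positives[, c("lncrna", "disease", "concordance")],
                   lncrna, disease),
    dplyr::arrange(kfold_n$positives[, c("lncrna", "disease", "concordance")],
                   lncrna, disease)
  )
})

test_that("repeated k-fold reports spread across partitions", {
  fit <- fvtlda_fit(fixture_data(), "mlr", fixture_params())
  cv <- cv_associations(fit, "kfold", k = 5, repeats = 3, seed = 2)
  expect_identical(nrow(cv$summary), 3L)
  expect_gt(glance(cv)$auc_sd, 0)
})

test_that("ROC points are monotone and integrate to the AUC", {
  fit <- fvtlda_fit(fixture_data(), "mlr", fixture_params())
  cv <- cv_associations(fit, "loocv")
  pts <- roc_points(cv)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(range(pts$fpr), c(0, 1))
  auc_step <- sum(diff(pts$fpr) * head(pts$tpr, -1))
  expect_equal(auc_step, mean(cv$summary$auc), tolerance = 1e-8)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("case studies report candidates, verified ranks and the score", {
  data <- fixture_data()
  fit <- fvtlda_fit(data, "mlr", fixture_params())
  disease <- colnames(fit$ld)[1]
  unknown <- rownames(fit$ld)[fit$ld[, disease] == 0]
  cs <- case_study(fit, disease, top = 5, verified = unknown[1:2])
  expect_identical(nrow(cs$candidates), 5L)
  expect_identical(cs$candidates$rank, 1:5)
  expect_length(cs$verified_ranks, 2)
  expect_equal(cs$contrast_score, contrast_score(cs$verified_ranks))
  expect_error(case_study(fit, "no-such-disease"), "not in")

  plain <- case_study(fit, disease, top = 3)
  expect_true(is.na(plain$contrast_score))
})

test_that("the shipped benchmark table has one rank list per method", {
  bench <- case_study_benchmark()
  expect_setequal(unique(bench$disease),
                  c("gastric cancer", "leukemia", "lung cancer"))
  counts <- dplyr::count(bench, disease, method)
  expect_identical(nrow(counts), 9L)
  expect_true(all(counts$n %in% c(8L, 10L)))
  scores <- benchmark_contrast_scores()
  expect_identical(nrow(scores), 9L)
  expect_true(all(scores$contrast_score > 0 & scores$contrast_score <= 1))
})
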