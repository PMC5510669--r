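labs4 <- c("cSDH", "cSDH", "HC", "HC")

test_that("ROC enumeration matches the hand-derived operating points", {
  roc <- roc_curve(c(2, 3, 0, 1), labs4)
  expect_equal(roc$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$tpr))
})

test_that("AUC reproduces worked examples and symmetries", {
  expect_equal(auc(c(2, 3, 0, 1), labs4), 1)
  expect_equal(auc(c(1, 3, 2, 0), labs4), 0.75)
  expect_equal(auc(c(1, 1), c("cSDH", "HC")), 0.5)    # tie convention
  # all scores equal: two-point curve, chance area
  roc <- roc_curve(rep(0.3, 4), labs4)
  expect_equal(nrow(roc), 2)
  expect_equal(auc(rep(0.3, 4), labs4), 0.5)
  # negating scores mirrors the curve
  set.seed(11)
  sc <- rnorm(12); lb <- rep(c("cSDH", "HC"), 6)
  expect_equal(auc(-sc, lb), 1 - auc(sc, lb), tolerance = 1e-12)
  expect_error(roc_curve(1:3, rep("cSDH", 3)), "each class")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  set.seed(12)
  for (i in 1:200) {
    n_pos <- sample(1:8, 1); n_neg <- sample(1:8, 1)
    sc <- sample(seq(-1, 1, by = 0.25), n_pos + n_neg, replace = TRUE)  # force ties
    lb <- c(rep("cSDH", n_pos), rep("HC", n_neg))
    expect_equal(auc(sc, lb), pair_count_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("specificity at full sensitivity counts negatives strictly below the minimum positive", {
  sc <- c(rep(1, 5), seq(-20, -1), 0.5)
  lb <- c(rep("cSDH", 5), rep("HC", 21))
  expect_equal(specificity_at_full_sensitivity(sc[1:25], lb[1:25]), 1)
  # 5 of 20 negatives strictly below the minimum positive
  sc2 <- c(rep(0, 5), rep(-1, 5), rep(0.2, 15))
  lb2 <- c(rep("cSDH", 5), rep("HC", 20))
  expect_equal(specificity_at_full_sensitivity(sc2, lb2), 0.25)
  # a negative tied with the minimum positive is a false positive
  expect_equal(specificity_at_full_sensitivity(c(1, 2, 1, 0),
                                               labs4), 0.5)
  # agreement with the ROC curve: max specificity among points at TPR 1
  set.seed(13)
  sc3 <- rnorm(20); lb3 <- rep(c("cSDH", "HC"), 10)
  roc <- roc_curve(sc3, lb3)
  expect_equal(specificity_at_full_sensitivity(sc3, lb3),
               max(1 - roc$fpr[roc$tpr == 1]))
})

test_that("score translation leaves ROC, AUC and specificity unchanged", {
  set.seed(14)
  sc <- rnorm(16); lb <- rep(c("cSDH", "HC"), 8)
  for (shift in c(-3, 0.7)) {
    expect_equal(auc(sc + shift, lb), auc(sc, lb), tolerance = 1e-12)
    expect_equal(specificity_at_full_sensitivity(sc + shift, lb),
                 specificity_at_full_sensitivity(sc, lb))
    expect_equal(roc_curve(sc + shift, lb)[, c("fpr", "tpr")],
                 roc_curve(sc, lb)[, c("fpr", "tpr")])
  }
})

test_that("leave-one-out matches a hand-rolled fit/score loop", {
  coh <- generate_cohort(synthetic_config(n_patients = 3, n_controls = 3,
                                          freq_start = 0.1, freq_stop = 0.5,
                                          freq_step = 0.1, seed = 3))
  cfg <- classifier_config(f_lo = 0.1, f_hi = 0.5)
  ev <- loo_cross_validate(coh, cfg)
  X <- cohort_features(coh, cfg$mask, cfg$f_lo, cfg$f_hi)
  labs <- attr(X, "labels")
  manual <- vapply(1:6, function(i) {
    tr <- X[, -i, drop = FALSE]
    tl <- labs[-i]
    m <- fit_subspace(tr[, tl == "cSDH", drop = FALSE],
                      tr[, tl == "HC", drop = FALSE], cfg)
    decision_value(m, X[, i])
  }, 1)
  expect_equal(ev$scores$score, manual, tolerance = 1e-12)
  expect_equal(ev$auc, auc(manual, labs), tolerance = 1e-12)
})

test_that("leave-one-out scores are invariant to subject ordering", {
  coh <- generate_cohort(small_config(seed = 5))
  cfg <- classifier_config(f_lo = 0.1, f_hi = 1.0)
  ev1 <- loo_cross_validate(coh, cfg)
  perm <- c(7, 2, 11, 4, 1, 12, 3, 10, 5, 8, 9, 6)
  coh2 <- coh
  coh2$subjects <- coh$subjects[perm]
  ev2 <- loo_cross_validate(coh2, cfg)
  m <- match(ev1$scores$subject_id, ev2$scores$subject_id)
  expect_equal(ev2$scores$score[m], ev1$scores$score, tolerance = 1e-10)
  expect_equal(ev2$auc, ev1$auc, tolerance = 1e-10)
})

test_that("perfectly separated cohorts evaluate to AUC 1 and full specificity", {
  sc <- c(1:20, -(20:1))
  lb <- c(rep("cSDH", 20), rep("HC", 20))
  expect_equal(auc(sc, lb), 1)
  expect_equal(specificity_at_full_sensitivity(sc, lb), 1)
})

test_that("leave-one-out refuses classes too small for the rank", {
  coh <- generate_cohort(synthetic_config(n_patients = 2, n_controls = 4,
                                          freq_start = 0.1, freq_stop = 0.5,
                                          freq_step = 0.1, seed = 2))
  expect_error(loo_cross_validate(coh, classifier_config(rank = 2, f_lo = 0.1,
                                                         f_hi = 0.5)),
               "cSDH")
})

test_that("interval enumeration matches the closed-form count", {
  expect_equal(nrow(enumerate_intervals(seq(0.10, 1.95, by = 0.05), 0.40)), 465)
  # minimum width equal to the span leaves exactly one interval
  expect_equal(nrow(enumerate_intervals(seq(0.10, 1.95, by = 0.05), 1.85)), 1)
  grid <- seq(0.1, 0.5, by = 0.1)
  # brute-force oracle
  brute <- sum(outer(grid, grid, function(a, b) b - a >= 0.2 - 0.05))
  expect_equal(nrow(enumerate_intervals(grid, 0.2)), brute)
})

test_that("the sweep selects rank and interval with deterministic tie-breaks", {
  coh <- generate_cohort(small_config(seed = 8))
  sw <- sweep_model_selection(coh, f_start = 0.1, f_stop = 1.0, step = 0.3,
                              min_width = 0.3, ranks = 1:2)
  expect_equal(nrow(sw$table), 2 * nrow(enumerate_intervals(seq(0.1, 1.0, by = 0.3), 0.3)))
  expect_true(sw$selected_rank %in% 1:2)
  # the selected row maximizes specificity at the selected rank
  at_rank <- sw$table[sw$table$rank == sw$selected_rank, ]
  expect_equal(sw$selected_spec_at_full_sens, max(at_rank$spec_at_full_sens))
  # mean-AUC rank selection honored
  expect_equal(unname(which.max(sw$mean_auc_by_rank)),
               unname(which(sort(unique(sw$table$rank)) == sw$selected_rank)))
  expect_error(sweep_model_selection(coh, f_start = 0.1, f_stop = 1.0,
                                     step = 0.3, min_width = 0.1), "min_width")
})

test_that("the sweep moves the selected interval off a signal-free low band", {
  # lesion contrast confined to >= 0.75 GHz; at a noise level where diluting
  # the features with the dead band measurably costs specificity, the sweep
  # should drop the bottom of the band. Full exclusion of the dead band is
  # not implied: once the remaining dead dimensions are performance-neutral,
  # the wider-interval tie-break deliberately keeps them.
  n_rep <- 20
  flo <- vapply(seq_len(n_rep), function(s) {
    coh <- generate_cohort(synthetic_config(seed = 1000 + s,
                                            lesion_f_min = 0.75,
                                            noise_sd = 0.15))
    sw <- sweep_model_selection(coh, f_start = 0.10, f_stop = 1.95,
                                step = 0.25, min_width = 0.50, ranks = 1)
    sw$selected_interval[["f_lo"]]
  }, 1)
  expect_gte(sum(flo > 0.10 + 1e-9), 0.8 * n_rep)
})
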