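test_that("AUC equals brute-force pair counting, ties included", {
  # worked example: 3 of 4 discordant-free pairs
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(compute_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(compute_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(compute_auc(1:4, rep(1, 4)), "both classes")

  pair_oracle <- function(scores, labels) {
    s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
    tot <- 0
    for (a in s1) for (b in s0) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
    tot / (length(s1) * length(s0))
  }
  withr::with_seed(101, {
    for (i in seq_len(200)) {
      n <- sample(4:25, 1)
      labels <- c(0, 1, sample(0:1, n - 2, TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, TRUE)  # heavy ties
      expect_equal(compute_auc(scores, labels), pair_oracle(scores, labels))
    }
  })
})

test_that("Wilcoxon exact p equals full enumeration for all n, m <= 8", {
  enum_oracle <- function(a, b) {
    r <- rank(c(a, b)); n <- length(a)
    sums <- utils::combn(r, n, sum)
    W <- sum(r[seq_len(n)])
    min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
  }
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  withr::with_seed(5, {
    for (n in 1:8) for (m in c(1, 4, 8)) {
      a <- sample(1:6, n, TRUE)   # ties across and within samples
      b <- sample(1:6, m, TRUE)
      got <- wilcoxon_rank_sum(a, b)
      expect_equal(got$p_value, enum_oracle(a, b), tolerance = 1e-12,
                   info = paste("n =", n, "m =", m))
    }
  })
})

test_that("Wilcoxon agrees with the classical test where comparable", {
  withr::with_seed(6, {
    a <- rnorm(7); b <- rnorm(6) + 0.5   # tie-free
    got <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    # large samples: normal approximation with tie correction
    a2 <- round(rnorm(40), 1); b2 <- round(rnorm(35, 0.3), 1)
    got2 <- wilcoxon_rank_sum(a2, b2)
    ref2 <- stats::wilcox.test(a2, b2, exact = FALSE, correct = FALSE)
    expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-6)
  })
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("precision and recall count the confusion table at 0.5", {
  # TP = 3, FP = 1, FN = 2
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.3, 0.1, 0.1)
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0)
  pr <- compute_precision_recall(scores, labels)
  expect_equal(unname(pr), c(0.75, 0.6))
  # threshold 0: everyone positive
  pr0 <- compute_precision_recall(scores, labels, threshold = 0)
  expect_equal(unname(pr0), c(mean(labels), 1))
  # threshold above all scores: no positives, precision undefined
  expect_warning(pr1 <- compute_precision_recall(scores, labels,
                                                 threshold = 1),
                 "undefined")
  expect_true(is.na(pr1[["precision"]]))
  expect_equal(pr1[["recall"]], 0)
})

test_that("SEM is the sample SD over sqrt(n)", {
  expect_equal(compute_sem(c(0.6, 0.7, 0.8)), 0.1 / sqrt(3))
  expect_equal(compute_sem(rep(0.5, 8)), 0)
  expect_equal(compute_sem(c(0.2, 0.6)), 0.2)  # |a - b| / 2
  expect_error(compute_sem(0.5), "at least 2")
})

test_that("split plans partition the cohort with balanced strata", {
  co <- generate_feature_cohort(feature_cohort_config(seed = 71))
  plan <- make_split_plan(co, k = 5, repetitions = 4, seed = 3)
  expect_equal(nrow(dplyr::distinct(plan[c("repetition", "fold")])), 20)
  counts <- table(plan$subject_id)
  expect_true(all(counts == 4))
  prev <- mean(co$label)
  for (r in 1:4) {
    for (f in 1:5) {
      ids <- plan$subject_id[plan$repetition == r & plan$fold == f]
      labs <- co$label[co$subject_id %in% ids]
      # stratification: fold prevalence within one subject of cohort's
      expect_lte(abs(sum(labs) - prev * length(labs)), 1 + 1e-9)
    }
    ids_r <- plan$subject_id[plan$repetition == r]
    expect_setequal(ids_r, co$subject_id)
  }
  expect_identical(
    as.data.frame(make_split_plan(co, seed = 3)),
    as.data.frame(make_split_plan(co, seed = 3)))
  tiny <- co[c(which(co$label == 0)[1:3], which(co$label == 1)[1:8]), ]
  expect_error(make_split_plan(tiny, k = 5, seed = 1), ">= k")
  small <- co[1:10, ]
  p2 <- make_split_plan(small, k = 5, repetitions = 1, stratified = FALSE,
                        seed = 2)
  expect_true(all(table(p2$fold) == 2))
})

test_that("cross-validation reports 20 folds with a recomputable SEM", {
  co <- small_cohort(n = 100, effect = c(0, 0, 0, 2, 0), seed = 72)
  plan <- make_split_plan(co, k = 5, repetitions = 4, seed = 7)
  rep <- run_cross_validation(co, plan, "mlp",
                              quick_mlp(seed = 7, max_epochs = 10))
  expect_equal(nrow(rep$folds), 20)
  expect_equal(sort(unique(rep$folds$fold)), 1:5)
  s <- rep$summary
  expect_equal(s$sem[s$metric == "auc"],
               stats::sd(rep$folds$auc) / sqrt(20))
  expect_true(all(rep$folds$auc >= 0 & rep$folds$auc <= 1))
  g <- glance(rep)
  expect_equal(g$n_folds, 20)
  td <- generics::tidy(rep)
  expect_identical(td, rep$folds)
})

test_that("external evaluation reuses fold models without refitting", {
  co <- small_cohort(n = 90, effect = c(0, 0, 0, 2, 0), seed = 73)
  ext <- small_cohort(n = 60, effect = c(0, 0, 0, 2, 0), seed = 74,
                      prevalence_methylated = 0.75)
  plan <- make_split_plan(co, k = 5, repetitions = 1, seed = 4)
  rep <- run_cross_validation(co, plan, "mlp",
                              quick_mlp(seed = 4, max_epochs = 10),
                              keep_models = TRUE)
  extrep <- evaluate_external(rep, ext)
  expect_equal(nrow(extrep$folds), 5)
  expect_true(all(c("auc", "precision", "recall") %in% names(extrep$folds)))
  rep_nomodels <- run_cross_validation(co, plan, "mlp",
                                       quick_mlp(seed = 4, max_epochs = 5))
  expect_error(evaluate_external(rep_nomodels, ext), "keep_models")
})

test_that("decision curves obey the net-benefit contracts", {
  # worked value: NB(t = 0.25; TP = 30, FP = 10, n = 100) = 0.2667
  probs <- c(rep(0.9, 30), rep(0.8, 10), rep(0.1, 25), rep(0.05, 35))
  labels <- c(rep(1, 30), rep(0, 10), rep(1, 25), rep(0, 35))
  dca <- decision_curve(probs, labels, thresholds = 0.25)
  expect_equal(dca$net_benefit_model, 0.30 - 0.10 * (0.25 / 0.75))
  expect_equal(dca$net_benefit_none, 0)

  # perfect classifier: NB equals prevalence at every threshold
  lab <- rep(c(0, 1), 25)
  d2 <- decision_curve(lab, lab)
  expect_equal(d2$net_benefit_model, rep(0.5, nrow(d2)))
  expect_equal(d2$net_benefit_none, rep(0, nrow(d2)))
  # treat-all tends to prevalence as t -> 0
  expect_equal(d2$net_benefit_all[1], 0.5 - 0.5 * (0.01 / 0.99))

  # model net benefit never exceeds prevalence
  withr::with_seed(9, {
    p <- runif(200); y <- rbinom(200, 1, 0.4)
    d3 <- decision_curve(p, y)
    expect_true(all(d3$net_benefit_model <= mean(y) + 1e-12))
  })
  expect_error(decision_curve(probs, labels, thresholds = c(0, 0.5)),
               "strictly")
})

test_that("fold-level report comparisons produce Wilcoxon p-values", {
  co <- small_cohort(n = 90, effect = c(0, 0, 0, 2, 0), seed = 75)
  plan <- make_split_plan(co, k = 5, repetitions = 1, seed = 5)
  r1 <- run_cross_validation(co, plan, "mlp", quick_mlp(seed = 5,
                                                        max_epochs = 8))
  cmp <- compare_cv_reports(r1, r1, "auc")
  expect_equal(cmp$p_value, 1)
  expect_true(cmp$statistic > 0)
})

test_that("plot builders return ggplot objects", {
  probs <- c(rep(0.9, 30), rep(0.2, 30))
  labels <- rep(c(1, 0), each = 30)
  expect_s3_class(ggplot2::autoplot(decision_curve(probs, labels)), "ggplot")
  co <- small_cohort(n = 80, effect = c(0, 0, 0, 2, 0), seed = 76)
  plan <- make_split_plan(co, k = 4, repetitions = 1, seed = 6)
  rep <- run_cross_validation(co, plan, "fusion",
                              quick_fusion(seed = 6, max_epochs = 6))
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_s3_class(plot_attention_weights(rep), "ggplot")
})
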